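# Independent oracles: deliberately naive re-derivations used to check the
# package implementations.  None of these share code with R/.

# brute-force 3' adapter scan: try every start position, compare the
# overlapping adapter prefix, leftmost acceptable hit wins
oracle_trim <- function(read, adapter, min_overlap = 8,
                        max_mm_rate = 0.1) {
  L <- nchar(read); A <- nchar(adapter)
  for (i in seq_len(L)) {
    ov <- min(L - i + 1L, A)
    if (ov < min_overlap) break
    rseg <- strsplit(substr(read, i, i + ov - 1L), "")[[1]]
    aseg <- strsplit(substr(adapter, 1, ov), "")[[1]]
    if (sum(rseg != aseg) <= floor(max_mm_rate * ov)) {
      return(substr(read, 1, i - 1L))
    }
  }
  read
}

# exhaustive maximum base pairing by recursion over all structures
# (no memoization; only for short sequences)
oracle_max_pairs <- function(seq) {
  v <- strsplit(chartr("U", "T", toupper(seq)), "")[[1]]
  ok <- function(a, b) {
    (a == "A" && b == "T") || (a == "T" && b == "A") ||
      (a == "G" && b == "C") || (a == "C" && b == "G") ||
      (a == "G" && b == "T") || (a == "T" && b == "G")
  }
  rec <- function(i, j) {
    if (j - i < 4L) return(0L)
    best <- rec(i, j - 1L)
    for (k in i:(j - 4L)) {
      if (ok(v[k], v[j])) {
        cand <- 1L + (if (k > i) rec(i, k - 1L) else 0L) + rec(k + 1L, j - 1L)
        if (cand > best) best <- cand
      }
    }
    best
  }
  if (length(v) < 5L) 0L else rec(1L, length(v))
}

# per-position majority tally over a member table, independent of the
# rle-based implementation
oracle_stable_range <- function(members, span, threshold = 0.8) {
  grand <- sum(members$total)
  ok <- logical(span)
  for (p in seq_len(span)) {
    votes <- c(A = 0, C = 0, G = 0, T = 0, N = 0, absent = 0)
    for (r in seq_len(nrow(members))) {
      rel <- p - members$offset[r]
      if (rel >= 1 && rel <= members$length[r]) {
        b <- substr(members$sequence[r], rel, rel)
        votes[b] <- votes[b] + members$total[r]
      } else {
        votes["absent"] <- votes["absent"] + members$total[r]
      }
    }
    m <- names(votes)[which.max(votes)]
    ok[p] <- votes[[m]] / grand >= threshold && m != "absent"
  }
  if (!any(ok)) return(NULL)
  # longest run, leftmost on ties
  best_len <- 0L; best_start <- NA_integer_
  i <- 1L
  while (i <= span) {
    if (ok[i]) {
      j <- i
      while (j < span && ok[j + 1L]) j <- j + 1L
      if (j - i + 1L > best_len) { best_len <- j - i + 1L; best_start <- i }
      i <- j + 1L
    } else i <- i + 1L
  }
  c(start0 = best_start - 1L, end0 = best_start - 1L + best_len)
}

# random cluster generator for the stable-range property tests
random_cluster <- function(span = 40L, n_members = 6L) {
  base <- paste(sample(c("A", "C", "G", "T"), span, TRUE), collapse = "")
  off <- sample(0:(span - 18L), n_members, TRUE)
  len <- pmin(sample(16:24, n_members, TRUE), span - off)
  members <- data.frame(
    sequence = substring(base, off + 1L, off + len),
    offset = off, length = len,
    total = sample(1:20, n_members, TRUE), stringsAsFactors = FALSE)
  structure(list(chrom = "chr1", strand = "+", start = 0L, end = span,
                 assembled_sequence = base, members = members),
            class = "ReadCluster")
}

# plain double-loop mutual information over discrete vectors
oracle_mi <- function(a, b) {
  n <- length(a)
  s <- 0
  for (x in unique(a)) for (y in unique(b)) {
    pxy <- sum(a == x & b == y) / n
    if (pxy > 0) s <- s + pxy * log(pxy / (sum(a == x) / n * sum(b == y) / n))
  }
  s
}

# upper binomial tail by direct summation
oracle_binom_tail <- function(g, n, p) {
  if (g <= 0) return(1)
  sum(vapply(g:n, function(k) choose(n, k) * p^k * (1 - p)^(n - k),
             numeric(1)))
}

rc <- function(s) {
  chartr("ACGT", "TGCA",
         paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

# tiny deterministic FASTA writer for fixtures
write_fasta_lines <- function(seqs, path) {
  writeLines(unlist(lapply(names(seqs), function(id) {
    c(paste0(">", id), seqs[[id]])
  })), path)
  path
}
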
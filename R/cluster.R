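# Novel miRNA discovery, step 1: genomic placement of unannotated reads,
# read clustering, the stable-range statistic, precursor extraction and
# folding, and the compositional + hairpin-structural feature vector.

#' Cluster configuration
#'
#' @param stable_threshold per-position major-symbol probability needed
#'   for a position to be stable (default 0.8); must be in (0.5, 1].
#' @param max_cluster_gap reads whose genomic spans are within this many
#'   nt are merged into one cluster (default 10).
#' @param flank_near,flank_far folding window flanks around the stable
#'   range: the range is modelled once as the 5' arm (near upstream, far
#'   downstream) and once as the 3' arm (far upstream, near downstream);
#'   defaults 10 / 70 nt.
#' @param min_total_reads,min_distinct_sequences candidate filter
#'   thresholds (defaults 10 reads, 3 distinct sequences).
#' @param max_loci reads placed at more than this many exact genomic loci
#'   are discarded as repetitive (default 20).
#' @return a `ClusterConfig` list.
#' @export
cluster_config <- function(stable_threshold = 0.8, max_cluster_gap = 10L,
                           flank_near = 10L, flank_far = 70L,
                           min_total_reads = 10L,
                           min_distinct_sequences = 3L, max_loci = 20L) {
  if (stable_threshold <= 0.5 || stable_threshold > 1) {
    stop("stable_threshold must lie in (0.5, 1]")
  }
  structure(list(stable_threshold = stable_threshold,
                 max_cluster_gap = as.integer(max_cluster_gap),
                 flank_near = as.integer(flank_near),
                 flank_far = as.integer(flank_far),
                 min_total_reads = as.integer(min_total_reads),
                 min_distinct_sequences = as.integer(min_distinct_sequences),
                 max_loci = as.integer(max_loci)),
            class = "ClusterConfig")
}

#' Place unannotated reads on the genome
#'
#' Exact-match placements at all loci on both strands.  Reads with no
#' full-length exact hit are retried with up to `max_soft_clip` 3' bases
#' soft-clipped (smallest clip that matches wins); the recorded span
#' still covers the whole read, so non-templated 3' tails overlap the
#' positions downstream of the matched core -- this is what lets the
#' tail-composition features see non-templated additions.  Reads hitting
#' more than `max_loci` loci are discarded as repetitive.
#'
#' @param ureads a `UniqueReads` data frame (typically the unmapped set
#'   from [cascade_annotate()]).
#' @param genome named character vector of chromosome sequences or a
#'   genome `SequenceLibrary`.
#' @param config a [cluster_config()].
#' @param max_soft_clip maximum 3' soft-clip (default 3).
#' @return data frame of placements: sequence, chrom, strand, start, end
#'   (0-based half-open, genome coordinates, full read span), clip_3p,
#'   total count and per-sample counts, sorted by (chrom, strand, start).
#' @export
map_unmapped_to_genome <- function(ureads, genome,
                                   config = cluster_config(),
                                   max_soft_clip = 3L) {
  if (inherits(genome, "SequenceLibrary")) genome <- genome$seqs
  samples <- sample_ids_of(ureads)
  rows <- list()
  scan <- function(idx, clip) {
    # search reads (minus `clip` 3' bases) on both strands of all chroms
    cores <- substr(ureads$sequence[idx], 1L,
                    nchar(ureads$sequence[idx]) - clip)
    hit_any <- rep(FALSE, length(idx))
    for (chrom in names(genome)) {
      for (strand in c("+", "-")) {
        subject <- if (strand == "+") genome[[chrom]] else
          revcomp(genome[[chrom]])
        clen <- nchar(subject)
        occ <- find_occurrences_cpp(cores, subject)
        for (k in seq_along(idx)) {
          st <- occ[[k]]
          if (!length(st)) next
          hit_any[k] <- TRUE
          i <- idx[k]
          L <- nchar(ureads$sequence[i])
          # full read span in genome (+) coordinates
          gs <- if (strand == "+") st else clen - (st + L)
          ge <- gs + L
          keep <- gs >= 0L & ge <= clen
          if (!any(keep)) next
          rows[[length(rows) + 1L]] <<- data.frame(
            sequence = ureads$sequence[i], chrom = chrom,
            strand = strand, start = as.integer(gs[keep]),
            end = as.integer(ge[keep]), clip_3p = clip,
            total = ureads$total[i], stringsAsFactors = FALSE)
        }
      }
    }
    hit_any
  }
  todo <- seq_len(nrow(ureads))
  for (clip in 0:max_soft_clip) {
    if (!length(todo)) break
    long_enough <- nchar(ureads$sequence[todo]) - clip >= 14L
    todo <- todo[long_enough]
    if (!length(todo)) break
    hit <- scan(todo, clip)
    todo <- todo[!hit]
  }
  if (!length(rows)) {
    return(data.frame(sequence = character(0), chrom = character(0),
                      strand = character(0), start = integer(0),
                      end = integer(0), clip_3p = integer(0),
                      total = integer(0), n_loci = integer(0),
                      stringsAsFactors = FALSE))
  }
  pl <- do.call(rbind, rows)
  nl <- table(pl$sequence)
  pl$n_loci <- as.integer(nl[pl$sequence])
  pl <- pl[pl$n_loci <= config$max_loci, , drop = FALSE]
  pl <- pl[order(pl$chrom, pl$strand, pl$start), , drop = FALSE]
  rownames(pl) <- NULL
  cntcols <- as.data.frame(
    ureads[match(pl$sequence, ureads$sequence), samples, drop = FALSE])
  names(cntcols) <- paste0("count.", samples)
  pl <- cbind(pl, cntcols)
  attr(pl, "sample_ids") <- samples
  pl
}

#' Build read clusters from genomic placements
#'
#' Placements on the same chromosome and strand whose spans lie within
#' `max_cluster_gap` nt of each other are merged transitively into one
#' cluster.  The assembled sequence is the genome slice over the cluster
#' span, reverse-complemented for minus-strand clusters so members are
#' always in transcript orientation.
#'
#' @param placements data frame from [map_unmapped_to_genome()].
#' @param genome genome sequences (named character vector or
#'   `SequenceLibrary`).
#' @param config a [cluster_config()].
#' @return list of `ReadCluster` objects: chrom, strand, start, end
#'   (genome, 0-based half-open), `assembled_sequence` (transcript
#'   orientation), `members` data frame (sequence, offset into the
#'   assembled sequence, length, total count).
#' @export
build_clusters <- function(placements, genome, config = cluster_config()) {
  if (inherits(genome, "SequenceLibrary")) genome <- genome$seqs
  out <- list()
  if (!nrow(placements)) return(out)
  for (grp in split(placements,
                    paste(placements$chrom, placements$strand))) {
    grp <- grp[order(grp$start), , drop = FALSE]
    ir <- IRanges::IRanges(start = grp$start + 1L, end = grp$end)
    red <- IRanges::reduce(ir, min.gapwidth = config$max_cluster_gap + 1L)
    hit <- IRanges::findOverlaps(ir, red,
                                 maxgap = config$max_cluster_gap)
    cl_of <- S4Vectors::subjectHits(hit)[match(seq_along(ir),
                                               S4Vectors::queryHits(hit))]
    for (ci in seq_along(red)) {
      mem <- grp[cl_of == ci, , drop = FALSE]
      cs <- min(mem$start); ce <- max(mem$end)
      chrom <- mem$chrom[1]; strand <- mem$strand[1]
      slice <- substr(genome[[chrom]], cs + 1L, ce)
      if (strand == "-") slice <- revcomp(slice)
      off <- if (strand == "+") mem$start - cs else ce - mem$end
      members <- data.frame(sequence = mem$sequence, offset = off,
                            length = mem$end - mem$start,
                            total = mem$total, stringsAsFactors = FALSE)
      members <- members[order(members$offset, members$sequence), ,
                         drop = FALSE]
      rownames(members) <- NULL
      out[[length(out) + 1L]] <- structure(
        list(chrom = chrom, strand = strand, start = cs, end = ce,
             assembled_sequence = slice, members = members),
        class = "ReadCluster")
    }
  }
  out
}

#' @export
print.ReadCluster <- function(x, ...) {
  cat(sprintf("<ReadCluster %s:%d-%d(%s): %d member(s), %d read(s)>\n",
              x$chrom, x$start, x$end, x$strand, nrow(x$members),
              sum(x$members$total)))
  invisible(x)
}

#' Compute the stable range of a read cluster
#'
#' At each position of the assembled span the covering reads vote with
#' their counts for their base; reads in the cluster that do not cover
#' the position vote for an explicit "absent" symbol, so ragged ends
#' destabilize the flanks.  The major-symbol probability is the largest
#' vote divided by the total cluster read count.  The stable range is the
#' longest contiguous run of positions whose major probability reaches
#' `stable_threshold` with a real base (not "absent") as major symbol;
#' ties go to the leftmost run.  Head/tail unstable lengths count covered
#' positions outside the stable range on each side.
#'
#' @param cluster a `ReadCluster`.
#' @param config a [cluster_config()].
#' @return the cluster with `stable_start`, `stable_end` (0-based
#'   half-open into the assembled sequence), `head_unstable_length`,
#'   `tail_unstable_length` added, or with `rejected =
#'   "no_stable_range"` when no position reaches the threshold.
#' @export
compute_stable_range <- function(cluster, config = cluster_config()) {
  span <- nchar(cluster$assembled_sequence)
  mem <- cluster$members
  totals <- mem$total
  grand <- sum(totals)
  major_ok <- logical(span)
  for (p in seq_len(span) - 1L) {
    votes <- c(A = 0, C = 0, G = 0, T = 0, N = 0, absent = 0)
    covering <- mem$offset <= p & p < mem$offset + mem$length
    if (any(covering)) {
      idx <- which(covering)
      b <- substr(mem$sequence[idx], p - mem$offset[idx] + 1L,
                  p - mem$offset[idx] + 1L)
      for (k in seq_along(idx)) {
        votes[b[k]] <- votes[b[k]] + totals[idx[k]]
      }
    }
    votes["absent"] <- grand - sum(totals[covering])
    best <- names(votes)[which.max(votes)]
    major_ok[p + 1L] <- (votes[[best]] / grand >= config$stable_threshold) &&
      best != "absent"
  }
  if (!any(major_ok)) {
    cluster$rejected <- "no_stable_range"
    return(cluster)
  }
  runs <- rle(major_ok)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  ok <- which(runs$values)
  best <- ok[which.max(runs$lengths[ok])]      # leftmost longest
  s0 <- starts[best] - 1L                      # 0-based
  e0 <- ends[best]                             # half-open
  covered <- range(c(mem$offset, mem$offset + mem$length - 1L))
  cluster$stable_start <- s0
  cluster$stable_end <- e0
  cluster$head_unstable_length <- max(0L, s0 - covered[1])
  cluster$tail_unstable_length <- max(0L, covered[2] + 1L - e0)
  cluster
}

#' Fold a sequence into dot-bracket structure
#'
#' Default engine: base-pair maximization (Watson-Crick + G:T wobble,
#' minimum hairpin loop 3 nt) with a pseudo minimum free energy of
#' -(pairs) - 0.5 x (stacked adjacencies).  A thermodynamic engine can be
#' substituted via `engine`; all structure-derived features are computed
#' from the dot-bracket alone, so either engine feeds them identically.
#'
#' @param sequence DNA (or RNA) string.
#' @param engine function(sequence) returning list(structure, mfe), or
#'   `NULL` for the built-in engine.
#' @return list with `structure` (dot-bracket), `mfe`, `n_pairs`.
#' @export
fold <- function(sequence, engine = NULL) {
  if (!is.null(engine)) {
    res <- engine(sequence)
    stopifnot(nchar(res$structure) == nchar(sequence))
    return(res)
  }
  fold_cpp(toupper(sequence))
}

# pair table from dot-bracket: mate index (1-based) or NA
pair_table <- function(structure) {
  v <- strsplit(structure, "", fixed = TRUE)[[1]]
  mate <- rep(NA_integer_, length(v))
  st <- integer(0)
  for (i in seq_along(v)) {
    if (v[i] == "(") st <- c(st, i)
    else if (v[i] == ")") {
      if (!length(st)) stop("unbalanced dot-bracket structure")
      j <- st[length(st)]
      st <- st[-length(st)]
      mate[i] <- j; mate[j] <- i
    }
  }
  if (length(st)) stop("unbalanced dot-bracket structure")
  mate
}

#' Structural statistics of a folded precursor
#'
#' Decomposes a dot-bracket string into hairpin loops (maximal unpaired
#' run directly enclosed by a pair with no pairs inside), interior
#' loops/bulges (unpaired run(s) between two pair blocks on a single
#' branch) and stems, and relates them to the stable range.
#'
#' @param structure dot-bracket string.
#' @param range_start,range_end stable range within the folded window,
#'   0-based half-open.
#' @return list: `hairpin_count`, `stem_length` (pairs on the longest
#'   root-to-hairpin helix path), `interiorLoopCount`, `binding_count`
#'   (total pairs), `count_bindings_in_miRNA` (pairs with at least one
#'   end inside the stable range), `percentage_PairedInMiRNA`,
#'   `distanceToloop` (nt between the stable-range end nearest the main
#'   terminal loop and that loop's boundary; 0 if overlapping),
#'   `armType` ("5p", "3p" or "loop").
#' @export
structure_stats <- function(structure, range_start, range_end) {
  mate <- pair_table(structure)
  n <- length(mate)
  paired <- !is.na(mate)
  binding_count <- sum(paired) / 2L

  # hairpin loops
  hairpins <- list()                    # list of c(from, to) 1-based unpaired run
  for (i in seq_len(n)) {
    j <- mate[i]
    if (!is.na(j) && j > i + 1L) {
      inner <- seq.int(i + 1L, j - 1L)
      if (all(is.na(mate[inner]))) {
        hairpins[[length(hairpins) + 1L]] <- c(inner[1], inner[length(inner)])
      }
    }
  }
  hairpin_count <- length(hairpins)

  # stems: follow each helix path; count pairs per root-to-hairpin path,
  # and interior loops (single-branch unpaired gaps between pair blocks)
  interior <- 0L
  stem_best <- 0L
  enclosed_children <- function(i, j) {
    kids <- list()
    k <- i + 1L
    while (k < j) {
      if (!is.na(mate[k]) && mate[k] > k) {
        kids[[length(kids) + 1L]] <- c(k, mate[k])
        k <- mate[k] + 1L
      } else k <- k + 1L
    }
    kids
  }
  walk <- function(i, j, acc) {
    # (i, j) is a base pair; acc = pairs so far on this path including it
    kids <- enclosed_children(i, j)
    if (length(kids) == 0L) {                   # hairpin loop below
      stem_best <<- max(stem_best, acc)
      return(invisible())
    }
    if (length(kids) == 1L) {
      k <- kids[[1]]
      if (k[1] > i + 1L || k[2] < j - 1L) interior <<- interior + 1L
      walk(k[1], k[2], acc + 1L)
    } else {
      for (k in kids) walk(k[1], k[2], acc + 1L)  # multiloop: paths split
    }
  }
  roots <- enclosed_children(0L, n + 1L)
  for (r in roots) walk(r[1], r[2], 1L)

  rs <- range_start + 1L; re <- range_end       # 1-based inclusive range
  in_range <- function(p) p >= rs & p <= re
  cbm <- 0L
  for (i in seq_len(n)) {
    j <- mate[i]
    if (!is.na(j) && j > i && (in_range(i) || in_range(j))) cbm <- cbm + 1L
  }
  range_len <- max(1L, range_end - range_start)
  pct <- cbm / range_len

  # main terminal loop: the hairpin under the longest-stem path; fall back
  # to the first hairpin
  main_hp <- NULL
  if (hairpin_count > 0L) {
    depth_of <- function(hp) {
      # pairs enclosing the hairpin
      sum(vapply(seq_len(n), function(i) {
        j <- mate[i]
        !is.na(j) && j > i && i < hp[1] && j > hp[2]
      }, logical(1)))
    }
    depths <- vapply(hairpins, depth_of, numeric(1))
    main_hp <- hairpins[[which.max(depths)]]
  }
  if (is.null(main_hp)) {
    dist <- NA_integer_
    arm <- if (re < ceiling(n / 2)) "5p" else "3p"
  } else if (rs <= main_hp[2] && re >= main_hp[1]) {
    dist <- 0L
    # overlap: loop arm only when the range center sits inside the loop
    center <- (rs + re) / 2
    arm <- if (center >= main_hp[1] && center <= main_hp[2]) "loop"
      else if (center < main_hp[1]) "5p" else "3p"
    if (rs >= main_hp[1] && re <= main_hp[2]) arm <- "loop"
  } else if (re < main_hp[1]) {
    dist <- main_hp[1] - re - 1L                # gap nt between range and loop
    arm <- "5p"
  } else {
    dist <- rs - main_hp[2] - 1L
    arm <- "3p"
  }

  list(hairpin_count = hairpin_count, stem_length = stem_best,
       interiorLoopCount = interior, binding_count = binding_count,
       count_bindings_in_miRNA = cbm, percentage_PairedInMiRNA = pct,
       distanceToloop = dist, armType = arm)
}

#' Extract and fold the best precursor candidate for a cluster
#'
#' The stable range is modelled once as the 5' arm (flank_near upstream,
#' flank_far downstream) and once as the 3' arm (flank_far upstream,
#' flank_near downstream); both windows are folded and the lower
#' pseudo-MFE wins (ties prefer the 5p model).  `pair_state` is `TRUE`
#' when another read subgroup of the cluster maps on the partner arm
#' (beyond the terminal loop relative to the stable range).
#'
#' @param cluster a `ReadCluster` with a computed stable range.
#' @param genome genome sequences.
#' @param config a [cluster_config()].
#' @param engine optional folding engine passed to [fold()].
#' @return the cluster with `precursor` (list: sequence, structure, mfe,
#'   window_start/window_end in genome coordinates of the transcript
#'   window, range_in_window, stats from [structure_stats()], pair_state)
#'   attached.
#' @export
extract_precursor <- function(cluster, genome, config = cluster_config(),
                              engine = NULL) {
  if (inherits(genome, "SequenceLibrary")) genome <- genome$seqs
  if (!is.null(cluster$rejected)) return(cluster)
  chrom_seq <- genome[[cluster$chrom]]
  clen <- nchar(chrom_seq)
  span <- nchar(cluster$assembled_sequence)
  range_len <- cluster$stable_end - cluster$stable_start
  # window in transcript coordinates, clipped at chromosome bounds
  tx_window <- function(up, down) {
    s0 <- cluster$stable_start - up
    e0 <- cluster$stable_end + down
    if (cluster$strand == "+") {
      gs <- cluster$start + s0; ge <- cluster$start + e0
    } else {
      gs <- cluster$end - e0; ge <- cluster$end - s0
    }
    clip_low <- max(0L, -gs); clip_high <- max(0L, ge - clen)
    if (clip_low > 0L || clip_high > 0L) {
      warning("precursor window truncated at chromosome bounds")
    }
    tgs <- gs + clip_low; tge <- ge - clip_high
    seqw <- substr(chrom_seq, tgs + 1L, tge)
    if (cluster$strand == "-") seqw <- revcomp(seqw)
    up_clip <- if (cluster$strand == "+") clip_low else clip_high
    range0 <- up - up_clip
    list(sequence = seqw, range0 = range0, range1 = range0 + range_len,
         gstart = tgs, gend = tge)
  }
  w5 <- tx_window(config$flank_near, config$flank_far)
  w3 <- tx_window(config$flank_far, config$flank_near)
  f5 <- fold(w5$sequence, engine)
  f3 <- fold(w3$sequence, engine)
  use5 <- f5$mfe <= f3$mfe                     # tie -> 5p model
  w <- if (use5) w5 else w3
  f <- if (use5) f5 else f3
  stats <- structure_stats(f$structure, w$range0, w$range1)

  # pair_state: any member subgroup on the opposite side of the terminal
  # loop from the stable range, within the winning window
  pair_state <- FALSE
  if (stats$armType %in% c("5p", "3p")) {
    win_off <- cluster$stable_start - w$range0   # window start in transcript
    mem0 <- cluster$members$offset - win_off     # member offsets in window
    mem1 <- mem0 + cluster$members$length
    mate <- tryCatch(pair_table(f$structure), error = function(e) NULL)
    if (!is.null(mate)) {
      if (stats$armType == "5p") {
        boundary <- w$range1
        pair_state <- any(mem0 >= boundary + 3L &
                            mem1 <= nchar(w$sequence))
      } else {
        boundary <- w$range0
        pair_state <- any(mem1 <= boundary - 3L & mem0 >= 0L)
      }
    }
  }
  cluster$precursor <- list(sequence = w$sequence,
                            structure = f$structure, mfe = f$mfe,
                            gstart = w$gstart, gend = w$gend,
                            range_in_window = c(w$range0, w$range1),
                            stats = stats, pair_state = pair_state)
  cluster
}

#' Compositional features of a read cluster
#'
#' Count-weighted flank composition around the stable range: for each
#' flank position (-3..-1 of the 5' end, +1..+6 of the 3' end), the
#' fraction of covering reads whose base equals the genomic base
#' (`*_TemplateNucleotide_percentage`), the A/T/C/G fractions among
#' covering reads, and for +1..+3 the fraction of covering reads with a
#' non-templated adenine (`tail_plus{n}_A_percentage`; 0 by definition
#' when the genomic base itself is A).  Positions covered by no read
#' yield 0 with a companion `covered_*` indicator of 0.  Also computes
#' `exactMatchRatio` (reads identical to the stable-range sequence /
#' total reads), `sequence_type_count`, `total_read_count` and the
#' unstable lengths.
#'
#' @param cluster a `ReadCluster` with a computed stable range.
#' @param genome genome sequences.
#' @return named list of features.
#' @export
compositional_features <- function(cluster, genome) {
  if (inherits(genome, "SequenceLibrary")) genome <- genome$seqs
  mem <- cluster$members
  grand <- sum(mem$total)
  span <- nchar(cluster$assembled_sequence)
  chrom_seq <- genome[[cluster$chrom]]
  clen <- nchar(chrom_seq)

  # genomic base at transcript position p (0-based, may exceed cluster span)
  tx_base <- function(p) {
    g <- if (cluster$strand == "+") cluster$start + p else
      cluster$end - 1L - p
    if (g < 0L || g >= clen) return(NA_character_)
    b <- substr(chrom_seq, g + 1L, g + 1L)
    if (cluster$strand == "-") b <- chartr("ACGT", "TGCA", b)
    b
  }
  read_base_at <- function(p) {
    covering <- mem$offset <= p & p < mem$offset + mem$length
    idx <- which(covering)
    if (!length(idx)) return(NULL)
    list(base = substr(mem$sequence[idx], p - mem$offset[idx] + 1L,
                       p - mem$offset[idx] + 1L),
         w = mem$total[idx])
  }

  out <- list()
  flanks <- c(head_minus3 = -3L, head_minus2 = -2L, head_minus1 = -1L,
              tail_plus1 = 1L, tail_plus2 = 2L, tail_plus3 = 3L,
              tail_plus4 = 4L, tail_plus5 = 5L, tail_plus6 = 6L)
  for (nm in names(flanks)) {
    k <- flanks[[nm]]
    p <- if (k < 0L) cluster$stable_start + k else
      cluster$stable_end + k - 1L
    gb <- tx_base(p)
    rb <- read_base_at(p)
    covered <- !is.null(rb) && !is.na(gb)
    if (covered) {
      wsum <- sum(rb$w)
      tmpl <- sum(rb$w[rb$base == gb]) / wsum
      comp <- vapply(DNA_BASES, function(b) sum(rb$w[rb$base == b]) / wsum,
                     numeric(1))
    } else {
      tmpl <- 0
      comp <- stats::setNames(numeric(4), DNA_BASES)
    }
    out[[paste0(nm, "_TemplateNucleotide_percentage")]] <- tmpl
    for (b in DNA_BASES) {
      out[[paste0(nm, "_", b, "_percentage")]] <- comp[[b]]
    }
    if (nm %in% c("tail_plus1", "tail_plus2", "tail_plus3")) {
      nta <- if (covered && !identical(gb, "A")) comp[["A"]] else 0
      out[[paste0(nm, "_A_percentage")]] <- nta
    }
    out[[paste0("covered_", nm)]] <- as.numeric(covered)
  }

  stable_seq <- substr(cluster$assembled_sequence,
                       cluster$stable_start + 1L, cluster$stable_end)
  out$exactMatchRatio <- sum(mem$total[mem$sequence == stable_seq]) / grand
  out$sequence_type_count <- length(unique(mem$sequence))
  out$total_read_count <- grand
  out$headUnstableLength <- cluster$head_unstable_length
  out$tailUnstableLength <- cluster$tail_unstable_length
  out
}

#' Full feature vector for one cluster
#'
#' Combines [compositional_features()] with the structural statistics and
#' pseudo-MFE of [extract_precursor()], plus the one-hot `pair_state_No`
#' / `pair_state_Yes` and `armType_5p` / `armType_3p` / `armType_loop`
#' indicators.
#'
#' @param cluster a `ReadCluster` after [compute_stable_range()] and
#'   [extract_precursor()].
#' @param genome genome sequences.
#' @return named numeric vector, or `NULL` for rejected clusters.
#' @export
cluster_features <- function(cluster, genome) {
  if (!is.null(cluster$rejected)) return(NULL)
  comp <- compositional_features(cluster, genome)
  st <- cluster$precursor$stats
  feats <- c(
    count_bindings_in_miRNA = st$count_bindings_in_miRNA,
    exactMatchRatio = comp$exactMatchRatio,
    pair_state_No = as.numeric(!cluster$precursor$pair_state),
    pair_state_Yes = as.numeric(cluster$precursor$pair_state),
    mFE = cluster$precursor$mfe,
    hairpin_count = st$hairpin_count,
    stem_length = st$stem_length,
    distanceToloop = if (is.na(st$distanceToloop)) 0 else st$distanceToloop,
    percentage_PairedInMiRNA = st$percentage_PairedInMiRNA,
    binding_count = st$binding_count,
    interiorLoopCount = st$interiorLoopCount,
    armType_5p = as.numeric(st$armType == "5p"),
    armType_3p = as.numeric(st$armType == "3p"),
    armType_loop = as.numeric(st$armType == "loop"))
  comp_v <- unlist(comp[setdiff(names(comp), "exactMatchRatio")])
  c(feats, comp_v)
}

#' Candidate cluster filter
#'
#' A cluster survives with at least `min_total_reads` reads and
#' `min_distinct_sequences` distinct member sequences (boundaries
#' inclusive).
#'
#' @param clusters list of `ReadCluster`s.
#' @param config a [cluster_config()].
#' @return list with `pass` (surviving clusters) and `rejected` (data
#'   frame of cluster index + reason).
#' @export
candidate_filter <- function(clusters, config = cluster_config()) {
  pass <- list()
  rej <- list()
  for (i in seq_along(clusters)) {
    cl <- clusters[[i]]
    reads <- sum(cl$members$total)
    nseq <- length(unique(cl$members$sequence))
    reason <- character(0)
    if (!is.null(cl$rejected)) reason <- cl$rejected
    if (reads < config$min_total_reads) reason <- c(reason, "min_reads")
    if (nseq < config$min_distinct_sequences) {
      reason <- c(reason, "min_sequences")
    }
    if (length(reason)) {
      rej[[length(rej) + 1L]] <- data.frame(
        index = i, reason = paste(reason, collapse = ","),
        stringsAsFactors = FALSE)
    } else {
      pass[[length(pass) + 1L]] <- cl
    }
  }
  list(pass = pass,
       rejected = if (length(rej)) do.call(rbind, rej) else
         data.frame(index = integer(0), reason = character(0)))
}

#' Run the full discovery feature pipeline
#'
#' unmapped reads -> genomic placements -> clusters -> stable ranges ->
#' precursors -> feature vectors.
#'
#' @param ureads unmapped `UniqueReads`.
#' @param genome genome sequences.
#' @param config a [cluster_config()].
#' @param filter apply [candidate_filter()] (default `TRUE`).
#' @param engine optional folding engine.
#' @return list with `clusters` (annotated `ReadCluster`s) and `features`
#'   (matrix, one row per surviving cluster).
#' @export
discover_clusters <- function(ureads, genome, config = cluster_config(),
                              filter = TRUE, engine = NULL) {
  pl <- map_unmapped_to_genome(ureads, genome, config)
  cls <- build_clusters(pl, genome, config)
  cls <- lapply(cls, compute_stable_range, config = config)
  if (filter) {
    cls <- candidate_filter(cls, config)$pass
  } else {
    cls <- Filter(function(cl) is.null(cl$rejected), cls)
  }
  cls <- lapply(cls, extract_precursor, genome = genome, config = config,
                engine = engine)
  feats <- lapply(cls, cluster_features, genome = genome)
  keep <- !vapply(feats, is.null, logical(1))
  mat <- if (any(keep)) do.call(rbind, feats[keep]) else NULL
  list(clusters = cls[keep], features = mat)
}
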
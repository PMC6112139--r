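# A-to-I editing detection: per-position A>G tallies on mature miRNAs,
# four exclusion criteria, and a binomial significance test against the
# sequencing error rate.
#
# The significance test is a declared stand-in: a one-sided binomial test
# of the G count against a configurable sequencing-error rate with
# Benjamini-Hochberg correction across tested site/sample pairs.

EXCLUSION_CRITERIA <- c("family_or_snp", "repeat_element",
                        "low_canonical_rpm", "multimapping")

#' Editing blacklists
#'
#' @param family_snp_sites data frame (mirna_id, position): positions
#'   where miRNA-family or SNP A/G differences mimic editing.
#' @param repeat_mirnas character vector of miRNAs located in repeat
#'   elements.
#' @return an `EditingBlacklists` list.
#' @export
editing_blacklists <- function(family_snp_sites =
                                 data.frame(mirna_id = character(0),
                                            position = integer(0)),
                               repeat_mirnas = character(0)) {
  structure(list(family_snp_sites = family_snp_sites,
                 repeat_mirnas = repeat_mirnas),
            class = "EditingBlacklists")
}

#' Tally candidate A-to-I sites from miRNA assignments
#'
#' For every A position of every mature miRNA with read coverage, counts
#' reads carrying A (reference), G (candidate edit) or another base at
#' that position.  Only the aligned core is used: soft-clipped 3' tails
#' never contribute, and coverage respects each read's 5' offset and 3'
#' extent.
#'
#' @param annotation result of [cascade_annotate()].
#' @param ureads the annotated `UniqueReads`.
#' @param mature_lib mature miRNA `SequenceLibrary`.
#' @param hairpin_lib optional hairpin `SequenceLibrary`; when given,
#'   reads assigned to a precursor by exact substring match also
#'   contribute coverage at the mature positions they overlap (they
#'   correspond to the miRNA and carry the reference base there, so
#'   omitting them would bias editing fractions upward).
#' @return data frame of `EditingSite` rows: mirna_id, position (1-based
#'   on the mature sequence), a_count, g_count, other_count, coverage,
#'   editing_fraction (pooled), per-sample `g.<s>` / `cov.<s>` columns.
#' @export
tally_sites <- function(annotation, ureads, mature_lib,
                        hairpin_lib = NULL) {
  samples <- sample_ids_of(ureads)
  a <- annotation$assignments
  hp <- a[a$library_kind == "hairpin", , drop = FALSE]
  a <- a[a$library_kind == "mature_miRNA", , drop = FALSE]
  if (!is.null(hairpin_lib) && nrow(hp)) {
    # translate precursor-mapped reads into mature-coordinate rows
    extra <- lapply(seq_len(nrow(hp)), function(i) {
      hpid <- hp$target_id[i]
      hpseq <- hairpin_lib$seqs[[hpid]]
      if (is.null(hpseq)) return(NULL)
      rows <- list()
      for (mid in names(mature_lib$seqs)) {
        m <- regexpr(mature_lib$seqs[[mid]], hpseq, fixed = TRUE)
        if (m < 1L) next
        r <- hp[i, , drop = FALSE]
        r$target_id <- mid
        r$offset_5p <- hp$ref_pos[i] - (as.integer(m) - 1L)
        rows[[length(rows) + 1L]] <- r
      }
      if (length(rows)) do.call(rbind, rows) else NULL
    })
    extra <- Filter(Negate(is.null), extra)
    if (length(extra)) a <- rbind(a, do.call(rbind, extra))
  }
  acc <- new.env(parent = emptyenv())

  for (i in seq_len(nrow(a))) {
    mid <- a$target_id[i]
    mseq <- mature_lib$seqs[[mid]]
    if (is.null(mseq)) next
    cnt <- as.integer(ureads[match(a$sequence[i], ureads$sequence),
                             samples])
    tot <- sum(cnt)
    L <- nchar(a$sequence[i])
    d <- a$offset_5p[i]
    clip <- a$clip_3p[i]
    lead <- max(0L, -d)
    core_from <- lead + 1L                      # read coords, 1-based
    core_to <- L - clip
    if (core_to < core_from) next
    # mature positions covered: d + t for read t (0-based) -> 1-based
    mpos <- d + (core_from:core_to)             # 1-based mature positions
    keep <- mpos >= 1L & mpos <= nchar(mseq)
    rpos <- (core_from:core_to)[keep]
    mpos <- mpos[keep]
    mbase <- substring(mseq, mpos, mpos)
    at_a <- which(mbase == "A")
    for (k in at_a) {
      key <- sprintf("%s\r%d", mid, mpos[k])
      rb <- substr(a$sequence[i], rpos[k], rpos[k])
      e <- get0(key, envir = acc)
      if (is.null(e)) {
        z <- stats::setNames(integer(length(samples)), samples)
        e <- list(a = 0L, g = 0L, o = 0L, cov = 0L,
                  g_s = z, o_s = z, cov_s = z)
      }
      e$cov <- e$cov + tot
      e$cov_s <- e$cov_s + cnt
      if (rb == "A") e$a <- e$a + tot
      else if (rb == "G") { e$g <- e$g + tot; e$g_s <- e$g_s + cnt }
      else { e$o <- e$o + tot; e$o_s <- e$o_s + cnt }
      assign(key, e, envir = acc)
    }
  }

  keys <- sort(ls(acc))
  rows <- lapply(keys, function(key) {
    e <- get(key, envir = acc)
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    row <- data.frame(mirna_id = parts[1],
                      position = as.integer(parts[2]),
                      a_count = e$a, g_count = e$g, other_count = e$o,
                      coverage = e$cov,
                      editing_fraction =
                        if (e$a + e$g > 0) e$g / (e$a + e$g) else 0,
                      stringsAsFactors = FALSE)
    for (s in samples) {
      row[[paste0("g.", s)]] <- e$g_s[[s]]
      row[[paste0("other.", s)]] <- e$o_s[[s]]
      row[[paste0("cov.", s)]] <- e$cov_s[[s]]
    }
    row
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(mirna_id = character(0), position = integer(0),
               a_count = integer(0), g_count = integer(0),
               other_count = integer(0), coverage = integer(0),
               editing_fraction = numeric(0))
  out <- out[order(out$mirna_id, out$position), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "sample_ids") <- samples
  out
}

#' Apply the four exclusion criteria to candidate editing sites
#'
#' 1. `family_or_snp`: the (miRNA, position) is blacklisted because a
#'    related family member or a known SNP differs by A/G there.
#' 2. `repeat_element`: the miRNA lies in a repeat element.
#' 3. `low_canonical_rpm`: the canonical sequence's RPM is below
#'    `min_canonical_rpm` (default 1) in every sample.
#' 4. `multimapping`: the A-to-G switched mature sequence, with its last
#'    two 3' nucleotides trimmed, matches more than one genomic locus
#'    exactly (both strands).
#'
#' The criteria are independent; applying them in any order yields the
#' same `excluded_by` sets.
#'
#' @param sites data frame from [tally_sites()].
#' @param blacklists an [editing_blacklists()].
#' @param rows a `MiRNACounts` data frame with RPM columns (see
#'   [compute_rpm()]); canonical RPM is approximated by
#'   rpm x canonical_ratio per sample.
#' @param genome named character vector of chromosome sequences, or a
#'   genome `SequenceLibrary`; `NULL` skips criterion 4 with an error if
#'   requested.
#' @param mature_lib mature miRNA `SequenceLibrary`.
#' @param min_canonical_rpm criterion-3 cutoff (default 1).
#' @return `sites` with an `excluded_by` character column
#'   (comma-separated criteria, "" if clean).
#' @export
apply_exclusions <- function(sites, blacklists, rows, genome, mature_lib,
                             min_canonical_rpm = 1) {
  if (inherits(genome, "SequenceLibrary")) genome <- genome$seqs
  if (is.null(genome)) {
    stop("criterion 4 (multimapping) requires a genome")
  }
  if (nrow(sites) == 0L) {
    sites$excluded_by <- character(0)
    return(sites)
  }
  samples <- attr(rows, "sample_ids") %||%
    sub("^total\\.", "", grep("^total\\.", names(rows), value = TRUE))
  rpm_cols <- paste0("rpm.", samples)
  if (!all(rpm_cols %in% names(rows))) {
    stop("apply_exclusions needs RPM columns; run compute_rpm() first")
  }
  subject <- paste(c(genome, revcomp(genome)), collapse =
                     paste(rep("X", 50), collapse = ""))

  excl <- character(nrow(sites))
  for (i in seq_len(nrow(sites))) {
    mid <- sites$mirna_id[i]
    pos <- sites$position[i]
    hits <- character(0)
    if (any(blacklists$family_snp_sites$mirna_id == mid &
            blacklists$family_snp_sites$position == pos)) {
      hits <- c(hits, "family_or_snp")
    }
    if (mid %in% blacklists$repeat_mirnas) {
      hits <- c(hits, "repeat_element")
    }
    r <- which(rows$mirna_id == mid)
    if (length(r) == 1L) {
      can_rpm <- as.numeric(rows[r, rpm_cols]) * rows$canonical_ratio[r]
      if (all(can_rpm < min_canonical_rpm)) {
        hits <- c(hits, "low_canonical_rpm")
      }
    }
    mseq <- mature_lib$seqs[[mid]]
    if (!is.null(mseq) && pos <= nchar(mseq)) {
      sw <- mseq
      substr(sw, pos, pos) <- "G"
      probe <- substr(sw, 1L, nchar(sw) - 2L)
      nhit <- length(find_occurrences_cpp(probe, subject)[[1]])
      if (nhit > 1L) hits <- c(hits, "multimapping")
    }
    excl[i] <- paste(hits, collapse = ",")
  }
  sites$excluded_by <- excl
  sites
}

#' Binomial significance test for editing sites
#'
#' Non-excluded sites are tested per sample with a one-sided binomial test
#' of the G count out of the A+G coverage against `error_rate`;
#' Benjamini-Hochberg correction runs across all tested site/sample
#' pairs.  A site is significant when, in at least one sample, the
#' adjusted p-value is at most `alpha` and the per-sample editing
#' fraction is at least `min_fraction`.
#'
#' @param sites data frame from [apply_exclusions()].
#' @param error_rate assumed per-base sequencing error rate
#'   (default 0.001).
#' @param alpha adjusted-p cutoff (default 0.05).
#' @param min_fraction minimum editing fraction (default 0.01).
#' @return `sites` with `p_value` (minimum across samples),
#'   `p_adjusted`, and `significant` columns.
#' @export
test_significance <- function(sites, error_rate = 0.001, alpha = 0.05,
                              min_fraction = 0.01) {
  samples <- attr(sites, "sample_ids") %||%
    sub("^g\\.", "", grep("^g\\.", names(sites), value = TRUE))
  n <- nrow(sites)
  sites$p_value <- rep(NA_real_, n)
  sites$p_adjusted <- rep(NA_real_, n)
  sites$significant <- rep(FALSE, n)
  if (n == 0L) return(sites)
  testable <- !nzchar(sites$excluded_by %||% character(n))

  pmat <- matrix(NA_real_, n, length(samples))
  fmat <- matrix(NA_real_, n, length(samples))
  for (j in seq_along(samples)) {
    g <- sites[[paste0("g.", samples[j])]]
    cov <- sites[[paste0("cov.", samples[j])]]
    oth <- sites[[paste0("other.", samples[j])]] %||% rep(0L, n)
    ag <- cov - oth
    ok <- testable & ag > 0
    pmat[ok, j] <- stats::pbinom(g[ok] - 1L, ag[ok], error_rate,
                                 lower.tail = FALSE)
    fmat[ok, j] <- ifelse(ag[ok] > 0, g[ok] / ag[ok], 0)
  }
  adj <- matrix(stats::p.adjust(as.vector(pmat), method = "BH"),
                n, length(samples))
  hit <- adj <= alpha & fmat >= min_fraction
  hit[is.na(hit)] <- FALSE
  sites$p_value <- suppressWarnings(apply(pmat, 1, min, na.rm = TRUE))
  sites$p_value[!is.finite(sites$p_value)] <- NA_real_
  sites$p_adjusted <- suppressWarnings(apply(adj, 1, min, na.rm = TRUE))
  sites$p_adjusted[!is.finite(sites$p_adjusted)] <- NA_real_
  sites$significant <- rowSums(hit) > 0
  sites$significant[!testable] <- FALSE
  sites
}

#' Write the editing site report
#'
#' @param sites the fully annotated site table.
#' @param path output TSV path.
#' @export
write_editing_report <- function(sites, path) {
  utils::write.table(sites, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
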
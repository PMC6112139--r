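# Cascade annotation of unique reads against the RNA libraries, with an
# isomiR-tolerant mature-miRNA pass run last, canonical-ratio filtering and
# count / RPM tables.

# Library kinds in cascade order.  The tolerant miRNA pass runs after every
# exact pass so that isomiR matching cannot steal reads that belong to
# other RNA classes.
CASCADE_ORDER <- c("spike_in", "mature_miRNA", "hairpin", "tRNA_mature",
                   "tRNA_precursor", "snoRNA", "rRNA", "ncRNA", "mRNA")

#' Annotation configuration
#'
#' @param max_mismatch maximum internal mismatches in the tolerant miRNA
#'   pass (default 1).
#' @param max_clip3p maximum soft-clipped (non-templated) 3' bases
#'   (default 3).
#' @param max_offset5p maximum absolute 5' offset from the canonical start
#'   (default 2).
#' @param min_core minimum aligned core length for an isomiR call.
#' @return an `AnnotateConfig` list.
#' @export
annotate_config <- function(max_mismatch = 1L, max_clip3p = 3L,
                            max_offset5p = 2L, min_core = 14L) {
  structure(list(max_mismatch = as.integer(max_mismatch),
                 max_clip3p = as.integer(max_clip3p),
                 max_offset5p = as.integer(max_offset5p),
                 min_core = as.integer(min_core)),
            class = "AnnotateConfig")
}

#' Cascade-annotate unique reads against the RNA libraries
#'
#' Each read is assigned at most once.  Pass order: optional spike-in,
#' mature miRNA (exact, full-length), then exact substring matching to
#' hairpin, mature tRNA, precursor tRNA, snoRNA, rRNA, other ncRNA and
#' mRNA, and finally the isomiR-tolerant mature miRNA pass (at most
#' `max_mismatch` internal mismatches, `max_clip3p` non-templated 3'
#' bases, 5' offset within `max_offset5p`).  Reads surviving every pass
#' form the unmapped set fed to novel miRNA discovery.  Counts of SNP
#' variant entries and merged-group members are attributed to their parent
#' or representative id.
#'
#' @param ureads a `UniqueReads` data frame from [collapse_reads()].
#' @param libraries named list of `SequenceLibrary` objects; names must be
#'   library kinds.  `mature_miRNA` is mandatory.
#' @param config an [annotate_config()].
#' @return list with `assignments` (data frame: sequence, library_kind,
#'   target_id, pass_type, offset_5p, clip_3p, n_mismatch, mm_pos,
#'   mm_read, mm_ref, ambiguous), and `unmapped` (the unassigned subset of
#'   `ureads`).
#' @export
cascade_annotate <- function(ureads, libraries, config = annotate_config()) {
  kinds <- vapply(libraries, function(l) l$kind, character(1))
  names(libraries) <- kinds
  if (!"mature_miRNA" %in% kinds) {
    stop("a mature_miRNA library is required")
  }
  seqs <- ureads$sequence
  assigned <- rep(FALSE, length(seqs))
  rows <- list()

  mature <- libraries[["mature_miRNA"]]

  for (kind in CASCADE_ORDER) {
    if (!kind %in% kinds) next
    lib <- libraries[[kind]]
    if (length(lib$seqs) == 0L) next
    todo <- which(!assigned)
    if (!length(todo)) break
    if (kind %in% c("spike_in", "mature_miRNA")) {
      # exact full-length equality
      hit <- match(seqs[todo], lib$seqs)
      got <- which(!is.na(hit))
      if (length(got)) {
        idx <- todo[got]
        ids <- names(lib$seqs)[hit[got]]
        rows[[length(rows) + 1L]] <- data.frame(
          sequence = seqs[idx], library_kind = kind,
          target_id = unname(lib$parent[ids]), pass_type = "exact",
          offset_5p = 0L, clip_3p = 0L, n_mismatch = 0L,
          mm_pos = NA_integer_, mm_read = NA_character_,
          mm_ref = NA_character_, ambiguous = FALSE,
          ref_pos = 0L, stringsAsFactors = FALSE)
        assigned[idx] <- TRUE
      }
    } else {
      # exact substring containment in (long) reference entries
      ord <- order(names(lib$seqs))
      res <- substring_assign_cpp(seqs[todo], unname(lib$seqs[ord]))
      got <- which(res$ref > 0L)
      if (length(got)) {
        idx <- todo[got]
        ids <- names(lib$seqs)[ord][res$ref[got]]
        rows[[length(rows) + 1L]] <- data.frame(
          sequence = seqs[idx], library_kind = kind,
          target_id = unname(lib$parent[ids]), pass_type = "exact",
          offset_5p = 0L, clip_3p = 0L, n_mismatch = 0L,
          mm_pos = NA_integer_, mm_read = NA_character_,
          mm_ref = NA_character_, ambiguous = FALSE,
          ref_pos = res$pos[got], stringsAsFactors = FALSE)
        assigned[idx] <- TRUE
      }
    }
  }

  # tolerant isomiR pass against mature miRNAs, last
  todo <- which(!assigned)
  if (length(todo)) {
    ord <- order(names(mature$seqs))
    m <- isomir_match_cpp(seqs[todo], unname(mature$seqs[ord]),
                          config$max_mismatch, config$max_clip3p,
                          config$max_offset5p, config$min_core)
    got <- which(m$ref > 0L)
    if (length(got)) {
      idx <- todo[got]
      ids <- names(mature$seqs)[ord][m$ref[got]]
      rows[[length(rows) + 1L]] <- data.frame(
        sequence = seqs[idx], library_kind = "mature_miRNA",
        target_id = unname(mature$parent[ids]), pass_type = "isomir",
        offset_5p = m$offset[got], clip_3p = m$clip[got],
        n_mismatch = m$n_mismatch[got], mm_pos = m$mm_pos[got],
        mm_read = as.character(m$mm_read[got]),
        mm_ref = as.character(m$mm_ref[got]),
        ambiguous = m$ambiguous[got],
        ref_pos = NA_integer_, stringsAsFactors = FALSE)
      assigned[idx] <- TRUE
    }
  }

  assignments <- if (length(rows)) do.call(rbind, rows) else
    data.frame(sequence = character(0), library_kind = character(0),
               target_id = character(0), pass_type = character(0),
               offset_5p = integer(0), clip_3p = integer(0),
               n_mismatch = integer(0), mm_pos = integer(0),
               mm_read = character(0), mm_ref = character(0),
               ambiguous = logical(0), ref_pos = integer(0),
               stringsAsFactors = FALSE)
  assignments <- assignments[order(match(assignments$sequence, seqs)), ,
                             drop = FALSE]
  rownames(assignments) <- NULL
  unmapped <- ureads[!assigned, , drop = FALSE]
  class(unmapped) <- class(ureads)
  attr(unmapped, "sample_ids") <- sample_ids_of(ureads)
  list(assignments = assignments, unmapped = unmapped)
}

#' Per-miRNA count rows from assignments
#'
#' Canonical counts are reads that matched a library mature sequence
#' exactly at full length (the exact pass); total counts add the isomiR
#' pass.  `canonical_ratio` is pooled over samples.
#'
#' @param annotation result of [cascade_annotate()].
#' @param ureads the `UniqueReads` the annotation was computed from.
#' @return a `MiRNACounts` data frame: `mirna_id`, per-sample canonical
#'   and total count columns, `canonical_ratio`, `filtered` (all `FALSE`
#'   until [canonical_ratio_filter()] runs).
#' @export
summarize_mirna_counts <- function(annotation, ureads) {
  samples <- sample_ids_of(ureads)
  a <- annotation$assignments
  a <- a[a$library_kind == "mature_miRNA", , drop = FALSE]
  ids <- sort(unique(a$target_id))
  cmat <- matrix(0L, length(ids), length(samples),
                 dimnames = list(ids, samples))
  tmat <- cmat
  if (nrow(a)) {
    cnt <- as.matrix(ureads[match(a$sequence, ureads$sequence), samples,
                            drop = FALSE])
    for (i in seq_len(nrow(a))) {
      t <- a$target_id[i]
      tmat[t, ] <- tmat[t, ] + cnt[i, ]
      if (a$pass_type[i] == "exact") cmat[t, ] <- cmat[t, ] + cnt[i, ]
    }
  }
  ratio <- ifelse(rowSums(tmat) > 0, rowSums(cmat) / rowSums(tmat), 0)
  out <- data.frame(mirna_id = ids, stringsAsFactors = FALSE)
  for (s in samples) {
    out[[paste0("canonical.", s)]] <- cmat[, s]
    out[[paste0("total.", s)]] <- tmat[, s]
  }
  out$canonical_ratio <- unname(ratio)
  out$filtered <- FALSE
  attr(out, "sample_ids") <- samples
  class(out) <- c("MiRNACounts", "data.frame")
  out
}

#' Canonical-ratio filter
#'
#' Marks miRNAs whose proportion of canonical (exact full-length) reads
#' among all assigned reads falls below `threshold` and zeroes them in the
#' primary count columns; the originals stay available via the
#' `diagnostics` attribute.  This suppresses apparent miRNAs made up
#' almost entirely of non-templated isomiRs, which typically arise from
#' other genomic loci or contamination.
#'
#' @param rows a `MiRNACounts` data frame.
#' @param threshold canonical-ratio cutoff, in \[0, 0.5\] (default 0.1).
#' @return the filtered `MiRNACounts`; filtered rows have `filtered =
#'   TRUE` and zero counts.
#' @export
canonical_ratio_filter <- function(rows, threshold = 0.1) {
  if (!is.numeric(threshold) || threshold < 0 || threshold > 0.5) {
    stop("canonical-ratio threshold must lie in [0, 0.5]")
  }
  diagnostics <- rows
  bad <- rows$canonical_ratio < threshold
  rows$filtered <- bad
  numcols <- grep("^(canonical|total)\\.", names(rows), value = TRUE)
  for (cc in numcols) rows[[cc]][bad] <- 0L
  attr(rows, "diagnostics") <- diagnostics
  attr(rows, "threshold") <- threshold
  rows
}

#' Reads-per-million normalization
#'
#' RPM = total count x 1e6 / per-sample miRNA-mapped total, computed over
#' unfiltered miRNAs, so each sample's RPM column sums to 1e6 (up to
#' rounding).  Spike-in reads never enter the denominator (they are not
#' miRNA rows).  A sample with zero miRNA-mapped reads gets all-zero RPM
#' with a warning.
#'
#' @param rows a `MiRNACounts` data frame (after
#'   [canonical_ratio_filter()] if filtering is wanted).
#' @return `rows` with one `rpm.<sample>` column per sample.
#' @export
compute_rpm <- function(rows) {
  samples <- attr(rows, "sample_ids") %||%
    sub("^total\\.", "", grep("^total\\.", names(rows), value = TRUE))
  for (s in samples) {
    tot <- rows[[paste0("total.", s)]]
    denom <- sum(tot[!rows$filtered])
    if (denom <= 0) {
      warning("sample '", s, "' has zero miRNA-mapped reads; RPM set to 0")
      rows[[paste0("rpm.", s)]] <- 0
    } else {
      rows[[paste0("rpm.", s)]] <- tot * 1e6 / denom
    }
  }
  rows
}

#' Annotation summary per RNA class
#'
#' @param annotation result of [cascade_annotate()].
#' @param ureads the annotated `UniqueReads`.
#' @return data frame of read counts per library kind (rows) and sample
#'   (columns), with an `unmapped` row.
#' @export
annotation_summary <- function(annotation, ureads) {
  samples <- sample_ids_of(ureads)
  a <- annotation$assignments
  kinds <- c(CASCADE_ORDER, "unmapped")
  out <- matrix(0L, length(kinds), length(samples),
                dimnames = list(kinds, samples))
  if (nrow(a)) {
    cnt <- as.matrix(ureads[match(a$sequence, ureads$sequence), samples,
                            drop = FALSE])
    for (k in unique(a$library_kind)) {
      sel <- a$library_kind == k
      out[k, ] <- colSums(cnt[sel, , drop = FALSE])
    }
  }
  if (nrow(annotation$unmapped)) {
    out["unmapped", ] <- colSums(
      as.matrix(annotation$unmapped[, samples, drop = FALSE]))
  }
  as.data.frame(out)
}
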
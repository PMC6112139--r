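# IsomiR classification relative to the precursor and miRTop-style GFF3
# serialization with a reconstructible CIGAR dialect.
#
# CIGAR dialect: run-length "nM" for positions matching the precursor; a
# substituted position appears as the read's base letter interrupting the M
# runs (e.g. "13MA8M").  Non-templated 3' additions are not part of the
# precursor span: coordinates are clamped to the templated part, the tail
# is declared by iso_add3p and carried in the Read attribute, so the read
# is always reconstructible from precursor[start..end] + cigar + tail.

#' Classify one read relative to its canonical miRNA and precursor
#'
#' Variant tags are emitted in fixed order iso_5p, iso_3p, iso_add3p,
#' iso_snp.  Sign conventions: `iso_5p:+n` = read starts n nt upstream
#' (5') of the canonical start; `iso_3p:+n` = templated 3' extension by n
#' nt (the extension matches the precursor), `iso_3p:-n` = 3' trimming;
#' `iso_add3p:+n` = n non-templated 3' bases.
#'
#' @param read read sequence (DNA).
#' @param mature_id,mature_seq canonical miRNA id and sequence.
#' @param precursor_id,precursor_seq precursor (hairpin) id and sequence.
#' @param mature_offset 0-based offset of the mature sequence within the
#'   precursor.
#' @param offset_5p signed 5' offset from the annotate contract (read
#'   start minus canonical start).
#' @param expression integer vector of per-sample counts.
#' @return an `IsomiRRecord` (list) with fields precursor_id, mature_id,
#'   start, end (1-based inclusive on the precursor), type, variant_tags,
#'   cigar, read, expression, filter.
#' @export
classify_isomir <- function(read, mature_id, mature_seq, precursor_id,
                            precursor_seq, mature_offset, offset_5p = 0L,
                            expression = 1L) {
  L <- nchar(read)
  M <- nchar(mature_seq)
  P <- nchar(precursor_seq)
  start0 <- mature_offset + offset_5p         # 0-based on precursor
  if (start0 < 0L || start0 >= P) {
    return(isomir_reject(read, mature_id, precursor_id, expression,
                         "start outside precursor"))
  }
  # longest suffix of the read that cannot be templated: walk back from the
  # 3' end while the read base disagrees with the precursor (or falls off)
  tail_len <- 0L
  while (tail_len < L) {
    t <- L - tail_len                          # 1-based read pos of candidate
    p0 <- start0 + t - 1L                      # 0-based precursor pos
    if (p0 < P &&
        substr(read, t, t) == substr(precursor_seq, p0 + 1L, p0 + 1L)) {
      break
    }
    tail_len <- tail_len + 1L
    if (tail_len > 5L) break                   # cap runaway tails
  }
  core_len <- L - tail_len
  if (core_len < 1L || start0 + core_len > P) {
    return(isomir_reject(read, mature_id, precursor_id, expression,
                         "read not alignable to precursor"))
  }
  start <- start0 + 1L                         # 1-based
  end <- start0 + core_len
  pre_slice <- substr(precursor_seq, start, end)
  core <- substr(read, 1L, core_len)

  # cigar over the templated core
  pv <- strsplit(pre_slice, "", fixed = TRUE)[[1]]
  rv <- strsplit(core, "", fixed = TRUE)[[1]]
  same <- pv == rv
  cigar <- encode_cigar(rv, same)
  mm_pos <- which(!same)

  # variant tags ---------------------------------------------------------
  tags <- character(0)
  if (offset_5p != 0L) {
    tags <- c(tags, sprintf("iso_5p:%+d", -offset_5p))
  }
  canonical_end0 <- mature_offset + M          # 0-based, exclusive
  d3 <- (start0 + core_len) - canonical_end0   # templated 3' shift
  if (d3 != 0L) tags <- c(tags, sprintf("iso_3p:%+d", d3))
  if (tail_len > 0L) tags <- c(tags, sprintf("iso_add3p:+%d", tail_len))
  if (length(mm_pos)) tags <- c(tags, "iso_snp")

  type <- if (length(tags) == 0L) "ref_miRNA" else "isomiR"
  structure(list(precursor_id = precursor_id, mature_id = mature_id,
                 start = start, end = end, type = type,
                 variant_tags = tags, cigar = cigar, read = read,
                 expression = as.integer(expression), filter = "Pass"),
            class = "IsomiRRecord")
}

isomir_reject <- function(read, mature_id, precursor_id, expression,
                          reason) {
  structure(list(precursor_id = precursor_id, mature_id = mature_id,
                 start = NA_integer_, end = NA_integer_, type = "isomiR",
                 variant_tags = character(0), cigar = "",
                 read = read, expression = as.integer(expression),
                 filter = paste0("Reject:", reason)),
            class = "IsomiRRecord")
}

encode_cigar <- function(read_chars, same) {
  out <- character(0)
  run <- 0L
  for (i in seq_along(same)) {
    if (same[i]) run <- run + 1L
    else {
      if (run > 0L) out <- c(out, paste0(run, "M"))
      out <- c(out, read_chars[i])
      run <- 0L
    }
  }
  if (run > 0L) out <- c(out, paste0(run, "M"))
  if (!length(out)) out <- "0M"
  paste(out, collapse = "")
}

#' Reconstruct a read from precursor coordinates, CIGAR and declared tail
#'
#' The inverse of the CIGAR dialect: applies `cigar` to
#' `precursor[start..end]` and appends the `iso_add3p` tail taken from the
#' record's `read`.
#'
#' @param record an `IsomiRRecord`.
#' @param precursor_seq the precursor sequence.
#' @return the reconstructed read string.
#' @export
reconstruct_isomir <- function(record, precursor_seq) {
  slice <- substr(precursor_seq, record$start, record$end)
  sv <- strsplit(slice, "", fixed = TRUE)[[1]]
  out <- character(0)
  i <- 1L
  for (tok in cigar_tokens(record$cigar)) {
    if (grepl("^[0-9]+M$", tok)) {
      n <- as.integer(sub("M$", "", tok))
      if (n > 0L) {
        out <- c(out, sv[seq.int(i, i + n - 1L)])
        i <- i + n
      }
    } else {
      out <- c(out, tok)                       # substituted base letter
      i <- i + 1L
    }
  }
  add <- tail_length_of(record)
  if (add > 0L) {
    L <- nchar(record$read)
    out <- c(out, substr(record$read, L - add + 1L, L))
  }
  paste(out, collapse = "")
}

cigar_tokens <- function(cigar) {
  regmatches(cigar, gregexpr("[0-9]+M|[ACGTN]", cigar))[[1]]
}

tail_length_of <- function(record) {
  tag <- grep("^iso_add3p:", record$variant_tags, value = TRUE)
  if (!length(tag)) return(0L)
  as.integer(sub("^iso_add3p:\\+", "", tag[1]))
}

#' Classify all miRNA-assigned reads and build GFF3 records
#'
#' @param annotation result of [cascade_annotate()].
#' @param ureads the annotated `UniqueReads`.
#' @param mature_lib mature miRNA `SequenceLibrary` (post-merge).
#' @param hairpin_lib hairpin `SequenceLibrary`; mature ids are located in
#'   precursors by exact substring search of the mature sequence (merged
#'   representatives are reported against the representative's precursor).
#' @return list of `IsomiRRecord`s (reads whose mature id has no hairpin
#'   are skipped with a message).
#' @export
build_isomir_records <- function(annotation, ureads, mature_lib,
                                 hairpin_lib) {
  samples <- sample_ids_of(ureads)
  a <- annotation$assignments
  a <- a[a$library_kind == "mature_miRNA", , drop = FALSE]
  records <- list()
  skipped <- 0L
  for (i in seq_len(nrow(a))) {
    mid <- a$target_id[i]
    mseq <- mature_lib$seqs[[mid]]
    if (is.null(mseq)) { skipped <- skipped + 1L; next }
    hp <- locate_precursor(mseq, hairpin_lib)
    if (is.null(hp)) { skipped <- skipped + 1L; next }
    expr <- as.integer(ureads[match(a$sequence[i], ureads$sequence),
                              samples])
    rec <- classify_isomir(a$sequence[i], mid, mseq, hp$id, hp$seq,
                           hp$offset, a$offset_5p[i], expr)
    records[[length(records) + 1L]] <- rec
  }
  if (skipped > 0L) {
    sk_log("isomiR reporting: %d assignment(s) without a precursor skipped",
           skipped)
  }
  records
}

locate_precursor <- function(mature_seq, hairpin_lib) {
  for (id in names(hairpin_lib$seqs)) {
    p <- regexpr(mature_seq, hairpin_lib$seqs[[id]], fixed = TRUE)
    if (p > 0L) {
      return(list(id = id, seq = hairpin_lib$seqs[[id]],
                  offset = as.integer(p) - 1L))
    }
  }
  NULL
}

#' Write isomiR records as miRTop-style GFF3
#'
#' Nine tab-separated columns, `##gff-version 3` header and column
#' pragmas; attributes `UID`, `Read`, `Name`, `Parent`, `Variant`,
#' `Cigar`, `Expression`, `Filter`.  `Expression` holds comma-separated
#' per-sample counts in `sample_ids` order.
#'
#' @param records list of `IsomiRRecord`s.
#' @param path output path.
#' @param sample_ids sample names recorded in the header.
#' @param source_tag value for GFF3 column 2.
#' @export
write_gff3 <- function(records, path, sample_ids = NULL,
                       source_tag = "srnakit") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  writeLines("## source-ontology: miRTop-style isomiR report", con)
  if (!is.null(sample_ids)) {
    writeLines(paste0("## COLDATA: ", paste(sample_ids, collapse = ",")),
               con)
  }
  writeLines(paste0("## FILTER: Pass records reconstruct the read from ",
                    "the precursor slice, CIGAR and declared additions"),
             con)
  n <- 0L
  for (rec in records) {
    if (is.na(rec$start) || is.na(rec$end) || rec$end < rec$start) {
      sk_log("refused GFF3 record for %s (%s)", rec$mature_id, rec$filter)
      next
    }
    n <- n + 1L
    attrs <- paste0(
      "UID=", sprintf("iso-%06d", n), ";",
      "Read=", rec$read, ";",
      "Name=", rec$mature_id, ";",
      "Parent=", rec$precursor_id, ";",
      "Variant=", if (length(rec$variant_tags))
        paste(rec$variant_tags, collapse = ",") else "NA", ";",
      "Cigar=", rec$cigar, ";",
      "Expression=", paste(rec$expression, collapse = ","), ";",
      "Filter=", rec$filter, ";")
    writeLines(paste(rec$precursor_id, source_tag, rec$type,
                     rec$start, rec$end, ".", "+", ".", attrs,
                     sep = "\t"), con)
  }
  invisible(path)
}

#' Parse a GFF3 isomiR report back into records
#'
#' Strict inverse of [write_gff3()]: `parse(write(x))` equals `x` for all
#' Pass records.
#'
#' @param path GFF3 path.
#' @return list of `IsomiRRecord`s.
#' @export
read_gff3 <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || lines[1] != "##gff-version 3") {
    stop("not a GFF3 file: missing '##gff-version 3' header")
  }
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  records <- vector("list", length(body))
  for (i in seq_along(body)) {
    f <- strsplit(body[i], "\t", fixed = TRUE)[[1]]
    if (length(f) != 9L) stop("GFF3 line ", i, ": expected 9 columns")
    kv <- strsplit(strsplit(f[9], ";", fixed = TRUE)[[1]], "=", fixed = TRUE)
    att <- stats::setNames(vapply(kv, `[`, character(1), 2),
                           vapply(kv, `[`, character(1), 1))
    tags <- if (identical(att[["Variant"]], "NA")) character(0) else
      strsplit(att[["Variant"]], ",", fixed = TRUE)[[1]]
    records[[i]] <- structure(list(
      precursor_id = f[1], mature_id = att[["Name"]],
      start = as.integer(f[4]), end = as.integer(f[5]),
      type = f[3], variant_tags = tags, cigar = att[["Cigar"]],
      read = att[["Read"]],
      expression = as.integer(strsplit(att[["Expression"]], ",",
                                       fixed = TRUE)[[1]]),
      filter = att[["Filter"]]), class = "IsomiRRecord")
  }
  records
}
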
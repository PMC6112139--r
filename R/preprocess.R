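# Pre-alignment: FASTQ input, quality control, 3' adapter removal, length
# filtering and collapsing into unique reads merged across samples.

TRIM_STATUS <- c("trimmed", "untrimmed", "too_short", "too_long",
                 "low_quality", "has_N", "bad_alphabet", "no_adapter")

#' Preprocessing configuration
#'
#' @param adapter 3' adapter sequence, or `"none"` to skip adapter removal.
#' @param min_length,max_length retained read length window after trimming
#'   (nt).  Defaults 16-40 span mature miRNAs, isomiRs and tRNA-fragment
#'   length reads.
#' @param min_quality minimum mean phred score (phred+33) of the retained
#'   portion; 0 disables the filter.
#' @param adapter_min_overlap minimum adapter/read overlap for a trim.
#' @param adapter_max_mismatch_rate maximum mismatch fraction in the
#'   overlap.
#' @param require_adapter reject reads in which no adapter is found
#'   (default `FALSE`: untrimmed reads are kept unchanged).
#' @return a `PreprocessConfig` list.
#' @export
preprocess_config <- function(adapter = "none", min_length = 16L,
                              max_length = 40L, min_quality = 20,
                              adapter_min_overlap = 8L,
                              adapter_max_mismatch_rate = 0.1,
                              require_adapter = FALSE) {
  adapter <- toupper(adapter)
  if (!identical(adapter, "NONE") &&
      grepl("[^ACGT]", adapter)) {
    stop("adapter must be a DNA string or 'none'")
  }
  if (min_length > max_length) stop("min_length must be <= max_length")
  structure(list(adapter = adapter, min_length = as.integer(min_length),
                 max_length = as.integer(max_length),
                 min_quality = min_quality,
                 adapter_min_overlap = as.integer(adapter_min_overlap),
                 adapter_max_mismatch_rate = adapter_max_mismatch_rate,
                 require_adapter = isTRUE(require_adapter)),
            class = "PreprocessConfig")
}

#' Read a FASTQ file
#'
#' Four-line records, phred+33; gzipped input is handled transparently.
#'
#' @param path FASTQ or FASTQ.GZ path.
#' @return list with `sequence` and `quality` character vectors.
#' @export
read_fastq <- function(path) {
  set <- Biostrings::readDNAStringSet(path, format = "fastq",
                                      with.qualities = TRUE)
  list(sequence = as.character(set),
       quality = as.character(S4Vectors::mcols(set)$qualities))
}

#' Trim 3' adapters and filter reads
#'
#' The leftmost suffix-anchored alignment of the adapter prefix (overlap at
#' least `adapter_min_overlap`, mismatch rate at most
#' `adapter_max_mismatch_rate`) is removed together with everything 3' of
#' it.  Reads with no adapter hit are kept unchanged unless
#' `require_adapter`.  After trimming, reads outside the length window,
#' with mean phred below `min_quality`, or containing `N` are rejected.
#'
#' @param sequences character vector of read sequences.
#' @param qualities matching phred+33 quality strings (or `NULL` to skip
#'   quality filtering).
#' @param config a [preprocess_config()].
#' @return data frame with `sequence` (post-trim) and `status` (factor over
#'   trimmed/untrimmed/rejection reasons); rows align with the input.
#' @export
trim_adapter <- function(sequences, qualities = NULL, config = preprocess_config()) {
  no_qual <- is.null(qualities)
  if (no_qual) qualities <- rep(NA_character_, length(sequences))
  adapter <- if (identical(config$adapter, "NONE")) "" else config$adapter
  res <- trim_reads_cpp(toupper(sequences), qualities, adapter,
                        config$adapter_min_overlap,
                        config$adapter_max_mismatch_rate,
                        config$min_length, config$max_length,
                        if (no_qual) 0 else config$min_quality,
                        config$require_adapter)
  data.frame(sequence = res$sequence,
             status = factor(TRIM_STATUS[res$status + 1L],
                             levels = TRIM_STATUS),
             stringsAsFactors = FALSE)
}

#' Collapse trimmed reads into unique sequences
#'
#' One row per distinct sequence with exact per-sample counts, merged
#' across all samples, sorted by total count descending then sequence
#' ascending, so the output is deterministic whatever the stream order.
#'
#' @param read_streams list of character vectors (one per sample) of reads
#'   that passed all filters.
#' @param sample_ids sample names; default `sample1..N`.
#' @return a `UniqueReads` data frame: `sequence`, one count column per
#'   sample, `total`.
#' @export
collapse_reads <- function(read_streams, sample_ids = NULL) {
  if (!is.list(read_streams)) read_streams <- list(read_streams)
  ns <- length(read_streams)
  if (is.null(sample_ids)) sample_ids <- paste0("sample", seq_len(ns))
  stopifnot(length(sample_ids) == ns)
  all_seq <- sort(unique(unlist(read_streams, use.names = FALSE)))
  counts <- matrix(0L, nrow = length(all_seq), ncol = ns,
                   dimnames = list(NULL, sample_ids))
  for (k in seq_len(ns)) {
    tb <- table(read_streams[[k]])
    if (length(tb)) {
      counts[match(names(tb), all_seq), k] <- as.integer(tb)
    }
  }
  total <- as.integer(rowSums(counts))
  ord <- order(-total, all_seq)
  out <- data.frame(sequence = all_seq[ord], stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(counts[ord, , drop = FALSE]))
  out$total <- total[ord]
  class(out) <- c("UniqueReads", "data.frame")
  attr(out, "sample_ids") <- sample_ids
  out
}

sample_ids_of <- function(ureads) {
  attr(ureads, "sample_ids") %||%
    setdiff(names(ureads), c("sequence", "total"))
}

#' Run the full pre-alignment stage on FASTQ files
#'
#' @param fastq_paths character vector of FASTQ(.GZ) paths, one per sample.
#' @param config a [preprocess_config()].
#' @param sample_ids sample names; default file basenames.
#' @return list with `unique_reads` (a `UniqueReads` data frame) and
#'   `stats` (per-sample read counts by trim status).
#' @export
preprocess_fastq <- function(fastq_paths, config = preprocess_config(),
                             sample_ids = NULL) {
  if (is.null(sample_ids)) {
    sample_ids <- sub("\\.(fastq|fq)(\\.gz)?$", "",
                      basename(fastq_paths))
  }
  streams <- vector("list", length(fastq_paths))
  stats <- list()
  for (k in seq_along(fastq_paths)) {
    fq <- read_fastq(fastq_paths[k])
    tr <- trim_adapter(fq$sequence, fq$quality, config)
    keep <- tr$status %in% c("trimmed", "untrimmed")
    streams[[k]] <- tr$sequence[keep]
    stats[[sample_ids[k]]] <- table(tr$status)
  }
  list(unique_reads = collapse_reads(streams, sample_ids),
       stats = stats)
}

#' Write collapsed reads as TSV
#'
#' @param ureads a `UniqueReads` data frame.
#' @param path output path.
#' @export
write_unique_reads <- function(ureads, path) {
  utils::write.table(ureads, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
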
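# Annotation library curation: FASTA ingestion, tRNA CCA editing, SNP
# expansion and merging of near-identical mature miRNAs.

LIBRARY_KINDS <- c("mature_miRNA", "hairpin", "tRNA_mature", "tRNA_precursor",
                   "snoRNA", "rRNA", "ncRNA", "mRNA", "spike_in", "genome")

#' Build an annotation library from a FASTA file
#'
#' Reads a (possibly RNA-alphabet) FASTA file, converts U to T, validates
#' record ids and sequence content and returns an indexed
#' `SequenceLibrary`.  Mature miRNA entries must be 15-30 nt over
#' \{A,C,G,T\}; `N` bases are tolerated only in genome libraries.
#'
#' @param fasta_path path to a FASTA file (uncompressed or gzipped).
#' @param kind library kind, one of
#'   `r paste0('\x60', LIBRARY_KINDS, '\x60', collapse = ", ")`.
#' @param name optional display label; defaults to `kind`.
#' @return an object of class `SequenceLibrary`: a list with `name`,
#'   `kind`, `seqs` (named uppercase DNA character vector) and `parent`
#'   (named character vector mapping each entry to the id its counts are
#'   attributed to; identity for plain entries).
#' @export
build_library <- function(fasta_path, kind, name = kind) {
  kind <- match.arg(kind, LIBRARY_KINDS)
  if (!file.exists(fasta_path)) {
    stop("library FASTA not found: ", fasta_path)
  }
  set <- tryCatch(
    Biostrings::readBStringSet(fasta_path),
    error = function(e) stop("malformed FASTA '", fasta_path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  seqs <- rna_to_dna(as.character(set))
  ids <- sub("\\s.*$", "", names(set) %||% character(0))
  names(seqs) <- ids
  new_library(seqs, kind = kind, name = name)
}

#' @rdname build_library
#' @param seqs named character vector of sequences (DNA or RNA alphabet).
#' @export
new_library <- function(seqs, kind, name = kind) {
  kind <- match.arg(kind, LIBRARY_KINDS)
  seqs <- rna_to_dna(seqs)
  ids <- names(seqs)
  if (length(seqs) == 0L) {
    warning("library '", name, "' is empty")
  } else {
    if (is.null(ids) || any(!nzchar(ids))) {
      stop("library '", name, "': records must carry non-empty ids")
    }
    if (anyDuplicated(ids)) {
      stop("library '", name, "': duplicate ids: ",
           paste(unique(ids[duplicated(ids)]), collapse = ", "))
    }
    if (any(!nzchar(seqs))) {
      stop("library '", name, "': empty sequence for ",
           paste(ids[!nzchar(seqs)], collapse = ", "))
    }
    allowed <- if (kind == "genome") "ACGTN" else "ACGT"
    bad <- grepl(sprintf("[^%s]", allowed), seqs)
    if (any(bad)) {
      stop("library '", name, "': invalid characters in ",
           paste(ids[bad], collapse = ", "))
    }
    if (kind == "mature_miRNA") {
      len <- nchar(seqs)
      off <- len < 15L | len > 30L
      if (any(off)) {
        stop("mature miRNA length outside [15, 30] for ",
             paste(ids[off], collapse = ", "))
      }
    }
  }
  structure(list(name = name, kind = kind, seqs = seqs,
                 parent = stats::setNames(ids, ids)),
            class = "SequenceLibrary")
}

#' @export
print.SequenceLibrary <- function(x, ...) {
  cat(sprintf("<SequenceLibrary '%s' (%s): %d entries>\n",
              x$name, x$kind, length(x$seqs)))
  invisible(x)
}

#' Write a library back to FASTA
#'
#' Sequences are wrapped at 70 columns.
#'
#' @param lib a `SequenceLibrary`.
#' @param path output path.
#' @export
write_library <- function(lib, path) {
  stopifnot(inherits(lib, "SequenceLibrary"))
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(lib$seqs)) {
    writeLines(paste0(">", id), con)
    s <- lib$seqs[[id]]
    starts <- seq(1L, nchar(s), by = 70L)
    writeLines(substring(s, starts, pmin(starts + 69L, nchar(s))), con)
  }
  invisible(path)
}

#' Append the post-transcriptional CCA tail to tRNA entries
#'
#' Mature tRNAs carry a 3' CCA that is added enzymatically and absent from
#' many reference FASTAs; reads derived from mature tRNAs therefore fail to
#' align unless the library is edited.  This appends "CCA" to every entry.
#' No attempt is made to detect a pre-existing CCA: calling it twice
#' appends twice.
#'
#' @param lib a `SequenceLibrary` of kind `tRNA_mature` or
#'   `tRNA_precursor`.
#' @return the edited library.
#' @export
add_cca_to_trnas <- function(lib) {
  stopifnot(inherits(lib, "SequenceLibrary"))
  if (!lib$kind %in% c("tRNA_mature", "tRNA_precursor")) {
    stop("add_cca_to_trnas expects a tRNA library, got kind '",
         lib$kind, "'")
  }
  lib$seqs <- stats::setNames(paste0(lib$seqs, "CCA"), names(lib$seqs))
  lib
}

#' Read / write a SNP annotation table
#'
#' Tab-separated columns: `mirna_id`, `position` (1-based on the mature
#' sequence), `ref`, `alt`, `frequency`.
#'
#' @param path file path.
#' @export
read_snp_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("mirna_id", "position", "ref", "alt", "frequency")
  if (!all(need %in% names(df))) {
    stop("SNP table must have columns: ", paste(need, collapse = ", "))
  }
  df
}

#' @rdname read_snp_table
#' @param snps data frame of SNP annotations.
#' @export
write_snp_table <- function(snps, path) {
  utils::write.table(snps, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Expand a mature miRNA library with SNP variant entries
#'
#' For each annotated SNP a variant entry `<mirna_id>.SNP<n>` is added with
#' the alternate base substituted; `n` counts SNPs per miRNA in input
#' order.  Variant entries are mapped back to their parent id so all
#' downstream counting is attributed to the parent miRNA; parent sequences
#' are never altered.  A-to-G SNPs are additionally recorded in the
#' `ag_snp_sites` attribute so the editing module can blacklist them.
#'
#' @param lib a mature miRNA `SequenceLibrary`.
#' @param snps data frame with columns `mirna_id`, `position`, `ref`,
#'   `alt`, `frequency` (see [read_snp_table()]).
#' @return the expanded library; `attr(, "ag_snp_sites")` holds a data
#'   frame of (mirna_id, position) for A/G SNPs.
#' @export
expand_snps <- function(lib, snps) {
  stopifnot(inherits(lib, "SequenceLibrary"))
  if (nrow(snps) == 0L) {
    attr(lib, "ag_snp_sites") <- data.frame(mirna_id = character(0),
                                            position = integer(0))
    return(lib)
  }
  missing_ids <- setdiff(snps$mirna_id, names(lib$seqs))
  if (length(missing_ids)) {
    stop("SNPs reference unknown miRNAs: ",
         paste(unique(missing_ids), collapse = ", "))
  }
  counter <- integer(0)
  add_seq <- character(0)
  add_parent <- character(0)
  ag <- data.frame(mirna_id = character(0), position = integer(0))
  for (i in seq_len(nrow(snps))) {
    id <- snps$mirna_id[i]
    pos <- as.integer(snps$position[i])
    ref <- toupper(snps$ref[i]); alt <- toupper(snps$alt[i])
    parent_seq <- lib$seqs[[id]]
    if (pos < 1L || pos > nchar(parent_seq)) {
      stop(sprintf("SNP %d: position %d outside %s (length %d)",
                   i, pos, id, nchar(parent_seq)))
    }
    have <- substr(parent_seq, pos, pos)
    if (have != ref) {
      stop(sprintf(
        "SNP %d: ref '%s' does not match base '%s' at position %d of %s",
        i, ref, have, pos, id))
    }
    if (ref == alt) stop(sprintf("SNP %d: ref equals alt", i))
    counter[id] <- (if (id %in% names(counter)) counter[[id]] else 0L) + 1L
    vid <- sprintf("%s.SNP%d", id, counter[[id]])
    vseq <- parent_seq
    substr(vseq, pos, pos) <- alt
    add_seq[vid] <- vseq
    add_parent[vid] <- id
    if ((ref == "A" && alt == "G") || (ref == "G" && alt == "A")) {
      ag <- rbind(ag, data.frame(mirna_id = id, position = pos))
    }
  }
  lib$seqs <- c(lib$seqs, add_seq)
  lib$parent <- c(lib$parent, add_parent)
  attr(lib, "ag_snp_sites") <- ag
  lib
}

# Hamming distance after 3'-padding the shorter sequence with wildcards
# (padded positions always match, so only the shared prefix is compared).
pad_hamming <- function(a, b) {
  la <- nchar(a); lb <- nchar(b)
  n <- min(la, lb)
  av <- strsplit(substr(a, 1, n), "", fixed = TRUE)[[1]]
  bv <- strsplit(substr(b, 1, n), "", fixed = TRUE)[[1]]
  sum(av != bv)
}

#' Merge near-identical mature miRNAs
#'
#' Mature miRNAs whose sequences are within `max_mismatch` of one another
#' (Hamming distance over the shared prefix after 3'-padding the shorter
#' sequence with wildcards) are collapsed to a single library entry, the
#' way highly similar pairs such as miR-192-5p and miR-215-5p are
#' conventionally reported together.  Groups are the transitive closure of
#' the pairwise relation, so the result does not depend on input order.
#' The merged entry is named by joining member ids with "/" in input
#' order; the representative sequence is the lexicographically-first
#' member's and the representative id is the lexicographically first.
#'
#' @param lib a mature miRNA `SequenceLibrary`.
#' @param max_mismatch merge distance (default 1).
#' @return list with `library` (merged `SequenceLibrary`) and `groups`
#'   (data frame: `representative_id`, `display_name`, `member_ids`
#'   semicolon-joined).
#' @export
merge_similar_mirnas <- function(lib, max_mismatch = 1L) {
  stopifnot(inherits(lib, "SequenceLibrary"))
  ids <- names(lib$seqs)
  n <- length(ids)
  comp <- seq_len(n)               # union-find
  find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq.int(i + 1L, n)) {
        if (pad_hamming(lib$seqs[[i]], lib$seqs[[j]]) <= max_mismatch) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) comp[max(ri, rj)] <- min(ri, rj)
        }
      }
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  groups <- split(seq_len(n), root)

  new_seqs <- character(0)
  new_parent <- character(0)
  grows <- list()
  for (g in groups) {
    members <- ids[g]                       # input order preserved
    rep_id <- sort(members)[1]
    display <- paste(members, collapse = "/")
    new_seqs[display] <- lib$seqs[[rep_id]]
    new_parent[display] <- display
    if (length(members) > 1L) {
      grows[[length(grows) + 1L]] <- data.frame(
        representative_id = rep_id,
        display_name = display,
        member_ids = paste(members, collapse = ";"),
        stringsAsFactors = FALSE)
    }
  }
  merged <- structure(list(name = lib$name, kind = lib$kind,
                           seqs = new_seqs, parent = new_parent),
                      class = "SequenceLibrary")
  gdf <- if (length(grows)) do.call(rbind, grows) else
    data.frame(representative_id = character(0),
               display_name = character(0), member_ids = character(0),
               stringsAsFactors = FALSE)
  attr(merged, "ag_snp_sites") <- attr(lib, "ag_snp_sites")
  list(library = merged, groups = gdf)
}

#' @rdname merge_similar_mirnas
#' @param groups merge-group data frame.
#' @param path output TSV path.
#' @export
write_merge_groups <- function(groups, path) {
  utils::write.table(groups, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
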
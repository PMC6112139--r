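# Synthetic-data generator: genomes with planted hairpin loci, annotation
# libraries, isomiR-structured reads with adapters, planted editing sites
# and truth tables.  Everything is deterministic under the configured seed.
#
# The generator states the world the method assumes: miRNA-derived read
# families share a tight 5' start, ragged 3' ends and non-templated A/U
# tails, while non-miRNA loci emit uniformly ragged reads without a tail
# bias.

#' Simulation configuration
#'
#' Defaults describe a desk-scale experiment that exercises every stage
#' of the pipeline in minutes: a 100 kb genome, 20 miRNA-like hairpin
#' loci and 40 negative loci, roughly 50k reads.
#'
#' @param seed integer RNG seed.
#' @param genome_length background genome length (nt).
#' @param n_mirna_loci planted hairpin (miRNA) loci.
#' @param n_negative_loci non-miRNA loci (mix of tRNA-like CCA-capped
#'   transcripts, snoRNA-like and fragment-like loci).
#' @param reads_per_locus mean reads per locus per sample (Poisson-ish
#'   via negative binomial, size 5).
#' @param n_samples number of samples.
#' @param p_start_shift probability that a miRNA read starts 1 nt off the
#'   canonical 5' end (split between -1/+1).
#' @param p_end_shift_each probability of each 3' end shift -2,-1,+1,+2
#'   for miRNA reads (canonical end gets the rest).
#' @param nta_probs probability vector for non-templated 3' tail lengths
#'   0..3 on miRNA reads; tails draw bases from \{A, T\} (A with
#'   `nta_a_frac`).
#' @param nta_a_frac fraction of tail bases that are A (default 0.7).
#' @param editing_sites data frame (locus, position, fraction): planted
#'   A-to-G editing, positions 1-based on the mature arm and never within
#'   the last two 3' bases.  `NULL` plants none.
#' @param adapter 3' adapter appended to every read.
#' @param error_rate per-base sequencing error rate.
#' @param mature_len mature arm length (nt).
#' @param loop_len hairpin loop length (nt).
#' @param arm_mutation_rate fraction of 3' arm positions perturbed so the
#'   duplex carries wobbles/mismatches like a real pre-miRNA.
#' @return a `SimulationConfig` list.
#' @export
sim_config <- function(seed = 1L, genome_length = 100000L,
                       n_mirna_loci = 20L, n_negative_loci = 40L,
                       reads_per_locus = 400, n_samples = 2L,
                       p_start_shift = 0.08,
                       p_end_shift_each = 0.12,
                       nta_probs = c(0.55, 0.25, 0.15, 0.05),
                       nta_a_frac = 0.7,
                       editing_sites = NULL,
                       adapter = "AGATCGGAAGAGCACACGTCT",
                       error_rate = 0.001,
                       mature_len = 22L, loop_len = 14L,
                       arm_mutation_rate = 0.1) {
  stopifnot(abs(sum(nta_probs) - 1) < 1e-9)
  structure(list(seed = as.integer(seed),
                 genome_length = as.integer(genome_length),
                 n_mirna_loci = as.integer(n_mirna_loci),
                 n_negative_loci = as.integer(n_negative_loci),
                 reads_per_locus = reads_per_locus,
                 n_samples = as.integer(n_samples),
                 p_start_shift = p_start_shift,
                 p_end_shift_each = p_end_shift_each,
                 nta_probs = nta_probs, nta_a_frac = nta_a_frac,
                 editing_sites = editing_sites, adapter = toupper(adapter),
                 error_rate = error_rate,
                 mature_len = as.integer(mature_len),
                 loop_len = as.integer(loop_len),
                 arm_mutation_rate = arm_mutation_rate),
            class = "SimulationConfig")
}

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

# hairpin: 5' arm + loop + (reverse complement of arm, lightly perturbed)
make_hairpin <- function(config) {
  arm <- random_dna(config$mature_len)
  loop <- random_dna(config$loop_len)
  arm3 <- revcomp(arm)
  v <- strsplit(arm3, "", fixed = TRUE)[[1]]
  nmut <- rbinom(1, length(v), config$arm_mutation_rate)
  if (nmut > 0) {
    at <- sample(length(v), nmut)
    for (i in at) {
      # G:T wobble where possible, otherwise a random other base
      v[i] <- if (v[i] == "C") "T" else if (v[i] == "A") "G" else
        sample(setdiff(DNA_BASES, v[i]), 1)
    }
  }
  list(seq = paste0(arm, loop, paste(v, collapse = "")), mature5p = arm)
}

#' Generate a genome with planted loci and its truth table
#'
#' Positive loci are hairpins whose 5' arm is the mature miRNA; negative
#' loci are tRNA-like (CCA-capped) transcripts, snoRNA-like transcripts
#' and short fragment loci, all without hairpin bias.  One negative locus
#' is planted twice (verbatim duplicate elsewhere in the genome) to
#' exercise multimapping logic, and one extra copy of a designated miRNA
#' mature arm (A-to-G switched) can be planted via `editing_sites`
#' testing hooks.
#'
#' @param config a [sim_config()].
#' @return list with `genome` (named character vector, one chromosome)
#'   and `truth` (data frame: locus id, class, chrom, start, end 0-based
#'   half-open of the expressed span, mature sequence, strand).
#' @export
make_genome <- function(config = sim_config()) {
  set.seed(config$seed)
  n_loci <- config$n_mirna_loci + config$n_negative_loci
  spacing <- 150L
  hp_len <- 2L * config$mature_len + config$loop_len
  need <- n_loci * (200L + spacing) + 1000L
  if (config$genome_length < need) {
    stop("genome_length too small for the requested loci (need >= ",
         need, ")")
  }
  bg <- random_dna(config$genome_length)
  truth <- list()
  pos <- 500L
  neg_classes <- rep(c("tRNA_like", "snoRNA_like", "fragment_like"),
                     length.out = config$n_negative_loci)
  dup_idx <- if (config$n_negative_loci > 0) 1L else 0L
  dup_seq <- NULL

  insert <- function(g, at, s) {
    paste0(substr(g, 1, at), s, substr(g, at + nchar(s) + 1, nchar(g)))
  }

  for (i in seq_len(config$n_mirna_loci)) {
    hp <- make_hairpin(config)
    bg <- insert(bg, pos, hp$seq)
    truth[[length(truth) + 1L]] <- data.frame(
      locus = sprintf("mir-%03d", i), class = "miRNA", chrom = "chr1",
      start = pos, end = pos + config$mature_len,
      mature = hp$mature5p, strand = "+", stringsAsFactors = FALSE)
    pos <- pos + nchar(hp$seq) + spacing
  }
  for (i in seq_len(config$n_negative_loci)) {
    cls <- neg_classes[i]
    len <- switch(cls, tRNA_like = 72L, snoRNA_like = 100L,
                  fragment_like = 60L)
    s <- random_dna(len)
    if (cls == "tRNA_like") s <- paste0(substr(s, 1, len - 3L), "CCA")
    bg <- insert(bg, pos, s)
    truth[[length(truth) + 1L]] <- data.frame(
      locus = sprintf("neg-%03d", i), class = cls, chrom = "chr1",
      start = pos, end = pos + len, mature = s, strand = "+",
      stringsAsFactors = FALSE)
    if (i == dup_idx) dup_seq <- s
    pos <- pos + len + spacing
  }
  if (!is.null(dup_seq)) {
    bg <- insert(bg, pos, dup_seq)
    truth[[length(truth) + 1L]] <- data.frame(
      locus = "neg-dup", class = "duplicate_locus", chrom = "chr1",
      start = pos, end = pos + nchar(dup_seq), mature = dup_seq,
      strand = "+", stringsAsFactors = FALSE)
  }
  list(genome = c(chr1 = bg), truth = do.call(rbind, truth))
}

add_errors <- function(s, rate) {
  if (rate <= 0) return(s)
  v <- strsplit(s, "", fixed = TRUE)[[1]]
  hit <- which(runif(length(v)) < rate)
  for (i in hit) v[i] <- sample(setdiff(DNA_BASES, v[i]), 1)
  paste(v, collapse = "")
}

#' Generate per-sample FASTQ-style reads from the truth table
#'
#' miRNA loci emit reads with a tight 5' start (1 - `p_start_shift`
#' exactly canonical), ragged 3' ends, non-templated A/U tails drawn from
#' `nta_probs`, and planted A-to-G edits at the configured fractions;
#' negative loci emit uniformly ragged fragments with no tail bias.  The
#' adapter is appended to every read and phred qualities are emitted.
#'
#' @param sim result of [make_genome()].
#' @param config the same [sim_config()].
#' @param abundance optional matrix (loci x samples) of expected read
#'   counts; defaults to draws around `reads_per_locus`.
#' @return list of per-sample lists with `sequence` and `quality`
#'   vectors, plus a `truth_reads` attribute is deliberately not kept
#'   (reads map back to loci by construction).
#' @export
make_reads <- function(sim, config = sim_config(), abundance = NULL) {
  set.seed(config$seed + 1L)
  truth <- sim$truth
  genome <- sim$genome[[1]]
  nl <- nrow(truth)
  ns <- config$n_samples
  if (is.null(abundance)) {
    abundance <- matrix(stats::rnbinom(nl * ns, mu = config$reads_per_locus,
                                       size = 5) + 1L, nl, ns)
  }
  ed <- config$editing_sites
  out <- vector("list", ns)
  end_shifts <- c(-2L, -1L, 0L, 1L, 2L)
  end_probs <- c(config$p_end_shift_each, config$p_end_shift_each,
                 1 - 4 * config$p_end_shift_each,
                 config$p_end_shift_each, config$p_end_shift_each)

  for (s in seq_len(ns)) {
    seqs <- character(0)
    for (li in seq_len(nl)) {
      n <- abundance[li, s]
      if (n <= 0) next
      cls <- truth$class[li]
      if (cls == "miRNA") {
        base <- truth$mature[li]
        L <- nchar(base)
        starts <- ifelse(runif(n) < config$p_start_shift,
                         sample(c(-1L, 1L), n, replace = TRUE), 0L)
        ends <- sample(end_shifts, n, replace = TRUE, prob = end_probs)
        # genomic context for templated shifts
        gs <- truth$start[li]
        reads <- vapply(seq_len(n), function(r) {
          a <- gs + starts[r]
          b <- gs + L + ends[r]
          substr(genome, a + 1L, b)
        }, character(1))
        # planted editing
        if (!is.null(ed)) {
          here <- ed[ed$locus == truth$locus[li], , drop = FALSE]
          for (e in seq_len(nrow(here))) {
            p <- here$position[e]
            hit <- runif(n) < here$fraction[e]
            rp <- p - starts                 # position within each read
            for (r in which(hit)) {
              if (rp[r] >= 1 && rp[r] <= nchar(reads[r]) &&
                  substr(reads[r], rp[r], rp[r]) == "A") {
                substr(reads[r], rp[r], rp[r]) <- "G"
              }
            }
          }
        }
        # non-templated tails
        tl <- sample(0:3, n, replace = TRUE, prob = config$nta_probs)
        for (r in which(tl > 0)) {
          tail_b <- sample(c("A", "T"), tl[r], replace = TRUE,
                           prob = c(config$nta_a_frac,
                                    1 - config$nta_a_frac))
          reads[r] <- paste0(reads[r], paste(tail_b, collapse = ""))
        }
      } else {
        # fragments around a processing hotspot with loose ends on BOTH
        # sides (real tRNA/snoRNA fragments pile up near a cleavage site
        # but lack the miRNA's tight 5' end), no tail bias
        span <- truth$end[li] - truth$start[li]
        hot <- sample.int(max(1L, span - 30L), 1L) - 1L
        off <- pmax(0L, pmin(span - 18L,
                             hot + sample(-4:4, n, replace = TRUE)))
        len <- pmin(sample(18:26, n, replace = TRUE), span - off)
        reads <- substring(truth$mature[li], off + 1L, off + len)
      }
      reads <- vapply(reads, add_errors, character(1),
                      rate = config$error_rate, USE.NAMES = FALSE)
      seqs <- c(seqs, paste0(reads, config$adapter))
    }
    qual <- vapply(nchar(seqs), function(L) {
      paste(rep("I", L), collapse = "")       # phred 40
    }, character(1))
    out[[s]] <- list(sequence = seqs, quality = qual)
  }
  names(out) <- paste0("sample", seq_len(ns))
  out
}

#' Write simulated reads as FASTQ files
#'
#' @param reads result of [make_reads()].
#' @param dir output directory.
#' @return character vector of file paths.
#' @export
write_sim_fastq <- function(reads, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(length(reads))
  for (s in seq_along(reads)) {
    path <- file.path(dir, paste0(names(reads)[s], ".fastq"))
    n <- length(reads[[s]]$sequence)
    lines <- character(4L * n)
    lines[seq(1, by = 4, length.out = n)] <-
      sprintf("@%s_read%06d", names(reads)[s], seq_len(n))
    lines[seq(2, by = 4, length.out = n)] <- reads[[s]]$sequence
    lines[seq(3, by = 4, length.out = n)] <- "+"
    lines[seq(4, by = 4, length.out = n)] <- reads[[s]]$quality
    writeLines(lines, path)
    paths[s] <- path
  }
  paths
}

#' Build annotation libraries from the truth table
#'
#' Mature miRNA and hairpin libraries come from the planted hairpins;
#' negative loci provide tRNA / snoRNA / ncRNA libraries so the cascade
#' has realistic competition.
#'
#' @param sim result of [make_genome()].
#' @param config the [sim_config()].
#' @return named list of `SequenceLibrary` objects.
#' @export
make_libraries <- function(sim, config = sim_config()) {
  truth <- sim$truth
  genome <- sim$genome[[1]]
  mir <- truth[truth$class == "miRNA", , drop = FALSE]
  hp_len <- 2L * config$mature_len + config$loop_len
  flank <- 8L                       # genomic flank kept in the precursor
  mat <- stats::setNames(mir$mature, paste0(mir$locus, "-5p"))
  hp <- stats::setNames(
    vapply(seq_len(nrow(mir)), function(i) {
      substr(genome, mir$start[i] + 1L - flank,
             mir$start[i] + hp_len + flank)
    }, character(1)),
    mir$locus)
  trna <- truth[truth$class == "tRNA_like", , drop = FALSE]
  sno <- truth[truth$class == "snoRNA_like", , drop = FALSE]
  frag <- truth[truth$class == "fragment_like", , drop = FALSE]
  libs <- list(
    mature_miRNA = new_library(mat, "mature_miRNA"),
    hairpin = new_library(hp, "hairpin"))
  if (nrow(sno)) {
    libs$snoRNA <- new_library(stats::setNames(sno$mature, sno$locus),
                               "snoRNA")
  }
  if (nrow(frag)) {
    libs$ncRNA <- new_library(stats::setNames(frag$mature, frag$locus),
                              "ncRNA")
  }
  if (nrow(trna)) {
    # library WITHOUT the genomic CCA: the CCA edit must restore it
    libs$tRNA_mature <- new_library(
      stats::setNames(substr(trna$mature, 1L, nchar(trna$mature) - 3L),
                      trna$locus), "tRNA_mature")
  }
  libs
}

#' Generate a labeled cluster dataset for model training
#'
#' Runs the generator end-to-end through cluster discovery (reads ->
#' collapse -> genome placement -> clusters -> features) and labels every
#' cluster by overlap of its stable range with the truth loci
#' (0-based half-open intervals).  Clusters overlapping no truth locus
#' are dropped and reported.
#'
#' @param config a [sim_config()]; use equal locus counts for a balanced
#'   dataset.
#' @param cluster_cfg a [cluster_config()].
#' @return list: `x` feature matrix, `y` logical labels (TRUE = miRNA),
#'   `clusters`, `dropped` (count of unlabeled clusters).
#' @export
make_labeled_clusters <- function(config = sim_config(),
                                  cluster_cfg = cluster_config()) {
  sim <- make_genome(config)
  reads <- make_reads(sim, config)
  pcfg <- preprocess_config(adapter = config$adapter)
  streams <- lapply(reads, function(r) {
    tr <- trim_adapter(r$sequence, r$quality, pcfg)
    tr$sequence[tr$status %in% c("trimmed", "untrimmed")]
  })
  ureads <- collapse_reads(streams, names(reads))
  disc <- discover_clusters(ureads, sim$genome, cluster_cfg)
  truth <- sim$truth
  labs <- rep(NA, length(disc$clusters))
  for (i in seq_along(disc$clusters)) {
    cl <- disc$clusters[[i]]
    # stable range in genome coordinates
    if (cl$strand == "+") {
      gs <- cl$start + cl$stable_start; ge <- cl$start + cl$stable_end
    } else {
      gs <- cl$end - cl$stable_end; ge <- cl$end - cl$stable_start
    }
    ov <- truth$chrom == cl$chrom & truth$start < ge & gs < truth$end
    if (!any(ov)) next
    labs[i] <- any(truth$class[ov] == "miRNA")
  }
  keep <- !is.na(labs)
  dropped <- sum(!keep)
  if (dropped > 0) {
    sk_log("labeled clusters: %d cluster(s) overlapped no truth locus",
           dropped)
  }
  list(x = disc$features[keep, , drop = FALSE],
       y = as.logical(labs[keep]),
       clusters = disc$clusters[keep], dropped = dropped,
       sim = sim)
}
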
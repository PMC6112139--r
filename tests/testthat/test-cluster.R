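mk_ureads <- function(seqs, counts = rep(1L, length(seqs))) {
  ur <- collapse_reads(list(rep(seqs, counts)), "s1")
  ur
}

test_that("genome placement finds all exact loci on both strands", {
  set.seed(51)
  bg <- paste(sample(c("A", "C", "G", "T"), 3000, TRUE), collapse = "")
  read <- substr(bg, 501, 522)
  genome <- c(chr1 = bg)
  pl <- map_unmapped_to_genome(mk_ureads(read), genome)
  expect_equal(nrow(pl), 1L)
  expect_equal(pl$start, 500L)
  expect_equal(pl$end, 522L)
  expect_equal(pl$strand, "+")

  # absent read: no placements
  expect_equal(nrow(map_unmapped_to_genome(
    mk_ureads("TTTTTTTTTTTTTTTTTTTTGACGT"), genome)), 0L)

  # planted at two loci (one as reverse complement)
  g2 <- c(chr1 = paste0(bg, read, substr(bg, 1, 100), rc(read)))
  pl2 <- map_unmapped_to_genome(mk_ureads(read), g2)
  expect_equal(nrow(pl2), 3L)                  # original + 2 planted
  expect_setequal(pl2$strand, c("+", "-"))
  # oracle: exhaustive scan of both strands
  n_fwd <- length(gregexpr(read, g2[[1]], fixed = TRUE)[[1]])
  n_rev <- length(gregexpr(rc(read), g2[[1]], fixed = TRUE)[[1]])
  expect_equal(nrow(pl2), n_fwd + n_rev)

  # repetitive reads are dropped
  rep20 <- paste(rep(read, 25), collapse = "")
  g3 <- c(chr1 = rep20)
  expect_equal(nrow(map_unmapped_to_genome(mk_ureads(read), g3)), 0L)
})

test_that("cluster merging is transitive and gap-bounded (union-find oracle)", {
  set.seed(52)
  bg <- paste(sample(c("A", "C", "G", "T"), 2000, TRUE), collapse = "")
  genome <- c(chr1 = bg)
  # overlapping reads -> one cluster
  r1 <- substr(bg, 101, 122); r2 <- substr(bg, 108, 130)
  cl <- build_clusters(map_unmapped_to_genome(mk_ureads(c(r1, r2)),
                                              genome), genome)
  expect_length(cl, 1L)
  expect_equal(cl[[1]]$start, 100L)
  expect_equal(cl[[1]]$end, 130L)
  expect_equal(cl[[1]]$assembled_sequence, substr(bg, 101, 130))

  # 50 nt apart -> two clusters
  r3 <- substr(bg, 301, 322); r4 <- substr(bg, 373, 394)
  cl2 <- build_clusters(map_unmapped_to_genome(mk_ureads(c(r3, r4)),
                                               genome), genome)
  expect_length(cl2, 2L)

  # chain A-B-C with pairwise gaps <= 10 merges transitively
  rA <- substr(bg, 601, 620); rB <- substr(bg, 629, 648)
  rC <- substr(bg, 657, 676)
  cl3 <- build_clusters(map_unmapped_to_genome(mk_ureads(c(rA, rB, rC)),
                                               genome), genome)
  # oracle: union-find on pairwise gap <= 10
  spans <- list(c(600, 620), c(628, 648), c(656, 676))
  parent <- 1:3
  findp <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in 1:2) for (j in (i + 1):3) {
    gap <- max(spans[[i]][1], spans[[j]][1]) -
      min(spans[[i]][2], spans[[j]][2])
    if (gap <= 10) {
      a <- findp(i); b <- findp(j); if (a != b) parent[max(a, b)] <- min(a, b)
    }
  }
  expect_length(cl3, length(unique(vapply(1:3, findp, integer(1)))))
  expect_length(cl3, 1L)
})

test_that("stable range matches hand-computed cases", {
  # all reads identical: whole span stable, no unstable flanks
  seqs <- paste(rep("ACGTA", 5), collapse = "")  # not used directly
  base <- "ACGTACGTACGTACGTACGTAC"               # 22 nt
  members <- data.frame(sequence = base, offset = 0L, length = 22L,
                        total = 10L, stringsAsFactors = FALSE)
  cl <- structure(list(chrom = "chr1", strand = "+", start = 0L, end = 22L,
                       assembled_sequence = base, members = members),
                  class = "ReadCluster")
  out <- compute_stable_range(cl)
  expect_equal(out$stable_start, 0L)
  expect_equal(out$stable_end, 22L)
  expect_equal(out$head_unstable_length, 0L)
  expect_equal(out$tail_unstable_length, 0L)

  # 9 reads at x, 1 read 2 nt earlier: the 2 leading positions have major
  # probability 0.9 "absent"... wait, 0.9 is the ABSENT share -> excluded
  span <- 24L
  asm <- paste0("GG", base)
  members2 <- data.frame(
    sequence = c(base, asm), offset = c(2L, 0L),
    length = c(22L, 24L), total = c(9L, 1L), stringsAsFactors = FALSE)
  cl2 <- structure(list(chrom = "chr1", strand = "+", start = 0L,
                        end = span, assembled_sequence = asm,
                        members = members2), class = "ReadCluster")
  out2 <- compute_stable_range(cl2)
  expect_equal(out2$stable_start, 2L)          # leading 2 are absent-major
  expect_equal(out2$stable_end, 24L)
  expect_equal(out2$head_unstable_length, 2L)

  # a position with major probability 0.79 is outside the stable range:
  # 79 reads with A, 21 with C at one position
  v1 <- base; v2 <- base
  substr(v2, 11, 11) <- setdiff(c("A", "C", "G", "T"),
                                substr(base, 11, 11))[1]
  members3 <- data.frame(sequence = c(v1, v2), offset = 0L, length = 22L,
                         total = c(79L, 21L), stringsAsFactors = FALSE)
  cl3 <- structure(list(chrom = "chr1", strand = "+", start = 0L,
                        end = 22L, assembled_sequence = base,
                        members = members3), class = "ReadCluster")
  out3 <- compute_stable_range(cl3)
  # longest stable run excludes position 10 (0-based); left run 0..9,
  # right run 11..21 -> right is longer (11 vs 10)
  expect_equal(out3$stable_start, 11L)
  expect_equal(out3$stable_end, 22L)

  # no position above threshold -> rejected
  many <- vapply(1:6, function(i) {
    paste(sample(c("A", "C", "G", "T"), 22, TRUE), collapse = "")
  }, character(1))
  members4 <- data.frame(sequence = many, offset = 0L, length = 22L,
                         total = 1L, stringsAsFactors = FALSE)
  cl4 <- structure(list(chrom = "chr1", strand = "+", start = 0L,
                        end = 22L, assembled_sequence = base,
                        members = members4), class = "ReadCluster")
  set.seed(1)
  out4 <- compute_stable_range(cl4)
  expect_equal(out4$rejected, "no_stable_range")
})

test_that("folding handles trivial and planted-stem cases", {
  f <- fold(paste(rep("A", 12), collapse = ""))
  expect_equal(f$structure, paste(rep(".", 12), collapse = ""))
  expect_equal(f$mfe, 0)
  expect_equal(f$n_pairs, 0L)

  f2 <- fold("GGGGGAAAACCCCC")
  expect_equal(f2$n_pairs, 5L)
  expect_equal(f2$n_pairs, oracle_max_pairs("GGGGGAAAACCCCC"))
  # exactly one hairpin loop
  st <- structure_stats(f2$structure, 0L, 5L)
  expect_equal(st$hairpin_count, 1L)

  expect_error(fold("ACGTZ"), "invalid")

  # balanced structure and min loop >= 3 on random sequences
  set.seed(61)
  for (i in 1:25) {
    s <- paste(sample(c("A", "C", "G", "T"), sample(10:40, 1), TRUE),
               collapse = "")
    f <- fold(s)
    v <- strsplit(f$structure, "")[[1]]
    expect_equal(sum(v == "("), sum(v == ")"))
    # minimum hairpin loop: no ( directly followed by ) within 3
    expect_false(grepl("\\(\\.{0,2}\\)", f$structure))
  }
})

test_that("structure_stats matches hand-parsed fixtures", {
  # "((((...))))" range = first 4 positions
  st <- structure_stats("((((...))))", 0L, 4L)
  expect_equal(st$hairpin_count, 1L)
  expect_equal(st$binding_count, 4L)
  expect_equal(st$count_bindings_in_miRNA, 4L)
  expect_equal(st$percentage_PairedInMiRNA, 1.0)
  expect_equal(st$interiorLoopCount, 0L)
  expect_equal(st$stem_length, 4L)
  expect_equal(st$armType, "5p")

  # symmetric 2x2 interior loop
  st2 <- structure_stats("(((..(((...)))..)))", 0L, 3L)
  expect_equal(st2$interiorLoopCount, 1L)
  expect_equal(st2$hairpin_count, 1L)
  expect_equal(st2$stem_length, 6L)

  # stable range fully inside the hairpin loop
  st3 <- structure_stats("((((....))))", 4L, 8L)
  expect_equal(st3$distanceToloop, 0L)
  expect_equal(st3$armType, "loop")

  # 3p arm
  st4 <- structure_stats("((((...))))", 7L, 11L)
  expect_equal(st4$armType, "3p")

  expect_error(structure_stats("((..)", 0L, 2L), "unbalanced")
})

test_that("structure_stats is mirror-symmetric on symmetric fixtures", {
  fixtures <- c("((((...))))", "(((..(((...)))..)))",
                "((((((....))))))", "((...((((...))))...))")
  for (db in fixtures) {
    n <- nchar(db)
    mirrored <- chartr("()", ")(",
                       paste(rev(strsplit(db, "")[[1]]), collapse = ""))
    a <- structure_stats(db, 0L, 4L)
    b <- structure_stats(mirrored, n - 4L, n)
    for (f in c("hairpin_count", "stem_length", "interiorLoopCount",
                "binding_count", "count_bindings_in_miRNA")) {
      expect_equal(a[[f]], b[[f]], info = paste(db, f))
    }
  }
})

test_that("precursor extraction identifies arm and pair_state", {
  # plant a clean hairpin; reads on the 5' arm only
  set.seed(62)
  arm <- "TGAGGTAGTAGGTTGTATAGTT"
  hp <- paste0(arm, "CTGTACAG", rc(arm))       # 8 nt loop: arms cluster
  bg1 <- paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")
  bg2 <- paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")
  genome <- c(chr1 = paste0(bg1, hp, bg2))
  ur <- mk_ureads(c(arm, substr(arm, 1, 20), substr(arm, 1, 21)),
                  c(20L, 3L, 5L))
  pl <- map_unmapped_to_genome(ur, genome)
  # a perfect inverted repeat also places the arm on the minus strand at
  # the partner arm; the plus-strand cluster is the one under test
  cls <- build_clusters(pl[pl$strand == "+", ], genome)
  expect_length(cls, 1L)
  cl <- compute_stable_range(cls[[1]])
  cl <- extract_precursor(cl, genome)
  expect_equal(cl$precursor$stats$armType, "5p")
  expect_false(cl$precursor$pair_state)
  expect_lt(cl$precursor$mfe, -10)

  # reads on both arms -> pair_state TRUE (partner arm stays a minority so
  # the 5' arm still clears the 0.8 majority threshold)
  ur2 <- mk_ureads(c(arm, substr(arm, 1, 21), rc(arm)),
                   c(40L, 4L, 6L))
  pl2 <- map_unmapped_to_genome(ur2, genome)
  # note: rc(arm) maps to the 3' arm of the SAME hairpin on + strand
  cls2 <- build_clusters(pl2[pl2$strand == "+", ], genome)
  expect_length(cls2, 1L)
  cl2 <- compute_stable_range(cls2[[1]])
  cl2 <- extract_precursor(cl2, genome)
  expect_true(cl2$precursor$pair_state)
})

test_that("compositional features follow the weighted-tally oracle", {
  # cluster on a known genome span; half the tail-extending reads (by
  # count) carry non-templated A at +1 where the genome base is G
  base <- "ACGTACGTACGTACGTACGTAC"             # 22 nt core
  genome <- c(chr1 = paste0("TTTTT", base, "GGGGG"))
  core <- base
  extA <- paste0(base, "A")                    # non-templated (genome: G)
  extG <- paste0(base, "G")                    # templated
  members <- data.frame(sequence = c(core, extA, extG),
                        offset = c(0L, 0L, 0L),
                        length = c(22L, 23L, 23L),
                        total = c(10L, 5L, 5L), stringsAsFactors = FALSE)
  cl <- structure(list(chrom = "chr1", strand = "+", start = 5L,
                       end = 28L,
                       assembled_sequence = substr(genome, 6, 28),
                       members = members), class = "ReadCluster")
  cl <- compute_stable_range(cl)
  expect_equal(cl$stable_start, 0L)
  expect_equal(cl$stable_end, 22L)
  feats <- compositional_features(cl, genome)
  expect_equal(feats$tail_plus1_A_percentage, 0.5)
  expect_equal(feats$tail_plus1_TemplateNucleotide_percentage, 0.5)
  expect_equal(feats$tail_plus1_G_percentage, 0.5)
  expect_equal(feats$covered_tail_plus1, 1)
  # +2 is covered by nobody
  expect_equal(feats$covered_tail_plus2, 0)
  expect_equal(feats$tail_plus2_A_percentage, 0)
  # head -1: genome T upstream, no coverage
  expect_equal(feats$covered_head_minus1, 0)
  expect_equal(feats$exactMatchRatio, 0.5)     # 10 of 20 reads match core
  expect_equal(feats$sequence_type_count, 3L)
  expect_equal(feats$total_read_count, 20L)

  # fully templated extension at +1 -> template percentage 1
  members2 <- members
  members2$sequence[2] <- extG
  cl2 <- cl; cl2$members <- members2
  feats2 <- compositional_features(cl2, genome)
  expect_equal(feats2$tail_plus1_TemplateNucleotide_percentage, 1.0)
  expect_equal(feats2$tail_plus1_A_percentage, 0)
})

test_that("candidate_filter applies the >=10 reads / >=3 sequences rule", {
  mk_cl <- function(n_reads, n_seqs) {
    seqs <- vapply(seq_len(n_seqs), function(i) {
      s <- "ACGTACGTACGTACGTACGTAC"
      substr(s, 1, 1) <- c("A", "C", "G", "T")[1 + (i %% 4)]
      s
    }, character(1))
    counts <- rep(n_reads %/% n_seqs, n_seqs)
    counts[1] <- counts[1] + n_reads - sum(counts)
    structure(list(chrom = "chr1", strand = "+", start = 0L, end = 22L,
                   assembled_sequence = "ACGTACGTACGTACGTACGTAC",
                   members = data.frame(sequence = seqs, offset = 0L,
                                        length = 22L, total = counts,
                                        stringsAsFactors = FALSE)),
              class = "ReadCluster")
  }
  res <- candidate_filter(list(mk_cl(9L, 4L), mk_cl(50L, 2L),
                               mk_cl(10L, 3L)))
  expect_length(res$pass, 1L)
  expect_equal(sum(res$pass[[1]]$members$total), 10L)
  expect_equal(res$rejected$reason, c("min_reads", "min_sequences"))
})

test_that("miRNA-like clusters separate from negatives as expected", {
  # generator-truth direction: miRNA clusters have higher mean
  # tail_plus1 A fraction and lower head instability than negatives
  cfg <- sim_config(seed = 23, genome_length = 60000, n_mirna_loci = 10,
                    n_negative_loci = 10, reads_per_locus = 80,
                    n_samples = 1)
  lab <- make_labeled_clusters(cfg)
  expect_gt(sum(lab$y), 5)
  expect_gt(sum(!lab$y), 5)
  x <- lab$x
  expect_gt(mean(x[lab$y, "tail_plus1_A_percentage"]),
            mean(x[!lab$y, "tail_plus1_A_percentage"]))
  expect_lt(mean(x[lab$y, "headUnstableLength"]),
            mean(x[!lab$y, "headUnstableLength"]))
  # feature sanity: percentages in [0,1], one-hot indicators consistent
  pct <- grep("percentage", colnames(x), value = TRUE)
  expect_true(all(x[, pct] >= 0 & x[, pct] <= 1))
  expect_true(all(rowSums(x[, c("armType_5p", "armType_3p",
                                "armType_loop")]) == 1))
  expect_true(all(rowSums(x[, c("pair_state_No", "pair_state_Yes")]) == 1))
})
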
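# toy cascade fixture: two miRNAs, their hairpin, one tRNA
toy_libs <- function() {
  m1 <- "TGAGGTAGTAGGTTGTATAGTT"
  m2 <- "ACCCGTAGATCCGAACTTGTGA"
  hp <- paste0("GGCGGG", m1, "CTGTACAGTT", rc(m1), "CCGCCC")
  trna <- "GCATTGGTGGTTCAGTGGTAGAATTCTCGCCTGCCACGCGGGAGGCCCGGGTTCGATTCCCGG"
  list(mature_miRNA = new_library(c(mirA = m1, mirB = m2), "mature_miRNA"),
       hairpin = new_library(c(hpA = hp), "hairpin"),
       tRNA_mature = add_cca_to_trnas(
         new_library(c(trna1 = trna), "tRNA_mature")))
}

test_that("cascade assigns exact, tRNA-CCA and isomiR reads correctly", {
  libs <- toy_libs()
  m1 <- libs$mature_miRNA$seqs[["mirA"]]
  trna_cca <- libs$tRNA_mature$seqs[["trna1"]]
  reads <- c(
    m1,                                        # exact mature
    substr(trna_cca, nchar(trna_cca) - 21L, nchar(trna_cca)),  # tRNA+CCA 3' fragment
    paste0(m1, "AA"))                          # miRNA + non-templated AA
  ur <- collapse_reads(list(reads), "s1")
  ann <- cascade_annotate(ur, libs)
  a <- ann$assignments
  expect_equal(nrow(ann$unmapped), 0L)

  exact <- a[a$sequence == m1, ]
  expect_equal(exact$library_kind, "mature_miRNA")
  expect_equal(exact$pass_type, "exact")

  trow <- a[a$library_kind == "tRNA_mature", ]
  expect_equal(nrow(trow), 1L)                 # never reaches isomiR pass
  expect_equal(trow$pass_type, "exact")

  iso <- a[a$sequence == paste0(m1, "AA"), ]
  expect_equal(iso$library_kind, "mature_miRNA")
  expect_equal(iso$pass_type, "isomir")
  expect_equal(iso$clip_3p, 2L)
  expect_equal(iso$offset_5p, 0L)
})

test_that("isomiR pass agrees with an exhaustive scan oracle", {
  libs <- toy_libs()
  mats <- libs$mature_miRNA$seqs
  # oracle: try every (target, offset, clip) combination explicitly
  oracle_assign <- function(read) {
    best <- NULL
    for (id in sort(names(mats))) {
      mat <- mats[[id]]
      for (d in -2:2) {
        lead <- max(0, -d)
        for (cl in 0:3) {
          core_to <- nchar(read) - cl
          core_len <- core_to - lead
          if (core_len < 14) next
          if (d + core_to > nchar(mat)) next
          rseg <- strsplit(substr(read, lead + 1, core_to), "")[[1]]
          mseg <- strsplit(substr(mat, d + lead + 1, d + core_to), "")[[1]]
          mm <- sum(rseg != mseg)
          if (mm <= 1) {
            score <- mm + cl + abs(d)
            if (is.null(best) || score < best$score) {
              best <- list(id = id, score = score)
            }
          }
        }
      }
    }
    best
  }
  set.seed(11)
  for (i in 1:40) {
    id <- sample(names(mats), 1)
    mat <- mats[[id]]
    read <- mat
    if (runif(1) < 0.5) {                      # mutate one internal base
      p <- sample(5:18, 1)
      substr(read, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                           substr(read, p, p)), 1)
    }
    if (runif(1) < 0.5) {                      # add a 3' tail
      read <- paste0(read, paste(sample(c("A", "T"), sample(1:3, 1), TRUE),
                                 collapse = ""))
    }
    ur <- collapse_reads(list(read), "s1")
    ann <- cascade_annotate(ur, list(libs$mature_miRNA))
    want <- oracle_assign(read)
    if (is.null(want)) {
      expect_equal(nrow(ann$assignments), 0L, info = read)
    } else {
      expect_equal(nrow(ann$assignments), 1L, info = read)
      expect_equal(ann$assignments$target_id, want$id, info = read)
    }
  }
})

test_that("every read ends up assigned or unmapped, exactly once", {
  libs <- toy_libs()
  set.seed(5)
  reads <- c(libs$mature_miRNA$seqs,
             vapply(1:20, function(i) {
               paste(sample(c("A", "C", "G", "T"), 22, TRUE), collapse = "")
             }, character(1)))
  ur <- collapse_reads(list(unname(reads)), "s1")
  ann <- cascade_annotate(ur, libs)
  expect_equal(nrow(ann$assignments) + nrow(ann$unmapped), nrow(ur))
  expect_length(intersect(ann$assignments$sequence,
                          ann$unmapped$sequence), 0)
  expect_equal(anyDuplicated(ann$assignments$sequence), 0L)
})

test_that("canonical_ratio_filter thresholds and validates", {
  rows <- data.frame(mirna_id = c("a", "b", "c"),
                     canonical.s1 = c(100L, 5L, 100L),
                     total.s1 = c(100L, 100L, 1000L),
                     canonical_ratio = c(1, 0.05, 0.1),
                     filtered = FALSE, stringsAsFactors = FALSE)
  attr(rows, "sample_ids") <- "s1"
  out <- canonical_ratio_filter(rows, 0.1)
  expect_false(out$filtered[1])
  expect_true(out$filtered[2])                 # 0.05 < 0.1
  expect_false(out$filtered[3])                # boundary kept
  expect_equal(out$total.s1[2], 0L)            # zeroed in primary table
  expect_equal(attr(out, "diagnostics")$total.s1[2], 100L)

  out2 <- canonical_ratio_filter(rows, 0.05)   # ratio 0.05 accepted now
  expect_false(out2$filtered[2])
  expect_error(canonical_ratio_filter(rows, 0.6), "0, 0.5")
  expect_error(canonical_ratio_filter(rows, -0.1), "0, 0.5")
})

test_that("compute_rpm normalizes to 1e6 over unfiltered miRNAs", {
  rows <- data.frame(mirna_id = c("a", "b"),
                     canonical.s1 = c(750000L, 250000L),
                     total.s1 = c(750000L, 250000L),
                     canonical_ratio = 1, filtered = FALSE,
                     stringsAsFactors = FALSE)
  attr(rows, "sample_ids") <- "s1"
  out <- compute_rpm(rows)
  expect_equal(out$rpm.s1, c(750000, 250000))
  expect_equal(sum(out$rpm.s1), 1e6)

  one <- rows[1, , drop = FALSE]
  attr(one, "sample_ids") <- "s1"
  expect_equal(compute_rpm(one)$rpm.s1, 1e6)

  zero <- rows
  zero$total.s1 <- 0L
  attr(zero, "sample_ids") <- "s1"
  expect_warning(z <- compute_rpm(zero), "zero")
  expect_equal(z$rpm.s1, c(0, 0))
})

test_that("planted composition is recovered within multinomial error", {
  # 100k reads drawn from a fixed per-miRNA composition, annotated, and
  # compared with a chi-squared goodness-of-fit test
  set.seed(21)
  mats <- vapply(1:6, function(i) {
    paste(sample(c("A", "C", "G", "T"), 22, TRUE), collapse = "")
  }, character(1))
  names(mats) <- sprintf("mir%02d", 1:6)
  prob <- c(0.4, 0.25, 0.15, 0.1, 0.07, 0.03)
  draws <- sample(names(mats), 1e5, TRUE, prob)
  ur <- collapse_reads(list(unname(mats[draws])), "s1")
  libs <- list(mature_miRNA = new_library(mats, "mature_miRNA"))
  ann <- cascade_annotate(ur, libs)
  rows <- summarize_mirna_counts(ann, ur)
  got <- rows$total.s1[match(names(mats), rows$mirna_id)]
  expect_equal(sum(got), 1e5)
  gof <- suppressWarnings(stats::chisq.test(got, p = prob))
  expect_gt(gof$p.value, 0.01)
})
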
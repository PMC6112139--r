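# direct tally world: one miRNA, reads with a planted A>G at position 5
edit_world <- function(n_a = 90L, n_g = 10L, n_c = 0L) {
  mat <- "TGCAATAGTAGGTTGTATAGTT"           # A at positions 4,5,7,16,19
  stopifnot(substr(mat, 5, 5) == "A")
  gread <- mat; substr(gread, 5, 5) <- "G"
  cread <- mat; substr(cread, 5, 5) <- "C"
  reads <- c(rep(mat, n_a), rep(gread, n_g), rep(cread, n_c))
  libs <- list(mature_miRNA = new_library(c(mirE = mat), "mature_miRNA"))
  ur <- collapse_reads(list(reads), "s1")
  ann <- cascade_annotate(ur, libs)
  list(mat = mat, libs = libs, ur = ur, ann = ann)
}

test_that("tally_sites counts A/G/other exactly, 3' tails excluded", {
  w <- edit_world(90L, 10L, 0L)
  sites <- tally_sites(w$ann, w$ur, w$libs$mature_miRNA)
  s5 <- sites[sites$position == 5L, ]
  expect_equal(s5$a_count, 90L)
  expect_equal(s5$g_count, 10L)
  expect_equal(s5$editing_fraction, 0.10)
  # all other A positions have zero G
  expect_true(all(sites$g_count[sites$position != 5L] == 0L))
  expect_true(all(sites$editing_fraction[sites$position != 5L] == 0))
  # coverage partition invariant
  expect_true(all(sites$a_count + sites$g_count + sites$other_count ==
                    sites$coverage))

  # non-A-G base increments other_count, fraction unaffected
  w2 <- edit_world(90L, 10L, 10L)
  s5b <- tally_sites(w2$ann, w2$ur, w2$libs$mature_miRNA)
  s5b <- s5b[s5b$position == 5L, ]
  expect_equal(s5b$other_count, 10L)
  expect_equal(s5b$editing_fraction, 0.10)

  # a 3' tail never contributes to coverage at internal positions
  tailed <- paste0(w$mat, "AAA")
  urt <- collapse_reads(list(c(w$mat, tailed)), "s1")
  annt <- cascade_annotate(urt, w$libs)
  st <- tally_sites(annt, urt, w$libs$mature_miRNA)
  expect_true(all(st$g_count == 0L))
})

test_that("the four exclusion criteria fire independently and composably", {
  mat <- "TGCAATAGTAGGTTGTATAGTT"
  gsw <- mat; substr(gsw, 5, 5) <- "G"
  probe <- substr(gsw, 1, nchar(gsw) - 2)
  set.seed(31)
  bgparts <- replicate(4, paste(sample(c("A", "C", "G", "T"), 200, TRUE),
                                collapse = ""))
  # genome with TWO copies of the switched-and-trimmed probe
  genome_multi <- c(chr1 = paste0(bgparts[1], probe, bgparts[2], probe,
                                  bgparts[3]))
  genome_clean <- c(chr1 = paste0(bgparts[1], mat, bgparts[3]))

  w <- edit_world(90L, 10L, 0L)
  sites <- tally_sites(w$ann, w$ur, w$libs$mature_miRNA)
  rows <- compute_rpm(canonical_ratio_filter(
    summarize_mirna_counts(w$ann, w$ur)))

  # clean fixture: nothing fires
  clean <- apply_exclusions(sites, editing_blacklists(), rows,
                            genome_clean, w$libs$mature_miRNA)
  expect_true(all(clean$excluded_by == ""))

  # criterion 1: blacklisted family/SNP site
  bl <- editing_blacklists(
    family_snp_sites = data.frame(mirna_id = "mirE", position = 5L))
  c1 <- apply_exclusions(sites, bl, rows, genome_clean,
                         w$libs$mature_miRNA)
  expect_match(c1$excluded_by[c1$position == 5L], "family_or_snp")
  expect_true(all(c1$excluded_by[c1$position != 5L] == ""))

  # criterion 2: repeat-element miRNA (every site of it)
  c2 <- apply_exclusions(sites, editing_blacklists(repeat_mirnas = "mirE"),
                         rows, genome_clean, w$libs$mature_miRNA)
  expect_true(all(grepl("repeat_element", c2$excluded_by)))

  # criterion 3: canonical RPM below 1
  lowrows <- rows
  lowrows$rpm.s1 <- 0.9
  lowrows$canonical_ratio <- 0.5               # canonical RPM 0.45 < 1
  attr(lowrows, "sample_ids") <- "s1"
  c3 <- apply_exclusions(sites, editing_blacklists(), lowrows,
                         genome_clean, w$libs$mature_miRNA)
  expect_true(all(grepl("low_canonical_rpm", c3$excluded_by)))

  # criterion 4: switched sequence (last 2 nt trimmed) at 2 genome loci
  c4 <- apply_exclusions(sites, editing_blacklists(), rows,
                         genome_multi, w$libs$mature_miRNA)
  expect_match(c4$excluded_by[c4$position == 5L], "multimapping")

  # composability: same excluded_by whether criteria co-fire or not
  both <- apply_exclusions(sites, bl, lowrows, genome_multi,
                           w$libs$mature_miRNA)
  s5 <- both[both$position == 5L, ]
  expect_setequal(strsplit(s5$excluded_by, ",")[[1]],
                  c("family_or_snp", "low_canonical_rpm", "multimapping"))
})

test_that("binomial significance matches a summation oracle", {
  w <- edit_world(450L, 50L, 0L)               # fraction 0.1, huge support
  sites <- tally_sites(w$ann, w$ur, w$libs$mature_miRNA)
  sites$excluded_by <- ""
  out <- test_significance(sites, error_rate = 0.001, alpha = 0.05,
                           min_fraction = 0.01)
  s5 <- out[out$position == 5L, ]
  expect_true(s5$significant)
  # oracle tail probability
  expect_equal(s5$p_value, oracle_binom_tail(50, 500, 0.001),
               tolerance = 1e-12)

  # zero G: p = 1, not significant
  s0 <- out[out$position == 4L, ]
  expect_equal(s0$p_value, 1)
  expect_false(s0$significant)

  # below the 1% floor: never significant no matter the coverage
  w2 <- edit_world(99100L, 900L, 0L)           # fraction 0.009
  st2 <- tally_sites(w2$ann, w2$ur, w2$libs$mature_miRNA)
  st2$excluded_by <- ""
  out2 <- test_significance(st2)
  expect_false(out2$significant[out2$position == 5L])

  # excluded sites are never significant
  sites2 <- sites
  sites2$excluded_by <- "repeat_element"
  out3 <- test_significance(sites2)
  expect_false(any(out3$significant))
})

test_that("planted editing fractions are recovered through the pipeline", {
  cfg0 <- sim_config(seed = 17, genome_length = 20000, n_mirna_loci = 2,
                     n_negative_loci = 2, reads_per_locus = 500,
                     n_samples = 1)
  sim <- make_genome(cfg0)
  # choose an A position away from both ends of the first mature
  mat <- sim$truth$mature[1]
  apos <- which(strsplit(substr(mat, 5, 18), "")[[1]] == "A")[1] + 4L
  expect_false(is.na(apos))                    # deterministic under seed 17
  cfg <- sim_config(seed = 17, genome_length = 20000, n_mirna_loci = 2,
                    n_negative_loci = 2, reads_per_locus = 500,
                    n_samples = 1,
                    editing_sites = data.frame(locus = "mir-001",
                                               position = apos,
                                               fraction = 0.1))
  reads <- make_reads(sim, cfg)
  libs <- make_libraries(sim, cfg)
  pcfg <- preprocess_config(adapter = cfg$adapter)
  tr <- trim_adapter(reads[[1]]$sequence, reads[[1]]$quality, pcfg)
  ur <- collapse_reads(list(tr$sequence[tr$status %in%
                                          c("trimmed", "untrimmed")]), "s1")
  ann <- cascade_annotate(ur, libs)
  sites <- tally_sites(ann, ur, libs$mature_miRNA, libs$hairpin)
  hit <- sites[sites$mirna_id == "mir-001-5p" & sites$position == apos, ]
  expect_equal(nrow(hit), 1L)
  ci <- stats::binom.test(hit$g_count, hit$a_count + hit$g_count,
                          0.1)$conf.int
  expect_gt(hit$editing_fraction, 0.05)
  expect_lt(hit$editing_fraction, 0.2)
})
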
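test_that("site codon assignment enforces frame and bounds", {
  # five_prime 0: A-site start 16, out of frame -> reject
  expect_true(is.na(assign_site_codon(0L, 300L, "A")))
  # five_prime 2: A start 18 -> codon 6; P start 15 -> 5; E start 12 -> 4
  expect_equal(assign_site_codon(2L, 300L, "A"), 6L)
  expect_equal(assign_site_codon(2L, 300L, "P"), 5L)
  expect_equal(assign_site_codon(2L, 300L, "E"), 4L)
  # site must lie fully within the sequence
  expect_true(is.na(assign_site_codon(2L, 20L, "A")))
})

test_that("A/P/E codons of an accepted read are consecutive", {
  set.seed(44)
  fp <- sample(0:500, 300, replace = TRUE)
  len <- 600L
  a <- assign_site_codon(fp, len, "A")
  p <- assign_site_codon(fp, len, "P")
  e <- assign_site_codon(fp, len, "E")
  acc <- !is.na(a) & !is.na(p) & !is.na(e)
  expect_gt(sum(acc), 0)
  expect_true(all(a[acc] - p[acc] == 1L))
  expect_true(all(p[acc] - e[acc] == 1L))
  # in-frame acceptance forces 5' ends congruent to 2 mod 3
  expect_true(all(fp[!is.na(a)] %% 3 == 2))
})

test_that("observed occupancy counts A-site codons over accepted reads", {
  cds <- c(tx1 = paste0("ATG", strrep("GGG", 5), "AAA", strrep("CCC", 5),
                        "TAA"))
  # A-site on codon 6 (AAA): five_prime = 3*6-16 = 2
  fp <- footprint_table(data.frame(transcript_id = "tx1",
                                   five_prime_pos = 2L,
                                   read_length = 28L))
  occ <- observed_occupancy(fp, cds, "A")
  expect_equal(occ$n_reads_used, 1L)
  expect_equal(occ$obs_freq[["AAA"]], 1)
  expect_equal(sum(occ$obs_counts), occ$n_reads_used)

  # all reads rejected: no crash, zero used
  bad <- footprint_table(data.frame(transcript_id = "tx1",
                                    five_prime_pos = 0L,
                                    read_length = 28L))
  occ0 <- observed_occupancy(bad, cds, "A")
  expect_equal(occ0$n_reads_used, 0L)
  expect_equal(occ0$n_reads_rejected, 1L)
})

test_that("expected frequencies are abundance-weighted codon usage", {
  cds <- c(g1 = random_cds(30, seed = 1),
           g2 = random_cds(40, seed = 2),
           g3 = random_cds(50, seed = 3))
  # single gene: expected equals that gene's usage
  fp1 <- footprint_table(data.frame(transcript_id = "g1",
                                    five_prime_pos = 2L,
                                    read_length = 28L))
  expect_equal(expected_frequencies(fp1, cds["g1"]),
               codon_frequencies(cds[["g1"]]), tolerance = 1e-12)

  # read weights 0.2 / 0.3 / 0.5: hand-computed weighted mean
  fp <- footprint_table(data.frame(
    transcript_id = rep(c("g1", "g2", "g3"), times = c(2L, 3L, 5L)),
    five_prime_pos = 2L, read_length = 28L))
  expd <- expected_frequencies(fp, cds)
  manual <- 0.2 * codon_frequencies(cds[["g1"]]) +
    0.3 * codon_frequencies(cds[["g2"]]) +
    0.5 * codon_frequencies(cds[["g3"]])
  expect_equal(expd, manual, tolerance = 1e-12)
  expect_equal(sum(expd), 1, tolerance = 1e-9)

  expect_error(expected_frequencies(
    footprint_table(data.frame(transcript_id = "g1", five_prime_pos = 0L,
                               read_length = 28L)), cds),
    "no accepted")
})

test_that("pause scores are observed/expected ratios with amino acid means", {
  occ <- structure(list(
    site = "A",
    obs_counts = setNames(rep(0L, 64), all_codons()),
    obs_freq = setNames(rep(0, 64), all_codons()),
    n_reads_used = 100L, n_reads_rejected = 0L), class = "SiteOccupancy")
  occ$obs_freq[["AAA"]] <- 0.02
  expd <- setNames(rep(1 / 64, 64), all_codons())
  expd[["AAA"]] <- 0.01
  expd[["AAG"]] <- 0  # zero expected -> NA
  ps <- pause_scores(occ, expd)
  expect_equal(ps$score[ps$codon == "AAA"], 2)
  expect_true(is.na(ps$score[ps$codon == "AAG"]))
  aa <- attr(ps, "aa_score")
  # Lys = {AAA, AAG}: NA member omitted from the mean
  expect_equal(aa$score[aa$amino_acid == "K"], 2)
})

test_that("dwell multipliers are recovered from simulated footprints", {
  cfg <- sim_config(n_transcripts = 150L, seed = 37L)
  sim <- simulate_transcriptome(cfg)
  fp <- simulate_footprints(sim$cds, sim$truth, 5e4, seed = 38L)
  occ <- observed_occupancy(fp, sim$cds, "A")
  expd <- expected_frequencies(fp, sim$cds)
  ps <- pause_scores(occ, expd)
  sense <- sense_codons()
  sc <- setNames(ps$score, ps$codon)[sense]
  d <- sim$truth$dwell_multipliers[sense]
  expect_gt(spearman_cor(sc, d), 0.9)
})

test_that("terminal pause inflation enriches stop codons at the A site", {
  cfg <- sim_config(n_transcripts = 60L, length_range = c(30L, 60L),
                    seed = 41L, utr3_nt = 30L, stop_dwell = 8)
  sim <- simulate_transcriptome(cfg)
  fp <- simulate_footprints(sim$cds, sim$truth, 4e4, seed = 42L)
  expd <- expected_frequencies(fp, sim$cds)
  ps_a <- pause_scores(observed_occupancy(fp, sim$cds, "A"), expd)
  ps_p <- pause_scores(observed_occupancy(fp, sim$cds, "P"), expd)
  stop_a <- ps_a$score[ps_a$codon %in% stop_codons()]
  stop_p <- ps_p$score[ps_p$codon %in% stop_codons()]
  expect_gt(mean(stop_a, na.rm = TRUE), mean(stop_p, na.rm = TRUE))
})

test_that("tertile grouping is deterministic with a 21/20/20 split", {
  set.seed(50)
  vals <- setNames(runif(61), sense_codons())
  g <- tertile_groups(vals)
  expect_equal(as.vector(table(g)[c("slow", "neutral", "fast")]),
               c(21L, 20L, 20L))
  # slowest group holds the largest values
  expect_true(min(vals[g == "slow"]) >= max(vals[g == "neutral"]))

  # order invariance
  g2 <- tertile_groups(vals[rev(names(vals))])
  expect_identical(as.character(g2[names(g)]), as.character(g))

  # all-equal values: lexicographic, deterministic
  eq <- setNames(rep(1, 61), sense_codons())
  ge <- tertile_groups(eq)
  expect_identical(names(ge)[ge == "slow"], sort(sense_codons())[1:21])
})
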
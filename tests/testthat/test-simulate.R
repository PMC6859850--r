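test_that("simulated CDSs are well-formed and truth invariants hold", {
  cfg <- sim_config(n_transcripts = 40L, length_range = c(15L, 60L),
                    seed = 21L)
  sim <- simulate_transcriptome(cfg)
  lens <- nchar(sim$cds)
  expect_true(all(lens %% 3 == 0))
  expect_true(all(lens / 3 >= 15 & lens / 3 <= 60))
  expect_true(all(startsWith(sim$cds, "ATG")))
  for (s in sim$cds) {
    cods <- substring(s, seq(1, nchar(s) - 2, 3), seq(3, nchar(s), 3))
    expect_true(cods[length(cods)] %in% stop_codons())
    expect_false(any(cods[-length(cods)] %in% stop_codons()))
  }
  truth <- sim$truth
  expect_true(all(truth$k_true > 0))
  expect_equal(sum(truth$abundance), 1, tolerance = 1e-9)
  expect_true(all(truth$dwell_multipliers > 0))
  expect_setequal(names(truth$codon_weights), sense_codons())
  expect_true(all(sense_codons() %in% names(truth$dwell_multipliers)))
})

test_that("identical seeds give identical outputs; configs validate", {
  cfg <- sim_config(n_transcripts = 25L, length_range = c(12L, 30L),
                    seed = 5L)
  a <- simulate_transcriptome(cfg)
  b <- simulate_transcriptome(cfg)
  expect_identical(a$cds, b$cds)
  expect_identical(a$truth, b$truth)
  expect_identical(simulate_timecourse(a$truth, cfg)$counts,
                   simulate_timecourse(b$truth, cfg)$counts)
  expect_identical(
    as.data.frame(simulate_footprints(a$cds, a$truth, 500, seed = 3)),
    as.data.frame(simulate_footprints(b$cds, b$truth, 500, seed = 3)))

  expect_error(sim_config(length_range = c(5L, 30L)), ">= 10 codons")
  expect_error(sim_config(timepoints = c(2, 1)), "strictly increasing")
  expect_error(sim_config(timepoints = c(-1, 2)), "strictly increasing")
})

test_that("beta = 0 with auto noise gives equal decay constants", {
  cfg <- sim_config(n_transcripts = 30L, length_range = c(12L, 30L),
                    beta = 0, seed = 2L)
  truth <- simulate_transcriptome(cfg)$truth
  expect_equal(max(truth$k_true) - min(truth$k_true), 0, tolerance = 1e-12)
})

test_that("codon composition couples to log k at the configured strength", {
  # ~50% explained variance <=> |Spearman| between the codon score and
  # log k near sqrt(0.5) ~ 0.7, negative for stabilizing weights
  cfg <- sim_config(n_transcripts = 500L, seed = 11L)
  truth <- simulate_transcriptome(cfg)$truth
  r <- oracle_spearman(truth$codon_score, log(truth$k_true))
  expect_lt(r, -0.6)
  expect_gt(r, -0.8)
})

test_that("noise-free time courses follow bounded growth exactly", {
  cfg <- sim_config(n_transcripts = 12L, length_range = c(12L, 30L),
                    noise_model = "none", seed = 8L,
                    timepoints = c(1, 2, 4, 8, 12, 24))
  sim <- simulate_transcriptome(cfg)
  truth <- sim$truth
  tc <- simulate_timecourse(truth, cfg)

  # saturation: fast decay reaches y_eq at the last time point
  truth2 <- truth
  truth2$k_true <- rep(5, length(truth$k_true))
  tc2 <- simulate_timecourse(truth2, cfg)
  expect_equal(unname(tc2$counts[truth$transcript_id, "t24h"]),
               unname(truth$y_eq_true), tolerance = 1e-9)

  # half-saturation at t = ln(2)/k
  cfg3 <- sim_config(n_transcripts = 12L, length_range = c(12L, 30L),
                     noise_model = "none", seed = 8L,
                     timepoints = c(log(2) / 0.25, 10, 20))
  truth3 <- truth
  truth3$k_true <- rep(0.25, length(truth$k_true))
  tc3 <- simulate_timecourse(truth3, cfg3)
  expect_equal(unname(tc3$counts[truth$transcript_id, 1]),
               unname(truth$y_eq_true) / 2, tolerance = 1e-9)

  # spike rows have constant totals across samples
  spikes <- grep("^spike_dmel", rownames(tc$counts), value = TRUE)
  tot <- colSums(tc$counts[spikes, ])
  expect_equal(max(tot) - min(tot), 0, tolerance = 1e-9)
})

test_that("poisson counts match the generating means in both moments", {
  cfg <- sim_config(n_transcripts = 2000L, length_range = c(12L, 25L),
                    noise_model = "poisson", seed = 13L, median_y_eq = 200)
  sim <- simulate_transcriptome(cfg)
  truth <- sim$truth
  tc <- simulate_timecourse(truth, cfg)
  tps <- cfg$timepoints
  mu <- outer(truth$y_eq_true, tps,
              function(y, t) y * (1 - exp(-truth$k_true * t)))
  obs <- tc$counts[truth$transcript_id, ]
  # standardized residuals (x - mu)/sqrt(mu): mean ~ 0, var ~ 1
  keep <- mu > 5
  z <- (obs[keep] - mu[keep]) / sqrt(mu[keep])
  expect_lt(abs(mean(z)), 0.05)
  expect_lt(abs(var(z) - 1), 0.1)
})

test_that("footprint A-site sampling follows abundance and dwell", {
  # uniform dwell: occupancy tracks abundance-weighted codon usage
  # (UTR flanks make boundary codons observable, see the methods vignette)
  cfg <- sim_config(n_transcripts = 30L, length_range = c(50L, 80L),
                    seed = 17L, dwell_range = c(1, 1), stop_dwell = 1,
                    utr5_nt = 18L, utr3_nt = 18L)
  sim <- simulate_transcriptome(cfg)
  fp <- simulate_footprints(sim$cds, sim$truth, 4e4, seed = 18L)
  expect_true(all(fp$five_prime_pos + fp$read_length <=
                    nchar(sim$cds)[fp$transcript_id]))
  occ <- observed_occupancy(fp, sim$cds, "A")
  expd <- expected_frequencies(fp, sim$cds)
  sense <- sense_codons()
  big <- sense[occ$obs_counts[sense] >= 200]
  ratio <- occ$obs_freq[big] / expd[big]
  expect_true(all(abs(ratio - 1) < 0.25))

  # a single inflated dwell codon dominates the A site; AAA placed well
  # inside the ORF so every occurrence is reachable
  one <- c(tx1 = paste0("ATG", strrep("GGG", 10), strrep("AAA", 3),
                        strrep("CCC", 20), "TAA"))
  truth1 <- sim$truth
  truth1$transcript_id <- "tx1"
  truth1$abundance <- 1
  truth1$dwell_multipliers[] <- 1
  truth1$dwell_multipliers["AAA"] <- 10
  fp1 <- simulate_footprints(one, truth1, 5000, seed = 19L)
  occ1 <- observed_occupancy(fp1, one, "A")
  f_aaa <- codon_frequencies(one[[1]])[["AAA"]]
  expect_gt(occ1$obs_freq[["AAA"]], 2 * f_aaa)
})
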
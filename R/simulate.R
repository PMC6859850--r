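#' Simulation configuration
#'
#' Bundles and validates the parameters of the synthetic study: transcript
#' count, CDS length range, labeling time points, sequencing depth, count
#' noise model, and the effect size coupling codon composition to the decay
#' constant.
#'
#' The generative model for decay is linear on the log decay constant:
#' `log k_i = alpha + beta * sum_c f_i(c) w_c + eps_i`, where `f_i(c)` is
#' the frequency of codon `c` in transcript `i`, `w_c` is a latent
#' per-codon stability weight, and `eps_i` is Gaussian residual noise.
#' Negative `beta` makes high-weight (stabilizing) codons lower the decay
#' constant.  With `eps_sd = "auto"` the residual standard deviation is set
#' equal to the standard deviation of the codon term, so the codon
#' composition explains ~50% of the variance of `log k`.
#'
#' @param n_transcripts Number of transcripts to simulate.
#' @param length_range Integer vector of length 2: min and max CDS length in
#'   codons (including start and stop); min must be >= 10.
#' @param timepoints Labeling time points in hours, strictly increasing.
#' @param depth Expected total human-transcript counts per sample at
#'   steady-state saturation.
#' @param noise_model `"none"` (counts are exact expectations, real-valued)
#'   or `"poisson"`.
#' @param beta Effect size coupling codon composition to `log k`.
#' @param eps_sd Residual SD of `log k`; `"auto"` = `|beta| * sd(codon
#'   term)` (50% explained variance), or a non-negative number.
#' @param alpha Mean of `log k` (natural log of 1/h); the default places
#'   the median half-life at 8 h.
#' @param seed Integer seed; all generator randomness derives from it.
#' @param dirichlet_conc Total concentration of the per-transcript
#'   Dirichlet perturbation of global codon usage (smaller = more variable
#'   usage across transcripts).
#' @param spike_frac Spike-in read fraction per sample (labeled
#'   *D. melanogaster* spike; an unlabeled *S. cerevisiae* QC spike is
#'   emitted too but unused downstream).
#' @param median_y_eq If non-`NULL`, rescale steady-state expectations so
#'   their median equals this value (overrides `depth` scaling).
#' @param dwell_range Range of the log-uniform distribution of codon dwell
#'   multipliers.
#' @param stop_dwell Dwell multiplier assigned to stop codons (terminal
#'   pause).
#' @param utr5_nt,utr3_nt Lengths (nt, multiples of 3) of untranslated
#'   flanks around the ORF.  Footprints extend beyond the ORF boundaries in
#'   real data; without flanks, codons near the start (A site cannot reach
#'   the first 6 codons) and the stop codon are unobservable, which
#'   systematically deflates their occupancy scores.
#' @return A validated list of class `SimulationConfig`.
#' @export
sim_config <- function(n_transcripts = 500L,
                       length_range = c(100L, 500L),
                       timepoints = c(1, 2, 4, 8, 12, 24),
                       depth = 1e6,
                       noise_model = c("poisson", "none"),
                       beta = -2,
                       eps_sd = "auto",
                       alpha = log(log(2) / 8),
                       seed = 1L,
                       dirichlet_conc = 30,
                       spike_frac = 0.1,
                       median_y_eq = NULL,
                       dwell_range = c(0.5, 2),
                       stop_dwell = 2,
                       utr5_nt = 0L,
                       utr3_nt = 0L) {
  noise_model <- match.arg(noise_model)
  stopifnot(n_transcripts >= 1, length(length_range) == 2,
            length_range[1] <= length_range[2],
            depth > 0, dirichlet_conc > 0,
            spike_frac > 0, spike_frac < 1,
            length(dwell_range) == 2, all(dwell_range > 0),
            stop_dwell > 0, utr3_nt >= 0, utr3_nt %% 3 == 0,
            utr5_nt >= 0, utr5_nt %% 3 == 0)
  if (length_range[1] < 10) {
    stop("length_range minimum must be >= 10 codons")
  }
  if (any(timepoints <= 0) || any(diff(timepoints) <= 0)) {
    stop("timepoints must be strictly increasing and positive")
  }
  if (!identical(eps_sd, "auto") && (!is.numeric(eps_sd) || eps_sd < 0)) {
    stop("eps_sd must be \"auto\" or a non-negative number")
  }
  structure(
    list(n_transcripts = as.integer(n_transcripts),
         length_range = as.integer(length_range),
         timepoints = as.numeric(timepoints),
         depth = depth, noise_model = noise_model,
         beta = beta, eps_sd = eps_sd, alpha = alpha,
         seed = as.integer(seed), dirichlet_conc = dirichlet_conc,
         spike_frac = spike_frac, median_y_eq = median_y_eq,
         dwell_range = as.numeric(dwell_range), stop_dwell = stop_dwell,
         utr5_nt = as.integer(utr5_nt), utr3_nt = as.integer(utr3_nt)),
    class = "SimulationConfig"
  )
}

#' Simulate a synthetic transcriptome with known decay ground truth
#'
#' Generates CDS sequences (ATG start, single terminal stop, no internal
#' in-frame stop) whose codon usage varies across transcripts via a
#' Dirichlet perturbation of a uniform global usage, then draws
#' per-transcript decay constants from the linear model described in
#' [sim_config()].  Latent per-codon stability weights and A-site dwell
#' multipliers are drawn once and stored in the truth object.
#'
#' @param config A [sim_config()] object.
#' @return List with elements `cds` (named character vector of transcript
#'   records; with `utr5_nt` / `utr3_nt` > 0 each record carries that much
#'   random in-frame untranslated flank around the ORF; attribute `cds_nt`
#'   records the ORF lengths and `utr5_nt` the common 5' flank) and
#'   `truth` (class `SyntheticTruth`: per-transcript
#'   `k_true` in 1/h stored as magnitude, `y_eq_true`, `abundance` summing
#'   to 1, `pool_label`, plus `codon_weights` and `dwell_multipliers`
#'   per codon).
#' @export
simulate_transcriptome <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed)
  n <- config$n_transcripts
  sense <- sense_codons()
  stops <- stop_codons()

  # latent per-codon truth
  w <- rnorm(length(sense))
  w <- w - mean(w)
  codon_weights <- setNames(w, sense)
  dwell <- exp(runif(length(sense), log(config$dwell_range[1]),
                     log(config$dwell_range[2])))
  dwell_multipliers <- c(setNames(dwell, sense),
                         setNames(rep(config$stop_dwell, 3), stops))

  base_usage <- rep(1 / length(sense), length(sense))
  lens <- sample(seq(config$length_range[1], config$length_range[2]),
                 n, replace = TRUE)
  ids <- sprintf("tx%04d", seq_len(n))

  rand_nt <- function(k) {
    if (k <= 0) return("")
    paste(sample(c("A", "C", "G", "T"), k, replace = TRUE), collapse = "")
  }
  cds <- character(n)
  for (i in seq_len(n)) {
    p <- rgamma(length(sense), shape = config$dirichlet_conc * base_usage)
    p <- p / sum(p)
    body <- sample(sense, lens[i] - 2L, replace = TRUE, prob = p)
    cds[i] <- paste0(rand_nt(config$utr5_nt),
                     "ATG", paste(body, collapse = ""),
                     sample(stops, 1L), rand_nt(config$utr3_nt))
  }
  names(cds) <- ids
  cds_nt <- lens * 3L

  # codon-composition score over the ORF proper
  fm <- codon_frequency_matrix(
    substring(cds, config$utr5_nt + 1L, config$utr5_nt + cds_nt))
  s <- as.vector(fm[, sense, drop = FALSE] %*% codon_weights[sense])

  eps_sd <- if (identical(config$eps_sd, "auto")) {
    abs(config$beta) * stats::sd(s)
  } else config$eps_sd
  if (!is.finite(eps_sd)) eps_sd <- 0
  log_k <- config$alpha + config$beta * s + rnorm(n, sd = eps_sd)
  k_true <- exp(log_k)

  abundance <- rlnorm(n, meanlog = 0, sdlog = 1)
  abundance <- abundance / sum(abundance)
  y_eq <- abundance * config$depth
  if (!is.null(config$median_y_eq)) {
    y_eq <- y_eq * config$median_y_eq / stats::median(y_eq)
  }

  pool_label <- sample(c("pool_A", "pool_B", "none"), n, replace = TRUE,
                       prob = c(0.45, 0.45, 0.10))

  truth <- structure(
    list(transcript_id = ids, k_true = k_true, y_eq_true = y_eq,
         abundance = abundance, pool_label = pool_label,
         codon_weights = codon_weights,
         dwell_multipliers = dwell_multipliers,
         codon_score = setNames(s, ids), eps_sd = eps_sd),
    class = "SyntheticTruth"
  )
  attr(cds, "cds_nt") <- setNames(cds_nt, ids)
  attr(cds, "utr5_nt") <- config$utr5_nt
  list(cds = cds, truth = truth)
}

#' Simulate a 4SU approach-to-equilibrium labeling time course
#'
#' Expected labeled counts follow bounded growth,
#' `mu_i(t) = y_eq_i * (1 - exp(-k_i t))`, per transcript and time point.
#' Labeled fly spike-in rows (`spike_dmel|*`) and unlabeled yeast QC rows
#' (`spike_scer|*`) are emitted with constant expected totals per sample
#' (`spike_frac` and `spike_frac / 5` of `depth` respectively).  With
#' `noise_model = "poisson"` counts are Poisson draws around the
#' expectations; with `"none"` the expectations themselves (real-valued)
#' are returned so that downstream fits can be checked at solver precision.
#'
#' @param truth `SyntheticTruth` from [simulate_transcriptome()].
#' @param config The same [sim_config()].
#' @return A [timecourse_counts()] object with one sample per time point
#'   (sample ids `t<hours>h`, cell line `"sim"`).
#' @export
simulate_timecourse <- function(truth, config) {
  stopifnot(inherits(truth, "SyntheticTruth"),
            inherits(config, "SimulationConfig"))
  set.seed(config$seed + 1L)
  tps <- config$timepoints
  mu <- outer(truth$y_eq_true, tps,
              function(yeq, t) yeq * (1 - exp(-truth$k_true * t)))
  # constant-fraction spikes, split over a few rows each
  n_dmel <- 10L; n_scer <- 5L
  dmel <- matrix(config$spike_frac * config$depth / n_dmel,
                 nrow = n_dmel, ncol = length(tps))
  scer <- matrix(config$spike_frac * config$depth / 5 / n_scer,
                 nrow = n_scer, ncol = length(tps))
  m <- rbind(mu, dmel, scer)
  rownames(m) <- c(truth$transcript_id,
                   sprintf("spike_dmel|%02d", seq_len(n_dmel)),
                   sprintf("spike_scer|%02d", seq_len(n_scer)))
  colnames(m) <- sprintf("t%gh", tps)
  if (config$noise_model == "poisson") {
    m[] <- rpois(length(m), lambda = m)
  }
  sm <- data.frame(sample_id = colnames(m), cell_line = "sim",
                   timepoint_h = as.character(tps), treatment = "none")
  timecourse_counts(m, sm, allow_fractional = config$noise_model == "none")
}

#' Simulate ribosome footprint reads with codon-specific dwell times
#'
#' A-site codon positions are sampled with probability proportional to
#' `abundance_g * d_c` (transcript abundance times the dwell multiplier of
#' the codon at that position), mimicking steady-state ribosome density.
#' Read lengths are drawn uniformly from 28--30 nt and the read 5' end is
#' placed so the sampled codon occupies read positions 17--19 (1-based).
#' Sampled reads that cannot be placed within the record (5' end before the
#' start, or 3' end past the record) are skipped; the skip count is kept in
#' `attr(, "n_skipped")`.
#'
#' @param cds Named character vector of transcript sequences (from
#'   [simulate_transcriptome()]).
#' @param truth Matching `SyntheticTruth`.
#' @param n_reads Number of reads to attempt.
#' @param seed Integer seed.
#' @return A [footprint_table()] with attribute `n_skipped`.
#' @export
simulate_footprints <- function(cds, truth, n_reads, seed = 1L) {
  stopifnot(n_reads > 0, inherits(truth, "SyntheticTruth"))
  set.seed(seed)
  cds_nt <- attr(cds, "cds_nt")
  if (is.null(cds_nt)) cds_nt <- setNames(nchar(cds), names(cds))
  utr5 <- attr(cds, "utr5_nt") %||% 0L

  # enumerate (transcript, A-site codon) pairs over real ORF codons
  ids <- names(cds)
  per_tx <- lapply(seq_along(ids), function(i) {
    cods <- split_codons(substring(cds[i], utr5 + 1L, utr5 + cds_nt[i]))
    j <- seq_along(cods) - 1L                  # 0-based codon index
    wt <- truth$abundance[match(ids[i], truth$transcript_id)] *
      truth$dwell_multipliers[cods]
    wt[is.na(wt)] <- 0
    data.frame(transcript_id = ids[i], codon_index = j,
               weight = unname(wt))
  })
  tab <- do.call(rbind, per_tx)
  tab <- tab[tab$weight > 0, , drop = FALSE]

  pick <- sample.int(nrow(tab), n_reads, replace = TRUE, prob = tab$weight)
  read_len <- sample(28:30, n_reads, replace = TRUE)
  five_prime <- utr5 + 3L * tab$codon_index[pick] - 16L
  tx <- tab$transcript_id[pick]
  total_len <- nchar(cds)[match(tx, ids)]
  ok <- five_prime >= 0L & five_prime + read_len <= total_len
  fp <- data.frame(transcript_id = tx[ok],
                   five_prime_pos = five_prime[ok],
                   read_length = read_len[ok])
  out <- footprint_table(fp)
  attr(out, "n_skipped") <- sum(!ok)
  out
}

#' Simulate steady-state libraries for two ORFeome pool cell lines
#'
#' Plants a known classification design: transcripts labeled `pool_A` /
#' `pool_B` in the truth are expressed at `y_eq` in their own line and at a
#' small leakage fraction in the paired line; `none` transcripts
#' (endogenous) are expressed equally in both.  A fraction `fail_frac` of
#' pooled transcripts is planted to fail the threefold enrichment rule
#' (leakage raised above 1/3), so classification exactness can be checked
#' against `expected_label`.
#'
#' @param truth `SyntheticTruth`.
#' @param config [sim_config()]; `noise_model = "none"` gives exact planted
#'   expectations.
#' @param leak_frac Paired-line leakage for passing transcripts.
#' @param fail_frac Fraction of pooled transcripts planted to fail.
#' @return List: `counts` (matrix, transcripts x `c("line_A", "line_B")`),
#'   `expected_label` (data.frame transcript_id, cell_line, label).
#' @export
simulate_steady_state <- function(truth, config, leak_frac = 0.05,
                                  fail_frac = 0.2) {
  stopifnot(inherits(truth, "SyntheticTruth"))
  set.seed(config$seed + 2L)
  n <- length(truth$transcript_id)
  pooled <- truth$pool_label != "none"
  fails <- pooled & runif(n) < fail_frac
  leak <- ifelse(fails, 0.6, leak_frac)

  own <- truth$y_eq_true
  a <- ifelse(truth$pool_label == "pool_A", own,
              ifelse(truth$pool_label == "pool_B", own * leak, own))
  b <- ifelse(truth$pool_label == "pool_B", own,
              ifelse(truth$pool_label == "pool_A", own * leak, own))
  m <- cbind(line_A = a, line_B = b)
  rownames(m) <- truth$transcript_id
  if (config$noise_model == "poisson") m[] <- rpois(length(m), m)

  # expected labels from the planted design, on the classifier's
  # library-size-normalized scale (noise-free expectations)
  mn <- library_size_normalize(cbind(line_A = a, line_B = b))
  lab_for <- function(self, paired, pool) {
    ifelse(!pool, "endogenous",
           ifelse(self > 3 * paired & self > 4, "orfeome", "excluded"))
  }
  el <- rbind(
    data.frame(transcript_id = truth$transcript_id, cell_line = "line_A",
               label = lab_for(mn[, 1], mn[, 2], truth$pool_label == "pool_A")),
    data.frame(transcript_id = truth$transcript_id, cell_line = "line_B",
               label = lab_for(mn[, 2], mn[, 1], truth$pool_label == "pool_B"))
  )
  list(counts = m, expected_label = el)
}
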
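# shared fixture builders (all fixtures are generated in code)

# brute-force Spearman oracle: average ranks computed by counting, Pearson
# on ranks evaluated from the definition -- independent of cor()
oracle_spearman <- function(x, y) {
  rk <- function(v) {
    vapply(v, function(vi) sum(v < vi) + (1 + sum(v == vi)) / 2, numeric(1))
  }
  rx <- rk(x); ry <- rk(y)
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

# exact bounded-growth series
bounded_growth <- function(yeq, k, tps) yeq * (1 - exp(k * tps))

# tiny validated time course with spike rows
toy_timecourse <- function(counts, tps = c(1, 2, 4, 8, 12, 24),
                           spike = 50) {
  m <- rbind(counts,
             `spike_dmel|01` = rep(spike, length(tps)),
             `spike_scer|01` = rep(10, length(tps)))
  colnames(m) <- sprintf("t%gh", tps)
  sm <- data.frame(sample_id = colnames(m), cell_line = "toy",
                   timepoint_h = as.character(tps), treatment = "none")
  timecourse_counts(m, sm)
}

# random CDS: ATG + n-2 sense codons + stop
random_cds <- function(n_codons, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste0("ATG",
         paste(sample(sense_codons(), n_codons - 2L, replace = TRUE),
               collapse = ""),
         sample(stop_codons(), 1L))
}
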
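#' Spike-in normalization
#'
#' Divides every transcript's count in each sample by the total of the
#' labeled *D. melanogaster* spike-in rows (`spike_dmel|*`) of that sample,
#' making time points comparable when the spike is added in fixed
#' proportion.  Spike rows (fly and yeast) are excluded from the output.
#'
#' @param tc A [timecourse_counts()] object with at least one `spike_dmel|`
#'   row.
#' @return Numeric matrix of normalized counts, human transcripts x
#'   samples.
#' @export
spike_normalize <- function(tc) {
  stopifnot(inherits(tc, "TimeCourseCounts"))
  dmel <- grep("^spike_dmel\\|", rownames(tc$counts), value = TRUE)
  if (length(dmel) == 0L) stop("no spike_dmel| rows present")
  spike_tot <- colSums(tc$counts[dmel, , drop = FALSE])
  zero <- spike_tot <= 0
  if (any(zero)) {
    stop("zero dmel spike total in sample(s): ",
         paste(names(spike_tot)[zero], collapse = ", "))
  }
  human <- setdiff(rownames(tc$counts), tc$spike_rows)
  sweep(tc$counts[human, , drop = FALSE], 2L, spike_tot, "/")
}

#' Minimum-coverage filter for half-life estimation
#'
#' Applied to raw (pre-normalization) counts of human transcripts: a
#' transcript is kept iff it has at least `min_each` read at every time
#' point and at least `min_any` reads at some time point.
#'
#' @param tc A [timecourse_counts()] object; spike rows are ignored.
#' @param min_each Minimum count required at every time point (default 1).
#' @param min_any Minimum count required at at least one time point
#'   (default 5).
#' @return List with character vectors `kept` and `dropped`.
#' @export
filter_timecourse <- function(tc, min_each = 1, min_any = 5) {
  stopifnot(inherits(tc, "TimeCourseCounts"))
  human <- setdiff(rownames(tc$counts), tc$spike_rows)
  m <- tc$counts[human, , drop = FALSE]
  keep <- apply(m, 1L, min) >= min_each & apply(m, 1L, max) >= min_any
  list(kept = human[keep], dropped = human[!keep])
}

#' Fit the bounded-growth labeling model to one time course
#'
#' Fits `y(t) = y_eq * (1 - exp(k t))` to spike-normalized labeled counts
#' by weighted nonlinear least squares (weights `1 / y(t)`), with start
#' values `y_eq = max(y)`, `k = -0.5`, and box constraints
#' `y_eq in [0, Inf)`, `k in (-Inf, 0]` (port algorithm).  `k` is reported
#' with its non-positive sign; the half-life is `ln(2) / |k|`.
#' Non-convergence — solver failure, or a fitted `k` at the zero bound
#' (`k >= -1e-9`) — yields `converged = FALSE` and `half_life = NA`.
#'
#' Weights `1/y` are undefined at zero, so series containing non-positive
#' values are rejected; the upstream raw-count filter
#' ([filter_timecourse()]) guarantees positivity on real data.
#'
#' @param times Time points in hours, strictly increasing, length >= 3.
#' @param y Normalized counts at `times`, all > 0.
#' @param transcript_id Optional id carried into the result.
#' @return List of class `DecayFit`: `transcript_id`, `y_eq`, `k` (1/h,
#'   <= 0), `half_life` (h or `NA`), `converged`, `n_timepoints_used`.
#' @export
fit_bounded_growth <- function(times, y, transcript_id = NA_character_) {
  if (length(times) != length(y) || length(y) < 3L) {
    stop("need equal-length times and y with at least 3 points")
  }
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (any(!is.finite(y)) || any(y <= 0)) {
    stop("all y must be positive (1/y weights are undefined at zero)")
  }
  df <- data.frame(t = times, y = y)
  fit <- tryCatch(
    nls(y ~ yeq * (1 - exp(k * t)), data = df,
        start = list(yeq = max(y), k = -0.5),
        algorithm = "port",
        weights = 1 / df$y,
        lower = c(yeq = 0, k = -Inf), upper = c(yeq = Inf, k = 0),
        control = stats::nls.control(maxiter = 200L, tol = 1e-8,
                                     warnOnly = FALSE)),
    error = function(e) NULL, warning = function(w) NULL
  )
  out <- list(transcript_id = transcript_id, y_eq = NA_real_, k = NA_real_,
              half_life = NA_real_, converged = FALSE,
              n_timepoints_used = length(y))
  if (!is.null(fit)) {
    cf <- stats::coef(fit)
    if (is.finite(cf[["k"]]) && cf[["k"]] < -1e-9) {
      out$y_eq <- unname(cf[["yeq"]])
      out$k <- unname(cf[["k"]])
      out$half_life <- half_life(out$k)
      out$converged <- TRUE
    }
  }
  structure(out, class = "DecayFit")
}

#' Half-life from a decay constant
#'
#' `HL = ln(2) / |k|`; `NA` for `k = 0` (no decay).  Accepts `k` in either
#' sign convention (the fitted non-positive `k`, or a stored magnitude).
#'
#' @param k Decay constant(s), 1/h.
#' @return Half-life in hours (vectorized), `NA` where `k = 0`.
#' @export
half_life <- function(k) {
  ifelse(is.na(k) | k == 0, NA_real_, log(2) / abs(k))
}

#' Combine replicate half-lives
#'
#' Arithmetic mean of the non-`NA` replicate half-lives; `NA` if all
#' replicates are `NA`.
#'
#' @param half_lives Numeric vector of replicate half-lives (hours).
#' @return Single combined half-life (hours) or `NA`.
#' @export
combine_replicates <- function(half_lives) {
  hl <- half_lives[!is.na(half_lives)]
  if (length(hl) == 0L) NA_real_ else mean(hl)
}

#' Fit half-lives for every transcript of a time course
#'
#' Pipeline wrapper: applies the raw-count coverage filter, spike-in
#' normalization, and the bounded-growth fit per transcript, using the
#' labeled samples (numeric `timepoint_h`) of one cell line.  Half-lives
#' above 100 h are reported uncapped but flagged in `long_lived`.
#'
#' @param tc A [timecourse_counts()] object.
#' @param cell_line Cell line to fit; default = the single line present.
#' @param min_each,min_any Coverage thresholds, see [filter_timecourse()].
#' @return data.frame with columns `transcript_id`, `cell_line`, `y_eq`,
#'   `k`, `half_life_h`, `converged`, `n_timepoints`, `long_lived`.
#' @export
fit_halflives <- function(tc, cell_line = NULL, min_each = 1, min_any = 5) {
  stopifnot(inherits(tc, "TimeCourseCounts"))
  sm <- tc$sample_meta
  if (is.null(cell_line)) {
    cl <- unique(sm$cell_line)
    if (length(cl) != 1L) stop("multiple cell lines; specify cell_line")
    cell_line <- cl
  }
  labeled <- sm$cell_line == cell_line & sm$timepoint_h != "steady_state"
  if (sum(labeled) < 4L) {
    stop("cell line ", cell_line, " has fewer than 4 labeled time points")
  }
  sub <- tc
  sub$counts <- tc$counts[, sm$sample_id[labeled], drop = FALSE]
  sub$sample_meta <- sm[labeled, , drop = FALSE]
  tps <- as.numeric(sub$sample_meta$timepoint_h)
  ord <- order(tps)
  tps <- tps[ord]
  sub$counts <- sub$counts[, ord, drop = FALSE]

  keep <- filter_timecourse(sub, min_each = min_each, min_any = min_any)$kept
  norm <- spike_normalize(sub)
  fits <- lapply(keep, function(id) {
    f <- fit_bounded_growth(tps, norm[id, ], transcript_id = id)
    data.frame(transcript_id = id, cell_line = cell_line,
               y_eq = f$y_eq, k = f$k, half_life_h = f$half_life,
               converged = f$converged, n_timepoints = f$n_timepoints_used)
  })
  out <- if (length(fits) > 0) do.call(rbind, fits) else
    data.frame(transcript_id = character(), cell_line = character(),
               y_eq = numeric(), k = numeric(), half_life_h = numeric(),
               converged = logical(), n_timepoints = integer())
  out$long_lived <- !is.na(out$half_life_h) & out$half_life_h > 100
  rownames(out) <- NULL
  out
}
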
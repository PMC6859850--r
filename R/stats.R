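#' Shared two-sample tests
#'
#' Thin, uniform wrappers around the standard two-sided tests used in the
#' analysis, returning a common `TestResult` shape.  Exact small-sample
#' p-values are used where feasible (the default `stats` switch points:
#' exact Wilcoxon for n < 50 without ties, exact KS for n1*n2 < 10000
#' without ties), with the normal / asymptotic approximation and tie
#' correction otherwise.
#'
#' @param x,y Numeric samples.
#' @param paired For [wilcoxon_test()]: paired (signed-rank) vs unpaired
#'   (rank-sum); paired requires equal lengths.
#' @return List of class `TestResult`: `statistic`, `p_value`, `n1`, `n2`,
#'   `method`.
#' @export
ks_test <- function(x, y) {
  res <- suppressWarnings(stats::ks.test(x, y, alternative = "two.sided"))
  test_result(unname(res$statistic), res$p.value, length(x), length(y),
              "two-sample Kolmogorov-Smirnov")
}

#' @rdname ks_test
#' @export
wilcoxon_test <- function(x, y, paired = FALSE) {
  if (paired && length(x) != length(y)) {
    stop("paired test requires equal-length samples")
  }
  if (paired && all(x == y)) {
    # all differences zero: no evidence against the null
    return(test_result(0, 1, length(x), length(y),
                       "paired Wilcoxon signed-rank"))
  }
  res <- suppressWarnings(stats::wilcox.test(x, y, paired = paired,
                                             alternative = "two.sided"))
  test_result(unname(res$statistic), res$p.value, length(x), length(y),
              if (paired) "paired Wilcoxon signed-rank" else
                "Wilcoxon rank-sum")
}

#' Variance ratio of two half-life distributions
#'
#' Compares spread on the log2 scale after median-centering:
#' `ratio = var(log2(y) centered) / var(log2(x) centered)`, with a
#' two-sided p-value from the F test.  Pass `log_scale = FALSE` if the
#' inputs are already log-transformed.
#'
#' @param x Reference half-lives (hours), e.g. endogenous transcripts.
#' @param y Comparison half-lives (hours), e.g. ORFeome reporters.
#' @param log_scale Apply `log2` before centering (default `TRUE`).
#' @return `TestResult` with `statistic` = variance ratio var(y)/var(x).
#' @export
variance_ratio <- function(x, y, log_scale = TRUE) {
  if (log_scale) {
    if (any(x <= 0) || any(y <= 0)) stop("half-lives must be positive")
    x <- log2(x); y <- log2(y)
  }
  xc <- median_center(x); yc <- median_center(y)
  res <- stats::var.test(yc, xc, alternative = "two.sided")
  test_result(unname(res$estimate), res$p.value, length(x), length(y),
              "F test on median-centered log2 half-lives")
}

#' Median-center a vector
#'
#' Subtracts the sample median (for even lengths, the mean of the two
#' middle order statistics), so the centered vector has median 0.
#'
#' @param x Numeric vector.
#' @return `x - median(x)`.
#' @export
median_center <- function(x) x - stats::median(x)

test_result <- function(statistic, p_value, n1, n2, method) {
  structure(list(statistic = statistic, p_value = p_value,
                 n1 = n1, n2 = n2, method = method),
            class = "TestResult")
}

#' @export
print.TestResult <- function(x, ...) {
  cat(x$method, ": statistic = ", format(x$statistic),
      ", p = ", format(x$p_value), " (n1 = ", x$n1, ", n2 = ", x$n2, ")\n",
      sep = "")
  invisible(x)
}
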
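#' Codon usage frequencies of a CDS, with frameshift controls
#'
#' Counts consecutive in-frame codons and returns their frequencies
#' (counts / total codons counted) over all 64 codons.  Frameshift
#' controls recompute the frequencies after shifting the reading frame:
#' `+1` removes positions 1, n-2 and n-1 (1-based, CDS of length n) before
#' counting, `+2` removes positions 1, 2 and n-1.  Stop codons are counted
#' like any other codon (they are excluded later, from CSC output, not
#' from the frequency denominator).
#'
#' @param cds A single CDS string; length divisible by 3 and >= 6 nt.
#' @param frameshift 0, 1 or 2.
#' @return Named numeric vector over [all_codons()] summing to 1.
#' @export
codon_frequencies <- function(cds, frameshift = 0) {
  cds <- toupper(cds)
  n <- nchar(cds)
  if (n %% 3L != 0L) stop("CDS length not divisible by 3")
  if (n < 6L) stop("CDS shorter than 2 codons")
  if (!frameshift %in% 0:2) stop("frameshift must be 0, 1 or 2")
  if (frameshift > 0L) {
    chars <- strsplit(cds, "")[[1]]
    drop <- if (frameshift == 1L) c(1L, n - 2L, n - 1L) else c(1L, 2L, n - 1L)
    cds <- paste(chars[-drop], collapse = "")
  }
  cods <- split_codons(cds)
  tab <- table(factor(cods, levels = all_codons()))
  setNames(as.vector(tab) / length(cods), all_codons())
}

#' Codon frequency matrix for a set of CDSs
#'
#' @param cds_set Named character vector of CDS sequences.
#' @param frameshift Passed to [codon_frequencies()].
#' @return Matrix, transcripts x 64 codons; rows sum to 1.  Transcripts
#'   whose length is not divisible by 3 are skipped with a warning.
#' @export
codon_frequency_matrix <- function(cds_set, frameshift = 0) {
  ok <- nchar(cds_set) %% 3L == 0L & nchar(cds_set) >= 6L
  if (any(!ok)) {
    warning(sum(!ok), " transcript(s) skipped: length not divisible by 3 ",
            "or shorter than 2 codons")
  }
  m <- t(vapply(cds_set[ok], codon_frequencies, numeric(64L),
                frameshift = frameshift))
  rownames(m) <- names(cds_set)[ok]
  m
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties; pairs with an `NA` in
#' either vector are dropped.  Requires >= 3 complete pairs.
#'
#' @param x,y Numeric vectors of equal length.
#' @return Spearman's rho.
#' @export
spearman_cor <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3L) stop("need at least 3 complete pairs")
  cor(x[ok], y[ok], method = "spearman")
}

#' Codon stability coefficients
#'
#' The CSC of a codon is the Spearman correlation, across transcripts,
#' between that codon's usage frequency and the transcript half-life.
#' Stop codons are excluded from the output (but counted in the frequency
#' denominator).  Codons with zero variance in frequency across the
#' transcript set get `NA` with a warning.
#'
#' @param freqs Codon frequency matrix from [codon_frequency_matrix()]
#'   (rows = transcripts).
#' @param half_lives Named numeric vector of half-lives (hours), names
#'   matching rows of `freqs`; `NA`s dropped pairwise.
#' @return data.frame of class `CSCTable` with columns `codon`,
#'   `amino_acid`, `csc`, `n` (61 rows, sense codons only); attribute
#'   `n_transcripts`.
#' @export
compute_csc <- function(freqs, half_lives) {
  common <- intersect(rownames(freqs), names(half_lives))
  hl <- half_lives[common]
  common <- common[!is.na(hl)]
  if (length(common) < 20L) {
    stop("need at least 20 transcripts with half-lives; got ",
         length(common))
  }
  f <- freqs[common, , drop = FALSE]
  hl <- half_lives[common]
  aa <- codon_to_aa()
  sense <- sense_codons()
  csc <- vapply(sense, function(cod) {
    x <- f[, cod]
    if (stats::sd(x) == 0) return(NA_real_)
    spearman_cor(x, hl)
  }, numeric(1))
  if (anyNA(csc)) {
    warning(sum(is.na(csc)), " codon(s) with zero frequency variance; CSC NA")
  }
  structure(
    data.frame(codon = sense, amino_acid = unname(aa[sense]),
               csc = unname(csc), n = length(common)),
    class = c("CSCTable", "data.frame"),
    n_transcripts = length(common)
  )
}

#' Amino acid stabilization coefficients
#'
#' AASC of an amino acid = arithmetic mean of the CSC values of its
#' synonymous codons (standard genetic code); `NA` CSCs are omitted from
#' the mean.
#'
#' @param csc A `CSCTable` from [compute_csc()].
#' @return data.frame of class `AASCTable` with columns `amino_acid`
#'   (20 standard, one-letter), `aasc`, `n_codons`.
#' @export
compute_aasc <- function(csc) {
  stopifnot(is.data.frame(csc), all(c("codon", "csc") %in% names(csc)))
  aa_map <- codon_to_aa()
  aas <- sort(unique(aa_map[aa_map != "*"]))
  rows <- lapply(aas, function(a) {
    cods <- names(aa_map)[aa_map == a]
    vals <- csc$csc[match(cods, csc$codon)]
    data.frame(amino_acid = a, aasc = mean(vals, na.rm = TRUE),
               n_codons = length(cods))
  })
  structure(do.call(rbind, rows), class = c("AASCTable", "data.frame"))
}

#' Permutation null band for CSC values
#'
#' Recomputes the full CSC table `n_perm` times with half-lives permuted
#' across transcripts and returns the pooled two-sided 95% band of the
#' permuted coefficients.  Under a null with no codon effect, ~5% of
#' observed CSCs are expected to fall outside the band.
#'
#' @param freqs Codon frequency matrix (see [compute_csc()]).
#' @param half_lives Named half-life vector.
#' @param n_perm Number of permutations (default 200).
#' @param level Band coverage (default 0.95).
#' @param seed Integer seed for the permutations.
#' @return Numeric vector `c(lower, upper)`.
#' @export
csc_permutation_band <- function(freqs, half_lives, n_perm = 200L,
                                 level = 0.95, seed = 1L) {
  set.seed(seed)
  common <- intersect(rownames(freqs), names(half_lives))
  hl <- half_lives[common]
  perm_vals <- unlist(lapply(seq_len(n_perm), function(b) {
    hp <- setNames(sample(hl), common)
    suppressWarnings(compute_csc(freqs, hp)$csc)
  }))
  alpha <- (1 - level) / 2
  unname(quantile(perm_vals, c(alpha, 1 - alpha), na.rm = TRUE))
}

#' Fisher r-to-z comparison of two independent correlations
#'
#' `z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3))`, with a
#' two-sided p-value from the standard normal.
#'
#' @param r1,r2 Correlations, `|r| < 1`.
#' @param n1,n2 Sample sizes, > 3.
#' @return List with `z` and `p_value`.
#' @export
fisher_r_to_z <- function(r1, n1, r2, n2) {
  stopifnot(abs(r1) < 1, abs(r2) < 1, n1 > 3, n2 > 3)
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  list(z = z, p_value = 2 * pnorm(-abs(z)))
}
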
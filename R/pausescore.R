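#' Ribosomal site windows within a footprint read
#'
#' In 28--30 nt footprints the A, P and E sites occupy read positions
#' 17--19, 14--16 and 11--13 (1-based).
#'
#' @return Named integer vector of 0-based offsets from the read 5' end to
#'   the first nucleotide of each site.
#' @export
site_offsets <- function() c(A = 16L, P = 13L, E = 10L)

#' Assign the codon under a ribosomal site, or reject the read
#'
#' The site start within the CDS (0-based) is `five_prime_pos + offset`
#' with offsets 16 / 13 / 10 nt for A / P / E.  The read is accepted for
#' that site iff the site start is in-frame (`start %% 3 == 0`) and the
#' site lies fully within the sequence; otherwise `NA` (reject) is
#' returned.  Because the three offsets are congruent mod 3, a read
#' accepted at one site is in-frame at all three, and its A/P/E codons are
#' consecutive codon indices `i, i-1, i-2`.
#'
#' @param five_prime_pos 0-based read 5' offset(s) within the CDS
#'   (vectorized).
#' @param cds_length Length(s) in nt of the sequence the read maps to.
#' @param site `"A"`, `"P"` or `"E"`.
#' @return Integer codon index (0-based) per read, `NA` where rejected.
#' @export
assign_site_codon <- function(five_prime_pos, cds_length, site = c("A", "P", "E")) {
  site <- match.arg(site)
  start <- five_prime_pos + site_offsets()[[site]]
  ok <- start %% 3L == 0L & start + 3L <= cds_length
  idx <- ifelse(ok, start %/% 3L, NA_integer_)
  as.integer(idx)
}

#' Observed codon occupancy of a ribosomal site
#'
#' Counts, over the accepted (in-frame, within-sequence) reads of a
#' footprint table, the codon found under the chosen site, and normalizes
#' to frequencies over accepted reads.  Reads mapping to transcripts
#' absent from `cds_set` are rejected and counted.
#'
#' @param fp A [footprint_table()].
#' @param cds_set Named character vector of transcript sequences.
#' @param site `"A"`, `"P"` or `"E"`.
#' @return List of class `SiteOccupancy`: `site`, `obs_counts` (named over
#'   the 64 codons), `obs_freq`, `n_reads_used`, `n_reads_rejected`.
#' @export
observed_occupancy <- function(fp, cds_set, site = c("A", "P", "E")) {
  site <- match.arg(site)
  known <- fp$transcript_id %in% names(cds_set)
  lens <- nchar(cds_set)[match(fp$transcript_id, names(cds_set))]
  lens[!known] <- 0L
  idx <- assign_site_codon(fp$five_prime_pos, lens, site)
  use <- !is.na(idx) & known
  cods <- substring(cds_set[fp$transcript_id[use]],
                    3L * idx[use] + 1L, 3L * idx[use] + 3L)
  counts <- table(factor(cods, levels = all_codons()))
  n_used <- sum(use)
  freq <- if (n_used > 0) as.vector(counts) / n_used else
    rep(NA_real_, 64L)
  structure(
    list(site = site,
         obs_counts = setNames(as.vector(counts), all_codons()),
         obs_freq = setNames(freq, all_codons()),
         n_reads_used = n_used,
         n_reads_rejected = nrow(fp) - n_used),
    class = "SiteOccupancy"
  )
}

#' Abundance-weighted null codon frequencies
#'
#' The expected frequency of a codon is its frequency in each gene's CDS
#' weighted by the gene's abundance in the footprint data, using only the
#' in-frame accepted 28--30 nt reads: `expected(c) = sum_g w_g * f_g(c)`
#' with `w_g` = (A-site-accepted reads of g) / (total accepted reads).
#' One consistent set of weights (A-site acceptance) is used for all three
#' site tables, since a single null is defined.
#'
#' @param fp A [footprint_table()].
#' @param cds_set Named character vector of transcript sequences (length
#'   divisible by 3).  If the vector carries `cds_nt` / `utr5_nt`
#'   attributes marking untranslated flanks (see
#'   [simulate_transcriptome()]), codon frequencies are computed on the
#'   ORF proper, matching the null's definition.
#' @return Named numeric vector over the 64 codons, summing to 1.
#' @export
expected_frequencies <- function(fp, cds_set) {
  known <- fp$transcript_id %in% names(cds_set)
  lens <- nchar(cds_set)[match(fp$transcript_id, names(cds_set))]
  lens[!known] <- 0L
  idx <- assign_site_codon(fp$five_prime_pos, lens, "A")
  use <- !is.na(idx) & known
  if (sum(use) == 0L) stop("no accepted in-frame reads")
  w <- table(factor(fp$transcript_id[use], levels = names(cds_set)))
  w <- as.vector(w) / sum(use)
  fm <- codon_frequency_matrix(orf_region(cds_set))
  expected <- as.vector(t(fm) %*% w[match(rownames(fm), names(cds_set))])
  setNames(expected, colnames(fm))
}

#' Codon pause scores (dwell-time proxy)
#'
#' Pause score = observed site frequency / expected null frequency, per
#' codon (stop codons included); codons with zero expected frequency get
#' `NA`.  Amino-acid scores are the arithmetic mean of the member codon
#' scores.
#'
#' @param obs A `SiteOccupancy` from [observed_occupancy()].
#' @param expected Named expected frequencies from
#'   [expected_frequencies()].
#' @return data.frame of class `PauseScoreTable` with columns `codon`,
#'   `amino_acid`, `obs_freq`, `expected_freq`, `score`; attribute
#'   `aa_score` (data.frame `amino_acid`, `score`) and `site`.
#' @export
pause_scores <- function(obs, expected) {
  stopifnot(inherits(obs, "SiteOccupancy"))
  cods <- all_codons()
  expected <- expected[cods]
  score <- ifelse(expected > 0, obs$obs_freq[cods] / expected, NA_real_)
  aa <- codon_to_aa()
  tab <- data.frame(codon = cods, amino_acid = unname(aa[cods]),
                    obs_freq = unname(obs$obs_freq[cods]),
                    expected_freq = unname(expected),
                    score = unname(score))
  aa_levels <- sort(unique(aa))
  aa_score <- vapply(aa_levels, function(a) {
    mean(score[aa[cods] == a], na.rm = TRUE)
  }, numeric(1))
  structure(tab, class = c("PauseScoreTable", "data.frame"),
            aa_score = data.frame(amino_acid = aa_levels,
                                  score = unname(aa_score)),
            site = obs$site)
}

#' Split codons into slow / neutral / fast tertiles
#'
#' Ranks codons by value (descending: highest pause score = slowest) and
#' splits them into three near-equal groups; for 61 codons the sizes are
#' 21 / 20 / 20.  Ties are broken by codon lexicographic order, so the
#' grouping is deterministic and order-invariant.
#'
#' @param values Named numeric vector (pause scores, or CSCs).
#' @param labels Group labels, largest-value group first.
#' @return Named factor of group labels, in the input's name order.
#' @export
tertile_groups <- function(values, labels = c("slow", "neutral", "fast")) {
  stopifnot(!is.null(names(values)), length(labels) == 3L)
  ord <- order(-values, names(values))
  n <- length(values)
  sizes <- c(ceiling(n / 3), rep(floor(n / 3), 2))
  sizes[2] <- n - sizes[1] - sizes[3]
  grp <- rep(labels, times = sizes)
  out <- factor(character(n), levels = labels)
  out[ord] <- factor(grp, levels = labels)
  names(out) <- names(values)
  out
}
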
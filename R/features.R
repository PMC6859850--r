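#' Sliding windows over a CDS
#'
#' Windows of `window` nt starting every `step` nt, kept only while they
#' fit entirely within the sequence; the window count is
#' `floor((len - window) / step) + 1`.
#'
#' @param cds A single sequence string, length >= `window`.
#' @param window Window width in nt (default 100).
#' @param step Start-to-start distance in nt (default 3).
#' @return Character vector of window subsequences; attribute `starts`
#'   gives the 0-based start offsets.
#' @export
sliding_windows <- function(cds, window = 100L, step = 3L) {
  n <- nchar(cds)
  if (n < window) stop("sequence shorter than window (", n, " < ", window, ")")
  starts <- seq(0L, n - window, by = step)
  out <- substring(cds, starts + 1L, starts + window)
  attr(out, "starts") <- starts
  out
}

#' Surrogate folding energy: negated maximal nested pairing
#'
#' A deterministic stand-in energy for ranking local structure: the
#' negative of the maximum number of complementary base pairs (A:U, G:C,
#' G:U) in a nested (pseudoknot-free) secondary structure with a minimum
#' hairpin loop of 3 nt, computed by dynamic programming.  Lower = more
#' structured; an unpairable sequence scores 0.  Thermodynamic folders
#' (e.g. RNAfold) can be plugged into [min_window_energy()] in its place
#' via `energy_fn`.
#'
#' @param seq A DNA sequence string (T read as U).
#' @return Non-positive numeric energy.
#' @export
pairing_energy <- function(seq) {
  -as.numeric(.max_pairs(toupper(seq)))
}

#' Minimum windowed folding energy of a CDS
#'
#' Evaluates `energy_fn` on every sliding window ([sliding_windows()]) and
#' returns the minimum — the most structured local region.
#'
#' @param cds A single sequence string.
#' @param energy_fn Function mapping a window string to a scalar energy;
#'   default [pairing_energy()].  Any external thermodynamic folder can be
#'   adapted as `function(window) <MFE of window>`.
#' @param window,step Window geometry, see [sliding_windows()].
#' @return Minimum energy over windows.
#' @export
min_window_energy <- function(cds, energy_fn = pairing_energy,
                              window = 100L, step = 3L) {
  wins <- sliding_windows(cds, window = window, step = step)
  min(vapply(wins, energy_fn, numeric(1)))
}

#' Scan a sequence for miRNA seed matches
#'
#' Flags, for each supplied seed (the 7-mer at miRNA positions 2--8),
#' whether its reverse complement (the 7mer-m8 site) occurs in the
#' sequence.  The seed list is supplied by the caller; no seeds are
#' hard-coded.
#'
#' @param seq Sequence string (DNA alphabet).
#' @param seeds Character vector of 7-mer seeds (miRNA sense, DNA
#'   alphabet); may be named.
#' @return Named logical vector, one flag per seed (empty if no seeds).
#' @export
scan_mirna_sites <- function(seq, seeds) {
  if (length(seeds) == 0L) return(setNames(logical(0), character(0)))
  if (any(nchar(seeds) != 7L)) stop("seeds must be 7-mers")
  sites <- vapply(seeds, function(s) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }, character(1))
  found <- vapply(sites, function(site) {
    grepl(site, toupper(seq), fixed = TRUE)
  }, logical(1))
  names(found) <- if (!is.null(names(seeds))) names(seeds) else seeds
  found
}

#' Detect an AU-rich element
#'
#' Default rule: at least `min_count` occurrence of the pentamer `ATTTA`
#' (AUUUA on the mRNA).  Both motif and threshold are configurable; this
#' is a deliberately simple ARE proxy, not a class I/II/III taxonomy.
#'
#' @param seq Sequence string.
#' @param motif Motif to count (default `"ATTTA"`).
#' @param min_count Minimum number of (possibly overlapping) occurrences.
#' @return Logical flag.
#' @export
detect_are <- function(seq, motif = "ATTTA", min_count = 1L) {
  seq <- toupper(seq)
  # overlapping occurrences via lookahead-free stepping
  hits <- 0L
  from <- 1L
  repeat {
    i <- regexpr(motif, substring(seq, from), fixed = TRUE)
    if (i < 0L) break
    hits <- hits + 1L
    from <- from + i  # advance one past the match start: overlaps count
    if (hits >= min_count) break
  }
  hits >= min_count
}

#' Compare half-life distributions with and without a feature
#'
#' Two-sample two-sided Kolmogorov-Smirnov test of the half-lives of
#' transcripts carrying vs lacking a feature.
#'
#' @param hl_with,hl_without Numeric half-life vectors (hours).
#' @return A `TestResult` (see [ks_test()]).
#' @export
group_compare <- function(hl_with, hl_without) {
  ks_test(hl_with, hl_without)
}

#' Build the ORF feature table
#'
#' Per transcript: ORF length (nt), minimum windowed surrogate folding
#' energy (`NA` for ORFs shorter than one window), per-seed miRNA site
#' flags, and the ARE flag.
#'
#' @param cds_set Named character vector of CDS sequences.
#' @param seeds Character vector of miRNA 7-mer seeds (may be empty).
#' @param energy_fn,window,step Passed to [min_window_energy()].
#' @return data.frame, one row per transcript.
#' @export
feature_table <- function(cds_set, seeds = character(),
                          energy_fn = pairing_energy,
                          window = 100L, step = 3L) {
  rows <- lapply(names(cds_set), function(id) {
    s <- cds_set[[id]]
    mwe <- if (nchar(s) >= window) {
      min_window_energy(s, energy_fn, window = window, step = step)
    } else NA_real_
    row <- data.frame(transcript_id = id, orf_length_nt = nchar(s),
                      min_window_energy = mwe,
                      has_are = detect_are(s))
    if (length(seeds) > 0L) {
      flags <- scan_mirna_sites(s, seeds)
      for (nm in names(flags)) row[[paste0("mirna_", nm)]] <- flags[[nm]]
    }
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
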
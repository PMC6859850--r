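#' Codon tables
#'
#' Helpers enumerating the 64 codons of the standard genetic code, the 61
#' sense (non-stop) codons, and the codon to amino-acid map (one-letter
#' code, `"*"` for stop).  All codon-indexed results in the package use the
#' lexicographic codon order returned by these functions.
#'
#' @return `all_codons()` and `sense_codons()` return character vectors of
#'   codons; `codon_to_aa()` returns a named character vector mapping codon
#'   to one-letter amino acid.
#' @examples
#' length(all_codons())   # 64
#' length(sense_codons()) # 61
#' codon_to_aa()[["ATG"]] # "M"
#' @export
all_codons <- function() {
  b <- c("A", "C", "G", "T")
  as.vector(t(outer(
    as.vector(t(outer(b, b, paste0))), b, paste0
  )))
}

#' @rdname all_codons
#' @export
sense_codons <- function() {
  setdiff(all_codons(), stop_codons())
}

#' @rdname all_codons
#' @export
stop_codons <- function() c("TAA", "TAG", "TGA")

#' @rdname all_codons
#' @export
codon_to_aa <- function() {
  gc <- Biostrings::GENETIC_CODE
  aa <- setNames(as.character(gc), chartr("U", "T", names(gc)))
  aa[all_codons()]
}

# codons of a CDS string, in frame 0; no validation (callers validate)
split_codons <- function(seq) {
  n <- nchar(seq)
  substring(seq, seq(1L, n - 2L, by = 3L), seq(3L, n, by = 3L))
}

# ORF substrings of transcript records; records may carry untranslated
# flanks recorded in the "cds_nt" / "utr5_nt" attributes
orf_region <- function(cds_set) {
  cds_nt <- attr(cds_set, "cds_nt")
  if (is.null(cds_nt)) return(cds_set)
  utr5 <- attr(cds_set, "utr5_nt") %||% 0L
  out <- substring(cds_set, utr5 + 1L, utr5 + cds_nt[names(cds_set)])
  names(out) <- names(cds_set)
  out
}
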
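#' Library-size normalization of steady-state counts
#'
#' Scales each sample by `mean(library totals) / (its library total)`, so
#' that values stay on a read-count scale while being comparable across
#' samples.
#'
#' @param counts Matrix of non-negative counts, transcripts x samples.
#' @return Matrix of the same shape, normalized.
#' @export
library_size_normalize <- function(counts) {
  counts <- as.matrix(counts)
  tot <- colSums(counts)
  if (any(tot <= 0)) {
    stop("sample(s) with zero total counts: ",
         paste(colnames(counts)[tot <= 0], collapse = ", "))
  }
  sweep(counts, 2L, mean(tot) / tot, "*")
}

#' Classify transcripts as ORFeome reporters vs endogenous
#'
#' For a given cell line, a transcript is labeled `"orfeome"` iff it is in
#' that line's infected pool AND its library-size-normalized steady-state
#' count strictly exceeds `fold` times that in the matched (paired) line
#' AND strictly exceeds `min_norm` reads.  Transcripts not in the pool are
#' `"endogenous"`; pooled transcripts failing either threshold are
#' `"excluded"`.  Both thresholds are strict inequalities.  Transcripts
#' present in the counts but absent from the pool registry are treated as
#' not in the pool.
#'
#' @param norm_self Named vector of normalized steady-state counts in the
#'   classified line.
#' @param norm_paired Same transcripts, normalized counts in the matched
#'   line.
#' @param pool_membership Character vector of transcript ids in the
#'   classified line's pool (or named logical vector).
#' @param cell_line Label recorded in the result.
#' @param fold Fold-enrichment threshold (default 3).
#' @param min_norm Minimum normalized count (default 4).
#' @return data.frame of class `ClassificationResult`: `transcript_id`,
#'   `cell_line`, `label`, `norm_count_self`, `norm_count_paired`.
#' @export
classify_orfeome <- function(norm_self, norm_paired, pool_membership,
                             cell_line = NA_character_,
                             fold = 3, min_norm = 4) {
  ids <- names(norm_self)
  if (is.null(ids)) stop("norm_self must be a named vector")
  if (!identical(ids, names(norm_paired))) {
    norm_paired <- norm_paired[ids]
  }
  in_pool <- if (is.logical(pool_membership)) {
    unname(pool_membership[ids]) %in% TRUE
  } else {
    ids %in% pool_membership
  }
  passes <- norm_self > fold * norm_paired & norm_self > min_norm
  label <- ifelse(!in_pool, "endogenous",
                  ifelse(passes, "orfeome", "excluded"))
  structure(
    data.frame(transcript_id = ids, cell_line = cell_line, label = label,
               norm_count_self = unname(norm_self),
               norm_count_paired = unname(norm_paired)),
    class = c("ClassificationResult", "data.frame")
  )
}

#' Read a pool registry
#'
#' @param path TSV with columns `transcript_id`, `pool_id`.
#' @return data.frame with those columns.
#' @export
read_pools <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("transcript_id", "pool_id")
  if (!all(need %in% names(tab))) {
    stop("pool registry must have columns transcript_id, pool_id")
  }
  tab[need]
}
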
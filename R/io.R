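#' Read a CDS FASTA file
#'
#' Reads coding sequences from FASTA.  Sequences are uppercased and must be
#' DNA over `A`, `C`, `G`, `T`, `N`.  Record ids (the first whitespace-
#' delimited token of each header) must be unique.  A length not divisible
#' by 3 triggers a warning, not an error, so that callers can decide how to
#' handle ragged records.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of uppercase DNA sequences, one element
#'   per record, names = record ids.
#' @export
read_cds_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0L) stop("FASTA file is empty: ", path)
  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    stop("duplicate FASTA record id(s): ", paste(unique(dup), collapse = ", "))
  }
  seqs <- toupper(as.character(set))
  names(seqs) <- ids
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    stop("non-DNA characters in record(s): ", paste(ids[bad], collapse = ", "))
  }
  ragged <- nchar(seqs) %% 3L != 0L
  if (any(ragged)) {
    warning(sum(ragged), " record(s) with length not divisible by 3: ",
            paste(utils::head(ids[ragged], 5L), collapse = ", "))
  }
  seqs
}

#' Write a CDS FASTA file
#'
#' @param cds Named character vector of DNA sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cds_fasta <- function(cds, path) {
  set <- Biostrings::DNAStringSet(toupper(cds))
  names(set) <- names(cds)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a sample sheet
#'
#' The sample sheet maps sample ids to cell line, time point and treatment.
#' Accepted formats: TSV with columns `sample_id`, `cell_line`,
#' `timepoint_h`, `treatment`, or YAML with a list of records carrying the
#' same fields.  `timepoint_h` is hours (numeric) or the literal string
#' `"steady_state"`.
#'
#' @param path Path to a `.tsv`/`.txt` or `.yaml`/`.yml` file.
#' @return data.frame with columns `sample_id`, `cell_line`, `timepoint_h`
#'   (character; numeric hours or `"steady_state"`), `treatment`.
#' @export
read_samplesheet <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    recs <- yaml::read_yaml(path)
    if (!is.null(recs$samples)) recs <- recs$samples
    sm <- do.call(rbind, lapply(recs, function(r) {
      data.frame(sample_id = as.character(r$sample_id),
                 cell_line = as.character(r$cell_line),
                 timepoint_h = as.character(r$timepoint_h),
                 treatment = as.character(r$treatment %||% "none"))
    }))
  } else {
    sm <- utils::read.delim(path, stringsAsFactors = FALSE,
                            colClasses = "character")
  }
  need <- c("sample_id", "cell_line", "timepoint_h", "treatment")
  miss <- setdiff(need, names(sm))
  if (length(miss) > 0L) {
    stop("sample sheet is missing column(s): ", paste(miss, collapse = ", "))
  }
  if (anyDuplicated(sm$sample_id)) stop("duplicate sample_id in sample sheet")
  bad <- sm$timepoint_h != "steady_state" &
    is.na(suppressWarnings(as.numeric(sm$timepoint_h)))
  if (any(bad)) {
    stop("unparseable timepoint_h for sample(s): ",
         paste(sm$sample_id[bad], collapse = ", "))
  }
  sm[need]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

spike_prefix_re <- "^spike_(dmel|scer)\\|"

#' Construct a validated time-course count object
#'
#' Bundles a transcript-by-sample matrix of non-negative integer read
#' counts with per-sample metadata.  Rows whose ids carry the
#' `spike_dmel|` / `spike_scer|` prefixes are recorded as spike-in rows.
#'
#' @param counts Integer matrix, transcripts x samples, with rownames
#'   (transcript ids) and colnames (sample ids).
#' @param sample_meta data.frame as returned by [read_samplesheet()],
#'   covering every column of `counts`.
#' @param allow_fractional Permit non-integer values; used for noise-free
#'   simulated expectations, which are real-valued by construction.
#' @return An object of class `TimeCourseCounts`: a list with elements
#'   `counts`, `sample_meta`, `spike_rows`.
#' @export
timecourse_counts <- function(counts, sample_meta, allow_fractional = FALSE) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must have rownames (transcripts) and colnames (samples)")
  }
  if (any(is.na(counts)) || any(counts < 0)) {
    stop("counts must be non-negative")
  }
  if (!allow_fractional && any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  storage.mode(counts) <- "double"
  missing_meta <- setdiff(colnames(counts), sample_meta$sample_id)
  if (length(missing_meta) > 0L) {
    stop("sample(s) missing from sample sheet: ",
         paste(missing_meta, collapse = ", "))
  }
  sample_meta <- sample_meta[match(colnames(counts), sample_meta$sample_id), ,
                             drop = FALSE]
  rownames(sample_meta) <- NULL
  structure(
    list(counts = counts,
         sample_meta = sample_meta,
         spike_rows = grep(spike_prefix_re, rownames(counts), value = TRUE)),
    class = "TimeCourseCounts"
  )
}

#' @export
print.TimeCourseCounts <- function(x, ...) {
  cat("TimeCourseCounts:", nrow(x$counts), "rows (",
      length(x$spike_rows), "spike ) x", ncol(x$counts), "samples\n")
  invisible(x)
}

#' Read a time-course count table
#'
#' @param path TSV with first column `transcript_id` and one column per
#'   sample; counts are non-negative integers.
#' @param samplesheet_path Sample sheet (TSV or YAML), see
#'   [read_samplesheet()].
#' @return A [timecourse_counts()] object.
#' @export
read_timecourse <- function(path, samplesheet_path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(tab)[1] != "transcript_id") {
    stop("first column of count table must be 'transcript_id'")
  }
  counts <- as.matrix(tab[, -1, drop = FALSE])
  rownames(counts) <- tab$transcript_id
  sm <- read_samplesheet(samplesheet_path)
  timecourse_counts(counts, sm)
}

#' Write a time-course count table
#'
#' @param tc A `TimeCourseCounts` object (or bare count matrix).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_timecourse <- function(tc, path) {
  counts <- if (inherits(tc, "TimeCourseCounts")) tc$counts else tc
  df <- data.frame(transcript_id = rownames(counts), counts,
                   check.names = FALSE)
  write_tsv(df, path)
}

#' Read a ribosome-footprint table
#'
#' Footprints are given in transcript (CDS) coordinates, 0-based half-open:
#' `five_prime_pos` is the offset of the read 5' end within the CDS.  For
#' users coming from a transcriptome SAM (RNAME = transcript, POS 1-based),
#' the conversion is `five_prime_pos = POS - 1`.  Rows with `read_length`
#' outside 28--30 nt are rejected with a warning; the rejection count is
#' kept in `attr(, "n_rejected")`.
#'
#' @param path TSV with columns `transcript_id`, `five_prime_pos`,
#'   `read_length`.
#' @return data.frame of accepted rows, class `FootprintTable`, with
#'   attribute `n_rejected`.
#' @export
read_footprints <- function(path) {
  fp <- utils::read.delim(path, stringsAsFactors = FALSE)
  footprint_table(fp)
}

#' Construct a validated footprint table
#'
#' @param fp data.frame with columns `transcript_id`, `five_prime_pos`,
#'   `read_length`.
#' @return data.frame of class `FootprintTable` with attribute
#'   `n_rejected` (rows dropped by the 28--30 nt length filter).
#' @export
footprint_table <- function(fp) {
  need <- c("transcript_id", "five_prime_pos", "read_length")
  miss <- setdiff(need, names(fp))
  if (length(miss) > 0L) {
    stop("footprint table missing column(s): ", paste(miss, collapse = ", "))
  }
  fp <- fp[need]
  if (any(fp$five_prime_pos < 0)) stop("five_prime_pos must be >= 0")
  keep <- fp$read_length %in% 28:30
  n_rej <- sum(!keep)
  if (n_rej > 0L) {
    warning(n_rej, " footprint row(s) rejected: read_length outside 28-30 nt")
  }
  fp <- fp[keep, , drop = FALSE]
  rownames(fp) <- NULL
  structure(fp, class = c("FootprintTable", "data.frame"), n_rejected = n_rej)
}

#' Write a footprint table
#'
#' @param fp `FootprintTable` (or compatible data.frame).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_footprints <- function(fp, path) {
  write_tsv(as.data.frame(fp), path)
}

#' Write / read the synthetic ground-truth table
#'
#' Flat TSV serialization of a `SyntheticTruth` object.  Per-transcript
#' scalars are stored as columns; per-codon maps (latent stability weights,
#' dwell multipliers) are stored as codon-named columns prefixed with `w_`
#' and `d_` in a single-row trailer section keyed `"__codon__"`.
#'
#' @param truth A `SyntheticTruth` object (see [simulate_transcriptome()]).
#' @param path Output TSV path.
#' @return `path` invisibly for the writer; a `SyntheticTruth` list for the
#'   reader.
#' @export
write_truth <- function(truth, path) {
  tx <- data.frame(record = "transcript",
                   id = truth$transcript_id,
                   value1 = truth$k_true,
                   value2 = truth$y_eq_true,
                   value3 = truth$abundance,
                   label = truth$pool_label)
  cw <- data.frame(record = "codon_weight",
                   id = names(truth$codon_weights),
                   value1 = unname(truth$codon_weights),
                   value2 = NA_real_, value3 = NA_real_, label = NA_character_)
  dm <- data.frame(record = "dwell",
                   id = names(truth$dwell_multipliers),
                   value1 = unname(truth$dwell_multipliers),
                   value2 = NA_real_, value3 = NA_real_, label = NA_character_)
  write_tsv(rbind(tx, cw, dm), path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  tx <- tab[tab$record == "transcript", ]
  cw <- tab[tab$record == "codon_weight", ]
  dm <- tab[tab$record == "dwell", ]
  structure(
    list(transcript_id = tx$id,
         k_true = tx$value1,
         y_eq_true = tx$value2,
         abundance = tx$value3,
         pool_label = tx$label,
         codon_weights = setNames(cw$value1, cw$id),
         dwell_multipliers = setNames(dm$value1, dm$id)),
    class = "SyntheticTruth"
  )
}

# fixed TSV dialect: header, tab delimiter, UTF-8, "NA" for missing
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}
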
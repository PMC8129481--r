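# TSV dialects shared by the pipeline and its generators. Numbers are written
# with 17 significant digits so write -> read round-trips to full double
# precision; missing cells may be encoded as empty strings or "NA".

format_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) NA_character_ else sprintf("%.17g", v)
  }, character(1))
  out
}

write_tsv_ <- function(df, path, na = "NA") {
  num <- vapply(df, is.numeric, logical(1))
  out <- df
  for (j in which(num)) out[[j]] <- format_num(df[[j]])
  utils::write.table(out, path, sep = "\t", quote = FALSE, na = na,
                     row.names = FALSE)
}

read_tsv_ <- function(path, required, label) {
  if (!file.exists(path)) stop_("%s file not found: %s", label, path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = c("NA", ""))
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop_("%s file %s is missing column(s): %s", label, path,
          paste(missing_cols, collapse = ", "))
  }
  df
}

#' Write an intensity matrix and its sample sheet
#'
#' The matrix TSV has columns `protein_id`, `peptide_count`, then one column
#' per sample; the companion sample sheet has `sample_id`, `condition`,
#' `pair_id`. Missing cells are written as `NA`.
#'
#' @param m an [intensity_matrix()].
#' @param matrix_path,samples_path output file paths.
#' @return invisibly, the two paths.
#' @export
write_intensity_matrix <- function(m, matrix_path, samples_path) {
  stopifnot(inherits(m, "intensity_matrix"))
  df <- data.frame(
    protein_id = protein_ids(m),
    peptide_count = m$peptide_counts,
    stringsAsFactors = FALSE, check.names = FALSE
  )
  df <- cbind(df, as.data.frame(m$intensities, check.names = FALSE))
  write_tsv_(df, matrix_path)
  write_tsv_(
    data.frame(sample_id = sample_ids(m), condition = m$condition,
               pair_id = m$pair_id, stringsAsFactors = FALSE),
    samples_path
  )
  invisible(c(matrix_path, samples_path))
}

#' Read an intensity matrix and its sample sheet
#'
#' Inverse of [write_intensity_matrix()]. Empty cells and `NA` both parse to
#' missing. Duplicated protein or sample ids, missing columns, and
#' non-numeric intensity cells are reported as errors naming the offenders
#' (with 1-based data line numbers for malformed cells).
#'
#' @param matrix_path,samples_path input file paths.
#' @return an [intensity_matrix()].
#' @export
read_intensity_matrix <- function(matrix_path, samples_path) {
  df <- read_tsv_(matrix_path, c("protein_id", "peptide_count"), "matrix")
  smp <- read_tsv_(samples_path, c("sample_id", "condition", "pair_id"),
                   "sample sheet")
  if (anyDuplicated(df$protein_id)) {
    stop_("duplicated protein_id in %s: %s", matrix_path,
          paste(unique(df$protein_id[duplicated(df$protein_id)]),
                collapse = ", "))
  }
  if (anyDuplicated(smp$sample_id)) {
    stop_("duplicated sample_id in %s", samples_path)
  }
  sample_cols <- setdiff(names(df), c("protein_id", "peptide_count"))
  if (!setequal(sample_cols, smp$sample_id)) {
    stop_("matrix sample columns and sample sheet disagree")
  }
  x <- matrix(NA_real_, nrow(df), length(sample_cols),
              dimnames = list(df$protein_id, smp$sample_id))
  for (s in smp$sample_id) {
    col <- df[[s]]
    if (is.character(col)) {
      num <- suppressWarnings(as.numeric(col))
      bad <- which(!is.na(col) & is.na(num))
      if (length(bad)) {
        stop_("non-numeric intensity in %s, column %s, data line(s) %s",
              matrix_path, s, paste(bad, collapse = ", "))
      }
      col <- num
    }
    x[, s] <- col
  }
  intensity_matrix(x, condition = smp$condition, pair_id = smp$pair_id,
                   peptide_counts = df$peptide_count)
}

#' Read GWAS-style summary statistics
#'
#' Expects the tab-delimited dialect `variant_id, effect_allele,
#' other_allele, beta, se` with optional `pvalue` and `eaf` columns.
#' Duplicated variant ids and non-positive standard errors are errors naming
#' the offending variants.
#'
#' @param path input TSV.
#' @return data.frame of associations.
#' @export
read_summary_stats <- function(path) {
  need <- c("variant_id", "effect_allele", "other_allele", "beta", "se")
  df <- read_tsv_(path, need, "summary statistics")
  if (anyDuplicated(df$variant_id)) {
    stop_("duplicated variant_id in %s: %s", path,
          paste(unique(df$variant_id[duplicated(df$variant_id)]),
                collapse = ", "))
  }
  if (any(!is.finite(df$se) | df$se <= 0)) {
    bad <- df$variant_id[!is.finite(df$se) | df$se <= 0]
    stop_("non-positive se in %s for: %s", path, paste(bad, collapse = ", "))
  }
  df
}

#' Write a results table (17-significant-digit TSV)
#'
#' Generic results emitter used for differential-enrichment, PRM and MR
#' outputs; numeric columns round-trip to full double precision.
#'
#' @param df a data.frame.
#' @param path output TSV path.
#' @return invisibly, `path`.
#' @export
write_results <- function(df, path) {
  write_tsv_(as.data.frame(df), path)
  invisible(path)
}

#' Read back a results table written by [write_results()]
#'
#' @param path input TSV path.
#' @return data.frame with numeric columns restored.
#' @export
read_results <- function(path) {
  df <- read_tsv_(path, character(0), "results")
  for (j in seq_along(df)) {
    if (is.character(df[[j]])) {
      num <- suppressWarnings(as.numeric(df[[j]]))
      if (all(is.na(num) == is.na(df[[j]]))) df[[j]] <- num
    }
  }
  df
}

#' Write/read a square LD matrix keyed by variant id
#'
#' @param ld square numeric matrix with variant-id dimnames.
#' @param path TSV path (first column `variant_id`).
#' @return `write_ld_matrix` invisibly returns `path`; `read_ld_matrix`
#'   returns the named matrix.
#' @export
write_ld_matrix <- function(ld, path) {
  df <- data.frame(variant_id = rownames(ld), stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(ld, check.names = FALSE))
  write_tsv_(df, path)
  invisible(path)
}

#' @rdname write_ld_matrix
#' @export
read_ld_matrix <- function(path) {
  df <- read_tsv_(path, "variant_id", "LD matrix")
  ids <- df$variant_id
  x <- as.matrix(df[setdiff(names(df), "variant_id")])
  rownames(x) <- ids
  storage.mode(x) <- "double"
  x
}
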
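#' Protein-by-sample intensity matrix for a paired lipoprotein design
#'
#' The central container of the label-free workflow: a non-negative intensity
#' matrix (proteins in rows, samples in columns) with an explicit missingness
#' mask (`NA` cells), a condition label per sample (`"LPA"` for the
#' lipoprotein(a) fraction, `"LDL"` for the low-density-lipoprotein fraction),
#' a subject (`pair_id`) label per sample, and the number of distinct peptides
#' supporting each protein's quantification.
#'
#' The design is strictly paired: every `pair_id` must occur exactly once per
#' condition. This mirrors fractions isolated from the same individuals and is
#' what makes the paired t-test downstream valid.
#'
#' @param intensities numeric matrix, proteins x samples; `NA` marks a missing
#'   (not detected) measurement; observed values must be `>= 0`.
#' @param condition character vector, one of `"LPA"`/`"LDL"` per sample.
#' @param pair_id vector of subject labels, one per sample.
#' @param peptide_counts integer vector, distinct peptides per protein
#'   (`>= 1`).
#' @param protein_ids,sample_ids identifiers; default to the matrix dimnames.
#'
#' @return an object of class `intensity_matrix`.
#' @seealso [simulate_lfq()], [median_normalize()], [lfq_diff()]
#' @export
intensity_matrix <- function(intensities, condition, pair_id, peptide_counts,
                             protein_ids = rownames(intensities),
                             sample_ids = colnames(intensities)) {
  if (!is.matrix(intensities) || !is.numeric(intensities)) {
    stop_("`intensities` must be a numeric matrix")
  }
  np <- nrow(intensities)
  ns <- ncol(intensities)
  if (np < 1L || ns < 1L) stop_("intensity matrix must be non-empty")
  if (is.null(protein_ids)) protein_ids <- sprintf("protein_%04d", seq_len(np))
  if (is.null(sample_ids)) sample_ids <- sprintf("sample_%02d", seq_len(ns))
  protein_ids <- as.character(protein_ids)
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(protein_ids)) {
    stop_("duplicated protein_id: %s",
          paste(unique(protein_ids[duplicated(protein_ids)]), collapse = ", "))
  }
  if (anyDuplicated(sample_ids)) stop_("duplicated sample_id")
  if (length(condition) != ns || length(pair_id) != ns) {
    stop_("`condition` and `pair_id` must have one entry per sample")
  }
  condition <- as.character(condition)
  if (!all(condition %in% c("LPA", "LDL"))) {
    stop_("`condition` labels must be 'LPA' or 'LDL'")
  }
  pair_id <- as.character(pair_id)
  tab <- table(pair_id, condition)
  if (!all(tab == 1L) || ncol(tab) != 2L) {
    stop_("paired design violated: each pair_id must occur exactly once per condition")
  }
  if (any(intensities < 0, na.rm = TRUE)) {
    stop_("observed intensities must be non-negative")
  }
  if (length(peptide_counts) != np) {
    stop_("`peptide_counts` must have one entry per protein")
  }
  if (any(!is.finite(peptide_counts)) || any(peptide_counts < 1) ||
      any(peptide_counts != round(peptide_counts))) {
    stop_("`peptide_counts` must be integers >= 1")
  }
  dimnames(intensities) <- list(protein_ids, sample_ids)
  structure(
    list(
      intensities = intensities,
      condition = condition,
      pair_id = pair_id,
      peptide_counts = as.integer(peptide_counts)
    ),
    class = "intensity_matrix"
  )
}

#' @export
print.intensity_matrix <- function(x, ...) {
  miss <- mean(is.na(x$intensities))
  cat(sprintf(
    "<intensity_matrix> %d proteins x %d samples (%d pairs), %.1f%% missing\n",
    nrow(x$intensities), ncol(x$intensities),
    length(unique(x$pair_id)), 100 * miss
  ))
  invisible(x)
}

#' @export
dim.intensity_matrix <- function(x) dim(x$intensities)

protein_ids <- function(m) rownames(m$intensities)
sample_ids <- function(m) colnames(m$intensities)
n_pairs <- function(m) length(unique(m$pair_id))

# columns of each condition, ordered so that position i in both vectors is the
# same subject (pair)
paired_columns <- function(m) {
  lpa <- which(m$condition == "LPA")
  ldl <- which(m$condition == "LDL")
  lpa <- lpa[order(m$pair_id[lpa])]
  ldl <- ldl[order(m$pair_id[ldl])]
  list(lpa = lpa, ldl = ldl)
}

# subset proteins, keeping all metadata (incl. any imputation mask) consistent
subset_proteins <- function(m, keep) {
  out <- intensity_matrix(
    m$intensities[keep, , drop = FALSE],
    condition = m$condition,
    pair_id = m$pair_id,
    peptide_counts = m$peptide_counts[keep]
  )
  if (!is.null(m$imputed)) out$imputed <- m$imputed[keep, , drop = FALSE]
  out
}
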
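#' Ground truth for a simulated paired label-free experiment
#'
#' Describes the generating model behind [simulate_lfq()]: per-protein true
#' log2 intensities, a minority of proteins truly enriched on Lp(a), log-normal
#' measurement noise, and logistic intensity-dependent missingness (so that
#' missing values concentrate at low abundance, the situation first-percentile
#' noise imputation presumes).
#'
#' Defaults describe a MaxQuant-scale experiment: base log2 intensities drawn
#' from N(25, 2), a 20% within-condition coefficient of variation, missingness
#' probability `plogis(missing_intercept + missing_slope * log2(true
#' intensity))` giving roughly 20% missing cells overall, and peptide support
#' `1 + Poisson(4)` per protein.
#'
#' @param n_proteins number of proteins.
#' @param n_pairs number of subjects; each contributes one Lp(a) and one LDL
#'   sample (`>= 2`).
#' @param enriched_ids integer indices of truly enriched proteins
#'   (subset of `1:n_proteins`).
#' @param log2_effect true log2(Lp(a)/LDL) enrichment, recycled over
#'   `enriched_ids`.
#' @param base_log_intensity per-protein true log2 intensity in the LDL
#'   condition; drawn from N(25, 2) when `NULL`.
#' @param cv within-condition coefficient of variation on the natural scale;
#'   noise is normal on the log2 scale with
#'   `sd = sqrt(log(1 + cv^2)) / log(2)`.
#' @param missing_slope,missing_intercept logistic missingness model
#'   coefficients; a negative slope puts missingness at low abundance.
#' @param peptide_counts distinct peptides per protein; drawn as
#'   `1 + rpois(lambda = 4)` when `NULL`.
#' @param seed integer seed; expanded internally into per-stage substreams.
#'
#' @return object of class `lfq_sim_truth`.
#' @export
lfq_sim_truth <- function(n_proteins = 2000, n_pairs = 6,
                          enriched_ids = integer(0), log2_effect = 3,
                          base_log_intensity = NULL, cv = 0.2,
                          missing_slope = -1, missing_intercept = 23,
                          peptide_counts = NULL, seed = 1L) {
  n_proteins <- assert_count(n_proteins, "n_proteins")
  n_pairs <- assert_count(n_pairs, "n_pairs", min = 2L)
  assert_scalar_num(cv, "cv", lower = 0)
  assert_scalar_num(missing_slope, "missing_slope")
  # -Inf is a legitimate intercept: it switches missingness off entirely
  if (!is.numeric(missing_intercept) || length(missing_intercept) != 1L ||
      is.na(missing_intercept)) {
    stop_("`missing_intercept` must be a single number (possibly -Inf)")
  }
  enriched_ids <- as.integer(enriched_ids)
  if (length(enriched_ids) &&
      (any(enriched_ids < 1L) || any(enriched_ids > n_proteins) ||
       anyDuplicated(enriched_ids))) {
    stop_("`enriched_ids` must be distinct indices in 1..n_proteins")
  }
  effects <- numeric(n_proteins)
  if (length(enriched_ids)) {
    effects[enriched_ids] <- rep_len(log2_effect, length(enriched_ids))
  }
  seeds <- derive_seeds(seed, 3L)
  if (is.null(base_log_intensity)) {
    base_log_intensity <- with_seed(seeds[1L], stats::rnorm(n_proteins, 25, 2))
  }
  if (length(base_log_intensity) != n_proteins) {
    stop_("`base_log_intensity` must have length n_proteins")
  }
  if (is.null(peptide_counts)) {
    peptide_counts <- with_seed(seeds[2L], 1L + stats::rpois(n_proteins, 4))
  }
  if (length(peptide_counts) != n_proteins || any(peptide_counts < 1)) {
    stop_("`peptide_counts` must have length n_proteins, all >= 1")
  }
  structure(
    list(
      n_proteins = n_proteins, n_pairs = n_pairs,
      enriched_ids = enriched_ids, log2_effect = effects,
      base_log_intensity = as.numeric(base_log_intensity), cv = cv,
      missing_slope = missing_slope, missing_intercept = missing_intercept,
      peptide_counts = as.integer(peptide_counts),
      seed = as.integer(seed), noise_seed = seeds[3L]
    ),
    class = "lfq_sim_truth"
  )
}

# P(cell missing) under the truth's logistic model, at true log2 intensity mu
missing_probability <- function(truth, mu) {
  stats::plogis(truth$missing_intercept + truth$missing_slope * mu)
}

#' Simulate a paired Lp(a)/LDL label-free intensity matrix
#'
#' Draws one experiment from the model described by [lfq_sim_truth()]:
#' intensities are `2^(mu + eps)` with `eps ~ N(0, sd_log2)`, where `mu` is the
#' protein's base log2 intensity plus its log2 enrichment in the Lp(a)
#' condition, and each cell is masked (set `NA`) with probability
#' `plogis(missing_intercept + missing_slope * mu)` evaluated at the cell's
#' true mean. Identical seeds give bit-identical matrices.
#'
#' @param truth an [lfq_sim_truth()] object.
#' @return an [intensity_matrix()] with samples `LPA_1..LPA_n, LDL_1..LDL_n`.
#' @export
simulate_lfq <- function(truth) {
  if (!inherits(truth, "lfq_sim_truth")) {
    stop_("`truth` must be an lfq_sim_truth object")
  }
  np <- truth$n_proteins
  k <- truth$n_pairs
  # true mean log2 intensity per protein x condition
  mu_lpa <- truth$base_log_intensity + truth$log2_effect
  mu_ldl <- truth$base_log_intensity
  sd_log2 <- sqrt(log1p(truth$cv^2)) / log(2)
  mu <- cbind(
    matrix(mu_lpa, np, k),
    matrix(mu_ldl, np, k)
  )
  x <- with_seed(truth$noise_seed, {
    eps <- matrix(stats::rnorm(np * 2L * k, 0, sd_log2), np, 2L * k)
    vals <- 2^(mu + eps)
    pmiss <- missing_probability(truth, mu)
    drop <- matrix(stats::runif(np * 2L * k) < pmiss, np, 2L * k)
    vals[drop] <- NA_real_
    vals
  })
  sample_ids <- c(sprintf("LPA_%d", seq_len(k)), sprintf("LDL_%d", seq_len(k)))
  dimnames(x) <- list(sprintf("protein_%04d", seq_len(np)), sample_ids)
  intensity_matrix(
    x,
    condition = rep(c("LPA", "LDL"), each = k),
    pair_id = rep(seq_len(k), times = 2L),
    peptide_counts = truth$peptide_counts
  )
}
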
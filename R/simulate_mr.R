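#' Ground truth for a simulated two-sample MR protein panel
#'
#' Describes the generating model behind [simulate_mr_panel()]. Instruments
#' are strong by construction, mirroring genome-wide-significant, LD-clumped
#' lipid variants from large consortia: true instrument-exposure effects
#' `beta_x ~ U(0.03, 0.3)` (per SD of exposure) with reported standard error
#' `se_x = 0.003`, and outcome-side standard error `se_y = 0.025` (a
#' SOMAscan-scale pQTL cohort of ~3300 individuals). For a causal protein the
#' outcome effect at instrument j is drawn as
#' `beta_y ~ N(theta * beta_x_j + alpha_j, se_y^2)` with direct (pleiotropic)
#' effects `alpha_j ~ N(0, pleiotropy_sd^2)`; for a null protein `theta = 0`.
#'
#' @param n_instruments number of independent instruments (e.g. 26 for an
#'   Lp(a)-like instrument, 54 for an LDL-cholesterol-like one).
#' @param theta true causal effect of the exposure on each causal protein.
#' @param beta_x true per-instrument exposure effects; drawn `U(0.03, 0.3)`
#'   with random sign when `NULL`.
#' @param se_x,se_y reported standard errors (exposure / outcome side), `> 0`.
#' @param pleiotropy_sd spread of direct effects, `>= 0`.
#' @param n_null_proteins,n_causal_proteins panel composition.
#' @param flip_fraction fraction of outcome rows whose alleles (and effect
#'   sign) are flipped relative to the exposure reference, to exercise
#'   harmonization.
#' @param seed integer seed.
#' @return object of class `mr_sim_truth`.
#' @export
mr_sim_truth <- function(n_instruments = 54, theta = 0.4, beta_x = NULL,
                         se_x = 0.003, se_y = 0.025, pleiotropy_sd = 0,
                         n_null_proteins = 0, n_causal_proteins = 1,
                         flip_fraction = 0.2, seed = 1L) {
  n_instruments <- assert_count(n_instruments, "n_instruments")
  assert_scalar_num(theta, "theta")
  assert_scalar_num(se_x, "se_x", lower = 0, strict_lower = TRUE)
  assert_scalar_num(se_y, "se_y", lower = 0, strict_lower = TRUE)
  assert_scalar_num(pleiotropy_sd, "pleiotropy_sd", lower = 0)
  assert_scalar_num(flip_fraction, "flip_fraction", lower = 0, upper = 1)
  n_null_proteins <- assert_count(n_null_proteins, "n_null_proteins", min = 0L)
  n_causal_proteins <- assert_count(n_causal_proteins, "n_causal_proteins",
                                    min = 0L)
  if (n_null_proteins + n_causal_proteins < 1L) {
    stop_("panel must contain at least one protein")
  }
  seeds <- derive_seeds(seed, 2L)
  if (is.null(beta_x)) {
    beta_x <- with_seed(seeds[1L], {
      stats::runif(n_instruments, 0.03, 0.3) *
        sample(c(-1, 1), n_instruments, replace = TRUE)
    })
  }
  if (length(beta_x) != n_instruments || any(beta_x == 0)) {
    stop_("`beta_x` must have length n_instruments with no zero entries")
  }
  structure(
    list(
      n_instruments = n_instruments, theta = theta,
      beta_x = as.numeric(beta_x), se_x = se_x, se_y = se_y,
      pleiotropy_sd = pleiotropy_sd,
      n_null_proteins = n_null_proteins,
      n_causal_proteins = n_causal_proteins,
      flip_fraction = flip_fraction,
      seed = as.integer(seed), noise_seed = seeds[2L]
    ),
    class = "mr_sim_truth"
  )
}

# ordered, non-palindromic allele pairs (no A/T or C/G), so default simulated
# panels never hit the ambiguous-strand drop rule
.nonpalindromic_pairs <- matrix(c(
  "A", "C", "A", "G", "C", "A", "C", "T",
  "G", "A", "G", "T", "T", "C", "T", "G"
), ncol = 2, byrow = TRUE)

#' Simulate a two-sample MR screen: instruments plus per-protein outcomes
#'
#' Draws GWAS-style summary statistics under the model in [mr_sim_truth()].
#' The exposure table reports `beta_x + N(0, se_x^2)` (the two-sample design:
#' the analyst never sees the true effect); outcome means use the true
#' `beta_x`. A `flip_fraction` of each outcome table's rows has effect/other
#' alleles swapped with the effect sign negated, which harmonization must
#' undo. Causal proteins come first in the panel.
#'
#' @param truth an [mr_sim_truth()] object.
#' @return list with `instruments` (exposure association table), `panel`
#'   (named list of outcome association tables, one per protein) and `truth`
#'   (data.frame of per-protein true effects).
#' @export
simulate_mr_panel <- function(truth) {
  if (!inherits(truth, "mr_sim_truth")) {
    stop_("`truth` must be an mr_sim_truth object")
  }
  k <- truth$n_instruments
  npro <- truth$n_causal_proteins + truth$n_null_proteins
  theta_p <- c(rep(truth$theta, truth$n_causal_proteins),
               rep(0, truth$n_null_proteins))
  protein_id <- sprintf("P%04d", seq_len(npro))
  with_seed(truth$noise_seed, {
    pair_idx <- sample.int(nrow(.nonpalindromic_pairs), k, replace = TRUE)
    ea <- .nonpalindromic_pairs[pair_idx, 1L]
    oa <- .nonpalindromic_pairs[pair_idx, 2L]
    variant_id <- sprintf("rs%06d", sample.int(999999L, k))
    bx_hat <- truth$beta_x + stats::rnorm(k, 0, truth$se_x)
    instruments <- data.frame(
      variant_id = variant_id,
      effect_allele = ea, other_allele = oa,
      beta = bx_hat, se = truth$se_x,
      pvalue = 2 * stats::pnorm(-abs(bx_hat) / truth$se_x),
      stringsAsFactors = FALSE
    )
    panel <- vector("list", npro)
    names(panel) <- protein_id
    for (p in seq_len(npro)) {
      alpha <- if (truth$pleiotropy_sd > 0) {
        stats::rnorm(k, 0, truth$pleiotropy_sd)
      } else {
        numeric(k)
      }
      by <- theta_p[p] * truth$beta_x + alpha + stats::rnorm(k, 0, truth$se_y)
      flip <- stats::runif(k) < truth$flip_fraction
      out <- data.frame(
        variant_id = variant_id,
        effect_allele = ifelse(flip, oa, ea),
        other_allele = ifelse(flip, ea, oa),
        beta = ifelse(flip, -by, by),
        se = truth$se_y,
        pvalue = 2 * stats::pnorm(-abs(by) / truth$se_y),
        stringsAsFactors = FALSE
      )
      panel[[p]] <- out
    }
    list(
      instruments = instruments,
      panel = panel,
      truth = data.frame(
        protein_id = protein_id, theta = theta_p,
        causal = theta_p != 0, stringsAsFactors = FALSE
      )
    )
  })
}
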
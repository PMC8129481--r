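#' Paired ratio test per protein
#'
#' For each protein, reports the mean Lp(a) / mean LDL intensity ratio
#' (natural scale) and a paired two-sided t-test on the per-subject
#' differences — of log2 intensities by default, of raw intensities with
#' `log_transform = FALSE`.
#'
#' Degenerate inputs: when all per-pair differences are exactly equal
#' (zero variance), the P value is 1 if the common difference is 0, and the
#' smallest representable nonzero double otherwise; such proteins carry
#' `zero_variance = TRUE`.
#'
#' @param m an [intensity_matrix()], already normalized and imputed (no
#'   missing cells) with at least 2 pairs.
#' @param log_transform test on log2 intensities (default) or raw.
#' @return data.frame of class `diff_result` with columns `protein_id`,
#'   `ratio`, `t_plain`, `p_plain`, `n_obs_lpa`, `n_obs_ldl`,
#'   `zero_variance`.
#' @export
paired_ratio_test <- function(m, log_transform = TRUE) {
  stopifnot(inherits(m, "intensity_matrix"))
  if (anyNA(m$intensities)) {
    stop_("matrix still contains missing cells; impute before testing")
  }
  if (n_pairs(m) < 2L) stop_("paired test needs >= 2 pairs")
  cols <- paired_columns(m)
  lpa <- m$intensities[, cols$lpa, drop = FALSE]
  ldl <- m$intensities[, cols$ldl, drop = FALSE]
  n <- length(cols$lpa)
  ratio <- rowMeans(lpa) / rowMeans(ldl)
  d <- if (log_transform) log2(lpa) - log2(ldl) else lpa - ldl
  md <- rowMeans(d)
  vd <- row_vars(d)
  tt <- md / sqrt(vd / n)
  p <- 2 * stats::pt(-abs(tt), df = n - 1L)
  zero_var <- vd == 0
  if (any(zero_var)) {
    z0 <- zero_var & md == 0
    zs <- zero_var & md != 0
    tt[z0] <- 0
    p[z0] <- 1
    tt[zs] <- sign(md[zs]) * Inf
    p[zs] <- .Machine$double.xmin
  }
  obs <- !is.na(m$intensities)
  res <- data.frame(
    protein_id = protein_ids(m),
    ratio = ratio,
    t_plain = tt,
    p_plain = p,
    n_obs_lpa = rowSums(obs[, m$condition == "LPA", drop = FALSE]),
    n_obs_ldl = rowSums(obs[, m$condition == "LDL", drop = FALSE]),
    zero_variance = zero_var,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  class(res) <- c("diff_result", "data.frame")
  res
}

# per-protein paired differences on the testing scale
paired_diffs <- function(m, log_transform = TRUE) {
  cols <- paired_columns(m)
  lpa <- m$intensities[, cols$lpa, drop = FALSE]
  ldl <- m$intensities[, cols$ldl, drop = FALSE]
  if (log_transform) log2(lpa) - log2(ldl) else lpa - ldl
}

#' Empirical-Bayes moderation parameters from per-protein variances
#'
#' Fits the scaled-inverse-chi-square prior `s_g^2 ~ s0^2 * d0 / chisq(d0)`
#' by matching moments of the log variances against the theoretical log-F
#' distribution (digamma/trigamma moment equations). When the observed spread
#' of log variances does not exceed what sampling alone explains, `d0` is
#' `+Inf` (complete shrinkage to the common prior variance) — a legitimate
#' fit, not an error.
#'
#' @param variances per-protein residual variances; at least 10 finite,
#'   strictly positive values are required (non-positive ones are dropped
#'   with a warning).
#' @param df residual degrees of freedom, scalar or one per variance.
#' @return list of class `moderation_params` with `d0` (prior df), `s0_sq`
#'   (prior variance) and `residual_df`.
#' @export
fit_moderation <- function(variances, df) {
  variances <- as.numeric(variances)
  if (length(df) == 1L) df <- rep(df, length(variances))
  if (length(df) != length(variances)) {
    stop_("`df` must be scalar or match `variances` in length")
  }
  keep <- is.finite(variances) & variances > 0 & is.finite(df) & df > 0
  if (any(!keep)) {
    warning(sprintf("dropping %d non-positive/non-finite variances from the moderation fit",
                    sum(!keep)), call. = FALSE)
  }
  s2 <- variances[keep]
  df <- df[keep]
  if (length(s2) < 10L) {
    stop_("need >= 10 finite positive variances to fit moderation parameters")
  }
  # Moment matching on z = log(s^2):
  #   E[z] = log(s0^2) + digamma(df/2) - log(df/2) - digamma(d0/2) + log(d0/2)
  #   Var[z] = trigamma(df/2) + trigamma(d0/2)
  e <- log(s2) - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- stats::var(e) - mean(trigamma(df / 2))
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0_sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0_sq <- exp(emean)
  }
  structure(list(d0 = d0, s0_sq = s0_sq, residual_df = df),
            class = "moderation_params")
}

# Newton solve of trigamma(y) = x; monotone decreasing, convex in 1/y
trigamma_inverse <- function(x) {
  stopifnot(is.finite(x), x > 0)
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:75) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2L)
    y <- y + dif
    if (abs(dif) / y < 1e-10) break
  }
  y
}

#' @export
print.moderation_params <- function(x, ...) {
  cat(sprintf("<moderation_params> d0 = %s, s0_sq = %.6g\n",
              format(x$d0), x$s0_sq))
  invisible(x)
}

#' Moderated paired t-test
#'
#' Shrinks each protein's paired-difference variance toward the empirical-
#' Bayes prior, `s2_post = (d0 * s0_sq + df * s2) / (d0 + df)`, and tests
#' `t_mod = mean difference / sqrt(s2_post / n)` against a t distribution on
#' `d0 + df` degrees of freedom. With `d0 = 0` this is the ordinary paired t;
#' with `d0 = Inf` every protein is tested against the common prior variance.
#'
#' @param m an imputed [intensity_matrix()].
#' @param params a [fit_moderation()] object (or a list with `d0`, `s0_sq`).
#' @param log_transform as in [paired_ratio_test()].
#' @return data.frame with `protein_id`, `s2`, `s2_post`, `t_mod`, `p_mod`.
#' @export
moderated_test <- function(m, params, log_transform = TRUE) {
  stopifnot(inherits(m, "intensity_matrix"))
  if (anyNA(m$intensities)) {
    stop_("matrix still contains missing cells; impute before testing")
  }
  d0 <- params$d0
  s0_sq <- params$s0_sq
  if (!is.numeric(d0) || d0 < 0) stop_("`d0` must be >= 0")
  if (!is.numeric(s0_sq) || (s0_sq <= 0 && d0 > 0)) {
    stop_("`s0_sq` must be > 0")
  }
  d <- paired_diffs(m, log_transform)
  n <- ncol(d)
  df <- n - 1L
  md <- rowMeans(d)
  s2 <- row_vars(d)
  s2_post <- if (is.infinite(d0)) {
    rep(s0_sq, length(s2))
  } else {
    (d0 * s0_sq + df * s2) / (d0 + df)
  }
  t_mod <- md / sqrt(s2_post / n)
  df_total <- d0 + df
  p_mod <- 2 * stats::pt(-abs(t_mod), df = df_total)
  # degenerate posteriors (possible when d0 = 0 and a protein's paired
  # differences are constant): same rules as the plain paired test
  zero <- s2_post == 0
  if (any(zero)) {
    z0 <- zero & md == 0
    zs <- zero & md != 0
    t_mod[z0] <- 0
    p_mod[z0] <- 1
    t_mod[zs] <- sign(md[zs]) * Inf
    p_mod[zs] <- .Machine$double.xmin
  }
  data.frame(
    protein_id = protein_ids(m),
    s2 = s2, s2_post = s2_post,
    t_mod = t_mod, p_mod = p_mod,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Benjamini-Hochberg step-up adjustment
#'
#' `q_(i) = min over j >= i of m * p_(j) / j` on the sorted P values, capped
#' at 1; ties share the rank-based value and the adjusted values are monotone
#' in P-value rank.
#'
#' @param p numeric vector of P values in \[0, 1\].
#' @return vector of BH-adjusted values (q values), same order as `p`.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (!is.numeric(p) || anyNA(p) || any(p < 0) || any(p > 1)) {
    stop_("all P values must lie in [0, 1]")
  }
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  q <- pmin(1, cummin(m * p[o] / (m:1)))
  q[order(o)]
}

#' Full label-free differential-enrichment pipeline
#'
#' Runs the whole engine on a raw intensity matrix: quantifiability flags on
#' the pre-imputation mask, median normalization, first-percentile noise
#' imputation, paired ratio test, empirical-Bayes moderation (fit on the
#' quantifiable proteins' paired-difference variances) and BH adjustment of
#' both the plain and the moderated P values. Statistics are reported only
#' for quantifiable proteins; the others keep their flag and `NA` statistics.
#'
#' @param m a raw [intensity_matrix()].
#' @param frac,min_peptides quantifiability rule, see
#'   [quantifiability_filter()].
#' @param log_transform test on log2 intensities (default) or raw scale.
#' @param moderate fit and apply empirical-Bayes moderation (default TRUE).
#' @return a `diff_result` data.frame with one row per protein: `ratio`,
#'   `t_plain`, `p_plain`, `t_mod`, `p_mod`, `q` (BH on the moderated P),
#'   `q_plain`, observation counts and the `quantifiable` flag. The fitted
#'   [fit_moderation()] parameters ride along as attribute `"moderation"`.
#' @export
lfq_diff <- function(m, frac = 2 / 3, min_peptides = 2, log_transform = TRUE,
                     moderate = TRUE) {
  stopifnot(inherits(m, "intensity_matrix"))
  flags <- quantifiability_filter(m, frac = frac, min_peptides = min_peptides)
  norm <- median_normalize(m)
  imp <- impute_first_percentile(norm)
  keep <- which(flags)
  if (length(keep) == 0L) stop_("no quantifiable proteins")
  sub <- subset_proteins(imp, keep)
  res <- paired_ratio_test(sub, log_transform = log_transform)
  # observation counts must reflect the pre-imputation mask, not the imputed
  # (complete) matrix the test runs on
  obs <- !is.na(m$intensities[keep, , drop = FALSE])
  res$n_obs_lpa <- rowSums(obs[, m$condition == "LPA", drop = FALSE])
  res$n_obs_ldl <- rowSums(obs[, m$condition == "LDL", drop = FALSE])
  params <- NULL
  if (moderate) {
    d <- paired_diffs(sub, log_transform)
    s2 <- row_vars(d)
    df <- ncol(d) - 1L
    ok <- is.finite(s2) & s2 > 0
    if (sum(ok) >= 10L) {
      params <- fit_moderation(s2[ok], df)
      mod <- moderated_test(sub, params, log_transform = log_transform)
      res$t_mod <- mod$t_mod
      res$p_mod <- mod$p_mod
    } else {
      moderate <- FALSE
    }
  }
  if (!moderate) {
    res$t_mod <- res$t_plain
    res$p_mod <- res$p_plain
  }
  res$q <- bh_adjust(res$p_mod)
  res$q_plain <- bh_adjust(res$p_plain)
  # re-expand to all proteins, NA stats for the unquantifiable
  full <- data.frame(
    protein_id = protein_ids(m), stringsAsFactors = FALSE
  )
  full <- merge(full, res, by = "protein_id", all.x = TRUE, sort = FALSE)
  full <- full[match(protein_ids(m), full$protein_id), , drop = FALSE]
  full$quantifiable <- unname(flags)
  rownames(full) <- NULL
  class(full) <- c("diff_result", "data.frame")
  attr(full, "moderation") <- params
  full
}
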
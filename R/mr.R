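#' Genome-wide-significance instrument selection
#'
#' Keeps variants whose exposure association P value is strictly below the
#' threshold (`< 5e-8` by default), preserving row order.
#'
#' @param assocs association data.frame with a `pvalue` column.
#' @param p_threshold significance threshold (strict `<`).
#' @return the filtered data.frame.
#' @export
select_instruments <- function(assocs, p_threshold = 5e-8) {
  if (!"pvalue" %in% names(assocs)) {
    stop_("`assocs` must carry a `pvalue` column for instrument selection")
  }
  assert_scalar_num(p_threshold, "p_threshold", lower = 0, upper = 1,
                    strict_lower = TRUE)
  out <- assocs[assocs$pvalue < p_threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Greedy LD clumping
#'
#' Repeatedly retains the remaining variant with the smallest P value and
#' discards every remaining variant in linkage disequilibrium with it
#' (`r^2 >= r2_threshold`), so all retained pairs satisfy
#' `r^2 < r2_threshold`.
#'
#' @param assocs association data.frame with `variant_id` and `pvalue`.
#' @param ld square pairwise r-squared matrix with dimnames covering
#'   `assocs$variant_id`; symmetric, unit diagonal, entries in \[0, 1\].
#' @param r2_threshold independence threshold (default 0.1).
#' @return the retained subset of `assocs`, in decreasing significance order.
#' @export
ld_clump <- function(assocs, ld, r2_threshold = 0.1) {
  if (!all(c("variant_id", "pvalue") %in% names(assocs))) {
    stop_("`assocs` needs `variant_id` and `pvalue` columns")
  }
  assert_scalar_num(r2_threshold, "r2_threshold", lower = 0, upper = 1,
                    strict_lower = TRUE)
  ids <- assocs$variant_id
  if (!is.matrix(ld) || is.null(dimnames(ld)) ||
      !all(ids %in% rownames(ld)) || !all(ids %in% colnames(ld))) {
    stop_("`ld` must be a named square matrix covering all variant ids")
  }
  ld <- ld[ids, ids, drop = FALSE]
  if (any(ld < 0) || any(ld > 1) || !isTRUE(all.equal(ld, t(ld))) ||
      !isTRUE(all.equal(unname(diag(ld)), rep(1, length(ids))))) {
    stop_("`ld` must be symmetric with unit diagonal and entries in [0, 1]")
  }
  remaining <- seq_along(ids)
  kept <- integer(0)
  while (length(remaining)) {
    lead <- remaining[which.min(assocs$pvalue[remaining])]
    kept <- c(kept, lead)
    remaining <- remaining[ld[lead, remaining] < r2_threshold]
  }
  out <- assocs[kept, , drop = FALSE]
  rownames(out) <- NULL
  out
}

strand_complement <- function(a) chartr("ACGT", "TGCA", toupper(a))

is_palindromic <- function(ea, oa) strand_complement(ea) == toupper(oa)

#' Harmonize outcome alleles to the exposure reference
#'
#' Aligns the outcome association table onto the exposure's effect/other
#' allele orientation, variant by variant:
#' \itemize{
#'   \item alleles match: kept as is;
#'   \item alleles swapped: outcome beta negated;
#'   \item strand-complement (or complement-swapped) alleles: handled like
#'     match/swap when `allow_strand_flip = TRUE` (default), else dropped;
#'   \item palindromic variants (A/T, C/G): aligned by effect-allele
#'     frequency when both tables carry an `eaf` column and neither frequency
#'     is ambiguous (within `eaf_ambiguity` of 0.5); dropped otherwise;
#'   \item anything else: dropped as incompatible.
#' }
#' Drops are data, not errors: they are returned in the `"dropped"` attribute
#' with a reason per variant.
#'
#' @param exposure,outcome association data.frames with columns `variant_id`,
#'   `effect_allele`, `other_allele`, `beta`, `se` (optional `eaf`).
#' @param allow_strand_flip accept strand-complement reports.
#' @param eaf_ambiguity half-width of the frequency window around 0.5 inside
#'   which a palindromic variant is considered unresolvable (default 0.08).
#' @return data.frame with exposure-oriented columns `variant_id`,
#'   `effect_allele`, `other_allele`, `beta_x`, `se_x`, `beta_y`, `se_y`;
#'   attribute `"dropped"` lists excluded variants and reasons.
#' @export
harmonize <- function(exposure, outcome, allow_strand_flip = TRUE,
                      eaf_ambiguity = 0.08) {
  need <- c("variant_id", "effect_allele", "other_allele", "beta", "se")
  if (!all(need %in% names(exposure)) || !all(need %in% names(outcome))) {
    stop_("exposure and outcome need columns: %s", paste(need, collapse = ", "))
  }
  common <- intersect(exposure$variant_id, outcome$variant_id)
  ex <- exposure[match(common, exposure$variant_id), , drop = FALSE]
  ou <- outcome[match(common, outcome$variant_id), , drop = FALSE]
  n <- length(common)
  keep <- logical(n)
  flip <- logical(n)
  reason <- character(n)
  has_eaf <- "eaf" %in% names(ex) && "eaf" %in% names(ou)
  for (i in seq_len(n)) {
    ea_x <- toupper(ex$effect_allele[i]); oa_x <- toupper(ex$other_allele[i])
    ea_y <- toupper(ou$effect_allele[i]); oa_y <- toupper(ou$other_allele[i])
    if (is_palindromic(ea_x, oa_x)) {
      if (has_eaf && !is.na(ex$eaf[i]) && !is.na(ou$eaf[i]) &&
          abs(ex$eaf[i] - 0.5) > eaf_ambiguity &&
          abs(ou$eaf[i] - 0.5) > eaf_ambiguity) {
        # same minor/major side -> aligned, opposite -> flipped
        keep[i] <- TRUE
        flip[i] <- (ex$eaf[i] - 0.5) * (ou$eaf[i] - 0.5) < 0
      } else {
        reason[i] <- "palindromic_ambiguous"
      }
      next
    }
    if (ea_y == ea_x && oa_y == oa_x) {
      keep[i] <- TRUE
    } else if (ea_y == oa_x && oa_y == ea_x) {
      keep[i] <- TRUE; flip[i] <- TRUE
    } else if (allow_strand_flip &&
               ea_y == strand_complement(ea_x) &&
               oa_y == strand_complement(oa_x)) {
      keep[i] <- TRUE
    } else if (allow_strand_flip &&
               ea_y == strand_complement(oa_x) &&
               oa_y == strand_complement(ea_x)) {
      keep[i] <- TRUE; flip[i] <- TRUE
    } else {
      reason[i] <- "incompatible_alleles"
    }
  }
  out <- data.frame(
    variant_id = common[keep],
    effect_allele = toupper(ex$effect_allele[keep]),
    other_allele = toupper(ex$other_allele[keep]),
    beta_x = ex$beta[keep],
    se_x = ex$se[keep],
    beta_y = ifelse(flip[keep], -ou$beta[keep], ou$beta[keep]),
    se_y = ou$se[keep],
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  attr(out, "dropped") <- data.frame(
    variant_id = common[!keep], reason = reason[!keep],
    stringsAsFactors = FALSE
  )
  out
}

#' Wald ratio per instrument
#'
#' `theta = beta_y / beta_x`, first-order standard error
#' `se = se_y / |beta_x|` (exposure-side uncertainty ignored, the standard
#' strong-instrument approximation). With `second_order = TRUE` and `se_x`
#' supplied, the delta-method term `beta_y^2 se_x^2 / beta_x^4` is added.
#'
#' @param bx,by instrument-exposure and instrument-outcome effects.
#' @param se_y outcome-side standard errors.
#' @param se_x exposure-side standard errors (second-order only).
#' @param second_order include the exposure-variance term.
#' @return data.frame with `theta` and `se`.
#' @export
wald_ratio <- function(bx, by, se_y, se_x = NULL, second_order = FALSE) {
  if (any(bx == 0)) stop_("beta_x = 0: exclude null instruments upstream")
  if (any(se_y <= 0)) stop_("se_y must be > 0")
  se <- se_y / abs(bx)
  if (second_order) {
    if (is.null(se_x)) stop_("second-order SE needs `se_x`")
    se <- sqrt(se_y^2 / bx^2 + by^2 * se_x^2 / bx^4)
  }
  data.frame(theta = by / bx, se = se)
}

#' Inverse-variance-weighted meta-analysis of Wald ratios
#'
#' Fixed-effect IVW: weights `w_j = se_j^-2`, estimate
#' `sum(w theta) / sum(w)`, standard error `sum(w)^-1/2`, z test against the
#' standard normal. Equivalent to the zero-intercept weighted least-squares
#' regression of the outcome effects on the exposure effects with weights
#' `se_y^-2`. A multiplicative random-effects variant
#' (`random_effects = TRUE`) scales the SE by `max(1, sqrt(Q / (k - 1)))`.
#'
#' @param theta Wald ratios.
#' @param se their standard errors (`> 0`).
#' @param random_effects apply the multiplicative overdispersion correction.
#' @return list with `theta`, `se`, `z`, `pvalue`, `n_snps`, `Q`.
#' @export
ivw <- function(theta, se, random_effects = FALSE) {
  if (length(theta) == 0L) stop_("no Wald ratios to meta-analyse")
  if (length(se) != length(theta) || any(se <= 0)) {
    stop_("`se` must match `theta` and be > 0")
  }
  w <- se^-2
  est <- sum(w * theta) / sum(w)
  se_ivw <- sum(w)^-0.5
  k <- length(theta)
  q <- sum(w * (theta - est)^2)
  if (random_effects && k > 1L) {
    se_ivw <- se_ivw * max(1, sqrt(q / (k - 1)))
  }
  z <- est / se_ivw
  list(theta = est, se = se_ivw, z = z,
       pvalue = 2 * stats::pnorm(-abs(z)), n_snps = k, Q = q)
}

#' Bonferroni significance threshold
#'
#' @param alpha family-wise error rate, in (0, 1).
#' @param m number of tests (e.g. 3283 for an aptamer panel, 41 for a
#'   cytokine panel).
#' @return `alpha / m`.
#' @export
bonferroni_threshold <- function(alpha, m) {
  assert_scalar_num(alpha, "alpha", lower = 0, upper = 1, strict_lower = TRUE)
  if (alpha >= 1) stop_("`alpha` must be < 1")
  m <- assert_count(m, "m")
  alpha / m
}

#' Two-sample MR screen over a protein panel
#'
#' For each protein: harmonize its outcome table to the instrument set,
#' compute per-variant Wald ratios, meta-analyse by fixed-effect IVW, and
#' flag Bonferroni-significant effects at `alpha / m` (strict `<`). Proteins
#' with no harmonizable instrument are reported with missing results rather
#' than dropped.
#'
#' @param instruments exposure association table (the allele reference).
#' @param panel named list of per-protein outcome association tables.
#' @param alpha family-wise error rate.
#' @param m Bonferroni denominator; defaults to `length(panel)`. Set 3283
#'   for an aptamer-panel-scale screen regardless of how many proteins are
#'   actually replayed.
#' @param random_effects see [ivw()].
#' @param ... passed to [harmonize()].
#' @return data.frame of class `mr_result`, sorted by P value (missing
#'   results last): `outcome_id`, `theta`, `se`, `z`, `pvalue`, `n_snps`,
#'   `passes_bonferroni`.
#' @export
mr_screen <- function(instruments, panel, alpha = 0.05, m = NULL,
                      random_effects = FALSE, ...) {
  if (!is.list(panel) || length(panel) == 0L) stop_("`panel` must be a non-empty list")
  if (is.null(names(panel)) || anyDuplicated(names(panel))) {
    stop_("`panel` must be uniquely named by protein")
  }
  if (is.null(m)) m <- length(panel)
  thr <- bonferroni_threshold(alpha, m)
  rows <- lapply(names(panel), function(prot) {
    h <- harmonize(instruments, panel[[prot]], ...)
    h <- h[h$beta_x != 0, , drop = FALSE]
    if (nrow(h) == 0L) {
      return(data.frame(outcome_id = prot, theta = NA_real_, se = NA_real_,
                        z = NA_real_, pvalue = NA_real_, n_snps = 0L,
                        passes_bonferroni = NA, stringsAsFactors = FALSE))
    }
    wr <- wald_ratio(h$beta_x, h$beta_y, h$se_y)
    iv <- ivw(wr$theta, wr$se, random_effects = random_effects)
    data.frame(outcome_id = prot, theta = iv$theta, se = iv$se, z = iv$z,
               pvalue = iv$pvalue, n_snps = iv$n_snps,
               passes_bonferroni = iv$pvalue < thr, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$pvalue, out$outcome_id, na.last = TRUE), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "bonferroni_threshold") <- thr
  class(out) <- c("mr_result", "data.frame")
  out
}
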
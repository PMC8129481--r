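#' Average duplicate injections
#'
#' Collapses the two injection replicates of each calibration level (and each
#' sample) to the arithmetic mean of their peak areas. Single injections pass
#' through; more than two per key is an error.
#'
#' @param batch a [prm_batch()].
#' @return a [prm_batch()] with one record per (peptide, level) and per
#'   (peptide, sample).
#' @export
average_injections <- function(batch) {
  stopifnot(inherits(batch, "prm_batch"))
  avg <- function(df, key_cols) {
    key <- interaction(df[key_cols], drop = TRUE)
    counts <- table(key)
    if (any(counts > 2L)) {
      stop_("more than 2 injection replicates for: %s",
            paste(names(counts)[counts > 2L], collapse = ", "))
    }
    idx <- !duplicated(key)
    out <- df[idx, , drop = FALSE]
    for (col in c("light_area", "heavy_area", "is_area")) {
      means <- tapply(df[[col]], key, mean)
      out[[col]] <- as.numeric(means[as.character(key[idx])])
    }
    out$replicate <- 1L
    rownames(out) <- NULL
    out
  }
  calibration <- avg(batch$calibration, c("peptide_id", "level_fmol_per_ul"))
  samples <- NULL
  if (!is.null(batch$samples)) {
    samples <- avg(batch$samples, c("peptide_id", "sample_id"))
  }
  prm_batch(calibration, samples)
}

#' Internal-standard normalization
#'
#' Scales each record's light and heavy areas by its internal-standard
#' response relative to the peptide's reference IS area (the median IS area
#' over all of that peptide's records, calibration and samples jointly), so
#' injection-to-injection intensity drift cancels. The light/heavy ratio
#' within a record is untouched.
#'
#' @param batch a [prm_batch()] with strictly positive `is_area` everywhere.
#' @return the IS-normalized [prm_batch()].
#' @export
is_normalize <- function(batch) {
  stopifnot(inherits(batch, "prm_batch"))
  all_is <- c(batch$calibration$is_area,
              if (!is.null(batch$samples)) batch$samples$is_area)
  all_pep <- c(batch$calibration$peptide_id,
               if (!is.null(batch$samples)) batch$samples$peptide_id)
  if (any(all_is <= 0)) {
    bad <- which(all_is <= 0)
    stop_("zero/negative internal-standard area in record(s) %s",
          paste(bad, collapse = ", "))
  }
  ref <- tapply(all_is, all_pep, stats::median)
  ref <- stats::setNames(as.numeric(ref), names(ref))
  scale_tbl <- function(df) {
    fac <- df$is_area / ref[df$peptide_id]
    df$light_area <- df$light_area / fac
    df$heavy_area <- df$heavy_area / fac
    df
  }
  batch$calibration <- scale_tbl(batch$calibration)
  if (!is.null(batch$samples)) batch$samples <- scale_tbl(batch$samples)
  batch
}

#' Fit the heavy-peptide standard curve
#'
#' Ordinary (optionally 1/x-weighted) least squares of heavy peak area on
#' spiked amount, per peptide. The curve serves as a linearity/QC gate for
#' single-point quantification: a peptide whose `r_squared` falls below the
#' threshold should not be trusted (see [prm_quant()]).
#'
#' @param calibration calibration data.frame (see [prm_batch()]).
#' @param weighting `"none"` (default) or `"1/x"`.
#' @return data.frame per peptide: `slope`, `intercept`, `r_squared`.
#' @export
fit_standard_curve <- function(calibration, weighting = c("none", "1/x")) {
  weighting <- match.arg(weighting)
  need <- c("peptide_id", "level_fmol_per_ul", "heavy_area")
  if (!all(need %in% names(calibration))) {
    stop_("calibration needs columns: %s", paste(need, collapse = ", "))
  }
  peps <- unique(calibration$peptide_id)
  out <- lapply(peps, function(pep) {
    df <- calibration[calibration$peptide_id == pep, , drop = FALSE]
    if (length(unique(df$level_fmol_per_ul)) < 2L) {
      stop_("peptide %s: standard curve needs >= 2 distinct levels", pep)
    }
    w <- if (weighting == "1/x") 1 / df$level_fmol_per_ul else
      rep(1, nrow(df))
    fit <- stats::lm(heavy_area ~ level_fmol_per_ul, data = df, weights = w)
    y <- df$heavy_area
    ss_res <- sum(w * stats::residuals(fit)^2)
    ss_tot <- sum(w * (y - stats::weighted.mean(y, w))^2)
    data.frame(
      peptide_id = pep,
      slope = unname(stats::coef(fit)[2L]),
      intercept = unname(stats::coef(fit)[1L]),
      r_squared = if (ss_tot == 0) 1 else 1 - ss_res / ss_tot,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}

#' Single-point absolute quantification against the heavy spike
#'
#' `concentration = (light_area / heavy_area) * heavy_spike_fmol /
#' loaded_mass_ug`, in fmol per microgram of loaded fraction protein. A zero
#' light area is a true zero (`detected = FALSE`, concentration 0); a zero
#' heavy area means the reference itself failed, so the concentration is
#' reported missing with `detected = FALSE`, never as zero.
#'
#' @param samples sample data.frame (see [prm_batch()]); areas assumed
#'   IS-normalized and injection-averaged.
#' @return the data.frame with `conc_fmol_per_ug` and `detected` appended.
#' @export
quantify <- function(samples) {
  need <- c("peptide_id", "sample_id", "light_area", "heavy_area",
            "heavy_spike_fmol", "loaded_mass_ug")
  if (!all(need %in% names(samples))) {
    stop_("samples need columns: %s", paste(need, collapse = ", "))
  }
  if (any(samples$heavy_spike_fmol <= 0)) stop_("heavy_spike_fmol must be > 0")
  if (any(samples$loaded_mass_ug <= 0)) stop_("loaded_mass_ug must be > 0")
  conc <- (samples$light_area / samples$heavy_area) *
    samples$heavy_spike_fmol / samples$loaded_mass_ug
  detected <- samples$light_area > 0 & samples$heavy_area > 0
  conc[samples$heavy_area == 0] <- NA_real_
  conc[samples$light_area == 0 & samples$heavy_area > 0] <- 0
  samples$conc_fmol_per_ug <- conc
  samples$detected <- detected
  samples
}

#' Molar ratio of two co-measured proteins
#'
#' With both concentrations in fmol/ug of the same loaded fraction, the ratio
#' is dimensionless — e.g. PCSK9 molecules per particle when divided by apoB,
#' since each lipoprotein particle carries exactly one apoB. A missing
#' numerator propagates as missing (never as 0); a zero/missing denominator is
#' an error.
#'
#' @param num,denom concentrations in fmol/ug (vectors recycle).
#' @return numeric vector of ratios.
#' @export
molar_ratio <- function(num, denom) {
  if (any(!is.na(denom) & denom <= 0)) stop_("denominator must be > 0")
  if (anyNA(denom)) stop_("denominator concentration is missing")
  num / denom
}

#' Welch's unequal-variance t-test
#'
#' Two-sided Welch t with Satterthwaite degrees of freedom. Identical
#' constant groups return `t = 0, p = 1` rather than erroring.
#'
#' @param group_a,group_b numeric vectors, each with at least 2 values.
#' @return list with `t`, `df`, `p`.
#' @export
welch_test <- function(group_a, group_b) {
  if (length(group_a) < 2L || length(group_b) < 2L) {
    stop_("each group needs >= 2 values")
  }
  if (stats::sd(group_a) == 0 && stats::sd(group_b) == 0) {
    if (mean(group_a) == mean(group_b)) {
      return(list(t = 0, df = length(group_a) + length(group_b) - 2, p = 1))
    }
    return(list(t = sign(mean(group_a) - mean(group_b)) * Inf,
                df = length(group_a) + length(group_b) - 2, p = 0))
  }
  ht <- stats::t.test(group_a, group_b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value)
}

#' Targeted PRM quantification pipeline
#'
#' Averages injections, normalizes to the internal standard, fits the
#' standard curve as a linearity gate, quantifies every sample by
#' single-point heavy-standard ratio, and summarises each peptide with the
#' mean Lp(a)/LDL concentration ratio and a Welch P value. Ratios use
#' detected concentrations only; peptides undetected in a whole fraction
#' report a missing ratio.
#'
#' @param batch a [prm_batch()] with sample records.
#' @param r2_threshold minimum standard-curve r-squared to flag a peptide as
#'   linear (default 0.98).
#' @param weighting standard-curve weighting, see [fit_standard_curve()].
#' @return list of class `prm_result`: `curves`, `concentrations`, `summary`
#'   (per peptide: `mean_ratio`, `welch_t`, `welch_df`, `welch_p`, `linear`).
#' @export
prm_quant <- function(batch, r2_threshold = 0.98,
                      weighting = c("none", "1/x")) {
  stopifnot(inherits(batch, "prm_batch"))
  if (is.null(batch$samples)) stop_("batch has no sample records to quantify")
  weighting <- match.arg(weighting)
  b <- is_normalize(average_injections(batch))
  curves <- fit_standard_curve(b$calibration, weighting = weighting)
  curves$linear <- curves$r_squared >= r2_threshold
  conc <- quantify(b$samples)
  summ <- lapply(unique(conc$peptide_id), function(pep) {
    df <- conc[conc$peptide_id == pep & conc$detected &
                 !is.na(conc$conc_fmol_per_ug), , drop = FALSE]
    a <- df$conc_fmol_per_ug[df$fraction == "LPA"]
    b_ <- df$conc_fmol_per_ug[df$fraction == "LDL"]
    ratio <- if (length(a) && length(b_)) mean(a) / mean(b_) else NA_real_
    wt <- if (length(a) >= 2L && length(b_) >= 2L) {
      welch_test(a, b_)
    } else {
      list(t = NA_real_, df = NA_real_, p = NA_real_)
    }
    data.frame(
      peptide_id = pep, mean_ratio = ratio,
      welch_t = wt$t, welch_df = wt$df, welch_p = wt$p,
      linear = curves$linear[match(pep, curves$peptide_id)],
      stringsAsFactors = FALSE
    )
  })
  structure(
    list(curves = curves, concentrations = conc, summary = do.call(rbind, summ)),
    class = "prm_result"
  )
}

#' @export
print.prm_result <- function(x, ...) {
  cat("<prm_result>\n")
  print(x$summary)
  invisible(x)
}
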
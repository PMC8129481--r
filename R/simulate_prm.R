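#' PRM batch: calibration and sample peak areas for one or more peptides
#'
#' Container for a targeted parallel-reaction-monitoring experiment.
#' `calibration` holds the standard curve: known amounts of heavy
#' (isotope-labelled) peptide spiked into a pooled background, injected in
#' duplicate, with light (endogenous), heavy and internal-standard (IS) peak
#' areas. `samples` holds the measurements to be quantified: each sample is
#' spiked with a known heavy amount and the endogenous (light) signal is read
#' against it.
#'
#' @param calibration data.frame with columns `peptide_id`,
#'   `level_fmol_per_ul`, `replicate`, `light_area`, `heavy_area`, `is_area`.
#' @param samples optional data.frame with columns `peptide_id`, `sample_id`,
#'   `fraction` (`"LPA"`/`"LDL"`), `loaded_mass_ug`, `heavy_spike_fmol`,
#'   `replicate`, `light_area`, `heavy_area`, `is_area`.
#' @return object of class `prm_batch`.
#' @export
prm_batch <- function(calibration, samples = NULL) {
  cal_cols <- c("peptide_id", "level_fmol_per_ul", "replicate",
                "light_area", "heavy_area", "is_area")
  if (!is.data.frame(calibration) || !all(cal_cols %in% names(calibration))) {
    stop_("`calibration` must contain columns: %s",
          paste(cal_cols, collapse = ", "))
  }
  if (any(calibration$level_fmol_per_ul <= 0)) {
    stop_("calibration levels must be positive")
  }
  for (pep in unique(calibration$peptide_id)) {
    lv <- calibration$level_fmol_per_ul[calibration$peptide_id == pep]
    if (length(unique(lv)) < 2L) {
      stop_("peptide %s needs >= 2 distinct calibration levels", pep)
    }
  }
  area_cols <- c("light_area", "heavy_area", "is_area")
  if (any(unlist(calibration[area_cols]) < 0, na.rm = TRUE)) {
    stop_("peak areas must be non-negative")
  }
  if (!is.null(samples)) {
    smp_cols <- c("peptide_id", "sample_id", "fraction", "loaded_mass_ug",
                  "heavy_spike_fmol", "replicate", area_cols)
    if (!is.data.frame(samples) || !all(smp_cols %in% names(samples))) {
      stop_("`samples` must contain columns: %s",
            paste(smp_cols, collapse = ", "))
    }
    if (any(samples$loaded_mass_ug <= 0)) stop_("loaded_mass_ug must be > 0")
    if (any(unlist(samples[area_cols]) < 0, na.rm = TRUE)) {
      stop_("peak areas must be non-negative")
    }
  }
  structure(list(calibration = calibration, samples = samples),
            class = "prm_batch")
}

#' @export
print.prm_batch <- function(x, ...) {
  cat(sprintf(
    "<prm_batch> %d peptide(s), %d calibration record(s), %d sample record(s)\n",
    length(unique(x$calibration$peptide_id)), nrow(x$calibration),
    if (is.null(x$samples)) 0L else nrow(x$samples)
  ))
  invisible(x)
}

#' Simulate a PRM dilution series (and optionally quantification samples)
#'
#' Generates duplicate-injection peak areas that are linear in the spiked
#' heavy amount up to multiplicative log-normal noise:
#' `heavy_area = response * level * exp(eps)`, `eps ~ N(0, sqrt(log(1+cv^2)))`.
#' The light (endogenous) and internal-standard areas carry the same noise
#' model. With `noise_cv = 0` the fitted standard-curve slope recovers
#' `response` exactly.
#'
#' When `samples` is supplied (columns `sample_id`, `fraction`,
#' `loaded_mass_ug`, `heavy_spike_fmol`, `true_conc_fmol_per_ug`), duplicate
#' sample injections are generated with light and heavy areas that share the
#' peptide's response, so [quantify()] recovers `true_conc_fmol_per_ug` at
#' zero noise.
#'
#' @param levels spiked heavy amounts (fmol/uL); `>= 2` distinct positive
#'   values.
#' @param response instrument response (area units per fmol/uL).
#' @param noise_cv multiplicative noise coefficient of variation.
#' @param seed integer seed.
#' @param peptide_id peptide identifier.
#' @param endogenous_level light-channel signal expressed on the level scale;
#'   defaults to `median(levels) / 10`.
#' @param is_area_mean mean internal-standard area.
#' @param samples optional truth data.frame, see Details.
#' @return a [prm_batch()].
#' @export
simulate_prm <- function(levels, response, noise_cv = 0, seed = 1L,
                         peptide_id = "PEP1",
                         endogenous_level = NULL, is_area_mean = 1e5,
                         samples = NULL) {
  levels <- as.numeric(levels)
  if (length(unique(levels)) < 2L) stop_("need >= 2 distinct levels")
  if (any(levels <= 0)) stop_("levels must be positive")
  assert_scalar_num(response, "response", lower = 0, strict_lower = TRUE)
  assert_scalar_num(noise_cv, "noise_cv", lower = 0)
  if (is.null(endogenous_level)) endogenous_level <- stats::median(levels) / 10
  sdlog <- sqrt(log1p(noise_cv^2))
  noise <- function(n) exp(stats::rnorm(n, 0, sdlog))
  with_seed(seed, {
    lev <- rep(levels, each = 2L)
    n <- length(lev)
    calibration <- data.frame(
      peptide_id = peptide_id,
      level_fmol_per_ul = lev,
      replicate = rep(1:2, times = length(levels)),
      light_area = response * endogenous_level * noise(n),
      heavy_area = response * lev * noise(n),
      is_area = is_area_mean * noise(n),
      stringsAsFactors = FALSE
    )
    smp <- NULL
    if (!is.null(samples)) {
      need <- c("sample_id", "fraction", "loaded_mass_ug", "heavy_spike_fmol",
                "true_conc_fmol_per_ug")
      if (!all(need %in% names(samples))) {
        stop_("`samples` truth needs columns: %s", paste(need, collapse = ", "))
      }
      idx <- rep(seq_len(nrow(samples)), each = 2L)
      ns <- length(idx)
      # light/heavy share the response factor, so their ratio encodes
      # true_conc * loaded_mass / heavy_spike
      smp <- data.frame(
        peptide_id = peptide_id,
        sample_id = samples$sample_id[idx],
        fraction = samples$fraction[idx],
        loaded_mass_ug = samples$loaded_mass_ug[idx],
        heavy_spike_fmol = samples$heavy_spike_fmol[idx],
        replicate = rep(1:2, times = nrow(samples)),
        light_area = response * samples$true_conc_fmol_per_ug[idx] *
          samples$loaded_mass_ug[idx] * noise(ns),
        heavy_area = response * samples$heavy_spike_fmol[idx] * noise(ns),
        is_area = is_area_mean * noise(ns),
        stringsAsFactors = FALSE
      )
    }
    prm_batch(calibration, smp)
  })
}
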
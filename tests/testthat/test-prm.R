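cal_row <- function(level, rep, light = 10, heavy = 100, is = 1000,
                    pep = "P") {
  data.frame(peptide_id = pep, level_fmol_per_ul = level, replicate = rep,
             light_area = light, heavy_area = heavy, is_area = is,
             stringsAsFactors = FALSE)
}

smp_row <- function(id, fraction, light, heavy, is = 1000, spike = 20,
                    mass = 2, pep = "P", rep = 1L) {
  data.frame(peptide_id = pep, sample_id = id, fraction = fraction,
             loaded_mass_ug = mass, heavy_spike_fmol = spike,
             replicate = rep, light_area = light, heavy_area = heavy,
             is_area = is, stringsAsFactors = FALSE)
}

test_that("average_injections: means, pass-through, and >2 error", {
  cal <- rbind(cal_row(10, 1, heavy = 100), cal_row(10, 2, heavy = 102),
               cal_row(100, 1, heavy = 500))
  b <- average_injections(prm_batch(cal))
  expect_identical(nrow(b$calibration), 2L)
  expect_equal(b$calibration$heavy_area[b$calibration$level_fmol_per_ul == 10],
               101)
  expect_equal(b$calibration$heavy_area[b$calibration$level_fmol_per_ul == 100],
               500)
  bad <- rbind(cal_row(10, 1), cal_row(10, 2), cal_row(10, 3),
               cal_row(100, 1))
  expect_error(average_injections(prm_batch(bad)), "more than 2")
})

test_that("is_normalize: identity when IS constant, halves a doubled IS record", {
  cal <- rbind(cal_row(10, 1, is = 1000), cal_row(100, 1, is = 1000),
               cal_row(1000, 1, is = 1000))
  expect_equal(is_normalize(prm_batch(cal))$calibration$heavy_area,
               cal$heavy_area)
  # doubled IS -> areas halved relative to the others
  cal2 <- rbind(cal_row(10, 1, light = 10, heavy = 100, is = 1000),
                cal_row(100, 1, light = 20, heavy = 200, is = 2000),
                cal_row(1000, 1, light = 30, heavy = 300, is = 1000))
  n2 <- is_normalize(prm_batch(cal2))$calibration
  expect_equal(n2$heavy_area, c(100, 100, 300))
  # light/heavy ratio within a record is invariant
  expect_equal(n2$light_area / n2$heavy_area,
               cal2$light_area / cal2$heavy_area)
  # zero IS is an error naming the record
  cal3 <- rbind(cal_row(10, 1, is = 0), cal_row(100, 1))
  expect_error(is_normalize(prm_batch(cal3)), "record\\(s\\) 1")
})

test_that("standard curve: closed-form OLS and QC flagging", {
  cal <- rbind(cal_row(10, 1, heavy = 55), cal_row(100, 1, heavy = 505),
               cal_row(1000, 1, heavy = 5005))
  f <- fit_standard_curve(cal)
  expect_equal(f$slope, 5)
  expect_equal(f$intercept, 5)
  expect_equal(f$r_squared, 1)
  # flat response: r^2 near zero, flagged below the QC gate
  flat <- do.call(rbind, lapply(seq_len(5), function(i) {
    cal_row(10^i, 1, heavy = c(100, 98, 103, 99, 101)[i])
  }))
  ff <- fit_standard_curve(flat)
  expect_lt(ff$r_squared, 0.5)
  expect_lt(ff$r_squared, 0.98)
  expect_error(fit_standard_curve(cal_row(10, 1)), "2 distinct")
})

test_that("quantify: unit arithmetic, boundary cases, homogeneity", {
  s <- rbind(
    smp_row("a", "LPA", light = 500, heavy = 500),                 # 10 fmol/ug
    smp_row("b", "LDL", light = 250, heavy = 500, spike = 3000),   # 750
    smp_row("c", "LDL", light = 0, heavy = 500),                   # true zero
    smp_row("d", "LDL", light = 100, heavy = 0)                    # undetectable
  )
  q <- quantify(s)
  expect_equal(q$conc_fmol_per_ug[1], 10)
  expect_equal(q$conc_fmol_per_ug[2], 750)
  expect_identical(q$conc_fmol_per_ug[3], 0)
  expect_false(q$detected[3])
  expect_true(is.na(q$conc_fmol_per_ug[4]))
  expect_false(q$detected[4])
  # scaling both areas by c > 0 leaves the concentration unchanged
  s2 <- smp_row("a", "LPA", light = 500 * 17.3, heavy = 500 * 17.3)
  expect_equal(quantify(s2)$conc_fmol_per_ug, 10)
})

test_that("molar ratio semantics", {
  expect_equal(molar_ratio(3, 3), 1)
  expect_equal(molar_ratio(2, 1000), 0.002)
  expect_true(is.na(molar_ratio(NA_real_, 5)))   # undetected numerator
  expect_error(molar_ratio(1, 0), "> 0")
  expect_error(molar_ratio(1, NA_real_), "missing")
})

test_that("welch test matches the Welch-Satterthwaite closed form", {
  a <- c(10, 11, 12); b <- c(20, 21, 22)
  w <- welch_test(a, b)
  va <- stats::var(a) / 3; vb <- stats::var(b) / 3
  t_oracle <- (mean(a) - mean(b)) / sqrt(va + vb)
  df_oracle <- (va + vb)^2 / (va^2 / 2 + vb^2 / 2)
  expect_equal(w$t, t_oracle)
  expect_equal(w$df, df_oracle)
  expect_equal(w$p, 2 * stats::pt(-abs(t_oracle), df_oracle))
  # identical groups
  expect_equal(welch_test(c(1, 2, 3), c(1, 2, 3))$p, 1)
  w0 <- welch_test(c(2, 2, 2), c(2, 2, 2))
  expect_identical(w0$t, 0)
  expect_identical(w0$p, 1)
  expect_error(welch_test(1, c(1, 2)), ">= 2")
})

test_that("welch P is uniform under the null (KS over 2000 replicates)", {
  set.seed(2024)
  p <- vapply(1:2000, function(i) {
    welch_test(stats::rnorm(5), stats::rnorm(5))$p
  }, numeric(1))
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})

test_that("end-to-end prm_quant: ratios, Welch P, QC gate, missing propagation", {
  smp <- data.frame(
    sample_id = sprintf("S%d", 1:6),
    fraction = rep(c("LPA", "LDL"), each = 3),
    loaded_mass_ug = 2, heavy_spike_fmol = 20,
    true_conc_fmol_per_ug = c(10, 10.5, 9.5, 1, 1.1, 0.9)
  )
  b <- simulate_prm(c(0.4, 4, 10, 20, 40), response = 30, noise_cv = 0,
                    seed = 5, samples = smp)
  r <- prm_quant(b)
  expect_true(r$curves$linear)
  expect_equal(r$summary$mean_ratio, 10, tolerance = 1e-10)
  expect_lt(r$summary$welch_p, 0.01)
  # a peptide absent from one fraction reports a missing ratio, never 0
  b2 <- b
  b2$samples$light_area[b2$samples$fraction == "LDL"] <- 0
  r2 <- prm_quant(b2)
  expect_true(is.na(r2$summary$mean_ratio))
})
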
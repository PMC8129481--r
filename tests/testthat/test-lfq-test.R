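test_that("paired t matches the closed form computed from first principles", {
  d <- c(2.1, 1.9, 2.0, 2.2, 1.8, 2.0)
  m <- make_diff_matrix(d)
  r <- paired_ratio_test(m)
  t_oracle <- mean(d) / (stats::sd(d) / sqrt(6))
  p_oracle <- 2 * stats::pt(-abs(t_oracle), 5)
  expect_equal(r$t_plain[1], t_oracle)
  expect_equal(r$p_plain[1], p_oracle)
  # ratio is on the natural scale: mean(LPA)/mean(LDL)
  expect_equal(r$ratio[1], mean(2^(20 + d)) / mean(2^rep(20, 6)))
})

test_that("degenerate paired inputs follow the declared zero-variance rules", {
  # identical values across conditions: ratio 1, p 1
  same <- make_diff_matrix(rep(0, 6))
  r0 <- paired_ratio_test(same)
  expect_equal(r0$ratio[1], 1)
  expect_equal(r0$p_plain[1], 1)
  expect_true(r0$zero_variance[1])
  # constant nonzero difference: smallest representable nonzero P, flagged
  r1 <- paired_ratio_test(make_diff_matrix(rep(1, 6)))
  expect_identical(r1$p_plain[1], .Machine$double.xmin)
  expect_identical(r1$t_plain[1], Inf)
  expect_true(r1$zero_variance[1])
  # fewer than 2 pairs rejected
  expect_error(paired_ratio_test(make_paired_matrix(matrix(1:2), matrix(3:4))),
               ">= 2 pairs")
})

test_that("moderation fit recovers known hyperparameters and matches limma", {
  set.seed(301)
  d0 <- 4; s0_sq <- 1; df <- 5; n <- 5000
  # s^2 ~ s0^2 * d0/chisq(d0) * chisq(df)/df  (marginal scaled F)
  s2 <- s0_sq * d0 / stats::rchisq(n, d0) * stats::rchisq(n, df) / df
  fit <- fit_moderation(s2, df)
  expect_lt(abs(fit$d0 - d0) / d0, 0.15)
  expect_lt(abs(fit$s0_sq - s0_sq) / s0_sq, 0.05)
  # independent oracle: limma's fitFDist on the same draws
  lf <- limma::fitFDist(s2, df1 = df)
  expect_equal(fit$d0, lf$df2, tolerance = 1e-6)
  expect_equal(fit$s0_sq, lf$scale, tolerance = 1e-6)
})

test_that("moderation degenerate and limiting behaviour", {
  # all variances equal: complete shrinkage, posterior equals the common value
  fit <- fit_moderation(rep(2, 50), df = 5)
  expect_identical(fit$d0, Inf)
  m <- make_diff_matrix(c(2.1, 1.9, 2.0, 2.2, 1.8, 2.0))
  mod <- moderated_test(m, fit)
  expect_equal(mod$s2_post, rep(fit$s0_sq, 4))
  # d0 = 0: moderated t reduces to the plain t
  plain <- paired_ratio_test(m)
  mod0 <- moderated_test(m, list(d0 = 0, s0_sq = 1))
  expect_equal(mod0$t_mod, plain$t_plain)
  expect_equal(mod0$p_mod, plain$p_plain)
  # s^2 identical to s0_sq is a fixed point
  fixed <- moderated_test(m, list(d0 = 7, s0_sq = mod0$s2_post[1] * 0 +
                                    lipoproteomr:::row_vars(
                                      lipoproteomr:::paired_diffs(m))[1]))
  expect_equal(fixed$s2_post[1], fixed$s2[1])
})

test_that("moderated hand example: d0=4, s0=1, df=5, s2=2, diff=1, n=6", {
  # construct 6 paired log2 differences with mean 1, variance 2
  v <- c(-5, -3, -1, 1, 3, 5)
  d <- 1 + v * sqrt(2 / stats::var(v))
  stopifnot(abs(mean(d) - 1) < 1e-12, abs(stats::var(d) - 2) < 1e-12)
  m <- make_diff_matrix(d)
  mod <- moderated_test(m, list(d0 = 4, s0_sq = 1))
  s2_post_oracle <- (4 * 1 + 5 * 2) / (4 + 5)    # = 14/9
  t_oracle <- 1 / sqrt(s2_post_oracle / 6)       # = sqrt(54/14)
  expect_equal(mod$s2_post[1], s2_post_oracle)
  expect_equal(mod$t_mod[1], t_oracle)
  expect_equal(mod$p_mod[1], 2 * stats::pt(-t_oracle, df = 9))
})

test_that("bh_adjust follows the step-up definition", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(bh_adjust(numeric(0)), numeric(0))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(0.5, NA)), "\\[0, 1\\]")
})

test_that("bh_adjust equals brute force and p.adjust on random vectors", {
  set.seed(99)
  for (i in 1:100) {
    n <- sample(1:60, 1)
    p <- round(stats::runif(n), sample(c(1, 2, 3, 6), 1))  # force ties often
    q <- bh_adjust(p)
    expect_equal(q, bh_brute_force(p))
    expect_equal(q, stats::p.adjust(p, "BH"))
  }
})

test_that("null pipeline is calibrated and spiked pipeline has full power", {
  # calibration on complete data (see methods vignette: imputation distorts
  # the t-test by design, so calibration is a complete-data property)
  tr <- lfq_sim_truth(n_proteins = 1500, n_pairs = 6, cv = 0.2,
                      missing_intercept = -Inf, seed = 71)
  res <- lfq_diff(simulate_lfq(tr))
  frac <- mean(res$p_plain < 0.05, na.rm = TRUE)
  band <- 3 * sqrt(0.05 * 0.95 / sum(!is.na(res$p_plain)))
  expect_lt(abs(frac - 0.05), band)

  # BH at q < 0.05 rarely discovers anything under the null
  clean <- vapply(1:10, function(s) {
    t0 <- lfq_sim_truth(n_proteins = 400, n_pairs = 6, cv = 0.2,
                        missing_intercept = -Inf, seed = 7000 + s)
    r <- lfq_diff(simulate_lfq(t0))
    sum(r$q < 0.05, na.rm = TRUE) == 0L
  }, logical(1))
  expect_gte(sum(clean), 9L)

  # spiked run, low cv, complete data: all spikes found, ratios near 8
  ts <- lfq_sim_truth(n_proteins = 800, n_pairs = 6, enriched_ids = 1:10,
                      log2_effect = 3, cv = 0.05, missing_intercept = -Inf,
                      seed = 72)
  rs <- lfq_diff(simulate_lfq(ts))
  spiked <- rs[match(sprintf("protein_%04d", 1:10), rs$protein_id), ]
  expect_true(all(spiked$q < 0.05))
  expect_true(all(spiked$ratio > 6 & spiked$ratio < 10))
})
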
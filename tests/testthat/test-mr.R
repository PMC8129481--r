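assoc <- function(id, ea, oa, beta, se = 0.01, pvalue = NULL, eaf = NULL) {
  df <- data.frame(variant_id = id, effect_allele = ea, other_allele = oa,
                   beta = beta, se = se, stringsAsFactors = FALSE)
  if (!is.null(pvalue)) df$pvalue <- pvalue
  if (!is.null(eaf)) df$eaf <- eaf
  df
}

test_that("instrument selection uses strict < at the threshold", {
  tab <- assoc(sprintf("rs%d", 1:4), "A", "G", 0.1,
               pvalue = c(5e-8, 4.9e-8, 1e-3, 1e-20))
  sel <- select_instruments(tab)
  expect_identical(sel$variant_id, c("rs2", "rs4"))   # 5e-8 itself excluded
  expect_identical(nrow(select_instruments(tab[0, ])), 0L)
  # brute-force scan on a constructed table
  set.seed(8)
  tab2 <- assoc(sprintf("v%d", 1:10), "A", "G", 0.1,
                pvalue = 10^stats::runif(10, -12, -2))
  sel2 <- select_instruments(tab2, 5e-8)
  expect_identical(sel2$variant_id,
                   tab2$variant_id[tab2$pvalue < 5e-8])
})

test_that("ld_clump greedy retention and validation", {
  tab <- assoc(c("a", "b"), "A", "G", 0.1, pvalue = c(1e-10, 1e-5))
  id2 <- diag(2); dimnames(id2) <- list(c("a", "b"), c("a", "b"))
  expect_identical(ld_clump(tab, id2)$variant_id, c("a", "b"))
  # perfect correlation keeps only the smaller-P variant
  r1 <- matrix(c(1, 1, 1, 1), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_identical(ld_clump(tab, r1)$variant_id, "a")
  # dimension mismatch
  expect_error(ld_clump(assoc("z", "A", "G", 0.1, pvalue = 1e-9), id2),
               "covering")
})

test_that("ld_clump output satisfies the clumping properties on a block matrix", {
  ids <- sprintf("v%d", 1:5)
  tab <- assoc(ids, "A", "G", 0.1, pvalue = c(1e-12, 1e-4, 1e-8, 1e-3, 1e-6))
  ld <- diag(5)
  ld[1, 2] <- ld[2, 1] <- 0.9    # v2 tied to the lead v1
  ld[3, 4] <- ld[4, 3] <- 0.5    # v4 tied to v3
  ld[1, 3] <- ld[3, 1] <- 0.05
  dimnames(ld) <- list(ids, ids)
  kept <- ld_clump(tab, ld, 0.1)$variant_id
  # every retained pair independent
  for (i in kept) for (j in setdiff(kept, i)) expect_lt(ld[i, j], 0.1)
  # every dropped variant is in LD with a retained, more significant one
  for (d in setdiff(ids, kept)) {
    anchors <- kept[ld[d, kept] >= 0.1]
    expect_true(any(tab$pvalue[match(anchors, ids)] < tab$pvalue[match(d, ids)]))
  }
  expect_identical(kept, c("v1", "v3", "v5"))
})

test_that("harmonization handles match, swap, incompatibility and palindromes", {
  ex <- assoc("rs1", "A", "G", 0.1)
  expect_equal(harmonize(ex, assoc("rs1", "A", "G", 0.2))$beta_y, 0.2)
  expect_equal(harmonize(ex, assoc("rs1", "G", "A", 0.2))$beta_y, -0.2)
  h <- harmonize(ex, assoc("rs1", "C", "T", 0.2), allow_strand_flip = FALSE)
  expect_identical(nrow(h), 0L)
  expect_identical(attr(h, "dropped")$reason, "incompatible_alleles")
  # strand complement accepted by default: A/G on + is T/C on -
  expect_equal(harmonize(ex, assoc("rs1", "T", "C", 0.2))$beta_y, 0.2)
  expect_equal(harmonize(ex, assoc("rs1", "C", "T", 0.2))$beta_y, -0.2)
  # palindromic without frequencies: dropped with reason
  pal <- harmonize(assoc("rs2", "A", "T", 0.1), assoc("rs2", "A", "T", 0.2))
  expect_identical(nrow(pal), 0L)
  expect_identical(attr(pal, "dropped")$reason, "palindromic_ambiguous")
  # palindromic with clear, opposite-side frequencies: flipped
  pal2 <- harmonize(assoc("rs2", "A", "T", 0.1, eaf = 0.2),
                    assoc("rs2", "A", "T", 0.2, eaf = 0.8))
  expect_equal(pal2$beta_y, -0.2)
  # ambiguous frequency near 0.5: dropped
  pal3 <- harmonize(assoc("rs2", "A", "T", 0.1, eaf = 0.2),
                    assoc("rs2", "A", "T", 0.2, eaf = 0.52))
  expect_identical(nrow(pal3), 0L)
})

test_that("harmonization is an involution", {
  sim <- simulate_mr_panel(mr_sim_truth(n_instruments = 30, seed = 13,
                                        flip_fraction = 0.5))
  h1 <- harmonize(sim$instruments, sim$panel[[1]])
  # re-feed the harmonized outcome as an outcome table: nothing changes
  out2 <- data.frame(variant_id = h1$variant_id,
                     effect_allele = h1$effect_allele,
                     other_allele = h1$other_allele,
                     beta = h1$beta_y, se = h1$se_y,
                     stringsAsFactors = FALSE)
  h2 <- harmonize(sim$instruments, out2)
  expect_equal(h2$beta_y, h1$beta_y)
  expect_equal(h2$variant_id, h1$variant_id)
})

test_that("wald ratio arithmetic and invariances", {
  expect_equal(wald_ratio(1, 0.3, 0.1), data.frame(theta = 0.3, se = 0.1))
  expect_equal(wald_ratio(2, 1, 0.2), data.frame(theta = 0.5, se = 0.1))
  # negating bx negates theta, se unchanged
  w <- wald_ratio(-2, 1, 0.2)
  expect_equal(w$theta, -0.5)
  expect_equal(w$se, 0.1)
  expect_error(wald_ratio(0, 1, 0.1), "beta_x")
  # second-order needs se_x and is never smaller than first-order
  w2 <- wald_ratio(2, 1, 0.2, se_x = 0.05, second_order = TRUE)
  expect_gt(w2$se, 0.1)
})

test_that("ivw equals its closed forms and the WLS oracle", {
  expect_equal(ivw(0.4, 0.1)$theta, 0.4)
  expect_equal(ivw(0.4, 0.1)$se, 0.1)
  expect_equal(ivw(c(0.2, 0.6), c(0.1, 0.1))$theta, 0.4)
  set.seed(21)
  for (i in 1:25) {
    k <- sample(5:54, 1)
    bx <- stats::runif(k, 0.05, 0.4) * sample(c(-1, 1), k, TRUE)
    by <- 0.3 * bx + stats::rnorm(k, 0, 0.02)
    sey <- stats::runif(k, 0.005, 0.05)
    wr <- wald_ratio(bx, by, sey)
    iv <- ivw(wr$theta, wr$se)
    fit <- stats::lm(by ~ 0 + bx, weights = sey^-2)
    expect_equal(iv$theta, unname(stats::coef(fit)), tolerance = 1e-12)
    se_wls <- sqrt(1 / sum(bx^2 / sey^2))
    expect_equal(iv$se, se_wls, tolerance = 1e-12)
  }
  expect_error(ivw(numeric(0), numeric(0)), "no Wald")
})

test_that("bonferroni thresholds match the published panel arithmetic", {
  expect_equal(bonferroni_threshold(0.05, 3283), 0.05 / 3283)
  expect_equal(signif(bonferroni_threshold(0.05, 3283), 2), 1.5e-5)
  expect_equal(signif(bonferroni_threshold(0.05, 41), 2), 1.2e-3)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_error(bonferroni_threshold(1.2, 10), "alpha")
})

test_that("screen flags a strong signal and reports unharmonizable proteins", {
  sim <- simulate_mr_panel(mr_sim_truth(
    n_instruments = 26, theta = 1.5, n_causal_proteins = 1,
    n_null_proteins = 4, seed = 17
  ))
  scr <- mr_screen(sim$instruments, sim$panel, m = 3283)
  expect_s3_class(scr, "mr_result")
  expect_true(scr$passes_bonferroni[scr$outcome_id == "P0001"])
  expect_identical(scr$outcome_id[1], "P0001")   # sorted by P
  expect_true(all(scr$n_snps == 26))
  # a protein whose alleles never harmonize is reported, not dropped
  broken <- sim$panel
  broken[["P0002"]]$effect_allele <- "C"
  broken[["P0002"]]$other_allele <- "T"
  sim$instruments$effect_allele <- "A"
  sim$instruments$other_allele <- "G"
  scr2 <- mr_screen(sim$instruments, broken, m = 3283,
                    allow_strand_flip = FALSE)
  row <- scr2[scr2$outcome_id == "P0002", ]
  expect_true(is.na(row$theta))
  expect_identical(row$n_snps, 0L)
})
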
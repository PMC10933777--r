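test_that("wald ratio reproduces the blood-pressure worked example", {
  # Printed per-allele associations: 0.0617 SD of systolic BP and 0.0652
  # log-odds of coronary artery disease per effect allele. The outcome SE
  # is backed out of the printed 95% CI [0.19, 1.94].
  se_out <- (1.94 - 0.19) / (2 * qnorm(0.975)) * 0.0617
  est <- wald_ratio(0.0617, 0.003, 0.0652, se_out)
  expect_equal(round(est$estimate, 2), 1.06)
  expect_equal(round(est$pval, 3), 0.018, tolerance = 0.01)
  expect_equal(round(est$ci_low, 1), 0.2, tolerance = 0.3)
})

test_that("wald ratio handles zero outcome, delta SE, and zero exposure", {
  expect_equal(wald_ratio(0.5, 0.01, 0, 0.05)$estimate, 0)
  # se = se_outcome / |beta_exposure| = 0.05 / 0.5 = 0.1
  expect_equal(wald_ratio(0.5, 0.01, 0.2, 0.05)$se, 0.1, tolerance = 1e-12)
  expect_equal(wald_ratio(-0.5, 0.01, 0.2, 0.05)$se, 0.1, tolerance = 1e-12)
  expect_error(wald_ratio(0, 0.01, 0.2, 0.05), "undefined ratio")
})

test_that("ratio_set matches wald_ratio, handles weight orders, names zero SNPs", {
  h1 <- make_harmonised(0.5, 0.02, 0.2, 0.05)
  rs <- ratio_set(h1)
  expect_equal(nrow(rs), 1)
  wr <- wald_ratio(0.5, 0.02, 0.2, 0.05)
  expect_equal(rs$ratio, wr$estimate)
  expect_equal(rs$se, wr$se)

  # Independent spreadsheet-style check of weights for 3 rows.
  be <- c(0.04, 0.06, 0.08)
  se_o <- c(0.01, 0.02, 0.005)
  h3 <- make_harmonised(be, rep(0.005, 3), c(0.004, 0.012, 0.006), se_o)
  rs3 <- ratio_set(h3)
  expect_equal(rs3$weight, 1 / (se_o / abs(be))^2, tolerance = 1e-12)

  # Second order reduces to first order when exposure SEs vanish.
  h0 <- make_harmonised(be, rep(1e-300, 3), c(0.004, 0.012, 0.006), se_o)
  expect_equal(ratio_set(h0, "second_order")$se, ratio_set(h0)$se,
               tolerance = 1e-10)
  # And is otherwise strictly wider.
  expect_true(all(ratio_set(h3, "second_order")$se > rs3$se))

  hz <- make_harmonised(c(0.05, 0), c(0.005, 0.005), c(0.01, 0.01),
                        c(0.01, 0.01))
  expect_error(ratio_set(hz), "rs002")
})

test_that("IVW fixed effects equals the hand-computed weighted mean", {
  # Exposure betas of 1 make ratios equal outcome betas; weights 1/se^2.
  bo <- c(0.1, 0.2, 0.3)
  se_o <- c(0.05, 0.05, 0.10)
  h <- make_harmonised(rep(1, 3), rep(1e-6, 3), bo, se_o)
  w <- 1 / se_o^2
  expect_equal(mr_ivw(h, "fixed")$estimate, sum(w * bo) / sum(w),
               tolerance = 1e-12)
  expect_equal(mr_ivw(h, "fixed")$se, sqrt(1 / sum(w)), tolerance = 1e-12)
})

test_that("IVW fixed effects is identical to through-origin WLS on 100 random sets", {
  withr::with_seed(2024, {
    for (i in 1:100) {
      j <- sample(2:30, 1)
      be <- rnorm(j, 0.05, 0.02)
      be[abs(be) < 0.01] <- 0.01
      bo <- 0.1 * be + rnorm(j, 0, 0.01)
      se_o <- runif(j, 0.002, 0.02)
      h <- make_harmonised(be, rep(0.005, j), bo, se_o)
      # Independent oracle: weighted regression through the origin.
      wls <- lm(bo ~ 0 + be, weights = 1 / se_o^2)
      expect_equal(mr_ivw(h, "fixed")$estimate, unname(coef(wls)),
                   tolerance = 1e-10)
    }
  })
})

test_that("IVW with one instrument degenerates to the Wald ratio", {
  h <- make_harmonised(0.5, 0.02, 0.2, 0.05)
  expect_message(est <- mr_ivw(h), "Wald ratio")
  wr <- wald_ratio(0.5, 0.02, 0.2, 0.05)
  expect_equal(est$estimate, wr$estimate)
  expect_equal(est$se, wr$se)
})

test_that("IVW variants coincide under homogeneity and diverge sanely otherwise", {
  # Identical ratios: Q = 0, so all three models agree and tau2 = 0.
  h <- make_harmonised(c(0.5, 0.25, 0.1), rep(0.005, 3),
                       c(0.25, 0.125, 0.05), c(0.01, 0.005, 0.002))
  fixed <- mr_ivw(h, "fixed")
  mult <- mr_ivw(h, "multiplicative")
  add <- mr_ivw(h, "additive")
  expect_equal(fixed$estimate, 0.5, tolerance = 1e-12)
  expect_equal(mult$estimate, fixed$estimate)
  expect_equal(add$estimate, fixed$estimate, tolerance = 1e-12)
  expect_equal(mult$se, fixed$se)
  expect_equal(add$se, fixed$se, tolerance = 1e-12)
  expect_equal(add$extras$tau2, 0)

  # Heterogeneous ratios: same point estimate, multiplicative SE wider.
  h2 <- make_clean_pair(j = 15, noise = 0.01)
  f2 <- mr_ivw(h2, "fixed")
  m2 <- mr_ivw(h2, "multiplicative")
  expect_equal(m2$estimate, f2$estimate)
  expect_gte(m2$se, f2$se)
})

test_that("all estimators are invariant to joint sign flips of instrument subsets", {
  h <- make_clean_pair(j = 12, noise = 0.005)
  flip <- c(2, 5, 7, 11)
  h2 <- h
  h2$data$beta_exposure[flip] <- -h2$data$beta_exposure[flip]
  h2$data$beta_outcome[flip] <- -h2$data$beta_outcome[flip]
  expect_equal(mr_ivw(h2, "fixed")$estimate, mr_ivw(h, "fixed")$estimate,
               tolerance = 1e-12)
  expect_equal(mr_egger(h2)$estimate, mr_egger(h)$estimate, tolerance = 1e-12)
  expect_equal(mr_egger(h2)$extras$intercept, mr_egger(h)$extras$intercept,
               tolerance = 1e-12)
  expect_equal(mr_weighted_median(h2, n_boot = 50, seed = 1)$estimate,
               mr_weighted_median(h, n_boot = 50, seed = 1)$estimate,
               tolerance = 1e-12)
  expect_equal(mr_weighted_mode(h2, n_boot = 50, seed = 1)$estimate,
               mr_weighted_mode(h, n_boot = 50, seed = 1)$estimate,
               tolerance = 1e-12)
})

test_that("MR-Egger recovers exact lines, shifted intercepts, and scales errors", {
  be <- c(0.02, 0.04, 0.06, 0.08, 0.10)
  se_o <- rep(0.01, 5)
  h <- make_harmonised(be, rep(0.005, 5), 0.5 * be, se_o)
  est <- mr_egger(h)
  expect_equal(est$estimate, 0.5, tolerance = 1e-10)
  expect_equal(est$extras$intercept, 0, tolerance = 1e-10)

  h2 <- make_harmonised(be, rep(0.005, 5), 0.5 * be + 0.02, se_o)
  est2 <- mr_egger(h2)
  expect_equal(est2$estimate, 0.5, tolerance = 1e-10)
  expect_equal(est2$extras$intercept, 0.02, tolerance = 1e-10)

  # Exact WLS on the shifted line, computed independently.
  fit <- lm(I(0.5 * be + 0.02) ~ be, weights = 1 / se_o^2)
  expect_equal(est2$estimate, unname(coef(fit)[2]), tolerance = 1e-10)

  expect_error(mr_egger(make_harmonised(be[1:2], rep(0.005, 2),
                                        be[1:2], se_o[1:2])), "at least 3")
  expect_error(mr_egger(make_harmonised(rep(0.05, 4), rep(0.005, 4),
                                        rep(0.02, 4), rep(0.01, 4))),
               "unidentifiable")
})

test_that("weighted median interpolates cumulative weights at one half", {
  # Equal weights: plain median.
  h <- make_harmonised(rep(1, 5), rep(1e-6, 5), c(1, 2, 3, 4, 5), rep(1, 5))
  expect_equal(mr_weighted_median(h, n_boot = 50, seed = 1)$estimate, 3,
               tolerance = 1e-9)

  # One SNP holding 90% of the weight dominates: with ratios {1,2,3} and
  # weights {0.05, 0.9, 0.05} the cumulative midpoints are {0.025, 0.5, 0.975},
  # so interpolation at 0.5 returns exactly the heavy SNP's ratio.
  se_o <- 1 / sqrt(c(0.05, 0.9, 0.05))
  h2 <- make_harmonised(rep(1, 3), rep(1e-6, 3), c(1, 2, 3), se_o)
  expect_equal(mr_weighted_median(h2, n_boot = 50, seed = 1)$estimate, 2,
               tolerance = 1e-9)

  # Bootstrap SE is reproducible under a fixed seed.
  a <- mr_weighted_median(h2, n_boot = 200, seed = 42)
  b <- mr_weighted_median(h2, n_boot = 200, seed = 42)
  expect_identical(a$se, b$se)
  expect_gt(a$se, 0)
})

test_that("weighted mode finds the plurality cluster, not the mean", {
  withr::with_seed(5, {
    be <- rep(0.05, 7)
    bo <- c(0.2 + rnorm(5, 0, 0.002), 1.0, 1.05) * be
    h <- make_harmonised(be, rep(0.001, 7), bo, rep(0.002, 7))
    est <- mr_weighted_mode(h, n_boot = 50, seed = 1)
    ivw <- mr_ivw(h, "fixed")
    expect_lt(abs(est$estimate - 0.2), 0.05)
    expect_gt(abs(ivw$estimate - 0.2), 0.1)  # the mean is pulled away
  })

  # Degenerate bandwidth: identical ratios return the common value.
  h0 <- make_harmonised(c(0.5, 0.25, 0.1), rep(1e-6, 3),
                        0.4 * c(0.5, 0.25, 0.1), rep(0.01, 3))
  expect_equal(mr_weighted_mode(h0, n_boot = 20, seed = 1)$estimate, 0.4,
               tolerance = 1e-9)

  # Reproducibility under seed.
  h1 <- make_clean_pair(j = 8, noise = 0.01)
  expect_identical(mr_weighted_mode(h1, n_boot = 100, seed = 9)$se,
                   mr_weighted_mode(h1, n_boot = 100, seed = 9)$se)
})

test_that("larger mode bandwidths merge clusters instead of splitting them", {
  withr::with_seed(6, {
    be <- rep(0.05, 9)
    bo <- c(0.2 + rnorm(6, 0, 0.003), 0.9, 1.0, 1.1) * be
    h <- make_harmonised(be, rep(0.001, 9), bo, rep(0.002, 9))
    # Small bandwidth: estimate in the tight cluster. Very large bandwidth:
    # the density becomes unimodal between the clusters; the estimate moves
    # toward the overall weighted centre and never outside the ratio range.
    small <- mr_weighted_mode(h, phi = 0.5, n_boot = 20, seed = 1)$estimate
    large <- mr_weighted_mode(h, phi = 20, n_boot = 20, seed = 1)$estimate
    expect_lt(abs(small - 0.2), 0.05)
    expect_gt(large, small)
    rs <- ratio_set(h)
    expect_true(large >= min(rs$ratio) && large <= max(rs$ratio))
  })
})

test_that("multivariable IVW reduces to IVW and separates orthogonal exposures", {
  h <- make_clean_pair(j = 10, noise = 0.005)
  k <- kept_instruments(h)
  uni <- mr_mvmr_ivw(matrix(k$beta_exposure, ncol = 1,
                            dimnames = list(NULL, "x1")),
                     k$beta_outcome, k$se_outcome)
  expect_equal(uni[[1]]$estimate, mr_ivw(h, "fixed")$estimate,
               tolerance = 1e-10)

  # Orthogonal (in the weighted metric) exposure columns decouple: each
  # coefficient equals its own univariable through-origin WLS fit.
  x1 <- c(1, 1, 0, 0, 1, 1)
  x2 <- c(0, 0, 1, 1, 0, 0)
  se_o <- rep(0.1, 6)
  y <- 0.3 * x1 - 0.2 * x2 + c(0.01, -0.01, 0.02, -0.02, 0, 0)
  fits <- mr_mvmr_ivw(cbind(a = x1, b = x2), y, se_o)
  w <- 1 / se_o^2
  expect_equal(fits[[1]]$estimate, sum(w * x1 * y) / sum(w * x1^2),
               tolerance = 1e-10)
  expect_equal(fits[[2]]$estimate, sum(w * x2 * y) / sum(w * x2^2),
               tolerance = 1e-10)

  expect_error(mr_mvmr_ivw(cbind(x1, x1), y, se_o), "collinear")
  expect_error(mr_mvmr_ivw(cbind(x1[1:2], x2[1:2]), y[1:2], se_o[1:2]),
               "K \\+ 1")
})

test_that("mediation arithmetic is exact and the two methods agree in simulation", {
  m <- mr_mediation(0.5, 0.3, 0.5, 0.4)
  expect_equal(m$indirect_difference, 0.2)
  expect_equal(m$indirect_product, 0.2)
  expect_equal(m$total, 0.5)

  # Linear-Gaussian X -> M -> Y system: difference and product methods are
  # asymptotically equivalent; both estimated by OLS on one large sample.
  withr::with_seed(88, {
    n <- 20000
    x <- rnorm(n)
    mvar <- 0.5 * x + rnorm(n)
    y <- 0.4 * mvar + 0.1 * x + rnorm(n)
    tot <- coef(lm(y ~ x))[2]
    cdir <- coef(lm(y ~ x + mvar))[2]
    a <- coef(lm(mvar ~ x))[2]
    b <- coef(lm(y ~ x + mvar))[3]
    res <- mr_mediation(tot, cdir, a, b)
    expect_equal(res$indirect_difference, res$indirect_product,
                 tolerance = 0.02)
    expect_equal(unname(res$indirect_product), 0.2, tolerance = 0.03)
  })
})

test_that("the estimator battery returns one tidy row per applicable method", {
  h <- make_clean_pair(j = 10, noise = 0.005)
  tab <- mr_battery(h, seed = 3, n_boot = 50)
  expect_setequal(tab$method, c("ivw_fixed", "ivw_multiplicative",
                                "ivw_additive", "egger", "weighted_median",
                                "weighted_mode"))
  expect_true(all(tab$n_snps == 10))
  expect_true(all(tab$se > 0))
  # Extras are flattened into prefixed columns where scalar.
  expect_true("intercept" %in% names(tab))
})
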
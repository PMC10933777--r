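#' Construct an MR estimate object
#'
#' @param method method label.
#' @param estimate causal-effect point estimate (outcome units per exposure
#'   unit).
#' @param se standard error.
#' @param ci_low,ci_high 95% interval bounds.
#' @param pval two-sided p-value.
#' @param n_snps number of instruments used.
#' @param extras named list of method-specific values (Egger intercept and
#'   its se/p, additive random-effects tau2, multiplicative scale, removed
#'   outliers, ...).
#' @return Object of class `mr_estimate`.
#' @export
mr_estimate <- function(method, estimate, se, ci_low, ci_high, pval,
                        n_snps, extras = list()) {
  assert_that(ci_low <= estimate + 1e-12 && estimate <= ci_high + 1e-12,
              "confidence interval must bracket the estimate")
  assert_that(se > 0, "se must be > 0")
  assert_that(pval > 0 && pval <= 1, "pval must lie in (0, 1]")
  structure(list(method = method, estimate = estimate, se = se,
                 ci_low = ci_low, ci_high = ci_high, pval = pval,
                 n_snps = as.integer(n_snps), extras = extras),
            class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("<mr_estimate> %s: %.4g (se %.3g, 95%% CI [%.4g, %.4g], p = %.3g, %d SNPs)\n",
              x$method, x$estimate, x$se, x$ci_low, x$ci_high, x$pval, x$n_snps))
  if (length(x$extras)) {
    vals <- vapply(x$extras, function(v) paste(format(v, digits = 4), collapse = ","),
                   character(1))
    cat("  extras:", paste(names(vals), vals, sep = " = ", collapse = "; "), "\n")
  }
  invisible(x)
}

#' Flatten one or more MR estimates into a tidy data.frame
#'
#' @param x an `mr_estimate` or a list of them.
#' @param ... unused.
#' @return data.frame with one row per estimate; scalar extras become
#'   method-prefixed columns.
#' @export
as.data.frame.mr_estimate <- function(x, ...) {
  base <- data.frame(method = x$method, estimate = x$estimate, se = x$se,
                     ci_low = x$ci_low, ci_high = x$ci_high, pval = x$pval,
                     n_snps = x$n_snps, stringsAsFactors = FALSE)
  for (nm in names(x$extras)) {
    v <- x$extras[[nm]]
    if (is.numeric(v) && length(v) == 1) base[[nm]] <- v
  }
  base
}

#' Bind a list of MR estimates into one tidy table
#' @param estimates list of `mr_estimate` objects.
#' @return data.frame, one row per estimate (extras union-filled with NA).
#' @export
mr_tidy <- function(estimates) {
  rows <- lapply(estimates, as.data.frame)
  cols <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(r) {
    for (c in setdiff(cols, names(r))) r[[c]] <- NA
    r[cols]
  })
  do.call(rbind, rows)
}

mr_estimate_normal <- function(method, estimate, se, n_snps, extras = list()) {
  ci <- norm_ci(estimate, se)
  mr_estimate(method, estimate, se, ci[1], ci[2],
              norm_pval(estimate, se), n_snps, extras)
}

#' Wald ratio estimate from a single instrument
#'
#' The causal effect is the ratio of the SNP-outcome to the SNP-exposure
#' association, `beta_outcome / beta_exposure`, with a first-order
#' delta-method standard error `se_outcome / |beta_exposure|` (the
#' no-measurement-error approximation) and a normal CI and p-value.
#'
#' @param beta_exposure,se_exposure SNP-exposure association and SE.
#' @param beta_outcome,se_outcome SNP-outcome association and SE.
#' @return An [mr_estimate()] with method `"wald_ratio"`.
#' @export
wald_ratio <- function(beta_exposure, se_exposure, beta_outcome, se_outcome) {
  assert_that(beta_exposure != 0, "undefined ratio: beta_exposure is zero")
  estimate <- beta_outcome / beta_exposure
  se <- se_outcome / abs(beta_exposure)
  mr_estimate_normal("wald_ratio", estimate, se, 1L)
}

#' Per-SNP ratio estimates and inverse-variance weights
#'
#' @param h a [harmonise()] result with at least one kept instrument.
#' @param weight_order `"first_order"` (default; SE `se_O / |beta_E|`) or
#'   `"second_order"`, which adds the exposure-uncertainty term
#'   `sqrt(se_O^2/beta_E^2 + beta_O^2 * se_E^2 / beta_E^4)`.
#' @return Object of class `ratio_set`: data.frame with `snp_id`, `ratio`,
#'   `se`, `weight` (`1/se^2`).
#' @export
ratio_set <- function(h, weight_order = c("first_order", "second_order")) {
  weight_order <- match.arg(weight_order)
  k <- kept_instruments(h)
  assert_that(nrow(k) >= 1, "no kept instruments")
  zero <- k$snp_id[k$beta_exposure == 0]
  assert_that(length(zero) == 0,
              paste0("zero exposure association for SNP(s): ",
                     paste(zero, collapse = ", ")))
  ratio <- k$beta_outcome / k$beta_exposure
  se <- if (weight_order == "first_order") {
    k$se_outcome / abs(k$beta_exposure)
  } else {
    sqrt(k$se_outcome^2 / k$beta_exposure^2 +
           k$beta_outcome^2 * k$se_exposure^2 / k$beta_exposure^4)
  }
  structure(data.frame(snp_id = k$snp_id, ratio = ratio, se = se,
                       weight = 1 / se^2, stringsAsFactors = FALSE),
            class = c("ratio_set", "data.frame"),
            weight_order = weight_order)
}

#' Inverse-variance weighted MR estimate
#'
#' Combines per-SNP ratio estimates meta-analytically. `"fixed"` uses
#' `sum(w * b) / sum(w)` with `se = sum(w)^(-1/2)`. `"multiplicative"`
#' (the default) keeps the same point estimate and inflates the SE by
#' `sqrt(max(1, Q/(J-1)))`, so heterogeneity widens the interval without
#' moving the estimate. `"additive"` uses the DerSimonian-Laird
#' between-SNP variance `tau2 = max(0, (Q - (J-1)) / (sum(w) - sum(w^2)/sum(w)))`
#' and re-weights by `1/(se^2 + tau2)`. A single instrument degenerates to
#' the Wald ratio (noted via a message).
#'
#' @param h a [harmonise()] result.
#' @param model `"multiplicative"`, `"fixed"` or `"additive"`.
#' @param weight_order passed to [ratio_set()].
#' @return An [mr_estimate()]; `extras$tau2` for additive, `extras$scale`
#'   for multiplicative.
#' @export
mr_ivw <- function(h, model = c("multiplicative", "fixed", "additive"),
                   weight_order = "first_order") {
  model <- match.arg(model)
  rs <- ratio_set(h, weight_order)
  j <- nrow(rs)
  assert_that(j >= 1, "no instruments")
  if (j == 1) {
    message("mr_ivw: single instrument, degenerating to the Wald ratio")
    k <- kept_instruments(h)
    est <- wald_ratio(k$beta_exposure, k$se_exposure, k$beta_outcome, k$se_outcome)
    est$method <- paste0("ivw_", model)
    return(est)
  }
  w <- rs$weight
  beta <- sum(w * rs$ratio) / sum(w)
  se_fixed <- sqrt(1 / sum(w))
  q <- sum(w * (rs$ratio - beta)^2)

  if (model == "fixed") {
    return(mr_estimate_normal("ivw_fixed", beta, se_fixed, j))
  }
  if (model == "multiplicative") {
    scale <- sqrt(max(1, q / (j - 1)))
    return(mr_estimate_normal("ivw_multiplicative", beta, se_fixed * scale, j,
                              extras = list(scale = scale)))
  }
  tau2 <- max(0, (q - (j - 1)) / (sum(w) - sum(w^2) / sum(w)))
  w_star <- 1 / (rs$se^2 + tau2)
  beta_add <- sum(w_star * rs$ratio) / sum(w_star)
  se_add <- sqrt(1 / sum(w_star))
  mr_estimate_normal("ivw_additive", beta_add, se_add, j,
                     extras = list(tau2 = tau2))
}

# Orient instruments so every exposure association is non-negative
# (estimates are invariant to joint sign flips; Egger requires it).
orient_positive <- function(k) {
  flip <- k$beta_exposure < 0
  k$beta_exposure[flip] <- -k$beta_exposure[flip]
  k$beta_outcome[flip] <- -k$beta_outcome[flip]
  k
}

#' MR-Egger regression
#'
#' Weighted least squares of the SNP-outcome on the SNP-exposure
#' associations with a free intercept (weights `1/se_outcome^2`), after
#' orienting all instruments to non-negative exposure associations. A
#' non-zero intercept indicates directional pleiotropy; the slope is the
#' causal estimate under the InSIDE assumption. Standard errors carry a
#' multiplicative over-dispersion factor `sqrt(max(1, RSS_w/(J-2)))` and
#' p-values use a t distribution with `J - 2` degrees of freedom.
#'
#' @param h a [harmonise()] result with at least 3 kept instruments.
#' @return An [mr_estimate()] with `extras` `intercept`, `intercept_se`,
#'   `intercept_pval` and `scale`.
#' @export
mr_egger <- function(h) {
  k <- kept_instruments(h)
  j <- nrow(k)
  assert_that(j >= 3, "MR-Egger requires at least 3 instruments")
  k <- orient_positive(k)
  assert_that(stats::var(k$beta_exposure) > 0, "unidentifiable slope")
  w <- 1 / k$se_outcome^2
  fit <- stats::lm(beta_outcome ~ beta_exposure, data = k, weights = w)
  rss_w <- sum(w * stats::residuals(fit)^2)
  scale <- sqrt(max(1, rss_w / (j - 2)))
  # Unscaled coefficient covariance (X'WX)^-1, so an exact fit (RSS 0)
  # still yields positive SEs via the over-dispersion floor at 1.
  xmat <- cbind(1, k$beta_exposure)
  cov_unscaled <- chol2inv(chol(crossprod(xmat * sqrt(w))))
  coef_se <- sqrt(diag(cov_unscaled)) * scale
  slope <- stats::coef(fit)[["beta_exposure"]]
  slope_se <- coef_se[2]
  intercept <- stats::coef(fit)[["(Intercept)"]]
  intercept_se <- coef_se[1]
  tq <- stats::qt(0.975, df = j - 2)
  pv <- function(est, se) {
    pmax(2 * stats::pt(-abs(est / se), df = j - 2), .Machine$double.xmin)
  }
  mr_estimate("egger", slope, slope_se,
              slope - tq * slope_se, slope + tq * slope_se,
              pv(slope, slope_se), j,
              extras = list(intercept = intercept,
                            intercept_se = intercept_se,
                            intercept_pval = pv(intercept, intercept_se),
                            scale = scale))
}

# Weighted median of per-SNP ratios by linear interpolation of the
# standardised cumulative weights at 0.5.
weighted_median_point <- function(ratio, weight) {
  ord <- order(ratio)
  b <- ratio[ord]
  w <- weight[ord]
  s <- (cumsum(w) - w / 2) / sum(w)
  if (s[1] >= 0.5) return(b[1])
  if (s[length(s)] <= 0.5) return(b[length(b)])
  stats::approx(s, b, xout = 0.5, ties = "ordered")$y
}

# Parametric bootstrap SE for a statistic of the harmonised pairs:
# resample each association from a normal centred at its estimate.
bootstrap_se <- function(k, statistic, n_boot, seed) {
  with_seed(seed, {
    stats_boot <- vapply(seq_len(n_boot), function(i) {
      be <- stats::rnorm(nrow(k), k$beta_exposure, k$se_exposure)
      bo <- stats::rnorm(nrow(k), k$beta_outcome, k$se_outcome)
      statistic(bo / be, (k$se_outcome / abs(be))^-2)
    }, numeric(1))
    stats::sd(stats_boot)
  })
}

#' Weighted median MR estimate
#'
#' Consistent when at least half the weight comes from valid instruments.
#' Per-SNP ratios are sorted, cumulative inverse-variance weights are
#' standardised, and the estimate interpolates the ratio at cumulative
#' weight 0.5. The SE comes from a parametric bootstrap that resamples the
#' summary associations from normals with their reported SEs.
#'
#' @param h a [harmonise()] result with at least 3 kept instruments.
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed RNG seed for the bootstrap (required; recorded in extras).
#' @return An [mr_estimate()] with method `"weighted_median"`.
#' @export
mr_weighted_median <- function(h, n_boot = 1000, seed) {
  k <- kept_instruments(h)
  assert_that(nrow(k) >= 3, "weighted median requires at least 3 instruments")
  rs <- ratio_set(h)
  estimate <- weighted_median_point(rs$ratio, rs$weight)
  se <- bootstrap_se(k, function(b, w) weighted_median_point(b, w), n_boot, seed)
  mr_estimate_normal("weighted_median", estimate, se, nrow(k),
                     extras = list(n_boot = n_boot, seed = seed))
}

# Weighted-KDE mode of the per-SNP ratios; modified Silverman bandwidth.
weighted_mode_point <- function(ratio, weight, phi = 1) {
  s <- stats::sd(ratio)
  iqr <- stats::IQR(ratio) / 1.34
  bw <- phi * 0.9 * min(s, if (iqr > 0) iqr else s) * length(ratio)^(-1 / 5)
  if (!is.finite(bw) || bw <= 0) return(ratio[1])  # all ratios identical
  # density() interpolates onto the output grid; near-duplicate ratios make
  # that interpolation warn about tied abscissae, harmlessly.
  d <- suppressWarnings(
    stats::density(ratio, weights = weight / sum(weight), bw = bw,
                   n = 512, from = min(ratio) - 3 * bw,
                   to = max(ratio) + 3 * bw))
  d$x[which.max(d$y)]
}

#' Weighted mode MR estimate
#'
#' Consistent when the largest group of instruments sharing the same causal
#' effect (plurality) is valid. The estimate is the argmax of a weighted
#' Gaussian kernel density over the per-SNP ratios, with bandwidth
#' `phi * 0.9 * min(sd, IQR/1.34) * J^(-1/5)` evaluated on a 512-point grid
#' spanning the ratio range plus three bandwidths; the SE is a parametric
#' bootstrap as in [mr_weighted_median()].
#'
#' @param h a [harmonise()] result with at least 3 kept instruments.
#' @param phi bandwidth multiplier (default 1).
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed RNG seed (required).
#' @return An [mr_estimate()] with method `"weighted_mode"`.
#' @export
mr_weighted_mode <- function(h, phi = 1, n_boot = 1000, seed) {
  k <- kept_instruments(h)
  assert_that(nrow(k) >= 3, "weighted mode requires at least 3 instruments")
  rs <- ratio_set(h)
  estimate <- weighted_mode_point(rs$ratio, rs$weight, phi)
  se <- bootstrap_se(k, function(b, w) weighted_mode_point(b, w, phi), n_boot, seed)
  mr_estimate_normal("weighted_mode", estimate, se, nrow(k),
                     extras = list(phi = phi, n_boot = n_boot, seed = seed))
}

#' Multivariable IVW MR
#'
#' Weighted least squares of the SNP-outcome associations on the J x K
#' matrix of SNP-exposure associations, without intercept, weights
#' `1/se_outcome^2`. Each exposure's coefficient is its direct causal
#' effect controlling for the other exposures. SEs carry multiplicative
#' over-dispersion scaling with `J - K` residual degrees of freedom.
#'
#' @param beta_exposures numeric J x K matrix (columns named per exposure).
#' @param beta_outcome,se_outcome numeric vectors of length J.
#' @return List of [mr_estimate()] objects, one per exposure column.
#' @export
mr_mvmr_ivw <- function(beta_exposures, beta_outcome, se_outcome) {
  x <- as.matrix(beta_exposures)
  j <- nrow(x)
  k <- ncol(x)
  assert_that(j >= k + 1, "need at least K + 1 shared instruments")
  assert_that(qr(x)$rank == k, "collinear exposures")
  w <- 1 / se_outcome^2
  fit <- stats::lm.fit(x * sqrt(w), beta_outcome * sqrt(w))
  coefs <- unname(fit$coefficients)
  rss_w <- sum(fit$residuals^2)
  scale2 <- max(1, rss_w / (j - k))
  xtx_inv <- chol2inv(chol(crossprod(x * sqrt(w))))
  ses <- sqrt(diag(xtx_inv) * scale2)
  labels <- colnames(x) %||% paste0("exposure", seq_len(k))
  tq <- stats::qt(0.975, df = j - k)
  lapply(seq_len(k), function(i) {
    mr_estimate(paste0("mvmr_ivw:", labels[i]), coefs[i], ses[i],
                coefs[i] - tq * ses[i], coefs[i] + tq * ses[i],
                pmax(2 * stats::pt(-abs(coefs[i] / ses[i]), df = j - k),
                     .Machine$double.xmin), j,
                extras = list(scale = sqrt(scale2)))
  })
}

#' Mediation arithmetic: difference and product methods
#'
#' Given a total effect, a direct effect controlling for the mediator, and
#' the two legs of the exposure -> mediator -> outcome path, returns both
#' classical indirect-effect estimates: the difference
#' `beta_total - c_direct` and the product `a * b` (asymptotically
#' equivalent in linear-Gaussian systems). In the MR setting these
#' correspond to multivariable MR (difference) and two-step MR (product).
#'
#' @param beta_total total causal effect of exposure on outcome.
#' @param c_direct direct effect controlling for the mediator.
#' @param a_exposure_mediator causal effect of exposure on mediator.
#' @param b_mediator_outcome causal effect of mediator on outcome.
#' @return List of class `mediation_result` with `total`, `direct`,
#'   `indirect_difference`, `indirect_product`, `a`, `b`.
#' @export
mr_mediation <- function(beta_total, c_direct, a_exposure_mediator,
                         b_mediator_outcome) {
  structure(list(
    total = beta_total,
    direct = c_direct,
    indirect_difference = beta_total - c_direct,
    indirect_product = a_exposure_mediator * b_mediator_outcome,
    a = a_exposure_mediator,
    b = b_mediator_outcome
  ), class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf("<mediation_result> total %.4g | direct %.4g | indirect: difference %.4g, product %.4g\n",
              x$total, x$direct, x$indirect_difference, x$indirect_product))
  invisible(x)
}

#' Run the standard MR estimator battery
#'
#' Applies IVW (all three meta-analytic variants), MR-Egger, weighted
#' median and weighted mode to one harmonised exposure-outcome pair,
#' skipping methods whose instrument-count preconditions fail.
#'
#' @param h a [harmonise()] result.
#' @param seed RNG seed for the bootstrap-based methods.
#' @param n_boot bootstrap replicates for median/mode SEs.
#' @return data.frame with one row per method ([mr_tidy()] format).
#' @export
mr_battery <- function(h, seed, n_boot = 1000) {
  j <- nrow(kept_instruments(h))
  assert_that(j >= 1, "no kept instruments")
  ests <- list()
  for (model in c("fixed", "multiplicative", "additive")) {
    ests[[length(ests) + 1]] <- suppressMessages(mr_ivw(h, model = model))
  }
  if (j >= 3) {
    ests[[length(ests) + 1]] <- mr_egger(h)
    ests[[length(ests) + 1]] <- mr_weighted_median(h, n_boot = n_boot, seed = seed)
    ests[[length(ests) + 1]] <- mr_weighted_mode(h, n_boot = n_boot, seed = seed + 1L)
  }
  mr_tidy(ests)
}
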
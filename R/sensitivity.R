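# Sensitivity workflow: heterogeneity, leave-one-out, single-SNP, funnel
# data, Steiger directionality and filtering, threshold variation, and the
# bi-directional orchestration.

#' Cochran's Q heterogeneity statistic and Higgins' I-squared
#'
#' `Q = sum(w_j * (b_j - b)^2)` over per-SNP ratio estimates about a pooled
#' estimate, referred to a chi-square with `J - df_adjust` degrees of
#' freedom; `I2 = max(0, (Q - df) / Q)` quantifies the proportional excess.
#'
#' @param ratios a [ratio_set()].
#' @param pooled pooled estimate: an [mr_estimate()] or a number.
#' @param df_adjust parameters estimated from the same data (default 1 for
#'   IVW; use 2 after an Egger fit).
#' @return Object of class `heterogeneity_stats`: list `q`, `df`, `pval`,
#'   `i2`.
#' @export
cochran_q <- function(ratios, pooled, df_adjust = 1) {
  beta <- if (inherits(pooled, "mr_estimate")) pooled$estimate else pooled
  j <- nrow(ratios)
  assert_that(j > df_adjust, "need more instruments than estimated parameters")
  q <- sum(ratios$weight * (ratios$ratio - beta)^2)
  df <- j - df_adjust
  i2 <- if (q > 0) max(0, (q - df) / q) else 0
  structure(list(q = q, df = df,
                 pval = stats::pchisq(q, df = df, lower.tail = FALSE),
                 i2 = i2),
            class = "heterogeneity_stats")
}

#' @export
print.heterogeneity_stats <- function(x, ...) {
  cat(sprintf("<heterogeneity> Q = %.3f (df %d, p = %.3g), I2 = %.1f%%\n",
              x$q, x$df, x$pval, 100 * x$i2))
  invisible(x)
}

estimator_by_name <- function(method, seed = 1L) {
  switch(method,
    ivw_multiplicative = function(h) suppressMessages(mr_ivw(h, "multiplicative")),
    ivw_fixed = function(h) suppressMessages(mr_ivw(h, "fixed")),
    ivw_additive = function(h) suppressMessages(mr_ivw(h, "additive")),
    egger = mr_egger,
    weighted_median = function(h) mr_weighted_median(h, seed = seed),
    weighted_mode = function(h) mr_weighted_mode(h, seed = seed),
    stop("unknown method: ", method, call. = FALSE)
  )
}

#' Leave-one-out analysis
#'
#' Re-estimates the causal effect omitting each instrument in turn;
#' instruments whose omission moves the estimate most are the ones driving
#' it.
#'
#' @param h a [harmonise()] result with at least 3 kept instruments.
#' @param method estimator label (default `"ivw_multiplicative"`).
#' @param seed seed for bootstrap-based methods.
#' @return data.frame with one row per omitted SNP: `omitted_snp`,
#'   `estimate`, `se`, `ci_low`, `ci_high`, `pval`, `n_snps`.
#' @export
leave_one_out <- function(h, method = "ivw_multiplicative", seed = 1L) {
  k <- kept_instruments(h)
  assert_that(nrow(k) >= 3, "leave-one-out requires at least 3 instruments")
  f <- estimator_by_name(method, seed)
  rows <- lapply(k$snp_id, function(id) {
    est <- f(subset_instruments(h, setdiff(k$snp_id, id)))
    cbind(omitted_snp = id, as.data.frame(est)[
      c("estimate", "se", "ci_low", "ci_high", "pval", "n_snps")])
  })
  do.call(rbind, rows)
}

#' Single-SNP (per-instrument Wald ratio) analysis
#'
#' @param h a [harmonise()] result.
#' @return data.frame with one Wald-ratio row per kept SNP, order preserved.
#' @export
single_snp <- function(h) {
  k <- kept_instruments(h)
  assert_that(nrow(k) >= 1, "no kept instruments")
  rows <- lapply(seq_len(nrow(k)), function(i) {
    est <- wald_ratio(k$beta_exposure[i], k$se_exposure[i],
                      k$beta_outcome[i], k$se_outcome[i])
    cbind(snp_id = k$snp_id[i], as.data.frame(est)[
      c("estimate", "se", "ci_low", "ci_high", "pval")])
  })
  do.call(rbind, rows)
}

#' Funnel-plot data: per-SNP estimates against precision
#'
#' Instrument precision (1/SE of the ratio estimate) against the single
#' instrument estimate; under balanced pleiotropy the points form a
#' symmetric triangular envelope around the pooled estimate.
#'
#' @param h a [harmonise()] result.
#' @return data.frame `snp_id`, `estimate`, `precision`.
#' @export
funnel_data <- function(h) {
  rs <- ratio_set(h)
  data.frame(snp_id = rs$snp_id, estimate = rs$ratio, precision = 1 / rs$se,
             stringsAsFactors = FALSE)
}

#' Scatter-plot data: per-SNP exposure vs outcome associations
#'
#' @param h a [harmonise()] result.
#' @return data.frame of kept rows with both associations and SEs, oriented
#'   to non-negative exposure associations for plotting.
#' @export
scatter_data <- function(h) {
  k <- orient_positive(kept_instruments(h))
  k[, c("snp_id", "beta_exposure", "se_exposure", "beta_outcome", "se_outcome")]
}

# Per-SNP correlation magnitudes from t statistics: r = t / sqrt(t^2 + n - 2).
snp_correlations <- function(beta, se, n) {
  t <- beta / se
  t / sqrt(t^2 + n - 2)
}

#' Steiger directionality test
#'
#' Compares the aggregate variance explained by the instruments in the
#' exposure against the outcome. Per-SNP correlations come from the
#' t-statistics (`r = t/sqrt(t^2 + n - 2)`); per-trait R-squared sums the
#' squared correlations; the two aggregate correlations `sqrt(R2)` are
#' compared with a Fisher-z statistic
#' `z = (atanh(r_exp) - atanh(r_out)) / sqrt(1/(n_exp-3) + 1/(n_out-3))`.
#' A forward direction (exposure causes outcome) is supported when the
#' instruments explain significantly more variance in the exposure.
#'
#' @param h a [harmonise()] result; sample sizes for both traits must be
#'   available (from the datasets or via arguments).
#' @param alpha significance level for calling a direction (default 0.05).
#' @param n_exposure,n_outcome override sample sizes.
#' @return Object of class `steiger_result`: list `r2_exposure`,
#'   `r2_outcome`, `z`, `pval`, `direction` (forward / reverse /
#'   inconclusive), `alpha`.
#' @export
mr_steiger <- function(h, alpha = 0.05, n_exposure = NULL, n_outcome = NULL) {
  k <- kept_instruments(h)
  assert_that(nrow(k) >= 1, "no kept instruments")
  ne <- n_exposure %||% h$n_exposure
  no <- n_outcome %||% h$n_outcome
  assert_that(is.finite(ne) && is.finite(no), "sample sizes unavailable")
  assert_that(ne > 3 && no > 3, "sample sizes must exceed 3")

  r2_exp <- sum(snp_correlations(k$beta_exposure, k$se_exposure, ne)^2)
  r2_out <- sum(snp_correlations(k$beta_outcome, k$se_outcome, no)^2)
  r_exp <- sqrt(min(r2_exp, 1 - 1e-12))
  r_out <- sqrt(min(r2_out, 1 - 1e-12))
  z <- (atanh(r_exp) - atanh(r_out)) / sqrt(1 / (ne - 3) + 1 / (no - 3))
  pval <- pmax(2 * stats::pnorm(-abs(z)), .Machine$double.xmin)
  direction <- if (pval >= alpha) {
    "inconclusive"
  } else if (r2_exp > r2_out) "forward" else "reverse"
  structure(list(r2_exposure = r2_exp, r2_outcome = r2_out, z = z,
                 pval = pval, direction = direction, alpha = alpha),
            class = "steiger_result")
}

#' @export
print.steiger_result <- function(x, ...) {
  cat(sprintf("<steiger> R2 exposure %.4g vs outcome %.4g | z = %.3f, p = %.3g -> %s\n",
              x$r2_exposure, x$r2_outcome, x$z, x$pval, x$direction))
  invisible(x)
}

#' Steiger filtering of instruments
#'
#' Keeps instruments that explain more variance in the exposure than in the
#' outcome (per-SNP squared-correlation comparison); candidates for reverse
#' causation are removed and reported via a message.
#'
#' @param h a [harmonise()] result.
#' @param n_exposure,n_outcome override sample sizes.
#' @return The filtered `harmonised_instruments` (possibly with zero kept
#'   rows, with a warning).
#' @export
steiger_filter <- function(h, n_exposure = NULL, n_outcome = NULL) {
  k <- kept_instruments(h)
  ne <- n_exposure %||% h$n_exposure
  no <- n_outcome %||% h$n_outcome
  assert_that(is.finite(ne) && is.finite(no), "sample sizes unavailable")
  r2_exp <- snp_correlations(k$beta_exposure, k$se_exposure, ne)^2
  r2_out <- snp_correlations(k$beta_outcome, k$se_outcome, no)^2
  drop <- k$snp_id[r2_exp <= r2_out]
  if (length(drop)) {
    message("steiger_filter: removing ", length(drop), " SNP(s): ",
            paste(drop, collapse = ", "))
  }
  out <- subset_instruments(h, setdiff(k$snp_id, drop))
  if (nrow(kept_instruments(out)) == 0) {
    warning("steiger_filter removed every instrument")
  }
  out
}

#' Instrument-threshold sensitivity scan
#'
#' Repeats instrument selection, harmonisation and estimation over a grid
#' of SNP-exposure p-value thresholds (a liberal 1e-6, the conventional
#' 5e-8 and a conservative 1e-12 by default). Consistent estimates across
#' thresholds indicate a robust effect.
#'
#' @param exposure,outcome [summary_dataset()] objects.
#' @param thresholds p-value thresholds to scan.
#' @param method estimator label (default `"ivw_multiplicative"`).
#' @param seed seed for bootstrap-based methods.
#' @return data.frame with one row per threshold: `threshold`, `n_snps`,
#'   `status` plus estimate columns (NA when no instruments pass).
#' @export
threshold_scan <- function(exposure, outcome,
                           thresholds = c(1e-6, 5e-8, 1e-12),
                           method = "ivw_multiplicative", seed = 1L) {
  f <- estimator_by_name(method, seed)
  rows <- lapply(thresholds, function(thr) {
    sel <- suppressMessages(select_instruments(exposure, thr))
    if (nrow(sel$snps) == 0 ||
        length(intersect(sel$snps$snp_id, outcome$snps$snp_id)) == 0) {
      return(data.frame(threshold = thr, n_snps = 0L, status = "no_instruments",
                        estimate = NA_real_, se = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_, pval = NA_real_))
    }
    hh <- harmonise(sel, outcome)
    if (nrow(kept_instruments(hh)) == 0) {
      return(data.frame(threshold = thr, n_snps = 0L, status = "no_instruments",
                        estimate = NA_real_, se = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_, pval = NA_real_))
    }
    est <- f(hh)
    data.frame(threshold = thr, n_snps = est$n_snps, status = "estimated",
               estimate = est$estimate, se = est$se, ci_low = est$ci_low,
               ci_high = est$ci_high, pval = est$pval)
  })
  do.call(rbind, rows)
}

#' Full sensitivity report for one harmonised pair
#'
#' Assembles the standard sensitivity battery: heterogeneity (Q / I-squared
#' against the fixed-effects IVW and the Egger fit), the Egger intercept
#' triple, leave-one-out, single-SNP and funnel tables, and the Steiger
#' directionality test.
#'
#' @param h a [harmonise()] result with at least 3 kept instruments.
#' @param seed seed for bootstrap-based methods.
#' @param steiger logical; skip the Steiger test when sample sizes are
#'   unavailable.
#' @return Object of class `sensitivity_report` (a named list of the above).
#' @export
sensitivity_report <- function(h, seed = 1L, steiger = TRUE) {
  rs <- ratio_set(h)
  ivw_fix <- suppressMessages(mr_ivw(h, "fixed"))
  egger <- mr_egger(h)
  het_ivw <- cochran_q(rs, ivw_fix, df_adjust = 1)
  # Q about the Egger line: residual-based with two estimated parameters.
  k <- orient_positive(kept_instruments(h))
  resid <- k$beta_outcome - egger$extras$intercept -
    egger$estimate * k$beta_exposure
  q_egger <- sum(resid^2 / k$se_outcome^2)
  het_egger <- structure(list(
    q = q_egger, df = nrow(k) - 2,
    pval = stats::pchisq(q_egger, df = nrow(k) - 2, lower.tail = FALSE),
    i2 = if (q_egger > 0) max(0, (q_egger - (nrow(k) - 2)) / q_egger) else 0
  ), class = "heterogeneity_stats")

  structure(list(
    heterogeneity = list(ivw = het_ivw, egger = het_egger),
    egger_intercept = list(estimate = egger$extras$intercept,
                           se = egger$extras$intercept_se,
                           pval = egger$extras$intercept_pval),
    leave_one_out = leave_one_out(h, seed = seed),
    single_snp = single_snp(h),
    funnel = funnel_data(h),
    scatter = scatter_data(h),
    steiger = if (steiger && is.finite(h$n_exposure %||% NA) &&
                    is.finite(h$n_outcome %||% NA)) mr_steiger(h)
  ), class = "sensitivity_report")
}

#' Serialise a sensitivity report to JSON
#' @param x a [sensitivity_report()].
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_sensitivity_report <- function(x, path) {
  payload <- list(
    heterogeneity = lapply(x$heterogeneity, unclass),
    egger_intercept = x$egger_intercept,
    leave_one_out = x$leave_one_out,
    single_snp = x$single_snp,
    funnel = x$funnel,
    scatter = x$scatter,
    steiger = if (!is.null(x$steiger)) unclass(x$steiger)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Bi-directional MR analysis
#'
#' Runs the full pipeline (instrument selection, harmonisation, estimator
#' battery, optional sensitivity report) with trait `a` as exposure and
#' then with trait `b` as exposure. A direction with no instruments is a
#' first-class `"not_estimable"` result, never an error, so that screening
#' over many pairs cannot abort.
#'
#' @param a,b [summary_dataset()] objects.
#' @param p_threshold instrument p-value threshold (default 5e-8).
#' @param seed seed for bootstrap-based methods.
#' @param sensitivity logical; attach a [sensitivity_report()] per
#'   direction when at least 3 instruments are kept.
#' @return Object of class `bidirectional_result`: list of two direction
#'   entries, each with `direction`, `exposure`, `outcome`, `status`,
#'   `n_snps`, `results` (tidy battery table or NULL) and `sensitivity`.
#' @export
mr_bidirectional <- function(a, b, p_threshold = 5e-8, seed = 1L,
                             sensitivity = FALSE) {
  run_direction <- function(exposure, outcome, label, seed) {
    sel <- suppressMessages(select_instruments(exposure, p_threshold))
    shared <- intersect(sel$snps$snp_id, outcome$snps$snp_id)
    if (nrow(sel$snps) == 0 || length(shared) == 0) {
      return(list(direction = label, exposure = exposure$trait_name,
                  outcome = outcome$trait_name, status = "not_estimable",
                  n_snps = 0L, results = NULL, sensitivity = NULL))
    }
    hh <- harmonise(sel, outcome)
    j <- nrow(kept_instruments(hh))
    if (j == 0) {
      return(list(direction = label, exposure = exposure$trait_name,
                  outcome = outcome$trait_name, status = "not_estimable",
                  n_snps = 0L, results = NULL, sensitivity = NULL))
    }
    list(direction = label, exposure = exposure$trait_name,
         outcome = outcome$trait_name, status = "estimated", n_snps = j,
         results = mr_battery(hh, seed = seed),
         sensitivity = if (sensitivity && j >= 3) sensitivity_report(hh, seed))
  }
  structure(list(
    forward = run_direction(a, b, "forward", seed),
    reverse = run_direction(b, a, "reverse", seed + 1L)
  ), class = "bidirectional_result")
}

#' @export
print.bidirectional_result <- function(x, ...) {
  for (d in x) {
    cat(sprintf("[%s] %s -> %s: %s (%d SNPs)\n", d$direction, d$exposure,
                d$outcome, d$status, d$n_snps))
    if (!is.null(d$results)) {
      print(d$results[, c("method", "estimate", "se", "pval", "n_snps")])
    }
  }
  invisible(x)
}
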
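# MR-PRESSO: global heterogeneity test, per-SNP outlier test and distortion
# test, with outlier-removed re-estimation. All null distributions are
# simulated parametrically from the reported summary statistics.

# Leave-one-out fixed-effects IVW slopes (through-origin WLS, weights
# 1/se_O^2), computed for every SNP at once from running sums.
loo_ivw_slopes <- function(be, bo, w) {
  sxy <- sum(w * be * bo)
  sxx <- sum(w * be^2)
  (sxy - w * be * bo) / (sxx - w * be^2)
}

#' MR-PRESSO outlier detection
#'
#' Tests for horizontal pleiotropy via the weighted residual sum of squares
#' of the per-SNP outcome associations about their leave-one-out IVW
#' predictions. The null distribution is built by `n_sim` parametric draws
#' of both association vectors from normals centred at the fitted model.
#' Three results are reported: a global heterogeneity p-value; per-SNP
#' outlier p-values (empirical, Bonferroni-adjusted across instruments)
#' with flagged SNPs removed for re-estimation; and a distortion test
#' comparing the estimate shift after outlier removal against random
#' removals of the same number of instruments.
#'
#' @param h a [harmonise()] result with at least 4 kept instruments.
#' @param n_sim simulation count for the empirical nulls (default 1000).
#' @param outlier_alpha significance level for flagging outliers after
#'   Bonferroni adjustment (default 0.05).
#' @param seed RNG seed (required; all draws derive from it).
#' @param resample `"both"` resamples exposure and outcome associations
#'   (the reference construction); `"outcome"` is a faster variant that
#'   resamples only the outcome side.
#' @return Object of class `presso_result`: list with `global_rss_observed`,
#'   `global_pval`, `outlier_pvals` (data.frame, adjusted), `outlier_ids`,
#'   `estimate_raw` and `estimate_outlier_corrected` ([mr_estimate()]s),
#'   `distortion_coefficient`, `distortion_pval` (NA when no outliers),
#'   `n_sim`, `seed`.
#' @export
mr_presso <- function(h, n_sim = 1000, outlier_alpha = 0.05, seed,
                      resample = c("both", "outcome")) {
  resample <- match.arg(resample)
  k <- kept_instruments(h)
  j <- nrow(k)
  assert_that(j >= 4, "MR-PRESSO requires at least 4 instruments")
  be <- k$beta_exposure
  bo <- k$beta_outcome
  se_e <- k$se_exposure
  se_o <- k$se_outcome
  w <- 1 / se_o^2

  b_loo <- loo_ivw_slopes(be, bo, w)
  terms_obs <- w * (bo - b_loo * be)^2
  rss_obs <- sum(terms_obs)

  seeds <- derive_seeds(seed, 2L)
  sim_terms <- with_seed(seeds[1], {
    # n_sim x J matrices of resampled associations under the fitted model.
    be_mat <- if (resample == "both") {
      matrix(stats::rnorm(n_sim * j, mean = rep(be, each = n_sim),
                          sd = rep(se_e, each = n_sim)), n_sim, j)
    } else {
      matrix(be, n_sim, j, byrow = TRUE)
    }
    bo_mat <- matrix(stats::rnorm(n_sim * j, mean = rep(b_loo * be, each = n_sim),
                                  sd = rep(se_o, each = n_sim)), n_sim, j)
    w_mat <- matrix(w, n_sim, j, byrow = TRUE)
    sxy <- rowSums(w_mat * be_mat * bo_mat)
    sxx <- rowSums(w_mat * be_mat^2)
    b_loo_mat <- (sxy - w_mat * be_mat * bo_mat) / (sxx - w_mat * be_mat^2)
    w_mat * (bo_mat - b_loo_mat * be_mat)^2
  })
  rss_sim <- rowSums(sim_terms)
  global_pval <- empirical_pval(sum(rss_sim >= rss_obs), n_sim)

  outlier_raw <- vapply(seq_len(j), function(s) {
    empirical_pval(sum(sim_terms[, s] >= terms_obs[s]), n_sim)
  }, numeric(1))
  outlier_adj <- pmin(outlier_raw * j, 1)
  outlier_ids <- k$snp_id[outlier_adj < outlier_alpha]

  est_raw <- mr_ivw(h, model = "fixed")
  keep_ids <- setdiff(k$snp_id, outlier_ids)
  est_corrected <- if (length(keep_ids) >= 1) {
    suppressMessages(mr_ivw(subset_instruments(h, keep_ids), model = "fixed"))
  } else {
    NULL
  }

  distortion_coefficient <- NA_real_
  distortion_pval <- NA_real_
  if (length(outlier_ids) > 0 && !is.null(est_corrected) &&
      est_raw$estimate != 0) {
    distortion_coefficient <-
      (est_corrected$estimate - est_raw$estimate) / abs(est_raw$estimate)
    n_rem <- length(outlier_ids)
    null_shift <- with_seed(seeds[2], {
      vapply(seq_len(1000), function(i) {
        drop <- sample.int(j, n_rem)
        sxy <- sum(w[-drop] * be[-drop] * bo[-drop])
        sxx <- sum(w[-drop] * be[-drop]^2)
        (sxy / sxx - est_raw$estimate) / abs(est_raw$estimate)
      }, numeric(1))
    })
    distortion_pval <- empirical_pval(
      sum(abs(null_shift) >= abs(distortion_coefficient)), 1000)
  }

  structure(list(
    global_rss_observed = rss_obs,
    global_pval = global_pval,
    outlier_pvals = data.frame(snp_id = k$snp_id, pval_raw = outlier_raw,
                               pval_adjusted = outlier_adj,
                               stringsAsFactors = FALSE),
    outlier_ids = outlier_ids,
    estimate_raw = est_raw,
    estimate_outlier_corrected = est_corrected,
    distortion_coefficient = distortion_coefficient,
    distortion_pval = distortion_pval,
    n_sim = n_sim,
    seed = seed
  ), class = "presso_result")
}

#' @export
print.presso_result <- function(x, ...) {
  cat(sprintf("<presso_result> global RSS %.4g (p = %.3g, %d sims)\n",
              x$global_rss_observed, x$global_pval, x$n_sim))
  cat(sprintf("  outliers: %s\n",
              if (length(x$outlier_ids)) paste(x$outlier_ids, collapse = ", ")
              else "none"))
  if (!is.na(x$distortion_pval)) {
    cat(sprintf("  distortion: %.3g%% shift, p = %.3g\n",
                100 * x$distortion_coefficient, x$distortion_pval))
  }
  invisible(x)
}

#' Serialise an MR-PRESSO result to JSON
#'
#' @param x a [mr_presso()] result.
#' @param path output path; the flagged outlier ids are additionally
#'   written next to it as `<path>.outliers.txt` (one id per line) for
#'   exclusion-list consumption.
#' @return The path, invisibly.
#' @export
write_presso <- function(x, path) {
  payload <- list(
    global_rss_observed = x$global_rss_observed,
    global_pval = x$global_pval,
    outlier_pvals = x$outlier_pvals,
    outlier_ids = x$outlier_ids,
    estimate_raw = as.data.frame(x$estimate_raw),
    estimate_outlier_corrected = if (!is.null(x$estimate_outlier_corrected)) {
      as.data.frame(x$estimate_outlier_corrected)
    },
    distortion_coefficient = x$distortion_coefficient,
    distortion_pval = x$distortion_pval,
    n_sim = x$n_sim,
    seed = x$seed
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  writeLines(x$outlier_ids, paste0(path, ".outliers.txt"))
  invisible(path)
}
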
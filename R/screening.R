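# Exploratory screening pipeline: heritability filtering, correlation
# filtering, and bulk bi-directional IVW over many candidate trait pairs.
# Screening results are exploratory by construction: instruments selected on
# the same data inflate associations, so no multiplicity correction is
# applied at this stage (a Bonferroni-adjusted column is emitted alongside).

CONFIDENCE_LEVELS <- c("none", "low", "medium", "high")

as_confidence <- function(x) {
  f <- factor(as.character(x), levels = CONFIDENCE_LEVELS, ordered = TRUE)
  assert_that(!anyNA(f), paste0("confidence labels must be one of: ",
                                paste(CONFIDENCE_LEVELS, collapse = ", ")))
  f
}

#' Filter traits by heritability evidence
#'
#' Keeps traits whose LD-score-regression heritability is significant
#' (`h2_pval < p_max`, strict), whose confidence label is at least
#' `min_confidence`, and whose LD-score intercept does not exceed
#' `intercept_max` (a large intercept suggests population stratification or
#' confounding). Per-trait exclusion reasons are attached as the
#' `"exclusions"` attribute.
#'
#' @param records data.frame with columns `trait`, `h2`, `h2_pval`,
#'   `confidence` (ordered label none < low < medium < high),
#'   `ld_intercept`.
#' @param p_max heritability significance cut-off (default 0.05).
#' @param min_confidence minimum confidence label (default `"medium"`).
#' @param intercept_max maximum allowed LD intercept (default 1.1).
#' @return The kept subset of `records`, with attribute `exclusions`
#'   (data.frame `trait`, `reason`).
#' @export
filter_heritable <- function(records, p_max = 0.05, min_confidence = "medium",
                             intercept_max = 1.1) {
  conf <- as_confidence(records$confidence)
  min_conf <- as_confidence(min_confidence)
  reasons <- character(nrow(records))
  reasons[records$h2_pval >= p_max] <- "h2_pval"
  low_conf <- conf < min_conf
  reasons[low_conf] <- paste0(reasons[low_conf],
                              ifelse(nchar(reasons[low_conf]), ",", ""),
                              "confidence")
  high_int <- records$ld_intercept > intercept_max
  reasons[high_int] <- paste0(reasons[high_int],
                              ifelse(nchar(reasons[high_int]), ",", ""),
                              "intercept")
  keep <- reasons == ""
  out <- records[keep, , drop = FALSE]
  attr(out, "exclusions") <- data.frame(
    trait = records$trait[!keep], reason = reasons[!keep],
    stringsAsFactors = FALSE)
  out
}

#' Filter trait pairs by phenotypic correlation
#'
#' Keeps pairs with `|rho| > rho_min` and `-log10(pval) > neglog10p_min`
#' (both strict). A reported p-value of exactly zero is treated as
#' infinitely significant and kept (noted via a message).
#'
#' @param correlations data.frame with columns `trait_a`, `trait_b`, `rho`,
#'   `pval`.
#' @param rho_min minimum absolute correlation (default 0.10).
#' @param neglog10p_min minimum `-log10(p)` (default 12).
#' @return The kept subset, with attribute `exclusions` as in
#'   [filter_heritable()].
#' @export
filter_correlated <- function(correlations, rho_min = 0.10,
                              neglog10p_min = 12) {
  assert_that(all(abs(correlations$rho) <= 1), "|rho| must be <= 1")
  zero_p <- correlations$pval == 0
  if (any(zero_p)) {
    message("filter_correlated: ", sum(zero_p),
            " pair(s) with pval = 0 treated as -log10(p) = Inf")
  }
  neglog <- ifelse(zero_p, Inf, -log10(correlations$pval))
  reasons <- character(nrow(correlations))
  reasons[abs(correlations$rho) <= rho_min] <- "rho"
  weak_p <- neglog <= neglog10p_min
  reasons[weak_p] <- paste0(reasons[weak_p],
                            ifelse(nchar(reasons[weak_p]), ",", ""), "pval")
  keep <- reasons == ""
  out <- correlations[keep, , drop = FALSE]
  attr(out, "exclusions") <- data.frame(
    trait_a = correlations$trait_a[!keep],
    trait_b = correlations$trait_b[!keep],
    reason = reasons[!keep], stringsAsFactors = FALSE)
  out
}

#' Bulk bi-directional IVW screening over candidate trait pairs
#'
#' For every pair and each direction in turn: select instruments at
#' `p_instrument`, harmonise, and run multiplicative random-effects IVW.
#' Directions without usable instruments get status `"no_instruments"`;
#' two rows per pair are always emitted. Results are exploratory;
#' `significant` is an uncorrected flag at `alpha` and
#' `pval_bonferroni` adjusts across all emitted estimates.
#'
#' @param pairs data.frame with columns `trait_a`, `trait_b`.
#' @param datasets named list of [summary_dataset()] covering every trait.
#' @param p_instrument instrument p-value threshold (default 5e-8).
#' @param alpha screening significance level (default 0.05).
#' @return data.frame with two rows per pair: `trait_a`, `trait_b`,
#'   `direction` (`a_to_b` / `b_to_a`), `status`, `n_snps`, `estimate`,
#'   `se`, `ci_low`, `ci_high`, `pval`, `significant`, `pval_bonferroni`.
#' @export
screen_pairs <- function(pairs, datasets, p_instrument = 5e-8, alpha = 0.05) {
  missing_traits <- setdiff(unique(c(pairs$trait_a, pairs$trait_b)),
                            names(datasets))
  assert_that(length(missing_traits) == 0,
              paste0("missing dataset(s) for trait(s): ",
                     paste(missing_traits, collapse = ", ")))
  one_direction <- function(exp_name, out_name, label) {
    exposure <- datasets[[exp_name]]
    outcome <- datasets[[out_name]]
    sel <- suppressMessages(select_instruments(exposure, p_instrument))
    empty <- data.frame(direction = label, status = "no_instruments",
                        n_snps = 0L, estimate = NA_real_, se = NA_real_,
                        ci_low = NA_real_, ci_high = NA_real_,
                        pval = NA_real_, stringsAsFactors = FALSE)
    if (nrow(sel$snps) == 0 ||
        length(intersect(sel$snps$snp_id, outcome$snps$snp_id)) == 0) {
      return(empty)
    }
    hh <- harmonise(sel, outcome)
    if (nrow(kept_instruments(hh)) == 0) return(empty)
    est <- suppressMessages(mr_ivw(hh, "multiplicative"))
    data.frame(direction = label, status = "estimated", n_snps = est$n_snps,
               estimate = est$estimate, se = est$se, ci_low = est$ci_low,
               ci_high = est$ci_high, pval = est$pval,
               stringsAsFactors = FALSE)
  }
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    a <- pairs$trait_a[i]
    b <- pairs$trait_b[i]
    rbind(cbind(trait_a = a, trait_b = b, one_direction(a, b, "a_to_b")),
          cbind(trait_a = a, trait_b = b, one_direction(b, a, "b_to_a")))
  })
  out <- do.call(rbind, rows)
  out$significant <- ifelse(out$status == "estimated", out$pval < alpha, NA)
  n_tests <- sum(out$status == "estimated")
  out$pval_bonferroni <- pmin(out$pval * n_tests, 1)
  rownames(out) <- NULL
  out
}
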
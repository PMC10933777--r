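# Synthetic two-sample GWAS summary-statistics generator with known ground
# truth. The generative model is the standard instrumental-variable diagram:
# independent biallelic genotypes Z_j influence the exposure X through
# per-SNP effects gamma_j, a latent confounder U loads on both X and Y, and
# the outcome is Y = beta * X + sum_j alpha_j Z_j + kappa_y U + noise, where
# the alpha_j realise the pleiotropy regimes (none, balanced, directional,
# correlated). Two cohorts are summarised by per-SNP marginal regressions,
# optionally sharing individuals (sample overlap) or filtered by a logistic
# selection rule (collider bias).

#' Simulation configuration
#'
#' Defaults describe a well-powered two-sample study: 100 independent
#' instruments with mean strength F > 30 at 50,000 individuals per cohort,
#' a modest causal effect of 0.1 SD per SD, a latent confounder loading
#' 0.3 on both traits, and no pleiotropy, overlap or selection.
#'
#' @param n_snps number of instruments J.
#' @param n_exposure,n_outcome cohort sizes.
#' @param maf_range interval in (0, 0.5] for uniform minor-allele
#'   frequencies.
#' @param beta true causal effect of exposure on outcome.
#' @param gamma_mean,gamma_sd distribution of per-SNP instrument effects.
#' @param pleiotropy `"none"`, `"balanced"`, `"directional"` or
#'   `"correlated"`.
#' @param pleio_mean mean direct effect mu_alpha (directional regime).
#' @param pleio_sd sd sigma_alpha of direct effects (balanced, directional,
#'   and the noise term of the correlated regime).
#' @param pleio_theta slope theta of `alpha = theta * gamma + noise`
#'   (correlated regime; violates InSIDE).
#' @param pleio_prob fraction of instruments affected by pleiotropy
#'   (default 1; e.g. 0.3 makes 30% of instruments invalid).
#' @param confounder_x,confounder_y loadings of the latent confounder.
#' @param noise_sd_x,noise_sd_y residual noise scales.
#' @param overlap_fraction fraction of the smaller cohort shared between
#'   the two samples, in `[0, 1]`.
#' @param selection optional named list `(intercept, x, y, u)`: individuals
#'   are retained with probability `plogis(intercept + x*X + y*Y + u*U)`
#'   before summarisation (individual-level mode only).
#' @param reverse if TRUE the true causal arrow runs outcome -> exposure:
#'   the emitted datasets are label-swapped so an analysis of the nominal
#'   forward direction is mis-specified.
#' @param seed RNG seed (required).
#' @return Object of class `sim_config` (validated named list).
#' @export
sim_config <- function(n_snps = 100, n_exposure = 50000, n_outcome = 50000,
                       maf_range = c(0.05, 0.5), beta = 0.1,
                       gamma_mean = 0.05, gamma_sd = 0.01,
                       pleiotropy = c("none", "balanced", "directional", "correlated"),
                       pleio_mean = 0.02, pleio_sd = 0.01, pleio_theta = 0.2,
                       pleio_prob = 1,
                       confounder_x = 0.3, confounder_y = 0.3,
                       noise_sd_x = 1, noise_sd_y = 1,
                       overlap_fraction = 0, selection = NULL,
                       reverse = FALSE, seed) {
  pleiotropy <- match.arg(pleiotropy)
  assert_that(length(maf_range) == 2 && maf_range[1] > 0 &&
                maf_range[2] <= 0.5 && maf_range[1] <= maf_range[2],
              "maf_range must lie within (0, 0.5]")
  assert_that(overlap_fraction >= 0 && overlap_fraction <= 1,
              "overlap_fraction must lie in [0, 1]")
  assert_that(pleio_sd >= 0, "pleio_sd must be >= 0")
  assert_that(pleio_prob >= 0 && pleio_prob <= 1,
              "pleio_prob must lie in [0, 1]")
  assert_that(!missing(seed), "seed is required")
  structure(list(
    n_snps = n_snps, n_exposure = n_exposure, n_outcome = n_outcome,
    maf_range = maf_range, beta = beta,
    gamma_mean = gamma_mean, gamma_sd = gamma_sd,
    pleiotropy = pleiotropy, pleio_mean = pleio_mean, pleio_sd = pleio_sd,
    pleio_theta = pleio_theta, pleio_prob = pleio_prob,
    confounder_x = confounder_x, confounder_y = confounder_y,
    noise_sd_x = noise_sd_x, noise_sd_y = noise_sd_y,
    overlap_fraction = overlap_fraction, selection = selection,
    reverse = reverse, seed = as.integer(seed)
  ), class = "sim_config")
}

draw_alpha <- function(config, gamma) {
  j <- config$n_snps
  alpha <- switch(config$pleiotropy,
    none = rep(0, j),
    balanced = stats::rnorm(j, 0, config$pleio_sd),
    directional = stats::rnorm(j, config$pleio_mean, config$pleio_sd),
    correlated = config$pleio_theta * gamma +
      stats::rnorm(j, 0, config$pleio_sd)
  )
  if (config$pleio_prob < 1) {
    affected <- stats::runif(j) < config$pleio_prob
    alpha[!affected] <- 0
  }
  alpha
}

# Per-SNP simple linear regressions of y on each column of z, vectorised.
marginal_regressions <- function(z, y) {
  n <- length(y)
  zbar <- colMeans(z)
  ybar <- mean(y)
  szz <- colSums(z^2) - n * zbar^2
  szy <- as.vector(crossprod(z, y)) - n * zbar * ybar
  syy <- sum(y^2) - n * ybar^2
  beta <- szy / szz
  rss <- pmax(syy - beta * szy, 0)
  se <- sqrt(rss / ((n - 2) * szz))
  t <- beta / se
  pval <- pmax(2 * stats::pt(-abs(t), df = n - 2), .Machine$double.xmin)
  list(beta = beta, se = se, pval = pval, eaf = zbar / 2, n = n)
}

summary_from_marginals <- function(m, snp_ids, trait_name) {
  summary_dataset(data.frame(
    snp_id = snp_ids, effect_allele = "A", other_allele = "G",
    eaf = m$eaf, beta = m$beta, se = m$se, pval = m$pval, n = m$n,
    stringsAsFactors = FALSE
  ), trait_name = trait_name)
}

#' Simulate a two-sample GWAS summary study with known truth
#'
#' In `"individual"` mode two cohorts of genotypes and phenotypes are drawn
#' from the generative model and summarised by per-SNP marginal
#' regressions, so sample overlap, selection bias and winner's curse arise
#' exactly as they do in real data. `"direct"` mode draws the per-SNP
#' summary estimates straight from their asymptotic sampling distributions
#' (the same first two moments), which is orders of magnitude faster and is
#' intended for calibration loops; it does not support selection rules.
#'
#' @param config a [sim_config()].
#' @param mode `"individual"` or `"direct"`.
#' @param exposure_name,outcome_name trait labels.
#' @return Object of class `simulated_study`: list with `exposure` and
#'   `outcome` ([summary_dataset()]s, label-swapped when
#'   `config$reverse`), `truth` (list `beta`, `gamma`, `alpha`,
#'   `r2_instruments`, `direction`), `config`, `seed`.
#' @export
simulate_two_sample <- function(config, mode = c("individual", "direct"),
                                exposure_name = "exposure",
                                outcome_name = "outcome") {
  mode <- match.arg(mode)
  assert_that(inherits(config, "sim_config"), "config must be a sim_config")
  if (mode == "individual" &&
      min(config$n_exposure, config$n_outcome) < 10 * config$n_snps) {
    warning("cohort size below 10 * n_snps: weak-summary regime")
  }
  if (mode == "direct") {
    assert_that(is.null(config$selection),
                "selection rules require mode = 'individual'")
  }
  with_seed(config$seed, {
    j <- config$n_snps
    maf <- stats::runif(j, config$maf_range[1], config$maf_range[2])
    gamma <- stats::rnorm(j, config$gamma_mean, config$gamma_sd)
    alpha <- draw_alpha(config, gamma)
    snp_ids <- sprintf("rs%05d", seq_len(j))
    if (mode == "individual") {
      sim <- simulate_individual(config, maf, gamma, alpha)
    } else {
      sim <- simulate_direct(config, maf, gamma, alpha)
    }
    v_z <- 2 * maf * (1 - maf)
    var_x <- sum(gamma^2 * v_z) + config$confounder_x^2 + config$noise_sd_x^2
    truth <- list(beta = config$beta, gamma = gamma, alpha = alpha,
                  r2_instruments = gamma^2 * v_z / var_x,
                  direction = if (config$reverse) "reverse" else "forward")
    exp_ds <- summary_from_marginals(sim$exposure, snp_ids, exposure_name)
    out_ds <- summary_from_marginals(sim$outcome, snp_ids, outcome_name)
    if (config$reverse) {
      # The nominal exposure dataset now measures the causal downstream
      # trait: an analysis of the forward direction is mis-specified.
      tmp <- exp_ds; exp_ds <- out_ds; out_ds <- tmp
      exp_ds$trait_name <- exposure_name
      out_ds$trait_name <- outcome_name
    }
    structure(list(exposure = exp_ds, outcome = out_ds, truth = truth,
                   config = config, seed = config$seed),
              class = "simulated_study")
  })
}

simulate_individual <- function(config, maf, gamma, alpha) {
  ne <- config$n_exposure
  no <- config$n_outcome
  j <- config$n_snps
  n_shared <- floor(config$overlap_fraction * min(ne, no))
  n_total <- ne + no - n_shared

  z <- matrix(stats::rbinom(n_total * j, 2, rep(maf, each = n_total)),
              n_total, j)
  u <- stats::rnorm(n_total)
  x <- as.vector(z %*% gamma) + config$confounder_x * u +
    stats::rnorm(n_total, 0, config$noise_sd_x)
  y <- config$beta * x + as.vector(z %*% alpha) + config$confounder_y * u +
    stats::rnorm(n_total, 0, config$noise_sd_y)

  idx_e <- seq_len(ne)
  idx_o <- (ne - n_shared + 1):n_total

  if (!is.null(config$selection)) {
    s <- config$selection
    p_keep <- stats::plogis((s$intercept %||% 0) + (s$x %||% 0) * x +
                              (s$y %||% 0) * y + (s$u %||% 0) * u)
    keep <- stats::runif(n_total) < p_keep
    idx_e <- idx_e[keep[idx_e]]
    idx_o <- idx_o[keep[idx_o]]
    assert_that(length(idx_e) >= 0.1 * ne && length(idx_o) >= 0.1 * no,
                "selection removed more than 90% of a cohort")
  }

  list(exposure = marginal_regressions(z[idx_e, , drop = FALSE], x[idx_e]),
       outcome = marginal_regressions(z[idx_o, , drop = FALSE], y[idx_o]))
}

simulate_direct <- function(config, maf, gamma, alpha) {
  j <- config$n_snps
  ne <- config$n_exposure
  no <- config$n_outcome
  v_z <- 2 * maf * (1 - maf)
  kx <- config$confounder_x
  ky <- config$confounder_y
  b <- config$beta

  var_x <- sum(gamma^2 * v_z) + kx^2 + config$noise_sd_x^2
  b_out <- b * gamma + alpha
  var_y <- b^2 * var_x + sum(alpha^2 * v_z) + 2 * b * sum(gamma * alpha * v_z) +
    ky^2 + config$noise_sd_y^2 + 2 * b * kx * ky
  cov_xy <- b * var_x + sum(gamma * alpha * v_z) + kx * ky

  se_e <- sqrt(pmax(var_x - gamma^2 * v_z, 1e-12) / (ne * v_z))
  se_o <- sqrt(pmax(var_y - b_out^2 * v_z, 1e-12) / (no * v_z))

  # Estimation errors of the two marginal slopes are correlated only
  # through shared individuals.
  n_shared <- floor(config$overlap_fraction * min(ne, no))
  rho <- if (n_shared > 0) {
    resid_cov <- cov_xy - gamma * b_out * v_z
    (n_shared / sqrt(ne * no)) * resid_cov /
      sqrt(pmax(var_x - gamma^2 * v_z, 1e-12) *
             pmax(var_y - b_out^2 * v_z, 1e-12))
  } else {
    rep(0, j)
  }

  e1 <- stats::rnorm(j)
  e2 <- rho * e1 + sqrt(pmax(1 - rho^2, 0)) * stats::rnorm(j)
  beta_e <- gamma + se_e * e1
  beta_o <- b_out + se_o * e2

  mk <- function(beta, se, n) {
    list(beta = beta, se = se, pval = norm_pval(beta, se), eaf = maf, n = n)
  }
  list(exposure = mk(beta_e, se_e, ne), outcome = mk(beta_o, se_o, no))
}

#' @export
print.simulated_study <- function(x, ...) {
  cat(sprintf("<simulated_study> %d SNPs | beta = %.3g | pleiotropy %s | direction %s\n",
              x$config$n_snps, x$truth$beta, x$config$pleiotropy,
              x$truth$direction))
  invisible(x)
}

#' Write a simulated study as summary-statistic TSVs plus a truth side-car
#'
#' Emits `<prefix>_exposure.tsv` and `<prefix>_outcome.tsv` in the same
#' delimited format [read_summary_table()] consumes (round-trip guarantee),
#' and `<prefix>_truth.json` with the generating parameters.
#'
#' @param study a [simulate_two_sample()] result.
#' @param prefix output path prefix.
#' @return Named character vector of the three paths, invisibly.
#' @export
write_simulated_study <- function(study, prefix) {
  paths <- c(exposure = paste0(prefix, "_exposure.tsv"),
             outcome = paste0(prefix, "_outcome.tsv"),
             truth = paste0(prefix, "_truth.json"))
  write_tsv_diffable(study$exposure$snps, paths[["exposure"]])
  write_tsv_diffable(study$outcome$snps, paths[["outcome"]])
  jsonlite::write_json(study$truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}

#' Synthetic fixtures for the screening pipeline
#'
#' Builds the three inputs the screening stage consumes: a heritability
#' table, a phenotype-correlation table and a named collection of summary
#' datasets over a shared SNP panel, with a known subset of trait pairs
#' wired with true causal effects. Every numeric screening filter is given
#' both passing and failing exemplars: one trait fails the heritability
#' p-value cut, one the confidence label, one the LD-intercept bound, and
#' non-causal pairs receive correlations failing either the magnitude or
#' the significance threshold.
#'
#' @param n_traits number of traits (>= 6 so the failing exemplars and at
#'   least one causal pair fit).
#' @param n_causal_pairs number of wired causal pairs (directed, disjoint).
#' @param n_snps_per_trait instruments per trait block.
#' @param n GWAS sample size per trait.
#' @param causal_beta true causal effect for wired pairs.
#' @param seed RNG seed (required).
#' @return List with `heritability` (data.frame), `correlations`
#'   (data.frame), `studies` (named list of [summary_dataset()]) and
#'   `truth` (data.frame `exposure`, `outcome`, `beta`).
#' @export
simulate_screen_fixture <- function(n_traits = 10, n_causal_pairs = 2,
                                    n_snps_per_trait = 15, n = 50000,
                                    causal_beta = 0.2, seed) {
  assert_that(n_traits >= 6, "need at least 6 traits")
  assert_that(2 * n_causal_pairs <= n_traits - 3,
              "too many causal pairs for the trait count")
  with_seed(seed, {
    traits <- sprintf("trait%02d", seq_len(n_traits))
    j_total <- n_traits * n_snps_per_trait
    snp_ids <- sprintf("rs%05d", seq_len(j_total))
    maf <- stats::runif(j_total, 0.1, 0.5)
    v_z <- 2 * maf * (1 - maf)
    block <- rep(seq_len(n_traits), each = n_snps_per_trait)

    # Instrument effects: each trait has its own block of strong SNPs.
    gamma <- matrix(0, j_total, n_traits)
    for (t in seq_len(n_traits)) {
      gamma[block == t, t] <- stats::rnorm(n_snps_per_trait, 0.05, 0.01)
    }
    truth <- data.frame(
      exposure = traits[seq(1, by = 2, length.out = n_causal_pairs)],
      outcome = traits[seq(2, by = 2, length.out = n_causal_pairs)],
      beta = causal_beta, stringsAsFactors = FALSE
    )
    # Wire causal effects: the outcome trait inherits the exposure trait's
    # instrument effects scaled by the causal coefficient.
    effects <- gamma
    for (p in seq_len(nrow(truth))) {
      e_idx <- match(truth$exposure[p], traits)
      o_idx <- match(truth$outcome[p], traits)
      effects[, o_idx] <- effects[, o_idx] + causal_beta * gamma[, e_idx]
    }

    se <- sqrt(1 / (n * v_z))
    studies <- stats::setNames(lapply(seq_len(n_traits), function(t) {
      beta_hat <- effects[, t] + stats::rnorm(j_total, 0, se)
      summary_dataset(data.frame(
        snp_id = snp_ids, effect_allele = "A", other_allele = "G",
        eaf = maf, beta = beta_hat, se = se,
        pval = norm_pval(beta_hat, se), n = n, stringsAsFactors = FALSE
      ), trait_name = traits[t])
    }), traits)

    conf_levels <- c("none", "low", "medium", "high")
    heritability <- data.frame(
      trait = traits,
      h2 = stats::runif(n_traits, 0.05, 0.40),
      h2_pval = stats::runif(n_traits, 1e-12, 1e-4),
      confidence = sample(c("medium", "high"), n_traits, replace = TRUE),
      ld_intercept = stats::rnorm(n_traits, 1.0, 0.02),
      stringsAsFactors = FALSE
    )
    # Deterministic failing exemplars on the last three (never causal) traits.
    heritability$h2_pval[n_traits] <- 0.5
    heritability$confidence[n_traits - 1] <- "low"
    heritability$ld_intercept[n_traits - 2] <- 1.3
    heritability$confidence <- factor(heritability$confidence,
                                      levels = conf_levels, ordered = TRUE)

    pairs <- t(utils::combn(traits, 2))
    rho <- stats::rnorm(nrow(pairs), 0, 0.02)
    pval <- stats::runif(nrow(pairs), 1e-6, 1)
    for (p in seq_len(nrow(truth))) {
      hit <- (pairs[, 1] == truth$exposure[p] & pairs[, 2] == truth$outcome[p]) |
        (pairs[, 2] == truth$exposure[p] & pairs[, 1] == truth$outcome[p])
      rho[hit] <- causal_beta
      pval[hit] <- 1e-20
    }
    # Failing exemplars for each correlation filter: strong but
    # non-significant, and significant but weak.
    ok <- !(pairs[, 1] %in% truth$exposure & pairs[, 2] %in% truth$outcome)
    weak_idx <- which(ok)[1:2]
    rho[weak_idx[1]] <- 0.3; pval[weak_idx[1]] <- 1e-3
    rho[weak_idx[2]] <- 0.01; pval[weak_idx[2]] <- 1e-20
    correlations <- data.frame(trait_a = pairs[, 1], trait_b = pairs[, 2],
                               rho = rho, pval = pval, n = n,
                               stringsAsFactors = FALSE)
    list(heritability = heritability, correlations = correlations,
         studies = studies, truth = truth)
  })
}
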
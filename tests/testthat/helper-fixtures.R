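# Fixtures built in code: small summary datasets and harmonised pairs.

make_summary <- function(beta, se, trait = "trait", pval = NULL, n = 50000,
                         eaf = NULL, snp_id = NULL,
                         effect_allele = "A", other_allele = "G") {
  j <- length(beta)
  summary_dataset(data.frame(
    snp_id = snp_id %||% sprintf("rs%03d", seq_len(j)),
    effect_allele = effect_allele, other_allele = other_allele,
    eaf = eaf %||% rep(0.3, j),
    beta = beta, se = se,
    pval = pval %||% pmax(2 * pnorm(-abs(beta / se)), .Machine$double.xmin),
    n = n,
    stringsAsFactors = FALSE
  ), trait_name = trait)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Harmonised pair from raw association vectors (identical allele labels on
# both sides, so every row is kept).
make_harmonised <- function(beta_exposure, se_exposure, beta_outcome,
                            se_outcome, n_exposure = 50000,
                            n_outcome = 50000) {
  e <- make_summary(beta_exposure, se_exposure, "exposure", n = n_exposure)
  o <- make_summary(beta_outcome, se_outcome, "outcome", n = n_outcome)
  harmonise(e, o)
}

# A well-behaved harmonised pair with a known causal slope and no
# pleiotropy, for generic estimator checks.
make_clean_pair <- function(j = 20, slope = 0.1, seed = 101, noise = 0) {
  withr::with_seed(seed, {
    be <- rnorm(j, 0.05, 0.01)
    se_e <- rep(0.005, j)
    se_o <- rep(0.008, j)
    bo <- slope * be + rnorm(j, 0, noise)
    make_harmonised(be, se_e, bo, se_o)
  })
}
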
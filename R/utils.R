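# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}

# Two-sided normal p-value from an estimate and its SE, clamped away from
# exact zero so downstream (0, 1] validation holds for extreme z.
norm_pval <- function(estimate, se) {
  pmax(2 * stats::pnorm(-abs(estimate / se)), .Machine$double.xmin)
}

# 95% normal confidence bounds.
norm_ci <- function(estimate, se, level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  c(estimate - z * se, estimate + z * se)
}

# Empirical p-value with the plus-one correction: never exactly zero.
empirical_pval <- function(n_as_extreme, n_sim) {
  (n_as_extreme + 1) / (n_sim + 1)
}

# Derive a vector of child seeds (< 2^31) from a master seed, reproducibly.
derive_seeds <- function(seed, n) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}

# Run an expression under a fixed seed without disturbing the caller's RNG.
with_seed <- function(seed, expr) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(seed)
  expr
}

# Write a data.frame as TSV with a fixed column order and 10-significant-digit
# numeric formatting, so reruns diff cleanly.
write_tsv_diffable <- function(df, path) {
  out <- df
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(x) formatC(x, digits = 10, format = "g"))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
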
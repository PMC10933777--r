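#' Construct a GWAS summary dataset
#'
#' A summary dataset holds one trait's per-SNP marginal association estimates:
#' for each variant, the effect and other allele, the per-allele effect `beta`
#' (trait SD or log-odds per effect-allele copy), its standard error, the
#' association p-value, the effect-allele frequency and the sample size.
#'
#' @param snps data.frame with columns `snp_id`, `effect_allele`,
#'   `other_allele`, `beta`, `se`, and optionally `eaf`, `pval`, `n`.
#'   Missing `pval` is backfilled from `beta`/`se` via a two-sided normal
#'   test; missing `eaf`/`n` become `NA`.
#' @param trait_name trait label.
#' @param trait_type `"continuous"` or `"binary"`.
#'
#' @return An object of class `summary_dataset`: a list with elements
#'   `trait_name`, `trait_type` and `snps` (validated data.frame).
#' @export
summary_dataset <- function(snps, trait_name, trait_type = c("continuous", "binary")) {
  trait_type <- match.arg(trait_type)
  required <- c("snp_id", "effect_allele", "other_allele", "beta", "se")
  missing_cols <- setdiff(required, names(snps))
  assert_that(length(missing_cols) == 0,
              paste0("summary dataset is missing columns: ",
                     paste(missing_cols, collapse = ", ")))
  snps <- as.data.frame(snps, stringsAsFactors = FALSE)
  for (col in c("eaf", "pval", "n")) if (!col %in% names(snps)) snps[[col]] <- NA_real_
  snps$snp_id <- as.character(snps$snp_id)
  snps$effect_allele <- toupper(as.character(snps$effect_allele))
  snps$other_allele <- toupper(as.character(snps$other_allele))

  dup <- snps$snp_id[duplicated(snps$snp_id)]
  assert_that(length(dup) == 0,
              paste0("duplicate snp_id in '", trait_name, "': ",
                     paste(unique(dup), collapse = ", ")))
  assert_that(all(is.finite(snps$beta)), "non-finite beta values")
  assert_that(all(is.finite(snps$se) & snps$se > 0), "se must be finite and > 0")
  assert_that(all(snps$effect_allele != snps$other_allele),
              "effect_allele must differ from other_allele")

  backfill <- is.na(snps$pval)
  snps$pval[backfill] <- norm_pval(snps$beta[backfill], snps$se[backfill])
  assert_that(all(snps$pval > 0 & snps$pval <= 1), "pval must lie in (0, 1]")
  ok_eaf <- is.na(snps$eaf) | (snps$eaf > 0 & snps$eaf < 1)
  assert_that(all(ok_eaf), "eaf must lie in (0, 1) when present")

  snps <- snps[, c("snp_id", "effect_allele", "other_allele", "eaf",
                   "beta", "se", "pval", "n")]
  structure(list(trait_name = trait_name, trait_type = trait_type, snps = snps),
            class = "summary_dataset")
}

#' @export
print.summary_dataset <- function(x, ...) {
  cat(sprintf("<summary_dataset> %s (%s): %d SNPs\n",
              x$trait_name, x$trait_type, nrow(x$snps)))
  invisible(x)
}

#' Number of SNP records in a summary dataset
#' @param ds a [summary_dataset()].
#' @return integer count.
#' @export
n_snps <- function(ds) nrow(ds$snps)

#' Read a delimited GWAS summary-statistics table
#'
#' Reads a tab- or comma-delimited text file with a header row and maps its
#' columns onto the standard summary-dataset fields. The delimiter is
#' auto-detected from the header line (tab preferred, comma otherwise).
#'
#' @param path file path.
#' @param column_map named character vector mapping standard field names to
#'   file column names. Must name at least `snp`, `effect_allele`,
#'   `other_allele`, `beta`, `se`; `eaf`, `pval` and `n` are optional.
#' @param trait_name trait label for the resulting dataset.
#' @param trait_type `"continuous"` or `"binary"`.
#'
#' @return A [summary_dataset()]. Rows with missing `beta` or `se` are
#'   rejected and their count reported via a message; missing p-values are
#'   backfilled with a two-sided normal test on `beta/se`.
#' @export
read_summary_table <- function(path, column_map, trait_name,
                               trait_type = "continuous") {
  allowed <- c("snp", "effect_allele", "other_allele", "beta", "se",
               "eaf", "pval", "n")
  unknown <- setdiff(names(column_map), allowed)
  assert_that(length(unknown) == 0,
              paste0("unknown column_map entries: ", paste(unknown, collapse = ", "),
                     " (allowed: ", paste(allowed, collapse = ", "), ")"))
  required <- c("snp", "effect_allele", "other_allele", "beta", "se")
  missing_map <- setdiff(required, names(column_map))
  assert_that(length(missing_map) == 0,
              paste0("column_map must name: ", paste(missing_map, collapse = ", ")))

  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  absent <- setdiff(unname(column_map), names(raw))
  assert_that(length(absent) == 0,
              paste0("columns not found in ", path, ": ",
                     paste(absent, collapse = ", ")))

  snps <- data.frame(
    snp_id = as.character(raw[[column_map[["snp"]]]]),
    effect_allele = raw[[column_map[["effect_allele"]]]],
    other_allele = raw[[column_map[["other_allele"]]]],
    beta = as.numeric(raw[[column_map[["beta"]]]]),
    se = as.numeric(raw[[column_map[["se"]]]]),
    stringsAsFactors = FALSE
  )
  for (opt in c("eaf", "pval", "n")) {
    snps[[opt]] <- if (opt %in% names(column_map)) {
      as.numeric(raw[[column_map[[opt]]]])
    } else NA_real_
  }

  bad <- !is.finite(snps$beta) | !is.finite(snps$se)
  if (any(bad)) {
    message(sum(bad), " row(s) with missing beta or se rejected from '",
            trait_name, "'")
    snps <- snps[!bad, , drop = FALSE]
  }
  summary_dataset(snps, trait_name = trait_name, trait_type = trait_type)
}

COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

complement_allele <- function(a) {
  out <- unname(COMPLEMENT[a])
  ifelse(is.na(out), a, out)
}

is_palindromic <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' Harmonise exposure and outcome summary statistics
#'
#' Aligns the outcome dataset's effect alleles to the exposure dataset's so
#' that every kept (exposure, outcome) association pair refers to the same
#' effect allele. Swapped allele labels flip the outcome beta's sign and
#' complement its allele frequency; strand-complementary labels are
#' complemented before applying the same logic. Palindromic variants (A/T or
#' C/G), whose strand cannot be inferred from the labels, are resolved by
#' allele-frequency agreement and dropped when either frequency is missing
#' or too close to 0.5 to be informative.
#'
#' @param exposure,outcome [summary_dataset()] objects.
#' @param palindromic_eaf_window half-width of the frequency window around
#'   0.5 inside which palindromic SNPs are dropped (default 0.08, i.e. drop
#'   when the minor-allele frequency exceeds 0.42).
#'
#' @return An object of class `harmonised_instruments`: list with
#'   `exposure_name`, `outcome_name`, `n_exposure`, `n_outcome`,
#'   `trait_type_outcome` and `data`, a data.frame over the union of SNP ids
#'   with columns `snp_id`, `beta_exposure`, `se_exposure`, `pval_exposure`,
#'   `beta_outcome`, `se_outcome`, `pval_outcome`, `eaf`, `flag`. Flags are
#'   `kept`, `flipped`, `dropped_palindromic` or `dropped_unmatched`;
#'   dropped rows carry `NA` associations so they can never reach an
#'   estimator.
#' @export
harmonise <- function(exposure, outcome, palindromic_eaf_window = 0.08) {
  assert_that(inherits(exposure, "summary_dataset") &&
                inherits(outcome, "summary_dataset"),
              "exposure and outcome must be summary_dataset objects")
  e <- exposure$snps
  o <- outcome$snps
  shared <- intersect(e$snp_id, o$snp_id)
  assert_that(length(shared) > 0, "no shared instruments")

  all_ids <- union(e$snp_id, o$snp_id)
  ei <- match(all_ids, e$snp_id)
  oi <- match(all_ids, o$snp_id)

  n <- length(all_ids)
  flag <- rep("dropped_unmatched", n)
  beta_o <- se_o <- pval_o <- eaf <- rep(NA_real_, n)
  beta_e <- e$beta[ei]
  se_e <- e$se[ei]
  pval_e <- e$pval[ei]

  for (k in seq_len(n)) {
    if (is.na(ei[k]) || is.na(oi[k])) next
    ea_e <- e$effect_allele[ei[k]]; oa_e <- e$other_allele[ei[k]]
    ea_o <- o$effect_allele[oi[k]]; oa_o <- o$other_allele[oi[k]]
    eaf_e <- e$eaf[ei[k]]; eaf_o <- o$eaf[oi[k]]
    b_o <- o$beta[oi[k]]; s_o <- o$se[oi[k]]; p_o <- o$pval[oi[k]]

    if (is_palindromic(ea_e, oa_e)) {
      # Strand is ambiguous: use frequency agreement, drop near 0.5.
      alleles_match <- setequal(c(ea_e, oa_e), c(ea_o, oa_o))
      if (!alleles_match) next
      near_half <- function(f) is.na(f) || abs(f - 0.5) < palindromic_eaf_window
      if (near_half(eaf_e) || near_half(eaf_o)) {
        flag[k] <- "dropped_palindromic"
        next
      }
      if ((eaf_e < 0.5) == (eaf_o < 0.5)) {
        flag[k] <- "kept"
        beta_o[k] <- b_o; se_o[k] <- s_o; pval_o[k] <- p_o; eaf[k] <- eaf_e
      } else {
        flag[k] <- "flipped"
        beta_o[k] <- -b_o; se_o[k] <- s_o; pval_o[k] <- p_o; eaf[k] <- eaf_e
      }
      next
    }

    aligned <- NULL
    if (ea_o == ea_e && oa_o == oa_e) {
      aligned <- "kept"
    } else if (ea_o == oa_e && oa_o == ea_e) {
      aligned <- "flipped"
    } else {
      ea_c <- complement_allele(ea_o); oa_c <- complement_allele(oa_o)
      if (ea_c == ea_e && oa_c == oa_e) aligned <- "kept"
      else if (ea_c == oa_e && oa_c == ea_e) aligned <- "flipped"
    }
    if (is.null(aligned)) next
    flag[k] <- aligned
    if (aligned == "kept") {
      beta_o[k] <- b_o; se_o[k] <- s_o; pval_o[k] <- p_o
      eaf[k] <- if (!is.na(eaf_e)) eaf_e else eaf_o
    } else {
      beta_o[k] <- -b_o; se_o[k] <- s_o; pval_o[k] <- p_o
      eaf[k] <- if (!is.na(eaf_e)) eaf_e else if (!is.na(eaf_o)) 1 - eaf_o else NA_real_
    }
  }

  drop_assoc <- !(flag %in% c("kept", "flipped"))
  beta_e[drop_assoc] <- NA_real_
  se_e[drop_assoc] <- NA_real_
  pval_e[drop_assoc] <- NA_real_

  data <- data.frame(
    snp_id = all_ids,
    beta_exposure = beta_e, se_exposure = se_e, pval_exposure = pval_e,
    beta_outcome = beta_o, se_outcome = se_o, pval_outcome = pval_o,
    eaf = eaf, flag = flag,
    stringsAsFactors = FALSE
  )
  structure(list(
    exposure_name = exposure$trait_name,
    outcome_name = outcome$trait_name,
    n_exposure = stats::median(e$n, na.rm = TRUE),
    n_outcome = stats::median(o$n, na.rm = TRUE),
    trait_type_outcome = outcome$trait_type,
    data = data
  ), class = "harmonised_instruments")
}

#' @export
print.harmonised_instruments <- function(x, ...) {
  tab <- table(factor(x$data$flag,
                      levels = c("kept", "flipped", "dropped_palindromic",
                                 "dropped_unmatched")))
  cat(sprintf("<harmonised_instruments> %s -> %s\n",
              x$exposure_name, x$outcome_name))
  cat(sprintf("  kept %d | flipped %d | dropped_palindromic %d | dropped_unmatched %d\n",
              tab[["kept"]], tab[["flipped"]], tab[["dropped_palindromic"]],
              tab[["dropped_unmatched"]]))
  invisible(x)
}

#' Kept instrument rows of a harmonised pair
#'
#' @param h a [harmonise()] result.
#' @return data.frame of rows flagged `kept` or `flipped` (allele-aligned).
#' @export
kept_instruments <- function(h) {
  assert_that(inherits(h, "harmonised_instruments"),
              "h must be a harmonised_instruments object")
  h$data[h$data$flag %in% c("kept", "flipped"), , drop = FALSE]
}

# Subset a harmonised object to the given kept snp_ids (used by
# leave-one-out, Steiger filtering and outlier removal).
subset_instruments <- function(h, keep_ids) {
  h$data <- h$data[h$data$snp_id %in% keep_ids &
                     h$data$flag %in% c("kept", "flipped"), , drop = FALSE]
  h
}

#' Greedy LD pruning of a summary dataset
#'
#' Scans SNPs in ascending p-value order (ties broken by `snp_id`) and keeps
#' a SNP only if its squared LD correlation with every already-kept SNP is
#' at or below `r2_threshold`. Without an LD matrix all SNPs are retained and
#' independence is assumed (a message notes this), matching the common case
#' of pre-clumped summary sources.
#'
#' @param dataset a [summary_dataset()].
#' @param ld optional symmetric SNP-by-SNP r-squared matrix with unit
#'   diagonal and dimnames covering all SNP ids.
#' @param r2_threshold maximum pairwise r-squared among kept SNPs
#'   (default 0.001).
#' @return The pruned [summary_dataset()] (original row order preserved).
#' @export
ld_prune <- function(dataset, ld = NULL, r2_threshold = 0.001) {
  assert_that(inherits(dataset, "summary_dataset"), "dataset must be a summary_dataset")
  if (is.null(ld)) {
    message("ld_prune: no LD matrix supplied; assuming independent SNPs (no-op)")
    return(dataset)
  }
  ids <- dataset$snps$snp_id
  missing_ids <- setdiff(ids, rownames(ld))
  assert_that(length(missing_ids) == 0,
              paste0("LD matrix missing snp_id(s): ",
                     paste(missing_ids, collapse = ", ")))
  assert_that(isTRUE(all.equal(ld[ids, ids], t(ld[ids, ids]))),
              "LD matrix must be symmetric")
  assert_that(all(abs(diag(ld[ids, ids]) - 1) < 1e-8),
              "LD matrix must have unit diagonal")

  ord <- order(dataset$snps$pval, dataset$snps$snp_id)
  kept <- character(0)
  for (i in ord) {
    id <- ids[i]
    if (length(kept) == 0 || all(ld[id, kept] <= r2_threshold)) {
      kept <- c(kept, id)
    }
  }
  dataset$snps <- dataset$snps[dataset$snps$snp_id %in% kept, , drop = FALSE]
  dataset
}

#' Select genome-wide significant instruments
#'
#' @param dataset a [summary_dataset()].
#' @param p_threshold instrument p-value cut-off (default 5e-8; common
#'   alternatives are the liberal 1e-6 and conservative 1e-12).
#' @return The subset [summary_dataset()] with `pval < p_threshold`,
#'   original order preserved. An empty selection is allowed (message).
#' @export
select_instruments <- function(dataset, p_threshold = 5e-8) {
  assert_that(inherits(dataset, "summary_dataset"), "dataset must be a summary_dataset")
  assert_that(all(!is.na(dataset$snps$pval)), "pval required for all records")
  keep <- dataset$snps$pval < p_threshold
  if (!any(keep)) {
    message("select_instruments: no SNPs pass p < ", format(p_threshold),
            " for '", dataset$trait_name, "'")
  }
  dataset$snps <- dataset$snps[keep, , drop = FALSE]
  dataset
}

#' Instrument strength metrics (R-squared and F-statistic)
#'
#' Per SNP, with `t = beta/se`: the variance explained is
#' `r2 = t^2 / (t^2 + n - 2)` and the strength statistic
#' `F = (n - 2) * r2 / (1 - r2)`, which reduces algebraically to `t^2`.
#' A mean F above 10 is the conventional guard against weak-instrument bias.
#' The test-statistic form is the default because it is robust to missing
#' allele frequencies and unit conventions; `method = "eaf"` instead uses
#' `r2 = 2 * eaf * (1 - eaf) * beta^2` (standardised-trait approximation)
#' and is flagged in the output.
#'
#' @param dataset a [summary_dataset()].
#' @param n sample size to use for all records when the per-record `n`
#'   column is missing.
#' @param method `"tstat"` (default) or `"eaf"`.
#' @return An object of class `instrument_strength`: list with `per_snp`
#'   (data.frame `snp_id`, `r2`, `f_stat`), `mean_f`, `total_r2`, `method`.
#' @export
instrument_strength <- function(dataset, n = NULL, method = c("tstat", "eaf")) {
  method <- match.arg(method)
  assert_that(inherits(dataset, "summary_dataset"), "dataset must be a summary_dataset")
  snps <- dataset$snps
  nn <- if (!is.null(n)) rep(n, nrow(snps)) else snps$n
  assert_that(all(!is.na(nn)), "sample size n required (per record or via n =)")
  assert_that(all(nn > 2), "sample size must exceed 2")

  if (method == "tstat") {
    t2 <- (snps$beta / snps$se)^2
    r2 <- t2 / (t2 + nn - 2)
  } else {
    assert_that(all(!is.na(snps$eaf)), "eaf required for method = 'eaf'")
    r2 <- 2 * snps$eaf * (1 - snps$eaf) * snps$beta^2
    r2 <- pmin(r2, 1 - 1e-12)
  }
  f_stat <- (nn - 2) * r2 / (1 - r2)
  structure(list(
    per_snp = data.frame(snp_id = snps$snp_id, r2 = r2, f_stat = f_stat,
                         stringsAsFactors = FALSE),
    mean_f = mean(f_stat),
    total_r2 = sum(r2),
    method = method
  ), class = "instrument_strength")
}

#' @export
print.instrument_strength <- function(x, ...) {
  cat(sprintf("<instrument_strength> %d SNPs | mean F = %.2f | total R2 = %.4f (%s)\n",
              nrow(x$per_snp), x$mean_f, x$total_r2, x$method))
  invisible(x)
}

#' Write harmonised instrument pairs to TSV
#'
#' @param h a [harmonise()] result.
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_harmonised <- function(h, path) {
  df <- cbind(exposure = h$exposure_name, outcome = h$outcome_name, h$data)
  write_tsv_diffable(df, path)
}
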
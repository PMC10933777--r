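# Workflow front end: YAML-configured runs tying the modules into the
# standard analysis stages (data preparation, MR analysis, sensitivity
# analysis), plus simulate / screen / bayes-net / presso entry points.
# Every random operation receives a config-derived seed and all thresholds
# and seeds actually used are written to the run log.

#' Read a run configuration from YAML
#'
#' @param path YAML file. Keys mirror the arguments of [mr_run()] and
#'   friends; unknown keys are preserved.
#' @return Named list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  structure(cfg, class = c("run_config", class(cfg)))
}

#' Write a run configuration to YAML (lossless round trip)
#' @param config a list / `run_config`.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

default_column_map <- function(map = NULL) {
  base <- c(snp = "snp_id", effect_allele = "effect_allele",
            other_allele = "other_allele", beta = "beta", se = "se",
            eaf = "eaf", pval = "pval", n = "n")
  if (!is.null(map)) base[names(map)] <- unlist(map)
  base
}

run_log <- function(dir, lines) {
  path <- file.path(dir, "run_log.txt")
  con <- file(path, "a")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Run a full MR analysis for one exposure-outcome pair
#'
#' Executes instrument selection, harmonisation, the estimator battery and
#' the sensitivity workflow from a configuration list, writing tidy TSV
#' results, a sensitivity JSON, plot-data tables (scatter, funnel, forest /
#' leave-one-out, single-SNP) and a run log into `output_dir`.
#'
#' Config keys: `exposure` and `outcome` (each a list with `path`,
#' optional `column_map`, `trait_name`, `trait_type`), `p_threshold`
#' (default 5e-8), `thresholds` (optional scan grid), `bidirectional`
#' (logical), `seed`, `n_boot`, `output_dir` (overridden by the argument).
#'
#' @param config a `run_config` list or path to a YAML file.
#' @param output_dir output directory (created if needed).
#' @return Invisibly, a list with the harmonised pair, the tidy results
#'   table and the paths written.
#' @export
mr_run <- function(config, output_dir = config$output_dir) {
  if (is.character(config)) config <- read_run_config(config)
  assert_that(!is.null(output_dir), "output_dir is required")
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed %||% 1L)
  p_threshold <- config$p_threshold %||% 5e-8
  n_boot <- config$n_boot %||% 1000

  load_ds <- function(spec) {
    read_summary_table(spec$path, default_column_map(spec$column_map),
                       trait_name = spec$trait_name %||% "trait",
                       trait_type = spec$trait_type %||% "continuous")
  }
  exposure <- load_ds(config$exposure)
  outcome <- load_ds(config$outcome)

  sel <- suppressMessages(select_instruments(exposure, p_threshold))
  paths <- character(0)
  log_lines <- c(
    paste0("mrpipe ", as.character(utils::packageVersion("mrpipe"))),
    paste0("time: ", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
    paste0("exposure: ", exposure$trait_name, " (", n_snps(exposure), " SNPs)"),
    paste0("outcome: ", outcome$trait_name, " (", n_snps(outcome), " SNPs)"),
    paste0("p_threshold: ", format(p_threshold)),
    paste0("seed: ", seed),
    paste0("n_boot: ", n_boot),
    paste0("instruments_selected: ", n_snps(sel))
  )

  results <- NULL
  h <- NULL
  if (n_snps(sel) > 0 &&
      length(intersect(sel$snps$snp_id, outcome$snps$snp_id)) > 0) {
    h <- harmonise(sel, outcome)
    j <- nrow(kept_instruments(h))
    log_lines <- c(log_lines, paste0("instruments_kept: ", j))
    if (j > 0) {
      results <- mr_battery(h, seed = seed, n_boot = n_boot)
      results <- cbind(exposure = exposure$trait_name,
                       outcome = outcome$trait_name,
                       direction = "forward", results)
      paths["results"] <- file.path(output_dir, "results.tsv")
      write_tsv_diffable(results, paths[["results"]])
      paths["harmonised"] <- file.path(output_dir, "harmonised.tsv")
      write_harmonised(h, paths[["harmonised"]])
      if (j >= 3) {
        rep <- sensitivity_report(h, seed = seed)
        paths["sensitivity"] <- file.path(output_dir, "sensitivity.json")
        write_sensitivity_report(rep, paths[["sensitivity"]])
        for (tbl in c("scatter", "funnel", "leave_one_out", "single_snp")) {
          paths[tbl] <- file.path(output_dir, paste0(tbl, ".tsv"))
          write_tsv_diffable(rep[[if (tbl %in% c("scatter", "funnel")) tbl
                                  else tbl]], paths[[tbl]])
        }
      }
      if (!is.null(config$thresholds)) {
        scan <- threshold_scan(exposure, outcome,
                               thresholds = as.numeric(config$thresholds),
                               seed = seed)
        paths["threshold_scan"] <- file.path(output_dir, "threshold_scan.tsv")
        write_tsv_diffable(scan, paths[["threshold_scan"]])
        log_lines <- c(log_lines,
                       paste0("thresholds: ",
                              paste(format(as.numeric(config$thresholds)),
                                    collapse = ", ")))
      }
    }
  }
  if (is.null(results)) {
    log_lines <- c(log_lines, "status: not_estimable")
    paths["results"] <- file.path(output_dir, "results.tsv")
    write_tsv_diffable(data.frame(exposure = exposure$trait_name,
                                  outcome = outcome$trait_name,
                                  direction = "forward",
                                  status = "not_estimable"),
                       paths[["results"]])
  }
  if (isTRUE(config$bidirectional)) {
    bd <- mr_bidirectional(exposure, outcome, p_threshold = p_threshold,
                           seed = seed)
    rows <- lapply(bd, function(d) {
      if (d$status != "estimated") {
        return(data.frame(exposure = d$exposure, outcome = d$outcome,
                          direction = d$direction, status = d$status))
      }
      cbind(exposure = d$exposure, outcome = d$outcome,
            direction = d$direction, status = d$status, d$results)
    })
    cols <- unique(unlist(lapply(rows, names)))
    rows <- lapply(rows, function(r) {
      for (c in setdiff(cols, names(r))) r[[c]] <- NA
      r[cols]
    })
    paths["bidirectional"] <- file.path(output_dir, "bidirectional.tsv")
    write_tsv_diffable(do.call(rbind, rows), paths[["bidirectional"]])
  }
  run_log(output_dir, log_lines)
  invisible(list(harmonised = h, results = results, paths = paths))
}

#' Simulate a two-sample study from a configuration
#'
#' Config keys mirror [sim_config()] plus `mode`, `prefix` (file prefix
#' inside `output_dir`).
#'
#' @param config a `run_config` list or YAML path.
#' @param output_dir output directory.
#' @return Invisibly, the [simulate_two_sample()] result.
#' @export
mr_run_simulate <- function(config, output_dir = config$output_dir) {
  if (is.character(config)) config <- read_run_config(config)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  keep <- intersect(names(config), names(formals(sim_config)))
  cfg <- do.call(sim_config, config[keep])
  study <- simulate_two_sample(cfg, mode = config$mode %||% "individual")
  prefix <- file.path(output_dir, config$prefix %||% "sim")
  write_simulated_study(study, prefix)
  run_log(output_dir, c(paste0("simulate seed: ", cfg$seed),
                        paste0("pleiotropy: ", cfg$pleiotropy),
                        paste0("n_snps: ", cfg$n_snps)))
  invisible(study)
}

#' Run the screening pipeline from a configuration
#'
#' Config keys: `heritability` (TSV path), `correlations` (TSV path),
#' `datasets` (named list of `path`/`column_map`/`trait_name`), filter
#' thresholds (`h2_p_max`, `min_confidence`, `intercept_max`, `rho_min`,
#' `neglog10p_min`), `p_instrument`, `alpha`.
#'
#' @param config a `run_config` list or YAML path.
#' @param output_dir output directory.
#' @return Invisibly, the screening results data.frame.
#' @export
mr_run_screen <- function(config, output_dir = config$output_dir) {
  if (is.character(config)) config <- read_run_config(config)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  her <- utils::read.delim(config$heritability, stringsAsFactors = FALSE)
  cor_tab <- utils::read.delim(config$correlations, stringsAsFactors = FALSE)

  her_kept <- filter_heritable(her,
                               p_max = config$h2_p_max %||% 0.05,
                               min_confidence = config$min_confidence %||% "medium",
                               intercept_max = config$intercept_max %||% 1.1)
  cor_kept <- filter_correlated(cor_tab,
                                rho_min = config$rho_min %||% 0.10,
                                neglog10p_min = config$neglog10p_min %||% 12)
  pairs <- cor_kept[cor_kept$trait_a %in% her_kept$trait &
                      cor_kept$trait_b %in% her_kept$trait,
                    c("trait_a", "trait_b")]

  datasets <- lapply(config$datasets, function(spec) {
    read_summary_table(spec$path, default_column_map(spec$column_map),
                       trait_name = spec$trait_name)
  })
  names(datasets) <- vapply(config$datasets, function(s) s$trait_name,
                            character(1))
  results <- screen_pairs(pairs, datasets,
                          p_instrument = config$p_instrument %||% 5e-8,
                          alpha = config$alpha %||% 0.05)
  results$note <- "exploratory screen; uncorrected significance"
  write_tsv_diffable(results, file.path(output_dir, "screen_results.tsv"))
  excl <- c(
    if (nrow(attr(her_kept, "exclusions"))) {
      paste0("heritability\t", attr(her_kept, "exclusions")$trait, "\t",
             attr(her_kept, "exclusions")$reason)
    },
    if (nrow(attr(cor_kept, "exclusions"))) {
      paste0("correlation\t", attr(cor_kept, "exclusions")$trait_a, ":",
             attr(cor_kept, "exclusions")$trait_b, "\t",
             attr(cor_kept, "exclusions")$reason)
    })
  writeLines(excl %||% character(0), file.path(output_dir, "exclusions.txt"))
  run_log(output_dir, c(paste0("pairs screened: ", nrow(pairs)),
                        paste0("p_instrument: ",
                               format(config$p_instrument %||% 5e-8))))
  invisible(results)
}

#' Fit an anchored Bayesian network from a configuration
#'
#' Config keys: `data` (TSV of observations, columns are nodes),
#' `whitelist` / `blacklist` (lists of two-element parent/child pairs),
#' `n_boot` (default 1000), `threshold` (default 0.8), `seed`.
#'
#' @param config a `run_config` list or YAML path.
#' @param output_dir output directory.
#' @return Invisibly, the [bootstrap_edges()] result.
#' @export
mr_run_bn <- function(config, output_dir = config$output_dir) {
  if (is.character(config)) config <- read_run_config(config)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  data <- utils::read.delim(config$data, stringsAsFactors = FALSE)
  to_mat <- function(x) {
    if (is.null(x)) NULL else do.call(rbind, lapply(x, unlist))
  }
  constraints <- edge_constraints(whitelist = to_mat(config$whitelist),
                                  blacklist = to_mat(config$blacklist))
  seed <- as.integer(config$seed %||% 1L)
  res <- bootstrap_edges(data, constraints,
                         n_boot = config$n_boot %||% 1000,
                         threshold = config$threshold %||% 0.8,
                         seed = seed)
  write_tsv_diffable(res$support, file.path(output_dir, "edge_support.tsv"))
  write_dag(res$consensus, file.path(output_dir, "consensus_edges.tsv"))
  write_dot(res$consensus, file.path(output_dir, "consensus.dot"))
  run_log(output_dir, c(paste0("bn seed: ", seed),
                        paste0("n_boot: ", config$n_boot %||% 1000),
                        paste0("threshold: ", config$threshold %||% 0.8)))
  invisible(res)
}

#' Run MR-PRESSO from a configuration
#'
#' Config keys: `exposure`, `outcome` (as in [mr_run()]), `p_threshold`,
#' `n_sim`, `outlier_alpha`, `seed`.
#'
#' @param config a `run_config` list or YAML path.
#' @param output_dir output directory.
#' @return Invisibly, the [mr_presso()] result.
#' @export
mr_run_presso <- function(config, output_dir = config$output_dir) {
  if (is.character(config)) config <- read_run_config(config)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  load_ds <- function(spec) {
    read_summary_table(spec$path, default_column_map(spec$column_map),
                       trait_name = spec$trait_name %||% "trait")
  }
  exposure <- load_ds(config$exposure)
  outcome <- load_ds(config$outcome)
  sel <- suppressMessages(select_instruments(exposure,
                                             config$p_threshold %||% 5e-8))
  h <- harmonise(sel, outcome)
  seed <- as.integer(config$seed %||% 1L)
  res <- mr_presso(h, n_sim = config$n_sim %||% 1000,
                   outlier_alpha = config$outlier_alpha %||% 0.05,
                   seed = seed)
  write_presso(res, file.path(output_dir, "presso.json"))
  run_log(output_dir, c(paste0("presso seed: ", seed),
                        paste0("n_sim: ", config$n_sim %||% 1000),
                        paste0("outlier_alpha: ",
                               config$outlier_alpha %||% 0.05)))
  invisible(res)
}
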
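test_that("read_summary_table round-trips a hand-written TSV and backfills p-values", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "SNP\tEA\tOA\tFREQ\tBETA\tSE\tP\tN",
    "rs1\tA\tG\t0.30\t0.05\t0.01\t1e-8\t10000",
    "rs2\tC\tT\t0.10\t-0.02\t0.004\t2e-7\t10000",
    "rs3\tG\tA\t0.45\t1.96\t1.0\tNA\t10000"
  ), path)
  map <- c(snp = "SNP", effect_allele = "EA", other_allele = "OA",
           eaf = "FREQ", beta = "BETA", se = "SE", pval = "P", n = "N")
  ds <- read_summary_table(path, map, "bp")
  expect_s3_class(ds, "summary_dataset")
  expect_equal(n_snps(ds), 3)
  expect_equal(ds$snps$beta, c(0.05, -0.02, 1.96))
  # beta = 1.96, se = 1: two-sided normal p computed independently.
  expect_equal(ds$snps$pval[3], 2 * pnorm(-1.96), tolerance = 1e-12)
  expect_equal(round(ds$snps$pval[3], 2), 0.05)
})

test_that("read_summary_table autodetects commas, rejects bad maps and duplicates", {
  csv <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("snp,ea,oa,b,s", "rs1,A,G,0.1,0.01"), csv)
  map <- c(snp = "snp", effect_allele = "ea", other_allele = "oa",
           beta = "b", se = "s")
  ds <- read_summary_table(csv, map, "t")
  expect_equal(ds$snps$snp_id, "rs1")

  expect_error(read_summary_table(csv, c(map, bogus = "b"), "t"), "unknown")
  expect_error(read_summary_table(csv, map[-1], "t"), "column_map")

  dup <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("snp\tea\toa\tb\ts", "rs1\tA\tG\t0.1\t0.01",
               "rs1\tA\tG\t0.2\t0.01"), dup)
  expect_error(read_summary_table(dup, map, "t"), "rs1")
})

test_that("rows with missing beta or se are rejected with a count", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("snp\tea\toa\tb\ts", "rs1\tA\tG\t0.1\t0.01",
               "rs2\tA\tG\tNA\t0.01"), path)
  map <- c(snp = "snp", effect_allele = "ea", other_allele = "oa",
           beta = "b", se = "s")
  expect_message(ds <- read_summary_table(path, map, "t"), "1 row")
  expect_equal(n_snps(ds), 1)
})

test_that("harmonise keeps matching alleles, flips swapped ones, complements strands", {
  e <- summary_dataset(data.frame(
    snp_id = c("rs1", "rs2", "rs3"),
    effect_allele = c("A", "A", "A"), other_allele = c("G", "G", "G"),
    eaf = c(0.3, 0.3, 0.3), beta = c(0.1, 0.1, 0.1), se = 0.01,
    pval = 1e-10, n = 1e4), "exp")
  o <- summary_dataset(data.frame(
    snp_id = c("rs1", "rs2", "rs3"),
    effect_allele = c("A", "G", "C"),     # match / swapped / strand-swapped
    other_allele = c("G", "A", "T"),
    eaf = c(0.3, 0.7, 0.7), beta = c(0.2, 0.2, 0.2), se = 0.02,
    pval = 1e-10, n = 1e4), "out")
  h <- harmonise(e, o)
  expect_equal(h$data$flag, c("kept", "flipped", "flipped"))
  expect_equal(h$data$beta_outcome, c(0.2, -0.2, -0.2))
  expect_equal(h$data$eaf, c(0.3, 0.3, 0.3))
})

test_that("palindromic SNPs resolve by allele frequency and drop near 0.5", {
  e <- summary_dataset(data.frame(
    snp_id = c("rs1", "rs2", "rs3"),
    effect_allele = "A", other_allele = "T",
    eaf = c(0.20, 0.20, 0.50), beta = 0.1, se = 0.01, pval = 1e-10, n = 1e4),
    "exp")
  o <- summary_dataset(data.frame(
    snp_id = c("rs1", "rs2", "rs3"),
    effect_allele = "A", other_allele = "T",
    eaf = c(0.22, 0.80, 0.50), beta = 0.2, se = 0.02, pval = 1e-10, n = 1e4),
    "out")
  h <- harmonise(e, o)
  # rs1: frequencies agree -> kept; rs2: opposite side of 0.5 -> flipped;
  # rs3: eaf exactly 0.5 (window boundary) -> dropped.
  expect_equal(h$data$flag, c("kept", "flipped", "dropped_palindromic"))
  expect_equal(h$data$beta_outcome[1:2], c(0.2, -0.2))
  expect_true(is.na(h$data$beta_outcome[3]))
})

test_that("unmatched and missing SNPs are dropped and carry no associations", {
  e <- summary_dataset(data.frame(
    snp_id = c("rs1", "rs2"), effect_allele = "A", other_allele = "G",
    eaf = 0.3, beta = 0.1, se = 0.01, pval = 1e-10, n = 1e4), "exp")
  o <- summary_dataset(data.frame(
    snp_id = c("rs1", "rs9"), effect_allele = c("A", "A"),
    other_allele = c("C", "G"),   # rs1 irreconcilable alleles
    eaf = 0.3, beta = 0.2, se = 0.02, pval = 1e-10, n = 1e4), "out")
  h <- harmonise(e, o)
  expect_setequal(h$data$flag, "dropped_unmatched")
  expect_true(all(is.na(h$data$beta_outcome)))
  expect_equal(nrow(kept_instruments(h)), 0)

  o2 <- summary_dataset(data.frame(
    snp_id = "rs9", effect_allele = "A", other_allele = "G",
    eaf = 0.3, beta = 0.2, se = 0.02, pval = 1e-10, n = 1e4), "out")
  expect_error(harmonise(e, o2), "no shared instruments")
})

test_that("harmonisation is idempotent and coherent under outcome allele relabelling", {
  withr::with_seed(7, {
    j <- 12
    alleles <- list(c("A", "G"), c("C", "T"), c("A", "C"))
    pick <- sample(3, j, replace = TRUE)
    e <- summary_dataset(data.frame(
      snp_id = sprintf("rs%02d", 1:j),
      effect_allele = vapply(pick, function(i) alleles[[i]][1], ""),
      other_allele = vapply(pick, function(i) alleles[[i]][2], ""),
      eaf = runif(j, 0.1, 0.4), beta = rnorm(j, 0.05, 0.01), se = 0.005,
      pval = 1e-10, n = 1e4), "exp")
    flip <- sample(c(TRUE, FALSE), j, replace = TRUE)
    o_snps <- e$snps
    o_snps$beta <- rnorm(j, 0.01, 0.02)
    o_snps$se <- 0.01
    # Report a random subset of outcome rows for the other allele.
    tmp <- o_snps$effect_allele[flip]
    o_snps$effect_allele[flip] <- o_snps$other_allele[flip]
    o_snps$other_allele[flip] <- tmp
    o_snps$beta[flip] <- -o_snps$beta[flip]
    o_snps$eaf[flip] <- 1 - o_snps$eaf[flip]
    o <- summary_dataset(o_snps, "out")

    h <- harmonise(e, o)
    k <- kept_instruments(h)
    expect_equal(nrow(k), j)

    # Idempotence: rebuild the outcome on the exposure's alleles and rerun.
    o_aligned <- summary_dataset(data.frame(
      snp_id = k$snp_id, effect_allele = e$snps$effect_allele,
      other_allele = e$snps$other_allele, eaf = k$eaf,
      beta = k$beta_outcome, se = k$se_outcome, pval = k$pval_outcome,
      n = 1e4), "out")
    h2 <- harmonise(e, o_aligned)
    expect_true(all(h2$data$flag == "kept"))
    expect_equal(kept_instruments(h2)$beta_outcome, k$beta_outcome)

    # Sign coherence: relabelling every outcome row leaves kept pairs identical.
    o_flipped <- o$snps
    tmp <- o_flipped$effect_allele
    o_flipped$effect_allele <- o_flipped$other_allele
    o_flipped$other_allele <- tmp
    o_flipped$beta <- -o_flipped$beta
    o_flipped$eaf <- 1 - o_flipped$eaf
    h3 <- harmonise(e, summary_dataset(o_flipped, "out"))
    expect_equal(kept_instruments(h3)$beta_outcome, k$beta_outcome)
    expect_equal(kept_instruments(h3)$beta_exposure, k$beta_exposure)
  })
})

test_that("ld_prune keeps the lowest-p SNP per correlated cluster", {
  ds <- make_summary(c(0.1, 0.1), c(0.01, 0.012), pval = c(1e-10, 1e-8),
                     snp_id = c("rsA", "rsB"))
  ld <- matrix(c(1, 1, 1, 1), 2, 2, dimnames = list(c("rsA", "rsB"),
                                                    c("rsA", "rsB")))
  out <- ld_prune(ds, ld)
  expect_equal(out$snps$snp_id, "rsA")

  ident <- diag(2)
  dimnames(ident) <- dimnames(ld)
  expect_equal(n_snps(ld_prune(ds, ident)), 2)

  expect_message(ld_prune(ds, NULL), "independent")
  expect_equal(n_snps(suppressMessages(ld_prune(ds, NULL))), 2)
})

test_that("ld_prune agrees with a brute-force greedy scan and yields an independent set", {
  ids <- c("rs1", "rs2", "rs3", "rs4")
  ds <- make_summary(rep(0.1, 4), rep(0.01, 4),
                     pval = c(1e-12, 1e-10, 1e-8, 1e-6), snp_id = ids)
  ld <- diag(4)
  dimnames(ld) <- list(ids, ids)
  ld["rs1", "rs2"] <- ld["rs2", "rs1"] <- 0.5   # rs2 clumps with rs1
  ld["rs2", "rs3"] <- ld["rs3", "rs2"] <- 0.9   # rs3 only correlated with rs2
  thr <- 0.001

  # Independent oracle: explicit greedy scan in ascending p order.
  kept <- character(0)
  for (id in ids[order(ds$snps$pval, ids)]) {
    if (all(ld[id, kept] <= thr)) kept <- c(kept, id)
  }
  out <- ld_prune(ds, ld, thr)
  expect_equal(sort(out$snps$snp_id), sort(kept))
  expect_equal(sort(out$snps$snp_id), c("rs1", "rs3", "rs4"))

  pair_r2 <- ld[out$snps$snp_id, out$snps$snp_id]
  expect_true(all(pair_r2[upper.tri(pair_r2)] <= thr))

  expect_error(ld_prune(ds, ld[1:3, 1:3]), "rs4")
})

test_that("select_instruments applies a strict threshold and allows empty results", {
  ds <- make_summary(c(0.1, 0.05), c(0.01, 0.01), pval = c(1e-9, 1e-7))
  expect_equal(n_snps(select_instruments(ds, 5e-8)), 1)
  expect_equal(n_snps(select_instruments(ds, 1e-6)), 2)
  expect_message(out <- select_instruments(ds, 1e-12), "no SNPs")
  expect_equal(n_snps(out), 0)
})

test_that("instrument strength: F equals t-squared and aggregates correctly", {
  # beta = 0.05, se = 0.005, n = 10000: t^2 = 100 and F must equal it,
  # because F = (n-2) r2 / (1-r2) with r2 = t2/(t2+n-2) simplifies to t2.
  ds <- make_summary(0.05, 0.005, n = 10000)
  st <- instrument_strength(ds)
  expect_equal(st$per_snp$f_stat, 100, tolerance = 1e-12)
  expect_equal(st$per_snp$r2, 100 / (100 + 9998), tolerance = 1e-12)

  zero <- instrument_strength(make_summary(0, 0.01, n = 1000))
  expect_equal(zero$per_snp$r2, 0)
  expect_equal(zero$per_snp$f_stat, 0)

  # F values {4, 16} from t = 2 and 4 regardless of n; mean F = 10.
  two <- instrument_strength(make_summary(c(0.02, 0.04), c(0.01, 0.01),
                                          n = 5000))
  expect_equal(two$per_snp$f_stat, c(4, 16), tolerance = 1e-12)
  expect_equal(two$mean_f, 10, tolerance = 1e-12)
  expect_equal(two$total_r2, sum(two$per_snp$r2))

  withr::with_seed(3, {
    ds2 <- make_summary(rnorm(20, 0.05, 0.02), runif(20, 0.004, 0.02),
                        n = 30000)
    st2 <- instrument_strength(ds2)
    expect_equal(st2$per_snp$f_stat, (ds2$snps$beta / ds2$snps$se)^2,
                 tolerance = 1e-10)
  })

  expect_error(instrument_strength(make_summary(0.1, 0.01, n = 2)), "exceed 2")
})

test_that("EAF-based strength variant is available and flagged", {
  ds <- make_summary(0.1, 0.01, n = 10000, eaf = 0.25)
  st <- instrument_strength(ds, method = "eaf")
  expect_equal(st$method, "eaf")
  expect_equal(st$per_snp$r2, 2 * 0.25 * 0.75 * 0.1^2, tolerance = 1e-12)
})
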
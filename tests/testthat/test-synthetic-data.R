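test_that("raw tables carry the planted structure and are reproducible", {
  cfg <- generator_config(n_proteins = 10, n_ligands = 30, n_pairs = 80,
                          threshold_censoring_rate = 0.3, seed = 17)
  g1 <- generate_raw_table(cfg)
  g2 <- generate_raw_table(cfg)
  expect_identical(g1$records, g2$records)
  expect_equal(nrow(g1$records), nrow(g1$truth))
  # censored fraction near the configured rate (binomial check)
  frac <- mean(g1$records$relation != "exact")
  expect_gt(frac, 0.2); expect_lt(frac, 0.42)
  # censored records are reported at integer p-values
  cens <- g1$records$relation != "exact"
  p_rep <- 9 - log10(g1$records$value_nm[cens])
  expect_equal(p_rep, round(p_rep))
  # zero contamination -> filters remove nothing
  cfg0 <- generator_config(n_proteins = 6, n_ligands = 20, n_pairs = 40,
                           contamination = c(invalid_smiles = 0,
                                             short_protein = 0,
                                             long_protein = 0,
                                             excluded_kingdom = 0,
                                             bad_conditions = 0,
                                             missing_affinity = 0),
                           seed = 5)
  raw0 <- generate_raw_table(cfg0)
  out0 <- run_filters(raw0$records)
  expect_equal(nrow(out0$rejects), 0)
  # planted invalid-SMILES rows are exactly the ones the rule removes
  cfgk <- generator_config(n_proteins = 6, n_ligands = 20, n_pairs = 40,
                           contamination = c(invalid_smiles = 0.1,
                                             short_protein = 0,
                                             long_protein = 0,
                                             excluded_kingdom = 0,
                                             bad_conditions = 0,
                                             missing_affinity = 0),
                           seed = 6)
  rawk <- generate_raw_table(cfgk)
  outk <- run_filters(rawk$records)
  planted <- rawk$truth$row_id[!is.na(rawk$truth$planted_rule)]
  expect_setequal(outk$rejects$row_id, planted)
  expect_true(all(outk$rejects$reject_rule == "invalid_smiles"))
})

test_that("replicate aggregation recovers latent truth better with more replicates", {
  err_for <- function(rep_rate, lambda, seed) {
    cfg <- generator_config(n_proteins = 10, n_ligands = 40, n_pairs = 120,
                            replicate_rate = rep_rate,
                            replicate_lambda = lambda,
                            threshold_censoring_rate = 0, mutation_rate = 0,
                            contamination = c(invalid_smiles = 0,
                                              short_protein = 0,
                                              long_protein = 0,
                                              excluded_kingdom = 0,
                                              bad_conditions = 0,
                                              missing_affinity = 0),
                            seed = seed)
    raw <- generate_raw_table(cfg)
    cur <- suppressWarnings(curate(raw$records))
    truth <- dplyr::distinct(raw$truth, pair_id, .keep_all = TRUE)
    key <- raw$records
    key$canonical_smiles <- standardize_smiles(key$ligand_smiles)
    key$pair_id <- raw$truth$pair_id
    key <- dplyr::distinct(key, protein_sequence, canonical_smiles, pair_id)
    joined <- dplyr::inner_join(cur$pairs, key,
                                by = c("protein_sequence", "canonical_smiles"))
    joined <- dplyr::inner_join(joined, truth, by = "pair_id")
    # the 80th percentile is a deliberate soft maximum: compare medians of
    # absolute deviation from latent truth
    median(abs(joined$p_ki - joined$true_p_ki), na.rm = TRUE)
  }
  errs <- vapply(c(101, 202, 303), function(s) {
    c(err_for(0, 1, s), err_for(1, 6, s))
  }, numeric(2))
  # averaged over seeds, heavy replication reduces the error
  expect_lt(mean(errs[2, ]), mean(errs[1, ]))
})

test_that("per-pair experimental CI is positive and grows with noise", {
  ci_med <- function(noise, seed) {
    cfg <- generator_config(n_proteins = 8, n_ligands = 25, n_pairs = 60,
                            replicate_rate = 1, replicate_lambda = 4,
                            noise_sd = noise, threshold_censoring_rate = 0,
                            mutation_rate = 0,
                            contamination = c(invalid_smiles = 0,
                                              short_protein = 0,
                                              long_protein = 0,
                                              excluded_kingdom = 0,
                                              bad_conditions = 0,
                                              missing_affinity = 0),
                            seed = seed)
    raw <- generate_raw_table(cfg)
    cur <- suppressWarnings(curate(raw$records))
    median(cur$pairs$ci_exp, na.rm = TRUE)
  }
  lo <- ci_med(0.2, 7); hi <- ci_med(0.8, 7)
  expect_gt(lo, 0)
  expect_gt(hi, lo)
})

test_that("selective fixture has the printed composition", {
  sel <- generate_selective_subset(seed = 1)
  expect_equal(nrow(sel), 127)
  counts <- table(sel$protein)
  expect_equal(unname(counts[["MTR1B"]]), 7)
  expect_true(all(counts[setdiff(names(counts), "MTR1B")] == 20))
  expect_equal(sum(counts == 7), 1)
  expect_true(all(sel$experimental >= 2 & sel$experimental <= 10))
  # every rank category occurs somewhere in the synthetic scores
  cats <- c(rank_bin("glide", sel$glide_score),
            rank_bin("mm_gbsa", sel$dg_bind),
            rank_bin("qc", sel$dh_bind))
  expect_setequal(unique(cats), c("high", "medium", "low", "failed"))
})

test_that("benchmark folder layout round-trips through its reader", {
  cfg <- generator_config(n_proteins = 6, n_ligands = 15, n_pairs = 50,
                          seed = 9)
  dir <- withr::local_tempdir()
  long <- generate_benchmark_layout(cfg, dir, k = 3)
  expect_true(all(file.exists(file.path(
    dir, c("drugs.tsv", "targets.tsv", "affinity.tsv", "folds.json")))))
  back <- read_benchmark_folder(dir)
  key <- function(d) d[order(d$drug_id, d$target_id), ]
  expect_equal(as.data.frame(key(back$pairs)), as.data.frame(key(long)),
               tolerance = 1e-9)
  expect_length(back$folds$train_folds, 3)
  idx <- c(unlist(back$folds$train_folds), back$folds$test)
  expect_setequal(idx, seq_len(nrow(long)))
  # Davis-style raw-Kd matrices transform on read
  aff <- readr::read_tsv(file.path(dir, "affinity.tsv"),
                         show_col_types = FALSE)
  raw_nm <- 10^(9 - as.matrix(aff[, -1]))
  aff[, -1] <- as.data.frame(raw_nm)
  readr::write_tsv(aff, file.path(dir, "affinity.tsv"))
  back2 <- read_benchmark_folder(dir, kd_raw = TRUE)
  expect_equal(sort(back2$pairs$affinity), sort(long$affinity),
               tolerance = 1e-9)
})

test_that("dense benchmark matrices are fully present", {
  cfg <- generator_config(n_proteins = 4, n_ligands = 6, n_pairs = 24 * 10,
                          seed = 3)
  dir <- withr::local_tempdir()
  long <- generate_benchmark_layout(cfg, dir, k = 2)
  expect_equal(nrow(long), 4 * 6)
})
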
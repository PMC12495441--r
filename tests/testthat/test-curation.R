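test_that("protein mass matches residue-mass bookkeeping", {
  expect_equal(protein_mass_kda("G"), 0.0750672, tolerance = 1e-6)
  expect_equal(protein_mass_kda("GG"), 2 * 0.0750672 - 0.0180153,
               tolerance = 1e-6)
  expect_error(protein_mass_kda(""), "non-empty")
  expect_error(protein_mass_kda("GXZ"), "non-standard")
})

test_that("filters apply in order, attribute rejections uniquely, conserve counts", {
  rec <- clean_record(8)
  rec$value_nm[1] <- NA                       # missing affinity
  rec$kingdom[2] <- "bacteria"                # organism
  rec$temperature[3] <- 80                    # conditions
  rec$ligand_smiles[4] <- "C1CC"              # invalid SMILES
  rec$protein_sequence[5] <- strrep("A", 49)  # too short
  rec$protein_sequence[6] <- strrep("G", 60)  # 60 aa but < 1 kDa? no: 4.5 kDa
  # a record violating two rules is attributed to the first failing rule only
  rec$kingdom[7] <- "bacteriophage"; rec$ligand_smiles[7] <- "C1CC"
  out <- run_filters(rec)
  expect_equal(nrow(out$kept) + nrow(out$rejects), nrow(rec))
  got <- table(out$rejects$reject_rule)
  expect_equal(got[["missing_affinity"]], 1)
  expect_equal(got[["organism"]], 2)          # rows 2 and 7
  expect_equal(got[["conditions"]], 1)
  expect_equal(got[["invalid_smiles"]], 1)    # row 4 only; row 7 went to organism
  expect_equal(got[["protein_length"]], 1)
  # ledger chains
  expect_equal(out$ledger$n_out[-nrow(out$ledger)], out$ledger$n_in[-1])
  expect_equal(out$ledger$n_in - out$ledger$n_removed, out$ledger$n_out)
  expect_equal(out$ledger$n_out[nrow(out$ledger)], nrow(out$kept))
})

test_that("missing temperature and pH pass the conditions rule", {
  rec <- clean_record(2)
  rec$temperature <- NA_real_
  rec$ph <- NA_real_
  out <- run_filters(rec)
  expect_equal(nrow(out$kept), 2)
})

test_that("weights follow the criterion registry and square-root lightening", {
  expect_equal(assign_weight()$final_weight, 1)
  expect_equal(assign_weight(n_mut = 1)$final_weight, sqrt(3))
  w <- assign_weight("threshold_resolved")
  expect_equal(w$raw_weight, 1 / sqrt(10))
  expect_equal(w$final_weight, 10^(-1 / 4))
  expect_equal(assign_weight("approximate_relation")$raw_weight, 10^-0.25)
  # clamping keeps raw in [0.1, 10], final in [0.316, 3.163]
  heavy <- assign_weight(n_mut = 20)
  expect_equal(heavy$raw_weight, 10)
  expect_equal(heavy$final_weight, sqrt(10))
  light <- assign_weight(rep("threshold_resolved", 1), n_mut = 0)
  expect_gte(light$final_weight, 0.31)
  expect_error(assign_weight("not_a_criterion"), "unknown")
  led <- generics::tidy(assign_weight("threshold_resolved", n_mut = 2))
  expect_true("mutant_protein" %in% led$criterion)
})

test_that("weighted percentile equals the weight-replication oracle", {
  # degenerate and constant cases
  expect_equal(weighted_percentile(5, 2, 80), 5)
  expect_equal(weighted_percentile(rep(3, 7), runif(7, 0.5, 2), 80), 3)
  expect_equal(weighted_percentile(c(5, 7), c(1, 1), 80), 6.6)
  # unit weights reduce to the standard linear-interpolation percentile
  withr::with_seed(42, {
    for (i in 1:20) {
      v <- rnorm(sample(2:30, 1))
      q <- runif(1, 5, 95)
      expect_equal(weighted_percentile(v, rep(1, length(v)), q),
                   quantile(v, q / 100, type = 7, names = FALSE))
    }
    # integer weights equal the brute-force replication oracle
    for (i in 1:500) {
      n <- sample(1:12, 1)
      v <- round(rnorm(n, 6, 2), 3)
      w <- sample(1:5, n, replace = TRUE)
      q <- runif(1, 1, 99)
      expect_equal(weighted_percentile(v, w, q),
                   replication_percentile(v, w, q), tolerance = 1e-10)
    }
  })
  expect_error(weighted_percentile(numeric(), numeric()), "empty")
  expect_error(weighted_percentile(c(1, 2), c(1, -1)), "positive")
})

test_that("replicate confidence intervals: closed form, zero on ties, asymptotics", {
  expect_equal(pair_confidence_interval(c(6, 6, 6)), 0)
  expect_equal(pair_confidence_interval(c(6, 6, 6), "bootstrap"), 0)
  expect_equal(pair_confidence_interval(c(5, 7)),
               qt(0.975, 1) * sd(c(5, 7)) / sqrt(2))
  expect_true(is.na(pair_confidence_interval(5)))
  # both methods approach 1.96 * sigma / sqrt(n) for a large normal sample
  x <- withr::with_seed(9, rnorm(400, 0, 1))
  expected <- 1.96 * sd(x) / 20
  expect_equal(pair_confidence_interval(x), expected, tolerance = 0.05)
  expect_equal(pair_confidence_interval(x, "bootstrap", seed = 3), expected,
               tolerance = 0.1)
})

test_that("aggregation takes the weighted 80th percentile per channel", {
  rec <- tibble::tibble(
    protein_sequence = "P1", canonical_smiles = "CCO",
    measure_kind = c("Ki", "Kd", "IC50"),
    p_value = c(5, 7, 6.2), weight = 1
  )
  out <- aggregate_pairs(rec)
  expect_equal(nrow(out), 1)
  expect_equal(out$p_ki, 6.6)        # {5,7} at the 80th percentile
  expect_equal(out$p_ic50, 6.2)      # singleton channel
  expect_equal(out$n_replicates_ki, 2L)
  expect_equal(out$n_replicates_ic50, 1L)

  # missing channel stays missing
  only_ic <- rec[3, ]
  out2 <- aggregate_pairs(only_ic)
  expect_true(is.na(out2$p_ki))
  expect_false(is.na(out2$p_ic50))

  # soft-maximum: an outlier cluster far above barely moves the 80th pct
  main <- rnorm(20, 4.7, 0.3)
  vals <- c(main, 8.7, 8.5)
  agg <- weighted_percentile(vals, rep(1, length(vals)), 80)
  expect_lt(agg, 6)                 # near the main mass
  expect_gt(max(vals) - agg, 2)     # strict max far above

  # idempotence: aggregating singletons returns them unchanged
  singles <- tibble::tibble(
    protein_sequence = c("P1", "P2"), canonical_smiles = "CCO",
    measure_kind = "Ki", p_value = c(5.5, 8.1), weight = c(1, 2)
  )
  re <- aggregate_pairs(singles)
  expect_equal(sort(re$p_ki), sort(singles$p_value))

  # monotonicity: +delta on every replicate shifts the aggregate by delta
  shifted <- rec; shifted$p_value <- shifted$p_value + 0.7
  expect_equal(aggregate_pairs(shifted)$p_ki, out$p_ki + 0.7)
})

test_that("extreme-value clipping removes the planted tails only", {
  withr::with_seed(5, {
    pairs <- tibble::tibble(
      protein_sequence = paste0("P", 1:300), canonical_smiles = "CCO",
      p_ki = rnorm(300, 6, 0.5), p_ic50 = NA_real_, weight = 1
    )
    pairs$p_ki[1:2] <- c(20, -10)  # planted outliers
    out <- clip_extremes(pairs, percentile = 99)
    expect_true(all(c(20, -10) %in%
                      setdiff(pairs$p_ki, out$kept$p_ki)))
    expect_lte(out$n_removed, 4)
    # all-identical channel removes nothing
    const <- pairs; const$p_ki <- 6
    expect_equal(clip_extremes(const)$n_removed, 0)
  })
  expect_warning(clip_extremes(tibble::tibble(p_ki = 1:5, p_ic50 = NA)),
                 "fewer than 100")
})

test_that("end-to-end curation conserves records and bounds weights", {
  cfg <- generator_config(n_proteins = 8, n_ligands = 25, n_pairs = 60,
                          seed = 3)
  raw <- generate_raw_table(cfg)
  cur <- suppressWarnings(curate(raw$records))
  led <- cur$ledger
  expect_equal(led$n_out[-nrow(led)], led$n_in[-1])
  expect_equal(led$n_in[1], nrow(raw$records))
  expect_equal(led$n_out[nrow(led)], nrow(cur$pairs))
  # per-rule ledger counts equal the planted contamination counts
  planted <- table(raw$truth$planted_rule)
  got <- stats::setNames(led$n_removed, led$rule)
  expect_equal(got[["organism"]], unname(planted[["excluded_kingdom"]]))
  expect_equal(got[["invalid_smiles"]], unname(planted[["invalid_smiles"]]))
  expect_equal(got[["conditions"]], unname(planted[["bad_conditions"]]))
  expect_equal(got[["missing_affinity"]],
               unname(planted[["missing_affinity"]]))
  expect_equal(got[["protein_length"]],
               unname(planted[["short_protein"]] + planted[["long_protein"]]))
  # weight bounds from the default registry
  expect_true(all(cur$pairs$weight >= 0.31 & cur$pairs$weight <= 3.17))
  expect_true(all(!is.na(cur$pairs$p_ki) | !is.na(cur$pairs$p_ic50)))
})
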
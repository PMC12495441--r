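# Fragment grammar for valid-by-construction SMILES: a ring core decorated
# with simple substituents, optionally linked to a second ring. Invalid
# strings are injected explicitly, never produced accidentally.
.smiles_rings <- c("c1ccccc1", "C1CCCCC1", "c1ccncc1", "C1CCNCC1",
                   "c1ccc2ccccc2c1", "c1ccsc1", "C1CCOC1", "c1cnccn1")
.smiles_subs <- c("C", "CC", "CCC", "O", "N", "Cl", "F", "OC", "C(=O)O",
                  "C(=O)N", "C(C)C", "Br", "CO", "CN")
.smiles_links <- c("C", "CC", "O", "NC(=O)", "CO")
.invalid_smiles_pool <- c("C1CC", "c1ccccc", "X#Y@@", "CC)O",
                          "[Zz]CC", "C1CC2", "%%%")

# Replicate-level measurement error, log10 orders. Assay errors are far more
# likely to depress an affinity (degraded compound, incomplete binding) than
# to inflate it, which is what makes a soft maximum the right aggregate:
# a mixture of small symmetric noise, a heavy downward error mode, and rare
# high outlier clusters. `sd` sets the overall scale.
.replicate_noise <- function(n, sd) {
  mode <- sample(c("good", "down", "high"), n, replace = TRUE,
                 prob = c(0.65, 0.25, 0.10))
  out <- numeric(n)
  out[mode == "good"] <- stats::rnorm(sum(mode == "good"), 0, 0.4 * sd)
  out[mode == "down"] <- -abs(stats::rnorm(sum(mode == "down"), 0, 1.5 * sd))
  out[mode == "high"] <- abs(stats::rnorm(sum(mode == "high"), 0, 2 * sd))
  out
}

.hash_unit <- function(s, seed = 0L) {
  # deterministic value in [-1, 1]
  (.string_hash(s, seed) %% 20001L) / 10000 - 1
}

.composition_score <- function(string, seed) {
  mean(vapply(strsplit(string, "")[[1]], .hash_unit, numeric(1), seed = seed))
}

#' Synthetic-data generator configuration
#'
#' Defines the statistical structure of generated affinity tables: replicate
#' multiplicity, threshold censoring concentrated at integer p-values,
#' correlated sparse pKi/pIC50 targets, mutations, and per-rule
#' contamination. Defaults describe a desk-scale study: 30 proteins of
#' 60-180 residues, 150 fragment-grammar ligands, 500 protein-ligand pairs,
#' replicate noise of 0.5 log10 orders, task correlation 0.8 and 2%
#' contamination per filter rule.
#'
#' @param n_proteins,n_ligands,n_pairs Entity counts.
#' @param protein_length_range Length range of clean proteins (residues).
#' @param replicate_rate Fraction of pairs with more than one measurement.
#' @param replicate_lambda Poisson mean of extra replicates for such pairs.
#' @param threshold_censoring_rate Fraction of measurements reported only as
#'   a bound at an integer p-value.
#' @param noise_sd Replicate noise, log10 orders.
#' @param task_correlation Latent correlation between pKi and pIC50.
#' @param missing_ki,missing_ic50 Per-pair probability that a channel is
#'   unmeasured (a pair always keeps at least one channel).
#' @param mutation_rate Fraction of records carrying a (consistent) point
#'   mutation annotation.
#' @param contamination Named rates of planted violations per filter rule:
#'   `invalid_smiles`, `short_protein`, `long_protein`, `excluded_kingdom`,
#'   `bad_conditions`, `missing_affinity`.
#' @param seed Generator seed.
#' @return List of class `dta_generator_config`.
#' @export
generator_config <- function(n_proteins = 30, n_ligands = 150, n_pairs = 500,
                             protein_length_range = c(60, 180),
                             replicate_rate = 0.4, replicate_lambda = 2,
                             threshold_censoring_rate = 0.1, noise_sd = 0.5,
                             task_correlation = 0.8, missing_ki = 0.3,
                             missing_ic50 = 0.3, mutation_rate = 0.05,
                             contamination = c(invalid_smiles = 0.02,
                                               short_protein = 0.02,
                                               long_protein = 0.02,
                                               excluded_kingdom = 0.02,
                                               bad_conditions = 0.02,
                                               missing_affinity = 0.02),
                             seed = 1L) {
  stopifnot(all(c(replicate_rate, threshold_censoring_rate, missing_ki,
                  missing_ic50, mutation_rate, contamination) >= 0),
            all(c(replicate_rate, threshold_censoring_rate, missing_ki,
                  missing_ic50, mutation_rate, contamination) <= 1),
            n_proteins >= 2, n_ligands >= 2, n_pairs >= 1, noise_sd >= 0,
            task_correlation >= -1, task_correlation <= 1)
  structure(list(n_proteins = n_proteins, n_ligands = n_ligands,
                 n_pairs = n_pairs,
                 protein_length_range = protein_length_range,
                 replicate_rate = replicate_rate,
                 replicate_lambda = replicate_lambda,
                 threshold_censoring_rate = threshold_censoring_rate,
                 noise_sd = noise_sd, task_correlation = task_correlation,
                 missing_ki = missing_ki, missing_ic50 = missing_ic50,
                 mutation_rate = mutation_rate, contamination = contamination,
                 seed = as.integer(seed)),
            class = "dta_generator_config")
}

.random_protein <- function(len) {
  paste(sample(names(dtaforge_residue_masses()), len, replace = TRUE),
        collapse = "")
}

#' Standard residue mass table
#'
#' Average masses (Da) of the 20 standard amino-acid residues, as used by
#' the protein-mass filter.
#' @return Named numeric vector.
#' @export
dtaforge_residue_masses <- function() .residue_masses

.random_smiles <- function(n) {
  # suffixes attach to the ring-closure atom, which must be a carbon:
  # rings closing on an aromatic nitrogen would gain an invalid substituent
  suffix_safe <- .smiles_rings[!grepl("n1$", .smiles_rings)]
  out <- character(n)
  for (i in seq_len(n)) {
    ring <- sample(suffix_safe, 1)
    s <- paste0(sample(.smiles_subs, 1), ring)
    if (stats::runif(1) < 0.5) s <- paste0(s, sample(.smiles_subs, 1))
    if (stats::runif(1) < 0.3) {
      s <- paste0(s, sample(.smiles_links, 1), sample(.smiles_rings, 1))
    }
    out[i] <- s
  }
  out
}

# Latent affinity surface: a smooth function of hashed ligand/protein
# character composition, so that any encoder which sees token identities can
# in principle recover it. Ligand and protein contributions are standardized
# across the generated sets and mixed (ligand slightly dominant), then mapped
# to a realistic p-value scale.
.latent_affinity <- function(ligand, protein, lig_scores, prot_scores, r,
                             pair_seed) {
  zl <- lig_scores[ligand]; zp <- prot_scores[protein]
  z <- (zl + 0.8 * zp) / sqrt(1 + 0.8^2)
  p_ki <- 5.5 + 1.5 * z
  eps <- .hash_unit(paste0(ligand, "|", protein), pair_seed) * 1.5
  p_ic50 <- 5.5 + 1.5 * (r * z + sqrt(1 - r^2) * eps)
  c(p_ki = min(max(p_ki, 2.5), 9.5), p_ic50 = min(max(p_ic50, 2.5), 9.5))
}

.pair_universe <- function(config) {
  smiles <- unique(.random_smiles(config$n_ligands * 2))[seq_len(config$n_ligands)]
  smiles <- smiles[!is.na(smiles)]
  lens <- sample(seq(config$protein_length_range[1],
                     config$protein_length_range[2]), config$n_proteins,
                 replace = TRUE)
  proteins <- vapply(lens, .random_protein, character(1))
  zl <- vapply(smiles, .composition_score, numeric(1), seed = 11L)
  zp <- vapply(proteins, .composition_score, numeric(1), seed = 23L)
  zl <- (zl - mean(zl)) / max(stats::sd(zl), 1e-8)
  zp <- (zp - mean(zp)) / max(stats::sd(zp), 1e-8)
  names(zl) <- smiles; names(zp) <- proteins
  pairs <- tibble::tibble(
    ligand_smiles = sample(smiles, config$n_pairs, replace = TRUE),
    protein_sequence = sample(proteins, config$n_pairs, replace = TRUE)
  ) |> dplyr::distinct()
  while (nrow(pairs) < config$n_pairs) {
    extra <- tibble::tibble(
      ligand_smiles = sample(smiles, config$n_pairs - nrow(pairs),
                             replace = TRUE),
      protein_sequence = sample(proteins, config$n_pairs - nrow(pairs),
                                replace = TRUE))
    pairs <- dplyr::distinct(dplyr::bind_rows(pairs, extra))
  }
  lat <- t(vapply(seq_len(nrow(pairs)), function(i) {
    .latent_affinity(pairs$ligand_smiles[i], pairs$protein_sequence[i],
                     zl, zp, config$task_correlation, config$seed)
  }, numeric(2)))
  pairs$true_p_ki <- lat[, 1]
  pairs$true_p_ic50 <- lat[, 2]
  pairs$pair_id <- seq_len(nrow(pairs))
  pairs
}

#' Generate a clean curated-style pair table with latent truth
#'
#' Convenience generator for model experiments: curated pairs whose
#' observed targets are the latent affinities plus replicate-level noise,
#' with per-task missingness and unit weights. No contamination and no
#' censoring — this is what the curation pipeline would ideally recover.
#'
#' @param config A [generator_config()].
#' @return Tibble with `protein_sequence`, `canonical_smiles`, `p_ki`,
#'   `p_ic50`, `weight`, and the latent `true_p_ki` / `true_p_ic50`.
#' @export
generate_pair_table <- function(config = generator_config()) {
  withr::with_seed(config$seed, {
    pairs <- .pair_universe(config)
    n <- nrow(pairs)
    has_ki <- stats::runif(n) >= config$missing_ki
    has_ic <- stats::runif(n) >= config$missing_ic50
    neither <- !has_ki & !has_ic
    has_ki[neither] <- TRUE
    obs_noise <- function(m) stats::rnorm(m, 0, config$noise_sd)
    tibble::tibble(
      protein_sequence = pairs$protein_sequence,
      canonical_smiles = standardize_smiles(pairs$ligand_smiles),
      p_ki = ifelse(has_ki, pairs$true_p_ki + obs_noise(n), NA_real_),
      p_ic50 = ifelse(has_ic, pairs$true_p_ic50 + obs_noise(n), NA_real_),
      weight = 1,
      true_p_ki = pairs$true_p_ki,
      true_p_ic50 = pairs$true_p_ic50
    )
  })
}

#' Generate a raw BindingDB-dialect measurement table with ground truth
#'
#' Emits one row per measurement: replicated, noisy, threshold-censored
#' values over a universe of protein-ligand pairs with a known latent
#' affinity surface, plus planted violations of each curation filter rule at
#' the configured contamination rates (each contaminated row violates
#' exactly one rule, recorded in the ground truth).
#'
#' @param config A [generator_config()].
#' @return List with `records` (raw tibble: `ligand_smiles`,
#'   `protein_sequence`, `mutations`, `organism`, `kingdom`, `temperature`,
#'   `ph`, `measure_kind`, `value_nm`, `relation`, `source_tags`, `row_id`)
#'   and `truth` (per-row tibble: `row_id`, `pair_id`, `planted_rule`,
#'   `true_p_ki`, `true_p_ic50`, `censored`).
#' @export
generate_raw_table <- function(config = generator_config()) {
  withr::with_seed(config$seed + 101L, {
    pairs <- .pair_universe(config)
    n <- nrow(pairs)
    has_ki <- stats::runif(n) >= config$missing_ki
    has_ic <- stats::runif(n) >= config$missing_ic50
    neither <- !has_ki & !has_ic
    has_ki[neither] <- TRUE

    rows <- list()
    for (i in seq_len(n)) {
      n_rep <- 1L
      if (stats::runif(1) < config$replicate_rate) {
        n_rep <- 1L + max(1L, stats::rpois(1, config$replicate_lambda))
      }
      for (rep_i in seq_len(n_rep)) {
        kinds <- c(if (has_ki[i]) sample(c("Ki", "Kd"), 1), if (has_ic[i]) "IC50")
        for (kind in kinds) {
          p_true <- if (kind == "IC50") pairs$true_p_ic50[i] else
            pairs$true_p_ki[i]
          p_obs <- p_true + .replicate_noise(1, config$noise_sd)
          relation <- "exact"
          censored <- FALSE
          if (stats::runif(1) < config$threshold_censoring_rate) {
            censored <- TRUE
            # dilution series ended: report an integer-p bound
            if (stats::runif(1) < 0.5) {
              p_obs <- ceiling(p_obs) ; relation <- "less"    # conc < bound
            } else {
              p_obs <- floor(p_obs)   ; relation <- "greater" # conc > bound
            }
          }
          rows[[length(rows) + 1L]] <- tibble::tibble(
            pair_id = pairs$pair_id[i],
            ligand_smiles = pairs$ligand_smiles[i],
            protein_sequence = pairs$protein_sequence[i],
            measure_kind = kind,
            value_nm = 10^(9 - p_obs),
            relation = relation,
            censored = censored
          )
        }
      }
    }
    records <- dplyr::bind_rows(rows)
    m <- nrow(records)
    records$mutations <- NA_character_
    records$organism <- "Homo sapiens"
    records$kingdom <- "eukaryota"
    records$temperature <- ifelse(stats::runif(m) < 0.5, 25,
                                  NA_real_)
    records$ph <- ifelse(stats::runif(m) < 0.5, 7.4, NA_real_)
    records$source_tags <- ""

    # consistent point mutations on a subset of records
    mut_rows <- which(stats::runif(m) < config$mutation_rate)
    for (j in mut_rows) {
      sq <- records$protein_sequence[j]
      pos <- sample.int(nchar(sq), 1)
      ref <- substr(sq, pos, pos)
      alt <- sample(setdiff(names(dtaforge_residue_masses()), ref), 1)
      records$mutations[j] <- paste0(ref, pos, alt)
    }

    # plant violations: each contaminated row violates exactly one rule
    planted <- rep(NA_character_, m)
    pool <- seq_len(m)
    for (rule in names(config$contamination)) {
      k <- round(config$contamination[[rule]] * m)
      if (k == 0 || length(pool) == 0) next
      hit <- sample(pool, min(k, length(pool)))
      pool <- setdiff(pool, hit)
      planted[hit] <- rule
      for (j in hit) {
        switch(rule,
          invalid_smiles = {
            records$ligand_smiles[j] <- sample(.invalid_smiles_pool, 1)
          },
          short_protein = {
            records$protein_sequence[j] <- .random_protein(sample(10:49, 1))
            records$mutations[j] <- NA_character_
          },
          long_protein = {
            records$protein_sequence[j] <- .random_protein(2501 + sample(100, 1))
            records$mutations[j] <- NA_character_
          },
          excluded_kingdom = {
            records$kingdom[j] <- sample(c("bacteria", "bacteriophage"), 1)
            records$organism[j] <- "Escherichia coli"
          },
          bad_conditions = {
            if (stats::runif(1) < 0.5) records$temperature[j] <- 70
            else records$ph[j] <- 2
          },
          missing_affinity = {
            records$value_nm[j] <- NA_real_
          })
      }
    }
    records$row_id <- seq_len(m)
    truth <- tibble::tibble(
      row_id = records$row_id,
      pair_id = records$pair_id,
      planted_rule = planted,
      censored = records$censored
    ) |>
      dplyr::left_join(pairs[, c("pair_id", "true_p_ki", "true_p_ic50")],
                       by = "pair_id")
    records <- records[, c("row_id", "ligand_smiles", "protein_sequence",
                           "mutations", "organism", "kingdom", "temperature",
                           "ph", "measure_kind", "value_nm", "relation",
                           "source_tags")]
    list(records = records, truth = truth)
  })
}

#' Generate the 127-pair selective test fixture
#'
#' A synthetic stand-in for a selective evaluation subset: 7 named receptor
#' targets, 20 ligands each except the second melatonin receptor with 7
#' (127 pairs), experimental affinities spanning p-values 2-10, a DTA-like
#' prediction column correlated with experiment, and synthetic
#' docking/MM-GBSA/quantum-chemistry outputs drawn so that every rank
#' category (high, medium, low, failed) occurs.
#'
#' @param seed Integer seed.
#' @return Tibble: `protein`, `ligand_id`, `experimental`, `prediction`,
#'   `glide_score`, `dg_bind`, `dh_bind`.
#' @export
generate_selective_subset <- function(seed = 1L) {
  withr::with_seed(seed, {
    proteins <- c("MTR1A", "MTR1B", "OX1R", "OX2R", "FA11", "EGFR", "SC6A9")
    n_lig <- c(MTR1A = 20, MTR1B = 7, OX1R = 20, OX2R = 20, FA11 = 20,
               EGFR = 20, SC6A9 = 20)
    rows <- lapply(proteins, function(p) {
      n <- n_lig[[p]]
      experimental <- stats::runif(n, 2, 10)
      prediction <- pmin(pmax(
        experimental + stats::rnorm(n, 0, 1.0), 2), 10)
      # weak monotone signal plus noise; occasional out-of-range -> failed
      sig <- (experimental - 6) / 4
      glide <- -6 + -3 * sig + stats::rnorm(n, 0, 3)
      dg <- -60 + -25 * sig + stats::rnorm(n, 0, 25)
      dh <- -40 + -20 * sig + stats::rnorm(n, 0, 20)
      fail <- stats::runif(n) < 0.08
      glide[fail] <- 5
      tibble::tibble(protein = p, ligand_id = sprintf("%s_L%02d", p, seq_len(n)),
                     experimental = experimental, prediction = prediction,
                     glide_score = glide, dg_bind = dg, dh_bind = dh)
    })
    dplyr::bind_rows(rows)
  })
}

#' Generate a benchmark-layout folder (drug list, target list, matrix)
#'
#' Writes the community Davis/KIBA-style folder layout: `drugs.tsv` (id,
#' SMILES), `targets.tsv` (id, sequence), `affinity.tsv` (drugs x targets
#' matrix of p-values, empty cells = unmeasured) and `folds.json` (k train
#' fold index vectors plus a test index vector over the present cells in
#' column-major matrix order).
#'
#' @param config A [generator_config()]; `n_pairs` controls matrix density.
#' @param dir Output directory (created if needed).
#' @param k Number of train folds recorded in `folds.json`.
#' @return Invisibly, the in-memory long tibble (`drug_id`, `target_id`,
#'   `smiles`, `sequence`, `affinity`) the folder encodes.
#' @export
generate_benchmark_layout <- function(config = generator_config(), dir,
                                      k = 4) {
  withr::with_seed(config$seed + 202L, {
    smiles <- unique(.random_smiles(config$n_ligands * 2))[
      seq_len(config$n_ligands)]
    lens <- sample(seq(config$protein_length_range[1],
                       config$protein_length_range[2]), config$n_proteins,
                   replace = TRUE)
    proteins <- vapply(lens, .random_protein, character(1))
    nd <- length(smiles); nt <- length(proteins)
    dens <- min(1, config$n_pairs / (nd * nt))
    M <- matrix(NA_real_, nd, nt)
    present <- stats::runif(nd * nt) < dens
    M[present] <- round(stats::runif(sum(present), 4, 10), 3)
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    drugs <- tibble::tibble(drug_id = sprintf("D%03d", seq_len(nd)),
                            smiles = smiles)
    targets <- tibble::tibble(target_id = sprintf("T%03d", seq_len(nt)),
                              sequence = proteins)
    readr::write_tsv(drugs, file.path(dir, "drugs.tsv"))
    readr::write_tsv(targets, file.path(dir, "targets.tsv"))
    aff <- as.data.frame(M)
    names(aff) <- targets$target_id
    readr::write_tsv(tibble::as_tibble(cbind(drug_id = drugs$drug_id, aff)),
                     file.path(dir, "affinity.tsv"))
    cells <- which(!is.na(M), arr.ind = TRUE)
    ord <- sample.int(nrow(cells))
    n_test <- max(1L, round(0.2 * nrow(cells)))
    test_idx <- ord[seq_len(n_test)]
    train_idx <- ord[-seq_len(n_test)]
    folds <- split(train_idx, rep(seq_len(k), length.out = length(train_idx)))
    jsonlite::write_json(list(train_folds = unname(lapply(folds, as.integer)),
                              test = as.integer(test_idx)),
                         file.path(dir, "folds.json"))
    long <- tibble::tibble(
      drug_id = drugs$drug_id[cells[, 1]],
      target_id = targets$target_id[cells[, 2]],
      smiles = drugs$smiles[cells[, 1]],
      sequence = targets$sequence[cells[, 2]],
      affinity = M[cells]
    )
    invisible(long)
  })
}
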
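.normalize_relation <- function(relation) {
  r <- tolower(trimws(as.character(relation)))
  r[is.na(r) | r %in% c("", "=", "exact")] <- "exact"
  r[r %in% c(">", ">=", "≥", "greater")] <- "greater"
  r[r %in% c("<", "<=", "≤", "less")] <- "less"
  r[r %in% c("~", "approx", "approximate")] <- "approx"
  bad <- !r %in% c("exact", "greater", "less", "approx")
  if (any(bad)) {
    rlang::abort(paste0("unknown relation value(s): ",
                        paste(unique(relation[bad]), collapse = ", ")))
  }
  r
}

#' Curate a raw measurement table into a weighted training set
#'
#' The full preparation pipeline: resolve protein sequences (via an optional
#' accession-to-sequence map) and apply annotated point mutations; run the
#' rule-based filters; resolve threshold-censored values by the
#' half-dilution-step rule; transform to the p (log10) scale; assign
#' reliability weights; aggregate replicates per (protein, ligand) pair by
#' the weighted 80th percentile; and remove pairs outside the central
#' affinity range. Every stage's reduction is appended to the ledger, so
#' input size = curated size + total removed.
#'
#' @param records Raw measurement tibble (see [generate_raw_table()] or
#'   [read_bindingdb_tsv()]); needs `ligand_smiles`, `protein_sequence`
#'   and/or `protein_id`, `measure_kind`, `value_nm`, and optionally
#'   `relation`, `mutations`, `kingdom`, `temperature`, `ph`, `source_tags`.
#' @param config A [filter_config()].
#' @param registry A [weight_registry()].
#' @param id_map Optional named character vector: accession -> sequence.
#' @param aggregate_q Aggregation percentile (default 80).
#' @param unreviewed_tags `source_tags` values treated as unreviewed
#'   sources (down-weighted).
#' @return List of class `dta_curation`: `pairs` (curated tibble), `ledger`
#'   (chained reduction tibble), `rejects` (tibble with `reject_rule`).
#' @export
curate <- function(records, config = filter_config(),
                   registry = weight_registry(), id_map = NULL,
                   aggregate_q = 80, unreviewed_tags = c("user", "unreviewed")) {
  records <- tibble::as_tibble(records)
  n0 <- nrow(records)
  if (!"relation" %in% names(records)) records$relation <- "exact"
  records$relation <- .normalize_relation(records$relation)
  if (!"mutations" %in% names(records)) records$mutations <- NA_character_
  if (!"source_tags" %in% names(records)) records$source_tags <- ""

  # --- stage 1: sequence resolution + mutation application -------------------
  seqs <- if ("protein_sequence" %in% names(records)) {
    as.character(records$protein_sequence)
  } else rep(NA_character_, n0)
  if (!is.null(id_map) && "protein_id" %in% names(records)) {
    need <- is.na(seqs) & !is.na(records$protein_id)
    seqs[need] <- unname(id_map[as.character(records$protein_id[need])])
  }
  n_mut <- integer(n0)
  seq_fail <- rep(NA_character_, n0)
  for (i in seq_len(n0)) {
    if (is.na(seqs[i])) {
      seq_fail[i] <- "unresolved sequence"
      next
    }
    if (!is.na(records$mutations[i]) && nzchar(records$mutations[i])) {
      res <- tryCatch({
        muts <- parse_mutations(records$mutations[i])
        seqs[i] <- apply_mutations(seqs[i], muts)
        nrow(muts)
      }, error = function(e) conditionMessage(e))
      if (is.character(res)) seq_fail[i] <- res else n_mut[i] <- res
    }
  }
  records$protein_sequence <- seqs
  records$.n_mut <- n_mut
  ledger <- tibble::tibble(
    rule = "sequence_resolution", n_in = n0,
    n_removed = sum(!is.na(seq_fail)),
    n_out = n0 - sum(!is.na(seq_fail)))
  rejects <- records[!is.na(seq_fail), , drop = FALSE]
  if (nrow(rejects)) rejects$reject_rule <- "sequence_resolution"
  records <- records[is.na(seq_fail), , drop = FALSE]

  # --- stage 2: rule filters -------------------------------------------------
  filt <- run_filters(records, config)
  ledger <- dplyr::bind_rows(ledger, filt$ledger)
  rejects <- dplyr::bind_rows(rejects, filt$rejects)
  kept <- filt$kept
  kept$source_tags[is.na(kept$source_tags)] <- ""

  # --- stage 3: threshold resolution, log transform, weights -----------------
  if (nrow(kept)) {
    censored <- kept$relation %in% c("greater", "less")
    res <- resolve_threshold(kept$value_nm,
                             ifelse(censored, kept$relation, "exact"))
    kept$value_nm <- res$exact_value_nm
    kept$p_value <- to_log_scale(kept$measure_kind, kept$value_nm)
    kept$weight <- vapply(seq_len(nrow(kept)), function(i) {
      criteria <- c(
        if (censored[i]) "threshold_resolved",
        if (kept$relation[i] == "approx") "approximate_relation",
        if (any(strsplit(kept$source_tags[i], "[,;]")[[1]] %in%
                  unreviewed_tags)) "unreviewed_source"
      )
      assign_weight(criteria, n_mut = kept$.n_mut[i], registry)$final_weight
    }, numeric(1))
  }

  # --- stage 4: replicate aggregation ----------------------------------------
  pairs <- aggregate_pairs(kept, q = aggregate_q)
  ledger <- dplyr::bind_rows(ledger, tibble::tibble(
    rule = "aggregation", n_in = nrow(kept),
    n_removed = nrow(kept) - nrow(pairs), n_out = nrow(pairs)))

  # --- stage 5: extreme-value clipping ---------------------------------------
  clip <- clip_extremes(pairs, percentile = config$clip_percentile)
  ledger <- dplyr::bind_rows(ledger, tibble::tibble(
    rule = "clip_extremes", n_in = nrow(pairs),
    n_removed = clip$n_removed, n_out = nrow(clip$kept)))

  structure(list(pairs = clip$kept, ledger = ledger, rejects = rejects),
            class = "dta_curation")
}
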
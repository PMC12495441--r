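#' Default column map for BindingDB "ALL" dumps
#'
#' Maps the internal raw-measurement fields to the column headers of the
#' BindingDB tab-separated "ALL" export. Affinity constants live in three
#' separate columns (Ki/Kd/IC50) whose string values may carry `>`, `<`,
#' `>=`, `<=` or `~` prefixes.
#'
#' @return Named character vector (internal field -> source column).
#' @export
bindingdb_column_map <- function() {
  c(ligand_smiles = "Ligand SMILES",
    protein_id = "UniProt (SwissProt) Primary ID of Target Chain",
    protein_sequence = "BindingDB Target Chain Sequence",
    organism = "Target Source Organism According to Curator or DataSource",
    temperature = "Temp (C)",
    ph = "pH",
    ki = "Ki (nM)",
    kd = "Kd (nM)",
    ic50 = "IC50 (nM)",
    mutations = "Mutation",
    source = "Curation/DataSource")
}

.parse_affinity_string <- function(x) {
  x <- trimws(as.character(x))
  rel <- rep("exact", length(x))
  rel[grepl("^(>=?|≥)", x)] <- "greater"
  rel[grepl("^(<=?|≤)", x)] <- "less"
  rel[grepl("^~", x)] <- "approx"
  val <- suppressWarnings(as.numeric(gsub("^(>=?|<=?|~|≥|≤)\\s*", "", x)))
  tibble::tibble(value_nm = val, relation = rel)
}

#' Read a BindingDB-like TSV into raw measurement records
#'
#' Produces one row per measurement: rows of the source table with several
#' constants (e.g. both a Ki and an IC50) are unpivoted into separate
#' records. Threshold prefixes on the value strings become the `relation`
#' column (`exact` / `greater` / `less` / `approx`).
#'
#' @param path TSV file path.
#' @param column_map Named map from internal fields to source headers; see
#'   [bindingdb_column_map()]. Missing source columns are tolerated and
#'   yield `NA` fields.
#' @param kingdom_map Optional named vector mapping organism labels to
#'   kingdom tags; unmapped organisms get `NA` (and pass the organism rule).
#' @return Tibble of raw measurements.
#' @export
read_bindingdb_tsv <- function(path, column_map = bindingdb_column_map(),
                               kingdom_map = NULL) {
  raw <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = "c"))
  pick <- function(field) {
    cn <- column_map[[field]]
    if (!is.null(cn) && cn %in% names(raw)) raw[[cn]] else
      rep(NA_character_, nrow(raw))
  }
  base <- tibble::tibble(
    ligand_smiles = pick("ligand_smiles"),
    protein_id = pick("protein_id"),
    protein_sequence = pick("protein_sequence"),
    organism = pick("organism"),
    temperature = suppressWarnings(as.numeric(pick("temperature"))),
    ph = suppressWarnings(as.numeric(pick("ph"))),
    mutations = pick("mutations"),
    source_tags = pick("source")
  )
  if (!is.null(kingdom_map)) {
    base$kingdom <- unname(kingdom_map[base$organism])
  } else {
    base$kingdom <- NA_character_
  }
  out <- list()
  kinds <- c(Ki = "ki", Kd = "kd", IC50 = "ic50")
  for (kind in names(kinds)) {
    col <- pick(kinds[[kind]])
    aff <- .parse_affinity_string(col)
    keep <- !is.na(aff$value_nm)
    if (!any(keep)) next
    piece <- base[keep, , drop = FALSE]
    piece$measure_kind <- kind
    piece$value_nm <- aff$value_nm[keep]
    piece$relation <- aff$relation[keep]
    out[[kind]] <- piece
  }
  res <- dplyr::bind_rows(out)
  res$row_id <- seq_len(nrow(res))
  res
}

#' Write a curated pair table as TSV
#'
#' Column layout of a distributable curated-dataset file: sequence, SMILES,
#' pKi, pIC50, weight.
#'
#' @param pairs Curated-pair tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_curated_tsv <- function(pairs, path) {
  out <- tibble::tibble(sequence = pairs$protein_sequence,
                        smiles = pairs$canonical_smiles,
                        pKi = pairs$p_ki, pIC50 = pairs$p_ic50,
                        weight = pairs$weight)
  readr::write_tsv(out, path)
  invisible(path)
}

#' Read a curated pair table written by [write_curated_tsv()]
#' @param path TSV file.
#' @return Curated-pair tibble.
#' @export
read_curated_tsv <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE)
  tibble::tibble(protein_sequence = d$sequence, canonical_smiles = d$smiles,
                 p_ki = d$pKi, p_ic50 = d$pIC50, weight = d$weight)
}

#' Read and write protein FASTA
#'
#' Thin wrappers over `Biostrings` keeping IDs verbatim and wrapping
#' sequence lines at 80 columns.
#'
#' @param path FASTA file.
#' @return `read_protein_fasta()`: named character vector of sequences.
#' @export
read_protein_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(set), names(set))
}

#' @rdname read_protein_fasta
#' @param sequences Named character vector.
#' @export
write_protein_fasta <- function(sequences, path) {
  set <- Biostrings::AAStringSet(sequences)
  Biostrings::writeXStringSet(set, path, width = 80)
  invisible(path)
}

#' Read a benchmark-layout folder
#'
#' Reads the Davis/KIBA-style folder written by
#' [generate_benchmark_layout()] (drug list, target list, affinity matrix,
#' fold indices) back into a long pair table. For matrices holding raw Kd in
#' nM (the Davis convention) set `kd_raw = TRUE` to apply
#' `pKd = -log10(Kd * 1e-9)`.
#'
#' @param dir Folder path.
#' @param kd_raw Whether the matrix holds raw Kd nM values to transform.
#' @return List with `pairs` (long tibble: drug_id, target_id, smiles,
#'   sequence, affinity) and `folds` (list with `train_folds`, `test`,
#'   indices over the present cells in column-major matrix order).
#' @export
read_benchmark_folder <- function(dir, kd_raw = FALSE) {
  drugs <- readr::read_tsv(file.path(dir, "drugs.tsv"), show_col_types = FALSE)
  targets <- readr::read_tsv(file.path(dir, "targets.tsv"),
                             show_col_types = FALSE)
  aff <- readr::read_tsv(file.path(dir, "affinity.tsv"),
                         show_col_types = FALSE)
  M <- as.matrix(aff[, -1])
  cells <- which(!is.na(M), arr.ind = TRUE)
  vals <- M[cells]
  if (kd_raw) vals <- -log10(vals * 1e-9)
  pairs <- tibble::tibble(
    drug_id = drugs$drug_id[cells[, 1]],
    target_id = targets$target_id[cells[, 2]],
    smiles = drugs$smiles[cells[, 1]],
    sequence = targets$sequence[cells[, 2]],
    affinity = vals
  )
  folds_path <- file.path(dir, "folds.json")
  folds <- if (file.exists(folds_path)) {
    jsonlite::read_json(folds_path, simplifyVector = TRUE)
  } else NULL
  list(pairs = pairs, folds = folds)
}
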
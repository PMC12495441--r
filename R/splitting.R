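#' Bemis-Murcko scaffold of a molecule
#'
#' Reduces a molecule to its ring systems plus the linkers connecting them:
#' terminal (degree <= 1) heavy atoms are pruned iteratively from the
#' molecular graph and the remaining framework is re-canonicalized. Acyclic
#' molecules map to the empty scaffold `""`. Scaffold identity is the
#' grouping key of the scaffold split, so test ligands share no framework
#' with training ligands.
#'
#' @param smiles Character vector of valid SMILES (canonicalize first;
#'   invalid input is an error because curation removes it upstream).
#' @return Character vector of scaffold SMILES (`""` for acyclic molecules).
#' @examples
#' \donttest{murcko_scaffold("CCc1ccccc1O")  # "c1ccccc1"}
#' @export
murcko_scaffold <- function(smiles) {
  vapply(as.character(smiles), .murcko_one, character(1), USE.NAMES = FALSE)
}

.murcko_one <- function(smi) {
  if (is.na(smi) || !nzchar(smi)) rlang::abort("invalid SMILES for scaffold")
  sdf <- tryCatch(suppressWarnings(ChemmineR::smiles2sdf(smi)[[1]]),
                  error = function(e) NULL)
  if (is.null(sdf)) rlang::abort(paste0("invalid SMILES for scaffold: ", smi))
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  n <- nrow(ab)
  if (is.null(bb) || nrow(bb) == 0) return("")
  el <- cbind(as.integer(bb[, 1]), as.integer(bb[, 2]))
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
  igraph::V(g)$idx <- seq_len(n)
  repeat {
    term <- which(igraph::degree(g) <= 1)
    if (!length(term)) break
    g <- igraph::delete_vertices(g, term)
  }
  keep <- igraph::V(g)$idx
  if (!length(keep)) return("")
  elem <- sub("_.*", "", rownames(ab))
  map <- match(seq_len(n), keep)
  kb <- bb[el[, 1] %in% keep & el[, 2] %in% keep, , drop = FALSE]
  lines <- c("scaffold", "  dtaforge", "",
             sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                     length(keep), nrow(kb)))
  for (i in keep) {
    lines <- c(lines, sprintf(
      "%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
      0, 0, 0, elem[i]))
  }
  for (j in seq_len(nrow(kb))) {
    lines <- c(lines, sprintf("%3d%3d%3d  0  0  0  0",
                              map[as.integer(kb[j, 1])],
                              map[as.integer(kb[j, 2])],
                              as.integer(kb[j, 3])))
  }
  lines <- c(lines, "M  END", "$$$$")
  out <- suppressWarnings(
    ChemmineOB::convertFormat("SDF", "CAN", paste(lines, collapse = "\n")))
  out <- trimws(strsplit(out, "[\t\n]")[[1]][1])
  if (is.na(out)) "" else out
}

# Group-atomic split: sample whole groups into the test side until its pair
# count first reaches `fraction` of all pairs. Groups are atomic, so the test
# side may overshoot by at most one group.
.group_split <- function(pairs, groups, fraction, seed) {
  n <- nrow(pairs)
  stopifnot(n > 0, length(groups) == n)
  if (fraction <= 0 || fraction >= 1) {
    rlang::abort("test fraction must lie strictly inside (0, 1)")
  }
  ug <- unique(groups)
  if (length(ug) < 2) {
    rlang::abort("cannot split: all pairs belong to a single group")
  }
  ord <- withr::with_seed(seed, sample(ug))
  sizes <- table(groups)[ord]
  target <- fraction * n
  test_groups <- character(0)
  got <- 0
  for (i in seq_along(ord)) {
    if (got >= target) break
    test_groups <- c(test_groups, ord[i])
    got <- got + sizes[[i]]
  }
  if (length(test_groups) >= length(ug)) {
    rlang::abort("test fraction would consume every group; nothing left to train on")
  }
  in_test <- groups %in% test_groups
  list(train = pairs[!in_test, , drop = FALSE],
       test = pairs[in_test, , drop = FALSE])
}

#' Cold-target train/test split
#'
#' Whole proteins (grouped by exact sequence identity) are sampled into the
#' test side until its pair count first reaches `fraction`; every pair of a
#' test protein goes to test, so no test protein is ever seen in training.
#'
#' @param pairs Curated-pair tibble with a `protein_sequence` column.
#' @param fraction Target test fraction of pairs.
#' @param seed Integer seed; the same seed reproduces the same split.
#' @return List with `train` and `test` tibbles.
#' @export
cold_target_split <- function(pairs, fraction = 0.05, seed = 1L) {
  pairs <- tibble::as_tibble(pairs)
  .group_split(pairs, pairs$protein_sequence, fraction, seed)
}

#' Drug-scaffold train/test split
#'
#' As [cold_target_split()], but grouping ligands by Bemis-Murcko scaffold;
#' acyclic molecules form one shared empty-scaffold group. Uses an existing
#' `scaffold` column if present, otherwise computes it from
#' `canonical_smiles`.
#'
#' @inheritParams cold_target_split
#' @return List with `train` and `test` tibbles (a `scaffold` column added).
#' @export
scaffold_split <- function(pairs, fraction = 0.05, seed = 1L) {
  pairs <- tibble::as_tibble(pairs)
  if (!"scaffold" %in% names(pairs)) {
    pairs$scaffold <- murcko_scaffold(pairs$canonical_smiles)
  }
  .group_split(pairs, pairs$scaffold, fraction, seed)
}

#' Combined cold-target + scaffold test split
#'
#' Builds the test set half from a cold-target split and half from a drug
#' scaffold split: first whole proteins are carved out until the cold-target
#' half reaches `test_fraction * cold_target_share` of all pairs, then
#' scaffold groups are carved from the remainder for the other half. Scaffold
#' -half pairs whose protein is a cold-target test protein are reassigned to
#' the cold-target half, so the train side shares no protein with the
#' cold-target half and no scaffold with the scaffold half.
#'
#' @param pairs Curated-pair tibble with `protein_sequence` and
#'   `canonical_smiles` (or `scaffold`) columns.
#' @param test_fraction Total test share of pairs (default 0.05).
#' @param cold_target_share Share of the test set built cold-target
#'   (default 0.5).
#' @param seed Integer seed.
#' @return The input tibble with an `assignment` column
#'   (`train` / `test_cold_target` / `test_scaffold`), plus attributes
#'   `seed` and `leakage` (named counts, both zero by construction).
#' @export
combined_split <- function(pairs, test_fraction = 0.05,
                           cold_target_share = 0.5, seed = 1L) {
  pairs <- tibble::as_tibble(pairs)
  if (!"scaffold" %in% names(pairs)) {
    pairs$scaffold <- murcko_scaffold(pairs$canonical_smiles)
  }
  n <- nrow(pairs)
  cold <- .group_split(pairs, pairs$protein_sequence,
                       test_fraction * cold_target_share, seed)
  remainder <- cold$train
  scaf_fraction <- test_fraction * (1 - cold_target_share) * n / nrow(remainder)
  scaf <- .group_split(remainder, remainder$scaffold, scaf_fraction, seed + 1L)

  key <- function(d) paste(d$protein_sequence, d$canonical_smiles, sep = "\r")
  assignment <- rep("train", n)
  assignment[key(pairs) %in% key(cold$test)] <- "test_cold_target"
  assignment[key(pairs) %in% key(scaf$test)] <- "test_scaffold"
  # pairs in the scaffold half whose protein is a cold-target test protein
  # would leak; move them to the cold-target half
  cold_prot <- unique(cold$test$protein_sequence)
  leak <- assignment == "test_scaffold" & pairs$protein_sequence %in% cold_prot
  assignment[leak] <- "test_cold_target"

  pairs$assignment <- assignment
  train <- pairs[assignment == "train", , drop = FALSE]
  leakage <- c(
    cold_target = length(intersect(
      train$protein_sequence,
      pairs$protein_sequence[assignment == "test_cold_target"])),
    scaffold = length(intersect(
      train$scaffold, pairs$scaffold[assignment == "test_scaffold"]))
  )
  attr(pairs, "seed") <- seed
  attr(pairs, "leakage") <- leakage
  pairs
}

#' Classical K-fold cross-validation folds
#'
#' Shuffles the training pairs once and splits them into `k` disjoint
#' validation subsets whose union is the full set; each fold's training part
#' is the complement of its validation part.
#'
#' @param pairs Training-pair tibble.
#' @param k Number of folds (default 4).
#' @param seed Integer seed.
#' @return List of `k` lists, each with `train` and `validation` tibbles.
#' @export
kfold <- function(pairs, k = 4, seed = 1L) {
  pairs <- tibble::as_tibble(pairs)
  n <- nrow(pairs)
  if (k < 2) rlang::abort("k must be at least 2")
  if (k > n) rlang::abort("more folds than pairs")
  idx <- withr::with_seed(seed, sample.int(n))
  fold_of <- rep(seq_len(k), length.out = n)[order(idx)]
  lapply(seq_len(k), function(f) {
    list(train = pairs[fold_of != f, , drop = FALSE],
         validation = pairs[fold_of == f, , drop = FALSE])
  })
}
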
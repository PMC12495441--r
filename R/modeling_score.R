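#' Rank-bin table for molecular-modeling outputs
#'
#' Half-open score intervals `[a; b)` per method mapping raw outputs to
#' categories: Glide docking score `[-20;-7) -> high`, `[-7;-5) -> medium`,
#' `[-5;0) -> low`; MM-GBSA binding free energy (kcal/mol) `[-150;-70)`,
#' `[-70;-50)`, `[-50;0)`; PM7+COSMO binding enthalpy (kcal/mol)
#' `[-100;-50)`, `[-50;-30)`, `[-30;0)`. Any value outside all intervals of
#' its method — including missing outputs and positive energies — is
#' `failed`. Categories map to numeric ranks high 1, medium 0.5, low 0,
#' failed -1.
#'
#' @return List with per-method interval tibbles and the numeric map.
#' @export
rank_table <- function() {
  iv <- function(lo, hi, cat) tibble::tibble(lo = lo, hi = hi, category = cat)
  list(
    intervals = list(
      glide   = iv(c(-20, -7, -5),   c(-7, -5, 0),   c("high", "medium", "low")),
      mm_gbsa = iv(c(-150, -70, -50), c(-70, -50, 0), c("high", "medium", "low")),
      qc      = iv(c(-100, -50, -30), c(-50, -30, 0), c("high", "medium", "low"))
    ),
    numeric_map = c(high = 1, medium = 0.5, low = 0, failed = -1)
  )
}

#' Categorize one modeling output
#'
#' Assigns `high` / `medium` / `low` by half-open interval membership (the
#' left endpoint belongs to the interval, the right does not: Glide -7 is
#' medium, -5 is low); anything outside all intervals, including `NA`, is
#' `failed`.
#'
#' @param method `"glide"`, `"mm_gbsa"` or `"qc"`.
#' @param value Numeric score/energy (vectorised); `NA` allowed.
#' @param table A [rank_table()].
#' @return Character vector of categories.
#' @export
rank_bin <- function(method, value, table = rank_table()) {
  if (!method %in% names(table$intervals)) {
    rlang::abort(paste0("unknown modeling method: ", method))
  }
  iv <- table$intervals[[method]]
  vapply(value, function(v) {
    if (is.na(v)) return("failed")
    hit <- which(v >= iv$lo & v < iv$hi)
    if (length(hit)) iv$category[hit[1]] else "failed"
  }, character(1))
}

#' Consensus modeling score
#'
#' Mean of the numeric ranks of the configured methods: each method's raw
#' output is rank-binned, mapped through high 1 / medium 0.5 / low 0 /
#' failed -1, and averaged. Missing method outputs count as failed.
#'
#' @param glide_score,dg_bind,dh_bind Raw outputs (scalars or equal-length
#'   vectors; `NA` = method failed/absent).
#' @param methods Which methods enter the mean.
#' @param table A [rank_table()].
#' @return Numeric score(s) in `[-1, 1]`.
#' @examples
#' modeling_score(-8, -60, -20)   # (1 + 0.5 + 0) / 3 = 0.5
#' @export
modeling_score <- function(glide_score = NA_real_, dg_bind = NA_real_,
                           dh_bind = NA_real_,
                           methods = c("glide", "mm_gbsa", "qc"),
                           table = rank_table()) {
  if (!length(methods)) rlang::abort("at least one modeling method required")
  values <- list(glide = glide_score, mm_gbsa = dg_bind, qc = dh_bind)
  n <- max(lengths(values[methods]))
  ranks <- vapply(methods, function(m) {
    v <- rep_len(values[[m]], n)
    table$numeric_map[rank_bin(m, v, table)]
  }, numeric(n))
  if (n == 1) mean(ranks) else rowMeans(matrix(ranks, nrow = n))
}

#' Score table for a selective test set
#'
#' Attaches the consensus modeling score to each pair and compares two
#' predictors of experimental affinity by Spearman correlation: the modeling
#' score (`c_mod`) and the DTA model prediction (`c_dta`).
#'
#' @param data Tibble with columns `glide_score`, `dg_bind`, `dh_bind`,
#'   `experimental` (p-scale affinity) and optionally `prediction`.
#' @return List with `table` (input plus `modeling_score` and
#'   `modeling_category` columns) and `correlations`
#'   (`c_mod`, `c_dta`; `c_dta` is `NA` without a prediction column).
#' @export
score_table <- function(data) {
  data <- tibble::as_tibble(data)
  needed <- c("glide_score", "dg_bind", "dh_bind", "experimental")
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols)) {
    rlang::abort(paste0("score_table: missing column(s) ",
                        paste(missing_cols, collapse = ", ")))
  }
  data$modeling_score <- modeling_score(data$glide_score, data$dg_bind,
                                        data$dh_bind)
  data$modeling_category <- dplyr::case_when(
    data$modeling_score < 0 ~ "failed",
    data$modeling_score < 0.34 ~ "low",
    data$modeling_score < 0.67 ~ "medium",
    TRUE ~ "high"
  )
  c_dta <- if ("prediction" %in% names(data)) {
    spearman(data$prediction, data$experimental)
  } else NA_real_
  list(table = data,
       correlations = c(c_mod = spearman(data$modeling_score,
                                         data$experimental),
                        c_dta = c_dta))
}
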
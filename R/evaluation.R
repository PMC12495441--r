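#' Mean squared error and its root
#'
#' Standard regression error over cells where the target is present; missing
#' targets are skipped. RMSE shares the scale of the targets (log10 orders
#' here), which is why it is the headline accuracy number for affinity
#' models.
#'
#' @param predictions,targets Equal-length numeric vectors; `NA` targets are
#'   skipped.
#' @return Named vector `c(mse = , rmse = )`.
#' @export
mse_rmse <- function(predictions, targets) {
  if (length(predictions) != length(targets)) {
    rlang::abort("predictions and targets must have equal length")
  }
  ok <- !is.na(targets) & !is.na(predictions)
  if (!any(ok)) rlang::abort("no present prediction/target cells")
  mse <- mean((predictions[ok] - targets[ok])^2)
  c(mse = mse, rmse = sqrt(mse))
}

#' Concordance index for regression
#'
#' Fraction of target-discordant pairs ranked concordantly by the
#' predictions: over all pairs (i, j) with `targets[i] > targets[j]`, score 1
#' if `predictions[i] > predictions[j]`, 0.5 on a prediction tie, else 0.
#' Pairs with tied targets are excluded. This is the tie convention of the
#' reference DTA benchmark implementations.
#'
#' @param predictions,targets Equal-length numeric vectors (`NA`-free after
#'   internal filtering).
#' @return C-index in `[0, 1]`, or `NA_real_` when all targets are tied
#'   (undefined).
#' @export
c_index <- function(predictions, targets) {
  ok <- !is.na(predictions) & !is.na(targets)
  p <- predictions[ok]; t <- targets[ok]
  n <- length(p)
  if (n < 2) rlang::abort("c_index needs at least two observations")
  dt <- outer(t, t, ">")            # target-discordant, ordered pairs
  if (!any(dt)) return(NA_real_)
  dp <- outer(p, p, "-")[dt]
  mean((dp > 0) + 0.5 * (dp == 0))
}

#' Confidence interval of model predictions from their RMSE
#'
#' For a large evaluation set the standard error of estimation is numerically
#' the RMSE, so the 95% interval half-width of a prediction is
#' `1.96 * RMSE`.
#'
#' @param rmse Non-negative RMSE.
#' @return `1.96 * rmse`.
#' @examples
#' prediction_ci(0.67)  # ~1.3
#' @export
prediction_ci <- function(rmse) {
  if (any(!is.finite(rmse) | rmse < 0)) rlang::abort("rmse must be >= 0")
  1.96 * rmse
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (ties get average ranks). Returns `NA`
#' (undefined) if either vector is constant.
#'
#' @param x,y Equal-length numeric vectors; pairwise-complete.
#' @return Correlation in `[-1, 1]` or `NA_real_`.
#' @export
spearman <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2) rlang::abort("spearman needs at least two observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  suppressWarnings(stats::cor(x, y, method = "spearman"))
}

#' Metric report for a prediction table
#'
#' Computes per-task n, MSE, RMSE, C-index and the calculated prediction CI
#' (`1.96 * RMSE`) from a long table of predictions and targets.
#'
#' @param data Tibble with columns `task`, `prediction`, `target`, and
#'   optionally `split`.
#' @return Tibble of class `dta_metric_report`, one row per (split, task).
#' @export
metric_report <- function(data) {
  data <- tibble::as_tibble(data)
  if (!"split" %in% names(data)) data$split <- "test"
  out <- data |>
    dplyr::filter(!is.na(.data$target)) |>
    dplyr::group_by(.data$split, .data$task) |>
    dplyr::summarise(
      n = dplyr::n(),
      mse = mse_rmse(.data$prediction, .data$target)[["mse"]],
      rmse = sqrt(.data$mse),
      c_index = if (dplyr::n() >= 2) c_index(.data$prediction, .data$target)
                else NA_real_,
      ci_calc = prediction_ci(.data$rmse),
      .groups = "drop"
    )
  class(out) <- c("dta_metric_report", class(out))
  out
}

#' Evaluate an ensemble on a test table
#'
#' Runs [predict_ensemble()] over the test pairs and reduces the result to a
#' [metric_report()]; also returns the per-pair scatter table (prediction vs
#' target per task) for plotting or TSV export.
#'
#' @param ensemble A trained [train_ensemble()] object.
#' @param pairs Test tibble with `protein_sequence`, `canonical_smiles` and
#'   target columns `p_ki` / `p_ic50` (either may be `NA`).
#' @param ligand_provider,protein_provider Embedding providers.
#' @param cache Optional shared [embedding_cache()].
#' @param split Label recorded in the report.
#' @return List with `report` (a `dta_metric_report`) and `scatter` (long
#'   tibble: task, prediction, target).
#' @export
benchmark_harness <- function(ensemble, pairs, ligand_provider,
                              protein_provider, cache = NULL,
                              split = "test") {
  preds <- predict_ensemble(ensemble, pairs, ligand_provider,
                            protein_provider, cache = cache)
  scatter <- dplyr::bind_rows(
    tibble::tibble(task = "pKi", prediction = preds$pKi_pred,
                   target = pairs$p_ki),
    tibble::tibble(task = "pIC50", prediction = preds$pIC50_pred,
                   target = pairs$p_ic50)
  )
  scatter$split <- split
  list(report = metric_report(scatter), scatter = scatter)
}
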
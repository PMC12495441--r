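#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a trained ensemble
#'
#' One row per cross-validation submodel: fold, training seed, epochs run,
#' best epoch and best validation loss.
#'
#' @param x A `dta_ensemble`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy dta_ensemble
#' @export
tidy.dta_ensemble <- function(x, ...) {
  dplyr::bind_rows(lapply(seq_along(x$submodels), function(i) {
    sm <- x$submodels[[i]]
    tibble::tibble(fold = i, seed = sm$seed,
                   epochs = nrow(sm$manifest),
                   best_epoch = sm$best_epoch,
                   best_val_loss = sm$best_val_loss)
  }))
}

#' Glance at a trained ensemble
#'
#' @param x A `dta_ensemble`.
#' @param ... Unused.
#' @return One-row tibble: submodel count, total trainable parameters, mean
#'   best validation loss.
#' @method glance dta_ensemble
#' @export
glance.dta_ensemble <- function(x, ...) {
  n_par <- sum(vapply(x$submodels[[1]]$network$params, length, integer(1)))
  tibble::tibble(
    k = length(x$submodels),
    n_parameters = n_par,
    mean_val_loss = mean(vapply(x$submodels, function(s) s$best_val_loss,
                                numeric(1))),
    tasks = paste(x$config$tasks, collapse = ",")
  )
}

#' Tidy a weight ledger
#'
#' @param x A `dta_weight_ledger` from [assign_weight()].
#' @param ... Unused.
#' @return Tibble of applied factors plus the raw and final weight.
#' @method tidy dta_weight_ledger
#' @export
tidy.dta_weight_ledger <- function(x, ...) {
  f <- x$applied_factors
  if (!nrow(f)) {
    f <- tibble::tibble(criterion = character(), factor = numeric(),
                        direction = character())
  }
  f$raw_weight <- x$raw_weight
  f$final_weight <- x$final_weight
  f
}

#' Tidy a curation result
#'
#' @param x A `dta_curation` from [curate()].
#' @param ... Unused.
#' @return The chained reduction ledger as a tibble.
#' @method tidy dta_curation
#' @export
tidy.dta_curation <- function(x, ...) x$ledger

#' Glance at a curation result
#'
#' @param x A `dta_curation`.
#' @param ... Unused.
#' @return One-row tibble with input/kept/rejected counts and weight range.
#' @method glance dta_curation
#' @export
glance.dta_curation <- function(x, ...) {
  tibble::tibble(
    n_records_in = x$ledger$n_in[1],
    n_pairs = nrow(x$pairs),
    n_rejected = nrow(x$rejects),
    weight_min = if (nrow(x$pairs)) min(x$pairs$weight) else NA_real_,
    weight_max = if (nrow(x$pairs)) max(x$pairs$weight) else NA_real_
  )
}
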
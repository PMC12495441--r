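# Average residue masses (Da), standard 20-letter alphabet.
.residue_masses <- c(
  A =  71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G =  57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P =  97.1167,
  S =  87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V =  99.1326
)
.water_mass <- 18.0153

#' Average molecular mass of a protein in kDa
#'
#' Sum of average residue masses plus one water (the chain termini), i.e.
#' residue masses of the 20 standard amino acids with `(n-1)` condensations
#' from free amino-acid masses. Non-standard letters are an error; curation
#' rejects such records.
#'
#' @param sequence Amino-acid sequence (one string).
#' @return Mass in kDa.
#' @examples
#' protein_mass_kda("G")   # 0.07507 (free glycine)
#' @export
protein_mass_kda <- function(sequence) {
  if (length(sequence) != 1 || is.na(sequence) || !nzchar(sequence)) {
    rlang::abort("protein_mass_kda needs a non-empty sequence")
  }
  chars <- strsplit(toupper(sequence), "")[[1]]
  m <- .residue_masses[chars]
  if (anyNA(m)) {
    rlang::abort(paste0("non-standard residue letter(s): ",
                        paste(unique(chars[is.na(m)]), collapse = ", ")))
  }
  (sum(m) + .water_mass) / 1000
}

#' Curation filter configuration
#'
#' Defaults reflect the standard preparation of a BindingDB-style dump:
#' proteins of 50-2500 residues and 1-500 kDa, bacterial and bacteriophage
#' proteins excluded, and (when reported) physiological temperature and pH.
#' Records with missing temperature or pH pass those rules: absence of
#' metadata is not evidence of non-physiological conditions.
#'
#' @param min_protein_len,max_protein_len Length bounds in residues.
#' @param min_mass_kda,max_mass_kda Protein mass bounds in kDa.
#' @param excluded_kingdoms Kingdom tags removed by the organism rule.
#' @param temperature_range Acceptable degrees C, length-2 numeric.
#' @param ph_range Acceptable pH, length-2 numeric.
#' @param clip_percentile Central coverage (percent) kept by [clip_extremes()].
#' @return A list of class `dta_filter_config`.
#' @export
filter_config <- function(min_protein_len = 50, max_protein_len = 2500,
                          min_mass_kda = 1, max_mass_kda = 500,
                          excluded_kingdoms = c("bacteria", "bacteriophage"),
                          temperature_range = c(20, 45),
                          ph_range = c(5, 8),
                          clip_percentile = 99) {
  stopifnot(min_protein_len < max_protein_len, min_mass_kda < max_mass_kda,
            temperature_range[1] < temperature_range[2],
            ph_range[1] < ph_range[2],
            clip_percentile > 0, clip_percentile < 100)
  structure(list(min_protein_len = min_protein_len,
                 max_protein_len = max_protein_len,
                 min_mass_kda = min_mass_kda, max_mass_kda = max_mass_kda,
                 excluded_kingdoms = excluded_kingdoms,
                 temperature_range = temperature_range, ph_range = ph_range,
                 clip_percentile = clip_percentile),
            class = "dta_filter_config")
}

#' Rule-based filtering with a per-rule reduction ledger
#'
#' Applies the curation rules in a fixed order — missing affinity, organism,
#' temperature/pH, SMILES validity, protein length, protein mass — so that
#' every removed record is attributed to exactly one rule (its first failing
#' one). The ledger chains: records out of one rule are records into the next,
#' and kept + removed equals the input size.
#'
#' @param records Tibble of raw measurements; expected columns
#'   `ligand_smiles`, `protein_sequence`, `kingdom`, `temperature`, `ph`,
#'   `measure_kind`, `value_nm` (missing columns are treated as all-`NA`,
#'   except `value_nm`/`measure_kind` which then reject everything).
#' @param config A [filter_config()].
#' @return List with `kept` (tibble, plus a `canonical_smiles` column),
#'   `ledger` (tibble: rule, n_in, n_removed, n_out) and `rejects`
#'   (tibble with a `reject_rule` column).
#' @export
run_filters <- function(records, config = filter_config()) {
  stopifnot(inherits(config, "dta_filter_config"))
  records <- tibble::as_tibble(records)
  n0 <- nrow(records)
  col <- function(name, default = NA) {
    if (name %in% names(records)) records[[name]] else rep(default, n0)
  }

  value_nm <- suppressWarnings(as.numeric(col("value_nm")))
  kind <- as.character(col("measure_kind"))
  seqs <- as.character(col("protein_sequence"))
  canon <- rep(NA_character_, n0)

  fail_affinity <- is.na(value_nm) | value_nm <= 0 |
    is.na(kind) | !kind %in% c("Ki", "Kd", "IC50")
  fail_organism <- !is.na(col("kingdom")) &
    tolower(as.character(col("kingdom"))) %in% tolower(config$excluded_kingdoms)
  temp <- suppressWarnings(as.numeric(col("temperature")))
  ph <- suppressWarnings(as.numeric(col("ph")))
  fail_conditions <-
    (!is.na(temp) & (temp < config$temperature_range[1] |
                     temp > config$temperature_range[2])) |
    (!is.na(ph) & (ph < config$ph_range[1] | ph > config$ph_range[2]))

  # SMILES and protein checks are only evaluated for survivors of the earlier
  # rules (canonicalization is the expensive step).
  alive <- !(fail_affinity | fail_organism | fail_conditions)
  canon[alive] <- standardize_smiles(as.character(col("ligand_smiles"))[alive])
  fail_smiles <- alive & is.na(canon)

  len <- ifelse(is.na(seqs), NA_integer_, nchar(seqs))
  fail_length <- is.na(len) | len < config$min_protein_len |
    len > config$max_protein_len
  mass <- rep(NA_real_, n0)
  alive2 <- alive & !fail_smiles & !fail_length
  mass[alive2] <- vapply(seqs[alive2], function(s) {
    tryCatch(protein_mass_kda(s), error = function(e) NA_real_)
  }, numeric(1), USE.NAMES = FALSE)
  fail_mass <- is.na(mass) | mass < config$min_mass_kda |
    mass > config$max_mass_kda

  rules <- list(
    missing_affinity = fail_affinity,
    organism         = fail_organism,
    conditions       = fail_conditions,
    invalid_smiles   = fail_smiles,
    protein_length   = fail_length,
    protein_mass     = fail_mass
  )

  reject_rule <- rep(NA_character_, n0)
  for (rule in names(rules)) {
    hit <- is.na(reject_rule) & rules[[rule]]
    reject_rule[hit] <- rule
  }

  ledger <- tibble::tibble(rule = names(rules), n_in = NA_integer_,
                           n_removed = NA_integer_, n_out = NA_integer_)
  n_in <- n0
  for (i in seq_len(nrow(ledger))) {
    removed <- sum(reject_rule == ledger$rule[i], na.rm = TRUE)
    ledger$n_in[i] <- n_in
    ledger$n_removed[i] <- removed
    ledger$n_out[i] <- n_in - removed
    n_in <- n_in - removed
  }

  kept <- records[is.na(reject_rule), , drop = FALSE]
  kept$canonical_smiles <- canon[is.na(reject_rule)]
  rejects <- records[!is.na(reject_rule), , drop = FALSE]
  rejects$reject_rule <- reject_rule[!is.na(reject_rule)]
  list(kept = kept, ledger = ledger, rejects = rejects)
}

#' Default reliability-weighting criterion registry
#'
#' Each criterion multiplies (important record) or divides (questionable
#' record) the running weight. Significant criteria use `sqrt(10) ~ 3.16`
#' (half an order), insignificant ones `10^0.25 ~ 1.78` (a quarter order).
#' Threshold-resolved records are divided by `sqrt(10)`; mutant proteins are
#' up-weighted by `2 + n_mut`; approximate (`~`) relations and unreviewed
#' sources are mildly down-weighted. The raw weight product is clamped to
#' `[0.1, 10]` and then lightened by a square root, giving final weights in
#' roughly `[0.3, 3.2]`.
#'
#' @return Tibble with columns `criterion`, `factor`, `direction`
#'   (`"multiply"` or `"divide"`).
#' @export
weight_registry <- function() {
  tibble::tibble(
    criterion = c("threshold_resolved", "approximate_relation",
                  "unreviewed_source"),
    factor = c(sqrt(10), 10^0.25, 10^0.25),
    direction = c("divide", "divide", "divide")
  )
}

#' Assign a reliability weight to a curated record
#'
#' Starts from weight 1, applies the registry factor for each triggered
#' criterion, multiplies by `2 + n_mut` for mutant proteins, clamps the raw
#' product to `[0.1, 10]`, and lightens with a square root.
#'
#' @param criteria Character vector of triggered criterion names (may be
#'   empty); all must exist in `registry`.
#' @param n_mut Number of applied point mutations (0 for wild type).
#' @param registry A [weight_registry()]-shaped tibble.
#' @return List of class `dta_weight_ledger`: `base`, `applied_factors`
#'   (tibble), `raw_weight`, `final_weight`.
#' @export
assign_weight <- function(criteria = character(), n_mut = 0,
                          registry = weight_registry()) {
  unknown <- setdiff(criteria, registry$criterion)
  if (length(unknown)) {
    rlang::abort(paste0("unknown weighting criterion: ",
                        paste(unknown, collapse = ", ")))
  }
  applied <- registry[match(criteria, registry$criterion), , drop = FALSE]
  raw <- 1
  if (nrow(applied)) {
    eff <- ifelse(applied$direction == "multiply", applied$factor,
                  1 / applied$factor)
    raw <- prod(eff)
  }
  if (n_mut > 0) {
    raw <- raw * (2 + n_mut)
    applied <- dplyr::bind_rows(applied, tibble::tibble(
      criterion = "mutant_protein", factor = 2 + n_mut,
      direction = "multiply"))
  }
  raw <- min(max(raw, 0.1), 10)
  structure(list(base = 1, applied_factors = applied, raw_weight = raw,
                 final_weight = sqrt(raw)),
            class = "dta_weight_ledger")
}

#' Weighted percentile with linear interpolation
#'
#' Generalizes the standard linear-interpolation percentile (type 7) to
#' weighted observations: conceptually each value occupies a run of
#' `weight` ranks in the sorted list, and the percentile is read at
#' continuous rank `1 + (W - 1) q/100` with linear interpolation between
#' bracketing integer ranks. For integer weights this equals the plain
#' percentile of the weight-replicated list; for unit weights it reduces to
#' `quantile(..., type = 7)`.
#'
#' @param values Numeric vector.
#' @param weights Positive weights, same length.
#' @param q Percentile in (0, 100); default 80, the soft-maximum used for
#'   replicate aggregation.
#' @return The weighted percentile (scalar).
#' @export
weighted_percentile <- function(values, weights = rep(1, length(values)),
                                q = 80) {
  if (!length(values)) rlang::abort("weighted_percentile of an empty vector")
  if (length(weights) != length(values)) {
    rlang::abort("values and weights must have equal length")
  }
  if (any(!is.finite(weights) | weights <= 0)) {
    rlang::abort("weights must be positive")
  }
  if (q <= 0 || q >= 100) rlang::abort("q must lie strictly inside (0, 100)")
  ord <- order(values)
  v <- values[ord]
  cw <- cumsum(weights[ord])
  W <- cw[length(cw)]
  value_at <- function(r) {
    i <- which(cw >= r - 1e-9)[1]
    v[if (is.na(i)) length(v) else i]   # ranks past W hit the top value
  }
  if (W <= 1) return(value_at(W * q / 100))  # sub-unit total: step function
  h <- 1 + (W - 1) * q / 100
  h <- min(max(h, 1), W)
  lo <- floor(h); hi <- ceiling(h)
  vlo <- value_at(lo)
  if (hi == lo) return(vlo)
  vhi <- value_at(hi)
  vlo + (h - lo) * (vhi - vlo)
}

#' 95% confidence interval of replicate measurements
#'
#' Half-width of the two-sided 95% interval for the mean of replicate
#' log-scale measurements of one protein-ligand pair, by Student's t
#' (`t_{0.975, n-1} * sd / sqrt(n)`) or by a percentile bootstrap of the mean
#' (half the (2.5, 97.5) percentile span over `B` resamples). Identical
#' replicates give 0 under both methods; fewer than two replicates give `NA`
#' (undefined).
#'
#' @param values Numeric replicate measurements (log10 orders).
#' @param method `"student"` or `"bootstrap"`.
#' @param B Bootstrap resamples.
#' @param seed Bootstrap seed (local RNG; does not disturb the caller's
#'   random state).
#' @return CI half-width in log10 orders, or `NA_real_` if `n < 2`.
#' @export
pair_confidence_interval <- function(values, method = c("student", "bootstrap"),
                                     B = 1000, seed = 1L) {
  method <- match.arg(method)
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 2) return(NA_real_)
  if (stats::sd(values) == 0) return(0)
  if (method == "student") {
    stats::qt(0.975, df = n - 1) * stats::sd(values) / sqrt(n)
  } else {
    means <- withr::with_seed(seed, {
      vapply(seq_len(B), function(i) mean(sample(values, n, replace = TRUE)),
             numeric(1))
    })
    unname(diff(stats::quantile(means, c(0.025, 0.975))) / 2)
  }
}

#' Aggregate replicate measurements into curated pairs
#'
#' Groups log-scaled, weighted measurements by (protein sequence, canonical
#' SMILES) and reduces each channel — pKi (pooled Ki and Kd records) and
#' pIC50 — to its weighted 80th percentile, a soft maximum that tracks the
#' main mass of replicates while resisting outliers. A channel with no
#' measurements yields a missing target. The pair weight is the weighted mean
#' of member weights, and a per-pair 95% CI of the replicate spread
#' (`ci_exp`, Student) is attached.
#'
#' @param records Tibble with columns `protein_sequence`, `canonical_smiles`,
#'   `measure_kind` (Ki/Kd/IC50), `p_value` (log scale) and `weight`.
#' @param q Aggregation percentile (default 80).
#' @return Tibble of curated pairs: `protein_sequence`, `canonical_smiles`,
#'   `p_ki`, `p_ic50`, `weight`, `n_replicates_ki`, `n_replicates_ic50`,
#'   `ci_exp`.
#' @export
aggregate_pairs <- function(records, q = 80) {
  records <- tibble::as_tibble(records)
  needed <- c("protein_sequence", "canonical_smiles", "measure_kind",
              "p_value", "weight")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols)) {
    rlang::abort(paste0("aggregate_pairs: missing column(s) ",
                        paste(missing_cols, collapse = ", ")))
  }
  records$.channel <- ifelse(records$measure_kind == "IC50", "pIC50", "pKi")
  records |>
    dplyr::group_by(.data$protein_sequence, .data$canonical_smiles) |>
    dplyr::group_modify(function(g, key) {
      chan <- function(name) g[g$.channel == name, , drop = FALSE]
      ki <- chan("pKi"); ic <- chan("pIC50")
      agg <- function(d) {
        if (!nrow(d)) NA_real_ else weighted_percentile(d$p_value, d$weight, q)
      }
      ci <- c(pair_confidence_interval(ki$p_value),
              pair_confidence_interval(ic$p_value))
      ci <- ci[!is.na(ci)]
      tibble::tibble(
        p_ki = agg(ki), p_ic50 = agg(ic),
        weight = sum(g$weight * g$weight) / sum(g$weight),
        n_replicates_ki = nrow(ki), n_replicates_ic50 = nrow(ic),
        ci_exp = if (length(ci)) mean(ci) else NA_real_
      )
    }) |>
    dplyr::ungroup()
}

#' Remove pairs outside the central affinity range
#'
#' Per channel, drops pairs whose aggregated value lies outside the central
#' `percentile`% window (e.g. outside the 0.5th-99.5th percentiles for the
#' default 99). With fewer than 100 pairs the percentile estimate is
#' unstable and the operation is a warning no-op.
#'
#' @param pairs Curated-pair tibble with `p_ki` and `p_ic50` columns.
#' @param percentile Central coverage to keep, percent.
#' @return List with `kept` (tibble) and `n_removed`.
#' @export
clip_extremes <- function(pairs, percentile = 99) {
  pairs <- tibble::as_tibble(pairs)
  if (nrow(pairs) < 100) {
    rlang::warn("clip_extremes: fewer than 100 pairs; no clipping applied")
    return(list(kept = pairs, n_removed = 0L))
  }
  tail_frac <- (100 - percentile) / 200
  out <- rep(FALSE, nrow(pairs))
  for (chan in c("p_ki", "p_ic50")) {
    x <- pairs[[chan]]
    if (sum(!is.na(x)) < 2) next
    qs <- stats::quantile(x, c(tail_frac, 1 - tail_frac), na.rm = TRUE,
                          names = FALSE)
    out <- out | (!is.na(x) & (x < qs[1] | x > qs[2]))
  }
  list(kept = pairs[!out, , drop = FALSE], n_removed = sum(out))
}
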
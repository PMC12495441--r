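#' Convert an affinity constant in nM to the p-scale
#'
#' Binding constants (Ki, Kd, IC50) reported in nanomolar are mapped to the
#' negative decadic log of the molar value: `p = 9 - log10(value_nm)`, so
#' 1 nM gives 9 and 10 uM gives 5. Kd and Ki feed the same pKi channel
#' downstream; IC50 stays a separate target.
#'
#' @param kind Measurement kind, one of `"Ki"`, `"Kd"`, `"IC50"`. Vectorised.
#' @param value_nm Positive concentration in nM. Vectorised.
#' @return Numeric vector on the p (log10) scale.
#' @examples
#' to_log_scale("Ki", 1)      # 9
#' to_log_scale("Ki", 1e4)    # 5, i.e. 10 uM
#' @export
to_log_scale <- function(kind, value_nm) {
  kind <- as.character(kind)
  bad_kind <- !kind %in% c("Ki", "Kd", "IC50")
  if (any(bad_kind)) {
    rlang::abort(paste0("unknown measurement kind: ",
                        paste(unique(kind[bad_kind]), collapse = ", ")))
  }
  if (any(!is.finite(value_nm) | value_nm <= 0)) {
    rlang::abort("affinity values must be positive concentrations in nM")
  }
  9 - log10(value_nm)
}

#' Resolve a threshold-censored affinity value
#'
#' Bioassay databases report many values only as bounds (e.g. `Ki > 10 uM`)
#' because a serial dilution series ended. Under a 10x dilution hypothesis the
#' true value is estimated half a dilution step beyond the bound: the reported
#' concentration is multiplied (relation `"greater"`) or divided (`"less"`)
#' by `sqrt(10) ~ 3.16`, a 0.5 shift on the p-scale toward the allowed side.
#' The record's reliability weight is reduced by the same `sqrt(10)` factor.
#'
#' @param value_nm Positive concentration in nM. Vectorised.
#' @param relation One of `"exact"`, `"greater"`, `"less"` (both `>` and `>=`
#'   map to greater, `<` and `<=` to less). Vectorised.
#' @return A tibble with columns `exact_value_nm` and `weight_factor`.
#' @examples
#' resolve_threshold(1e4, "greater")  # 3.16e4 nM, weight factor 1/sqrt(10)
#' @export
resolve_threshold <- function(value_nm, relation) {
  if (any(!is.finite(value_nm) | value_nm <= 0)) {
    rlang::abort("threshold values must be positive concentrations in nM")
  }
  relation <- as.character(relation)
  bad <- !relation %in% c("exact", "greater", "less")
  if (any(bad)) {
    rlang::abort(paste0("unknown relation: ",
                        paste(unique(relation[bad]), collapse = ", ")))
  }
  step <- sqrt(10)
  exact <- ifelse(relation == "greater", value_nm * step,
           ifelse(relation == "less",    value_nm / step, value_nm))
  wf <- ifelse(relation == "exact", 1, 1 / step)
  tibble::tibble(exact_value_nm = exact, weight_factor = wf)
}

#' KIBA-style adjusted Ki from paired IC50 and Ki
#'
#' The KIBA benchmark unifies Ki and IC50 measurements into one bioactivity
#' value, `Ki_adj = IC50 / (1 + 0.3 * IC50 / Ki)`. This is a reader utility
#' for KIBA-style data; the curation pipeline keeps Ki and IC50 as separate
#' targets.
#'
#' @param ic50,ki Positive values on a common concentration scale. Vectorised.
#' @return Adjusted Ki on the same scale.
#' @export
kiba_adjusted_ki <- function(ic50, ki) {
  if (any(!is.finite(ic50) | ic50 <= 0) || any(!is.finite(ki) | ki <= 0)) {
    rlang::abort("KIBA adjustment requires positive IC50 and Ki")
  }
  ic50 / (1 + 0.3 * ic50 / ki)
}

#' Parse point-mutation annotations
#'
#' Accepts strings like `"A123T"`, `"A123T,C200W"`, separated by commas,
#' semicolons or whitespace. Returns a tibble of substitutions or raises a
#' parse error (callers route failing records to the rejection log).
#'
#' @param text A single annotation string; `NA` or `""` means no mutations.
#' @return Tibble with columns `ref` (single letter), `position` (1-based),
#'   `alt` (single letter); zero rows when there are none.
#' @export
parse_mutations <- function(text) {
  empty <- tibble::tibble(ref = character(), position = integer(),
                          alt = character())
  if (length(text) != 1) rlang::abort("parse_mutations takes one string")
  if (is.na(text) || !nzchar(trimws(text))) return(empty)
  parts <- strsplit(trimws(text), "[,;[:space:]]+")[[1]]
  parts <- parts[nzchar(parts)]
  m <- regmatches(parts, regexec("^([A-Za-z])([0-9]+)([A-Za-z])$", parts))
  ok <- lengths(m) == 4
  if (!all(ok)) {
    rlang::abort(paste0("unparseable mutation annotation: ",
                        paste(parts[!ok], collapse = ", ")))
  }
  out <- tibble::tibble(
    ref = toupper(vapply(m, `[`, "", 2)),
    position = as.integer(vapply(m, `[`, "", 3)),
    alt = toupper(vapply(m, `[`, "", 4))
  )
  if (any(out$position < 1)) rlang::abort("mutation positions are 1-based")
  if (any(out$ref == out$alt)) {
    rlang::abort("mutation with identical reference and alternate residue")
  }
  out
}

#' Apply point mutations to a protein sequence
#'
#' Each substitution is checked against the sequence: the residue at the
#' stated position must equal the annotated reference residue. A mismatch or
#' out-of-range position raises an error naming the offending mutation, so the
#' record can be routed to the rejection log instead of being silently patched.
#'
#' @param sequence Amino-acid sequence (one string).
#' @param mutations Tibble as returned by [parse_mutations()].
#' @return The mutated sequence; length unchanged.
#' @examples
#' apply_mutations("ACDEF", parse_mutations("C2W"))  # "AWDEF"
#' @export
apply_mutations <- function(sequence, mutations) {
  if (length(sequence) != 1 || is.na(sequence)) {
    rlang::abort("apply_mutations takes one sequence")
  }
  if (nrow(mutations) == 0) return(sequence)
  chars <- strsplit(sequence, "")[[1]]
  for (i in seq_len(nrow(mutations))) {
    pos <- mutations$position[i]
    tag <- paste0(mutations$ref[i], pos, mutations$alt[i])
    if (pos > length(chars)) {
      rlang::abort(paste0("mutation ", tag, " beyond sequence length ",
                          length(chars)))
    }
    if (chars[pos] != mutations$ref[i]) {
      rlang::abort(paste0("mutation ", tag, " reference mismatch: sequence has ",
                          chars[pos], " at position ", pos))
    }
    chars[pos] <- mutations$alt[i]
  }
  paste(chars, collapse = "")
}

#' Canonicalize SMILES strings
#'
#' Maps every notation of the same molecular graph to one canonical string
#' (OpenBabel canonical SMILES, via ChemmineOB), so that replicate
#' measurements of one ligand group together. Unparseable input yields `NA`,
#' which the curation filter consumes as the invalid-SMILES marker.
#'
#' @param smiles Character vector of SMILES strings.
#' @return Character vector of canonical SMILES, `NA` where invalid.
#' @examples
#' \donttest{standardize_smiles(c("OCC", "CCO"))  # identical canonical forms}
#' @export
standardize_smiles <- function(smiles) {
  vapply(as.character(smiles), function(s) {
    if (is.na(s) || !nzchar(trimws(s))) return(NA_character_)
    out <- tryCatch(
      suppressWarnings(ChemmineOB::convertFormat("SMI", "CAN", s)),
      error = function(e) ""
    )
    out <- trimws(strsplit(out, "[\t\n]")[[1]][1])
    if (is.na(out) || !nzchar(out)) NA_character_ else out
  }, character(1), USE.NAMES = FALSE)
}
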
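EVIDENCE_STRENGTHS <- c("supporting", "moderate", "strong", "stand_alone")

#' Construct evidence items
#'
#' An evidence item is an applied ACMG/AMP code with a direction and an
#' assigned (possibly modified) strength, e.g. PS4 applied at moderate.
#' Codes outside the seven evaluated by this package are accepted as
#' generic items for [combine_evidence()].
#'
#' @param code Character vector of ACMG code names (e.g. `"PS4"`).
#' @param direction `"pathogenic"` or `"benign"` (recycled).
#' @param strength One of `"supporting"`, `"moderate"`, `"strong"`,
#'   `"stand_alone"` (recycled).
#' @param rationale Optional explanation strings (recycled).
#' @return A tibble with columns `code`, `direction`, `strength`,
#'   `rationale`.
#' @examples
#' evidence_item("PS4", "pathogenic", "moderate")
#' @export
evidence_item <- function(code, direction, strength, rationale = NA_character_) {
  n <- length(code)
  direction <- rep_len(direction, n)
  strength <- rep_len(strength, n)
  if (!all(direction %in% c("pathogenic", "benign"))) {
    rlang::abort("direction must be \"pathogenic\" or \"benign\"",
                 class = "mtlhon_evidence_error")
  }
  if (!all(strength %in% EVIDENCE_STRENGTHS)) {
    rlang::abort(sprintf("strength must be one of %s",
                         paste(EVIDENCE_STRENGTHS, collapse = "/")),
                 class = "mtlhon_evidence_error")
  }
  tibble::tibble(code = code, direction = direction, strength = strength,
                 rationale = rep_len(rationale, n))
}

no_evidence <- function() {
  evidence_item(character(), character(), character(), character())
}

# default strength implied by a code's letter class; used to decide whether
# a strength modifier is printed (PS4 at moderate -> "PS4_moderate")
code_default_strength <- function(code) {
  cls <- substr(code, 2, 2)
  unname(c(A = "stand_alone", S = "strong", M = "moderate", P = "supporting")[cls])
}

#' Render applied codes with strength modifiers
#'
#' @param items An evidence-item tibble.
#' @return A single semicolon-joined string, e.g.
#'   `"BS1;PP3;PS4_moderate"`; strengths are printed only when they differ
#'   from the code's default letter strength.
#' @export
format_evidence_codes <- function(items) {
  if (nrow(items) == 0L) return("")
  lab <- ifelse(items$strength == code_default_strength(items$code),
                items$code,
                paste0(items$code, "_", items$strength))
  paste(lab, collapse = ";")
}

#' Evaluate the frequency codes BS1/BA1
#'
#' Applies BA1 (benign, stand-alone) when the maximum population frequency
#' across sources is at or above the BA1 cutoff, else BS1 (benign, strong)
#' when it exceeds the BS1 cutoff.  Records without frequency sources
#' yield no item.
#'
#' @param record A single snapshot row.
#' @param config An [engine_config()].
#' @return An evidence-item tibble with zero or one row.
#' @export
evaluate_bs1 <- function(record, config = engine_config()) {
  stopifnot(nrow(record) == 1L)
  f <- record$frequencies[[1]]
  if (length(f) == 0L) return(no_evidence())
  fmax <- max(f)
  src <- names(f)[which.max(f)]
  if (fmax >= config$ba1_threshold_percent) {
    evidence_item("BA1", "benign", "stand_alone",
                  glue::glue("maximum population frequency {fmax}% ({src}) at or above {config$ba1_threshold_percent}%"))
  } else if (fmax > config$bs1_threshold_percent) {
    evidence_item("BS1", "benign", "strong",
                  glue::glue("maximum population frequency {fmax}% ({src}) above {config$bs1_threshold_percent}%"))
  } else {
    no_evidence()
  }
}

#' Evaluate the in-silico code PP3
#'
#' PP3 (pathogenic, supporting) when the APOGEE score strictly exceeds the
#' configured threshold; absent scores disable PP3.
#'
#' @inheritParams evaluate_bs1
#' @return An evidence-item tibble with zero or one row.
#' @export
evaluate_pp3 <- function(record, config = engine_config()) {
  stopifnot(nrow(record) == 1L)
  s <- record$apogee_score
  if (is.na(s) || s <= config$pp3_apogee_threshold) return(no_evidence())
  evidence_item("PP3", "pathogenic", "supporting",
                glue::glue("APOGEE score {s} above {config$pp3_apogee_threshold}"))
}

#' Evaluate the proband-prevalence code PS4
#'
#' Strength ladder on the unrelated-proband count: at least 16 probands
#' (default) applies PS4 at strong, at least 4 at moderate, at least 2 at
#' supporting.
#'
#' @inheritParams evaluate_bs1
#' @return An evidence-item tibble with zero or one row.
#' @export
evaluate_ps4 <- function(record, config = engine_config()) {
  stopifnot(nrow(record) == 1L)
  n <- record$proband_count
  strength <-
    if (n >= config$ps4_strong_min_probands) "strong"
    else if (n >= config$ps4_moderate_min_probands) "moderate"
    else if (n >= config$ps4_supporting_min_probands) "supporting"
    else return(no_evidence())
  evidence_item("PS4", "pathogenic", strength,
                glue::glue("variant present in {n} unrelated probands"))
}

#' Evaluate the functional-evidence code PS3
#'
#' PS3 at the strength recorded in the snapshot's `functional_strength`
#' field (a pass-through of the curated functional-data assessment);
#' `"none"` yields no item.
#'
#' @param record A single snapshot row.
#' @return An evidence-item tibble with zero or one row.
#' @export
evaluate_ps3 <- function(record) {
  stopifnot(nrow(record) == 1L)
  s <- record$functional_strength
  if (s == "none") return(no_evidence())
  evidence_item("PS3", "pathogenic", s,
                glue::glue("curated functional evidence at {s} strength"))
}

#' Evaluate the phenotype-specificity code PP4
#'
#' PP4 (pathogenic, supporting) when the curated record marks the variant
#' as supported by a highly disease-specific phenotype AND the patient
#' under classification carries that phenotype flag.
#'
#' @param record A single snapshot row.
#' @param patient_phenotype Logical; the patient-level phenotype flag.
#' @return An evidence-item tibble with zero or one row.
#' @export
evaluate_pp4 <- function(record, patient_phenotype = TRUE) {
  stopifnot(nrow(record) == 1L)
  if (!isTRUE(record$phenotype_specific_supported) || !isTRUE(patient_phenotype)) {
    return(no_evidence())
  }
  evidence_item("PP4", "pathogenic", "supporting",
                "patient phenotype highly specific for the disease")
}

#' Evaluate the same-residue code PM5
#'
#' PM5 (pathogenic, moderate) when a different missense change at the same
#' residue is established pathogenic.
#'
#' @param record A single snapshot row.
#' @return An evidence-item tibble with zero or one row.
#' @export
evaluate_pm5 <- function(record) {
  stopifnot(nrow(record) == 1L)
  if (is.na(record$same_residue_pathogenic)) return(no_evidence())
  evidence_item("PM5", "pathogenic", "moderate",
                glue::glue("known pathogenic change {record$same_residue_pathogenic} at the same residue"))
}
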
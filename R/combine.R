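#' Five-tier classification levels
#'
#' @return Character vector of tiers in increasing pathogenicity order.
#' @export
classification_tiers <- function() {
  c("benign", "likely_benign", "VUS", "likely_pathogenic", "pathogenic")
}

# qualifying level of the pathogenic-side evidence alone:
# "pathogenic", "likely_pathogenic" or NA. Strengths are the ASSIGNED ones
# (a PS code applied at moderate counts as moderate).
pathogenic_side_level <- function(n_strong, n_moderate, n_supporting) {
  S <- n_strong; M <- n_moderate; Su <- n_supporting
  if (S >= 2 ||
      (S == 1 && (M >= 3 ||
                  (M == 2 && Su >= 2) ||
                  (M == 1 && Su >= 4)))) {
    return("pathogenic")
  }
  if ((S == 1 && (M >= 1 || Su >= 2)) ||
      M >= 3 ||
      (M == 2 && Su >= 2) ||
      (M == 1 && Su >= 4)) {
    return("likely_pathogenic")
  }
  NA_character_
}

benign_side_level <- function(stand_alone, n_strong, n_supporting) {
  if (stand_alone || n_strong >= 2) return("benign")
  if ((n_strong == 1 && n_supporting >= 1) || n_supporting >= 2) {
    return("likely_benign")
  }
  NA_character_
}

#' Combine applied evidence into a five-tier classification
#'
#' Applies the standard ACMG/AMP combining-rule table to a multiset of
#' evidence items, counting each item at its assigned strength (so
#' PS4 applied at moderate counts as one moderate item).  When both a
#' pathogenic-side and a benign-side combination are met the result is
#' VUS; when neither is met the result is VUS.  A lone benign-strong item
#' that satisfies no benign combination does not veto a met pathogenic
#' combination — the reading required to classify a variant
#' likely-pathogenic despite an applied BS1.  Deterministic and invariant
#' to item order.
#'
#' @param items An evidence-item tibble from [evidence_item()].
#' @return A single tier string from [classification_tiers()].
#' @examples
#' combine_evidence(dplyr::bind_rows(
#'   evidence_item("BS1", "benign", "strong"),
#'   evidence_item("PP3", "pathogenic", "supporting"),
#'   evidence_item("PS4", "pathogenic", "moderate")
#' ))
#' @export
combine_evidence <- function(items) {
  if (nrow(items) == 0L) return("VUS")
  path <- items[items$direction == "pathogenic", ]
  ben <- items[items$direction == "benign", ]
  p_level <- pathogenic_side_level(
    sum(path$strength == "strong") + sum(path$strength == "stand_alone"),
    sum(path$strength == "moderate"),
    sum(path$strength == "supporting")
  )
  b_level <- benign_side_level(
    any(ben$strength == "stand_alone"),
    sum(ben$strength == "strong"),
    # ACMG defines no benign-moderate class; any such generic item counts
    # conservatively as supporting
    sum(ben$strength %in% c("supporting", "moderate"))
  )
  if (is.na(p_level) && is.na(b_level)) return("VUS")
  if (!is.na(p_level) && !is.na(b_level)) return("VUS")
  if (!is.na(p_level)) p_level else b_level
}

# would one additional pathogenic item (of any strength) lift the
# pathogenic side to likely_pathogenic or better?
near_likely_pathogenic <- function(items) {
  path <- items[items$direction == "pathogenic", ]
  S <- sum(path$strength %in% c("strong", "stand_alone"))
  M <- sum(path$strength == "moderate")
  Su <- sum(path$strength == "supporting")
  for (add in list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))) {
    if (!is.na(pathogenic_side_level(S + add[1], M + add[2], Su + add[3]))) {
      return(TRUE)
    }
  }
  FALSE
}
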
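#' Classify mtDNA variants against an evidence snapshot
#'
#' Runs the full mtDNA ACMG/AMP evaluation for each variant: the frequency
#' codes BS1/BA1, in-silico PP3, functional PS3, phenotype-specificity PP4
#' (requires both the curated record flag and the patient-level phenotype
#' flag), same-residue PM5 and proband-prevalence PS4 with strength
#' modifiers, then combines the applied items into a five-tier verdict.
#' Variants absent from the snapshot are VUS with an empty evidence trail.
#' A VUS whose pathogenic-side evidence would reach likely-pathogenic with
#' one additional pathogenic item is annotated `"VUS_likely pathogenic"` in
#' `vus_note`; the annotation is metadata and never changes the tier.
#'
#' @param variants Character vector of variant labels, or a tibble from
#'   [parse_mt_variants()].
#' @param snapshot A snapshot tibble from [load_snapshot()].
#' @param config An [engine_config()].
#' @param phenotype_specific Logical vector (recycled): per-variant
#'   patient-level phenotype flag gating PP4.
#' @param reference Optional reference string from [read_mt_reference()];
#'   when supplied, a `protein_change` column is added.
#' @return A tibble with one row per variant: `variant`, `gene`, `tier`
#'   (factor ordered by [classification_tiers()]), `codes`
#'   (semicolon-joined applied codes with strength modifiers), `vus_note`,
#'   `applied` (list-column of evidence-item tibbles) and `rationale`
#'   (list-column of per-item explanations); plus `protein_change` when a
#'   reference is supplied.
#' @examples
#' snap <- load_snapshot(lhon_snapshot_path())
#' classify_variants("m.11253T>C", snap)
#' @export
classify_variants <- function(variants, snapshot,
                              config = engine_config(),
                              phenotype_specific = FALSE,
                              reference = NULL) {
  v <- if (is.character(variants)) parse_mt_variants(variants) else variants
  phen <- rep_len(as.logical(phenotype_specific), nrow(v))
  rows <- vector("list", nrow(v))
  for (i in seq_len(nrow(v))) {
    record <- lookup_evidence(snapshot, v$variant[i])
    items <- if (nrow(record) == 0L) {
      no_evidence()
    } else {
      dplyr::bind_rows(
        evaluate_bs1(record, config),
        evaluate_pp3(record, config),
        evaluate_ps3(record),
        evaluate_pp4(record, phen[i]),
        evaluate_pm5(record),
        evaluate_ps4(record, config)
      )
    }
    tier <- combine_evidence(items)
    note <- if (tier == "VUS" && nrow(items) > 0L && near_likely_pathogenic(items)) {
      "VUS_likely pathogenic"
    } else {
      NA_character_
    }
    rows[[i]] <- tibble::tibble(
      variant = v$variant[i],
      gene = v$gene[i],
      tier = tier,
      codes = format_evidence_codes(items),
      vus_note = note,
      applied = list(items[, c("code", "direction", "strength")]),
      rationale = list(items$rationale)
    )
  }
  out <- dplyr::bind_rows(rows)
  out$tier <- factor(out$tier, levels = classification_tiers(), ordered = TRUE)
  if (!is.null(reference)) {
    pc <- translate_consequence(v, reference)
    out <- dplyr::mutate(out, protein_change = pc$protein_change,
                         .after = "gene")
  }
  out
}

#' Render a classification report
#'
#' Flattens a [classify_variants()] result to plain columns for TSV
#' output: one row per variant with label, gene, optional protein change,
#' applied codes, tier and VUS note.
#'
#' @param classifications Tibble from [classify_variants()].
#' @param path Optional output TSV path; when given the report is written.
#' @return The report tibble (invisibly when `path` is given).
#' @export
classification_report <- function(classifications, path = NULL) {
  keep <- intersect(
    c("variant", "gene", "protein_change", "tier", "codes", "vus_note"),
    names(classifications)
  )
  rep <- dplyr::mutate(classifications[, keep], tier = as.character(.data$tier))
  if (!is.null(path)) {
    readr::write_tsv(rep, path)
    return(invisible(rep))
  }
  rep
}
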
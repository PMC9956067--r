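#' Summarise a screening cohort
#'
#' Computes the cohort-level statistics of the screening study design:
#' diagnostic yield, per-gene attribution of causal variants,
#' familial/sporadic breakdown, the full variant spectrum and
#' haplogroup-marker counts.  All percentages are integers rounded half
#' away from zero (20 of 32 diagnosed by *MT-ND4* prints as 63%).
#'
#' @param cohort A cohort tibble.
#' @param snapshot A snapshot tibble.
#' @param mode Diagnosis mode passed to [diagnose_patients()];
#'   `"mitomap_status"` (default) follows the MitoMap disease-causing
#'   flag, `"acmg_tier"` requires a likely-pathogenic-or-worse ACMG
#'   classification.
#' @param config An [engine_config()].
#' @return An object of class `lhon_cohort_summary`: a list with
#'   `n_patients`, `n_diagnosed`, `yield_percent`, `gene_attribution`
#'   (tibble gene/count/percent-of-diagnosed), `familial_yield`
#'   (named vector diagnosed/total), `sporadic_yield_percent`,
#'   `n_variant_carriers`, `spectrum` (tibble), `haplogroup_counts`
#'   (tibble tag/patients/percent), `patients` (the per-patient diagnosis
#'   table) and `mode`.
#' @examples
#' summarize_cohort(fixture_argentina(), argentina_snapshot())
#' @export
summarize_cohort <- function(cohort, snapshot,
                             mode = c("mitomap_status", "acmg_tier"),
                             config = engine_config()) {
  mode <- match.arg(mode)
  validate_cohort(cohort)
  if (nrow(cohort) == 0L) {
    rlang::abort("empty cohort: percentages are undefined",
                 class = "mtlhon_cohort_error")
  }
  diag <- diagnose_patients(cohort, snapshot, mode, config)
  n_patients <- nrow(diag)
  n_diagnosed <- sum(diag$diagnosed)

  attribution <- dplyr::count(diag[diag$diagnosed, ], .data$causal_gene,
                              name = "count")
  names(attribution)[1] <- "gene"
  attribution$percent <- if (n_diagnosed > 0) {
    round_half_up(100 * attribution$count / n_diagnosed)
  } else {
    integer()
  }

  fam <- diag[diag$familial, ]
  spo <- diag[!diag$familial, ]
  spectrum <- spectrum_table(cohort)

  tags <- tag_haplogroup_markers(cohort, snapshot)
  tag_long <- tidyr::unnest_longer(tags, "tags", values_to = "tag")
  hg <- dplyr::count(tag_long[!is.na(tag_long$tag), ], .data$tag,
                     name = "patients")
  hg$percent <- round_half_up(100 * hg$patients / n_patients)

  structure(
    list(
      n_patients = n_patients,
      n_diagnosed = n_diagnosed,
      yield_percent = round_half_up(100 * n_diagnosed / n_patients),
      gene_attribution = attribution,
      familial_yield = c(diagnosed = sum(fam$diagnosed), total = nrow(fam)),
      sporadic_yield_percent = if (nrow(spo) > 0) {
        round_half_up(100 * sum(spo$diagnosed) / nrow(spo))
      } else {
        NA_integer_
      },
      n_variant_carriers = length(unique(
        cohort$patient_id[!is.na(cohort$variant)]
      )),
      spectrum = spectrum,
      haplogroup_counts = hg,
      patients = diag,
      mode = mode
    ),
    class = "lhon_cohort_summary"
  )
}

#' @export
print.lhon_cohort_summary <- function(x, ...) {
  cat(sprintf("<LHON cohort summary | %s mode>\n", x$mode))
  cat(sprintf("  patients screened: %d (%d carry >=1 variant)\n",
              x$n_patients, x$n_variant_carriers))
  cat(sprintf("  diagnosed: %d (%d%%)\n", x$n_diagnosed, x$yield_percent))
  for (i in seq_len(nrow(x$gene_attribution))) {
    g <- x$gene_attribution[i, ]
    cat(sprintf("    %s: %d/%d (%d%%)\n", g$gene, g$count, x$n_diagnosed,
                g$percent))
  }
  cat(sprintf("  familial: %d/%d diagnosed; sporadic yield: %s%%\n",
              x$familial_yield[["diagnosed"]], x$familial_yield[["total"]],
              x$sporadic_yield_percent))
  cat(sprintf("  distinct variants: %d; haplogroup markers: %s\n",
              nrow(x$spectrum),
              paste(sprintf("%s=%d", x$haplogroup_counts$tag,
                            x$haplogroup_counts$patients), collapse = " ")))
  invisible(x)
}

#' Tidy a cohort summary
#'
#' Broom-style accessor: per-gene attribution of causal variants, one row
#' per gene with count and integer percent of diagnosed patients.
#'
#' @param x An `lhon_cohort_summary`.
#' @param ... Unused.
#' @return A tibble with columns `gene`, `count`, `percent`.
#' @method tidy lhon_cohort_summary
#' @export
tidy.lhon_cohort_summary <- function(x, ...) {
  x$gene_attribution
}

#' Glance at a cohort summary
#'
#' @param x An `lhon_cohort_summary`.
#' @param ... Unused.
#' @return A one-row tibble of the scalar cohort statistics.
#' @method glance lhon_cohort_summary
#' @export
glance.lhon_cohort_summary <- function(x, ...) {
  tibble::tibble(
    n_patients = x$n_patients,
    n_diagnosed = x$n_diagnosed,
    yield_percent = x$yield_percent,
    familial_diagnosed = x$familial_yield[["diagnosed"]],
    familial_total = x$familial_yield[["total"]],
    sporadic_yield_percent = x$sporadic_yield_percent,
    n_variants = nrow(x$spectrum),
    n_variant_carriers = x$n_variant_carriers,
    mode = x$mode
  )
}

#' Plot a cohort summary
#'
#' Two-panel figure in the style of a screening-study overview: overall
#' diagnostic yield split by familial/sporadic status, and per-gene
#' attribution of the causal variants among diagnosed patients.
#'
#' @param object An `lhon_cohort_summary`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot lhon_cohort_summary
#' @export
autoplot.lhon_cohort_summary <- function(object, ...) {
  fam <- object$familial_yield
  spo_total <- object$n_patients - fam[["total"]]
  spo_diag <- object$n_diagnosed - fam[["diagnosed"]]
  yield <- tibble::tibble(
    panel = "diagnostic yield",
    category = c("familial", "sporadic"),
    percent = c(
      if (fam[["total"]] > 0) round_half_up(100 * fam[["diagnosed"]] / fam[["total"]]) else NA_integer_,
      if (spo_total > 0) round_half_up(100 * spo_diag / spo_total) else NA_integer_
    )
  )
  genes <- dplyr::mutate(object$gene_attribution,
                         panel = "causal gene (% of diagnosed)")
  dat <- dplyr::bind_rows(
    yield,
    tibble::tibble(panel = genes$panel, category = genes$gene,
                   percent = genes$percent)
  )
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$category, y = .data$percent)) +
    ggplot2::geom_col(fill = "grey25") +
    ggplot2::geom_text(ggplot2::aes(label = paste0(.data$percent, "%")),
                       vjust = -0.4, size = 3) +
    ggplot2::facet_wrap(~.data$panel, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "percent of patients") +
    ggplot2::theme_minimal()
}

#' Write a cohort summary report
#'
#' Emits the summary as TSV files (glance, gene attribution, spectrum,
#' haplogroup counts, per-patient diagnoses) plus a human-readable
#' `summary.txt`, all into one directory.
#'
#' @param summary An `lhon_cohort_summary`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort_report <- function(summary, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_tsv(glance(summary), file.path(dir, "summary.tsv"))
  readr::write_tsv(summary$gene_attribution, file.path(dir, "gene_attribution.tsv"))
  readr::write_tsv(summary$spectrum, file.path(dir, "spectrum.tsv"))
  readr::write_tsv(summary$haplogroup_counts, file.path(dir, "haplogroups.tsv"))
  readr::write_tsv(summary$patients, file.path(dir, "patients.tsv"))
  txt <- utils::capture.output(print(summary))
  writeLines(txt, file.path(dir, "summary.txt"))
  invisible(dir)
}
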
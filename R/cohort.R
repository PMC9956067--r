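#' Read a cohort call table
#'
#' Reads the TSV cohort dialect: header
#' `patient_id  variant  heteroplasmy_fraction  familial  phenotype_specific`,
#' one row per (patient, variant) call.  Patients screened with no
#' detected variant appear as a single row with an empty `variant` field.
#' Variant labels are normalised through the parser.
#'
#' @param path Path to a TSV file.
#' @return A cohort tibble.
#' @export
read_cohort_tsv <- function(path) {
  raw <- readr::read_tsv(
    path,
    col_types = readr::cols(
      patient_id = readr::col_character(),
      variant = readr::col_character(),
      heteroplasmy_fraction = readr::col_double(),
      familial = readr::col_logical(),
      phenotype_specific = readr::col_logical()
    )
  )
  has_call <- !is.na(raw$variant) & raw$variant != ""
  if (any(has_call)) {
    parsed <- parse_mt_variants(raw$variant[has_call],
                                raw$heteroplasmy_fraction[has_call])
    raw$variant[has_call] <- parsed$variant
  }
  raw$variant[!has_call] <- NA_character_
  validate_cohort(raw)
}

#' Write a cohort call table
#'
#' @param cohort A cohort tibble.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_cohort_tsv <- function(cohort, path) {
  readr::write_tsv(cohort, path)
  invisible(path)
}

validate_cohort <- function(cohort) {
  needed <- c("patient_id", "variant", "heteroplasmy_fraction",
              "familial", "phenotype_specific")
  missing <- setdiff(needed, names(cohort))
  if (length(missing) > 0L) {
    rlang::abort(sprintf("cohort table lacks column(s): %s",
                         paste(missing, collapse = ", ")),
                 class = "mtlhon_cohort_error")
  }
  calls <- cohort[!is.na(cohort$variant), ]
  dup <- calls[duplicated(calls[, c("patient_id", "variant")]), ]
  if (nrow(dup) > 0L) {
    rlang::abort(
      sprintf("duplicated call(s) within a patient: %s",
              paste(sprintf("%s/%s", dup$patient_id, dup$variant), collapse = ", ")),
      class = "mtlhon_cohort_error"
    )
  }
  cohort
}

#' Write a cohort as a multi-sample VCF
#'
#' Contig `MT`, 1-based positions on the rCRS frame, one sample column per
#' patient, `GT:HF` genotype fields where `HF` is the heteroplasmy
#' fraction (1 = homoplasmic).  Familial and phenotype flags are not part
#' of the VCF dialect; they travel in the TSV table or a sidecar.
#'
#' @param cohort A cohort tibble.
#' @param path Output VCF path (plain text).
#' @return `path`, invisibly.
#' @export
write_cohort_vcf <- function(cohort, path) {
  patients <- unique(cohort$patient_id)
  calls <- cohort[!is.na(cohort$variant), ]
  pv <- parse_mt_variants(calls$variant, calls$heteroplasmy_fraction)
  sites <- dplyr::distinct(pv[, c("variant", "position", "ref", "alt")])
  sites <- dplyr::arrange(sites, .data$position, .data$alt)
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=MT,length=%d>", RCRS_LENGTH),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=HF,Number=1,Type=Float,Description=\"Heteroplasmy fraction of the alternate allele\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", patients), collapse = "\t")
  )
  body <- character(nrow(sites))
  for (i in seq_len(nrow(sites))) {
    s <- sites[i, ]
    hit <- calls$variant == s$variant
    hf <- stats::setNames(calls$heteroplasmy_fraction[hit], calls$patient_id[hit])
    gt <- vapply(patients, function(p) {
      if (!p %in% names(hf)) "0:." else sprintf("1:%s", format(hf[[p]]))
    }, character(1))
    body[i] <- paste(c("MT", s$position, ".", s$ref, s$alt, ".", "PASS", ".",
                       "GT:HF", gt), collapse = "\t")
  }
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a cohort from VCF
#'
#' Accepts contig `MT` or `chrM`; multi-allelic records are split.  The
#' heteroplasmy fraction is taken from the `HF` FORMAT field when present
#' (absent: calls are treated as homoplasmic).  Familial and phenotype
#' flags are not represented in VCF and default to `FALSE`.
#'
#' @param path Path to a VCF file.
#' @return A cohort tibble.
#' @export
read_cohort_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  if (!all(fix$CHROM %in% c("MT", "chrM"))) {
    rlang::abort("VCF contig must be named MT or chrM",
                 class = "mtlhon_cohort_error")
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  hf <- tryCatch(vcfR::extract.gt(vcf, element = "HF", as.numeric = TRUE),
                 error = function(e) NULL)
  patients <- colnames(gt)
  rows <- list()
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    for (ai in seq_along(alts)) {
      carried <- !is.na(gt[i, ]) & gt[i, ] == as.character(ai)
      if (!any(carried)) next
      frac <- if (is.null(hf)) rep(1, sum(carried)) else {
        f <- hf[i, carried]
        ifelse(is.na(f), 1, f)
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        patient_id = patients[carried],
        variant = sprintf("m.%s%s>%s", fix$POS[i], fix$REF[i], alts[ai]),
        heteroplasmy_fraction = as.numeric(frac)
      )
    }
  }
  calls <- if (length(rows) > 0) dplyr::bind_rows(rows) else {
    tibble::tibble(patient_id = character(), variant = character(),
                   heteroplasmy_fraction = numeric())
  }
  if (nrow(calls) > 0) {
    calls$variant <- parse_mt_variants(calls$variant)$variant
  }
  no_call <- setdiff(patients, calls$patient_id)
  cohort <- dplyr::bind_rows(
    calls,
    tibble::tibble(patient_id = no_call, variant = NA_character_,
                   heteroplasmy_fraction = NA_real_)
  )
  cohort$familial <- FALSE
  cohort$phenotype_specific <- FALSE
  validate_cohort(dplyr::arrange(cohort, .data$patient_id))
}

# integer percent, rounding half away from zero (20/32 -> 63)
round_half_up <- function(x) {
  as.integer(sign(x) * floor(abs(x) + 0.5))
}

#' Identify the causal variant per patient
#'
#' In `mitomap_status` mode (the default) a patient is diagnosed iff they
#' carry at least one variant whose snapshot record is flagged
#' disease-causing in MitoMap.  In `acmg_tier` mode a patient is diagnosed
#' iff at least one carried variant classifies likely-pathogenic or
#' pathogenic under the ACMG engine (PP4 gated by the patient's phenotype
#' flag).  Among several qualifying variants the highest evidence tier
#' wins, ties broken by lowest position; the result is order-invariant in
#' the patient's variant list.
#'
#' @param cohort A cohort tibble.
#' @param snapshot A snapshot tibble.
#' @param mode `"mitomap_status"` or `"acmg_tier"`.
#' @param config An [engine_config()] (used in `acmg_tier` mode).
#' @return A tibble with one row per patient: `patient_id`, `familial`,
#'   `phenotype_specific`, `diagnosed`, `causal_variant`, `causal_gene`.
#' @examples
#' fx <- fixture_argentina()
#' head(diagnose_patients(fx, argentina_snapshot()))
#' @export
diagnose_patients <- function(cohort, snapshot,
                              mode = c("mitomap_status", "acmg_tier"),
                              config = engine_config()) {
  mode <- match.arg(mode)
  validate_cohort(cohort)
  patients <- dplyr::summarise(
    dplyr::group_by(cohort, .data$patient_id),
    familial = any(.data$familial),
    phenotype_specific = any(.data$phenotype_specific),
    .groups = "drop"
  )
  calls <- cohort[!is.na(cohort$variant), ]
  if (nrow(calls) == 0L) {
    return(dplyr::mutate(patients, diagnosed = FALSE,
                         causal_variant = NA_character_,
                         causal_gene = NA_character_))
  }

  if (mode == "mitomap_status") {
    status <- snapshot[, c("variant", "position", "mitomap_status")]
    qual <- dplyr::inner_join(calls, status, by = "variant")
    qual <- qual[qual$mitomap_status == "disease_causing", ]
    qual$rank <- 1L  # all qualifying variants share the status tier
  } else {
    combos <- dplyr::distinct(calls[, c("variant", "phenotype_specific")])
    cls <- classify_variants(combos$variant, snapshot, config,
                             phenotype_specific = combos$phenotype_specific)
    combos$tier <- cls$tier
    qual <- dplyr::inner_join(calls, combos,
                              by = c("variant", "phenotype_specific"))
    qual <- qual[qual$tier %in% c("likely_pathogenic", "pathogenic"), ]
    qual$rank <- -as.integer(qual$tier)  # higher tier first
    qual$position <- parse_mt_variants(qual$variant)$position
  }

  qual <- dplyr::arrange(qual, .data$rank, .data$position)
  causal <- qual[!duplicated(qual$patient_id), c("patient_id", "variant")]
  names(causal)[2] <- "causal_variant"

  out <- dplyr::left_join(patients, causal, by = "patient_id")
  out$diagnosed <- !is.na(out$causal_variant)
  out$causal_gene <- NA_character_
  has <- out$diagnosed
  if (any(has)) {
    out$causal_gene[has] <- parse_mt_variants(out$causal_variant[has])$gene
  }
  out
}

#' Variant spectrum of a cohort
#'
#' Counts patients (not call instances) carrying each distinct variant,
#' ordered by rCRS position.
#'
#' @param cohort A cohort tibble.
#' @return A tibble with columns `variant`, `position`, `gene`,
#'   `carriers`.
#' @examples
#' spectrum_table(fixture_argentina())
#' @export
spectrum_table <- function(cohort) {
  calls <- cohort[!is.na(cohort$variant), ]
  if (nrow(calls) == 0L) {
    return(tibble::tibble(variant = character(), position = integer(),
                          gene = character(), carriers = integer()))
  }
  counts <- dplyr::count(
    dplyr::distinct(calls[, c("patient_id", "variant")]),
    .data$variant, name = "carriers"
  )
  parsed <- parse_mt_variants(counts$variant)
  counts$position <- parsed$position
  counts$gene <- parsed$gene
  dplyr::arrange(counts[, c("variant", "position", "gene", "carriers")],
                 .data$position)
}

#' Tag patients with haplogroup-marker variants
#'
#' Union of the haplogroup tags attached to a patient's variants in the
#' snapshot; purely a lookup of the bundled marker associations
#' (m.3547A>G for B2; m.14318T>C and m.3552T>A for C; m.4248T>C for AE;
#' m.4216T>C for JT), no haplogroup inference.
#'
#' @param cohort A cohort tibble.
#' @param snapshot A snapshot tibble.
#' @return A tibble with one row per patient: `patient_id` and `tags`
#'   (list-column of sorted character vectors; empty when no marker is
#'   carried).
#' @export
tag_haplogroup_markers <- function(cohort, snapshot) {
  markers <- snapshot[!is.na(snapshot$haplogroup_tag),
                      c("variant", "haplogroup_tag")]
  calls <- dplyr::distinct(cohort[!is.na(cohort$variant),
                                  c("patient_id", "variant")])
  tagged <- dplyr::inner_join(calls, markers, by = "variant")
  per <- split(tagged$haplogroup_tag, tagged$patient_id)
  tibble::tibble(
    patient_id = unique(cohort$patient_id),
    tags = purrr::map(unique(cohort$patient_id),
                      function(p) sort(unique(per[[p]] %||% character())))
  )
}
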
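SNAPSHOT_HEADER <- "#%mtlhon-evidence-snapshot schema=1"

KNOWN_SNAPSHOT_FIELDS <- c(
  "variant", "mitomap_status", "apogee_score", "proband_count",
  "functional_strength", "phenotype_specific_supported",
  "same_residue_pathogenic", "haplogroup_tag", "genbank_frequency_table1"
)

FUNCTIONAL_STRENGTHS <- c("none", "supporting", "moderate", "strong")
MITOMAP_STATUSES <- c("disease_causing", "benign", "unreported")
HAPLOGROUP_TAGS <- c("B2", "C", "AE", "JT")

#' Load a curated evidence snapshot
#'
#' Reads the flat, line-oriented evidence file that stands in for live
#' MitoMap/ClinVar/gnomAD/Helix queries: one record per variant, blank-line
#' separated, `key: value` fields, a mandatory schema-version header line.
#' Population frequencies are stored as percentages (`freq_GenBank: 0.49`
#' means 0.49%), one `freq_<Source>` key per source.  Unknown fields are
#' preserved in the `extra` list-column and flagged with a message;
#' duplicated variant labels are an error.
#'
#' @param path Path to a snapshot file.
#' @return A tibble with one row per variant: `variant`, `position`,
#'   `mitomap_status`, `frequencies` (list-column of named numeric percent
#'   vectors), `apogee_score`, `proband_count`, `functional_strength`,
#'   `phenotype_specific_supported`, `same_residue_pathogenic`,
#'   `haplogroup_tag`, `genbank_frequency_table1`, `extra`.
#' @examples
#' snap <- load_snapshot(lhon_snapshot_path())
#' nrow(snap)
#' @export
load_snapshot <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L || !identical(lines[1], SNAPSHOT_HEADER)) {
    rlang::abort(
      sprintf("snapshot file must start with the header line \"%s\"",
              SNAPSHOT_HEADER),
      class = "mtlhon_snapshot_error"
    )
  }
  body <- lines[-1]
  body <- body[!grepl("^\\s*#", body)]
  # split into blank-line separated records
  grp <- cumsum(c(TRUE, body[-length(body)] == "")) * (body != "")
  recs <- split(body[body != ""], grp[body != ""])
  if (length(recs) == 0L) {
    rlang::warn("empty evidence snapshot: no records found")
    return(empty_snapshot())
  }
  rows <- purrr::map(recs, parse_snapshot_record)
  snap <- dplyr::bind_rows(rows)
  dup <- snap$variant[duplicated(snap$variant)]
  if (length(dup) > 0L) {
    rlang::abort(
      sprintf("duplicated variant label(s) in snapshot: %s",
              paste(unique(dup), collapse = ", ")),
      class = "mtlhon_snapshot_error"
    )
  }
  dplyr::arrange(snap, .data$position)
}

empty_snapshot <- function() {
  tibble::tibble(
    variant = character(), position = integer(),
    mitomap_status = character(), frequencies = list(),
    apogee_score = numeric(), proband_count = integer(),
    functional_strength = character(),
    phenotype_specific_supported = logical(),
    same_residue_pathogenic = character(), haplogroup_tag = character(),
    genbank_frequency_table1 = numeric(), extra = list()
  )
}

parse_snapshot_record <- function(lines) {
  m <- stringr::str_match(lines, "^([A-Za-z0-9_]+):\\s*(.*?)\\s*$")
  if (anyNA(m[, 1])) {
    rlang::abort(
      sprintf("malformed snapshot line: \"%s\"", lines[is.na(m[, 1])][1]),
      class = "mtlhon_snapshot_error"
    )
  }
  keys <- m[, 2]; vals <- m[, 3]
  if (anyDuplicated(keys)) {
    rlang::abort(
      sprintf("duplicated field \"%s\" in snapshot record %s",
              keys[duplicated(keys)][1], vals[keys == "variant"][1]),
      class = "mtlhon_snapshot_error"
    )
  }
  kv <- stats::setNames(as.list(vals), keys)
  if (is.null(kv$variant)) {
    rlang::abort("snapshot record without a \"variant\" field",
                 class = "mtlhon_snapshot_error")
  }
  parsed <- tryCatch(
    parse_mt_variants(kv$variant),
    error = function(e) {
      rlang::abort(
        sprintf("snapshot record \"%s\": unparseable variant label", kv$variant),
        class = "mtlhon_snapshot_error", parent = e
      )
    }
  )

  freq_keys <- grep("^freq_", keys, value = TRUE)
  freqs <- stats::setNames(
    as.numeric(unlist(kv[freq_keys])),
    sub("^freq_", "", freq_keys)
  )
  if (any(is.na(freqs) | freqs < 0)) {
    rlang::abort(
      sprintf("snapshot record \"%s\": frequencies must be non-negative percentages",
              kv$variant),
      class = "mtlhon_snapshot_error"
    )
  }

  status <- kv$mitomap_status %||% "unreported"
  fstr <- kv$functional_strength %||% "none"
  check_enum(status, MITOMAP_STATUSES, "mitomap_status", kv$variant)
  check_enum(fstr, FUNCTIONAL_STRENGTHS, "functional_strength", kv$variant)
  tag <- kv$haplogroup_tag
  if (!is.null(tag)) check_enum(tag, HAPLOGROUP_TAGS, "haplogroup_tag", kv$variant)

  unknown <- setdiff(keys, c(KNOWN_SNAPSHOT_FIELDS, freq_keys))
  if (length(unknown) > 0L) {
    rlang::inform(
      sprintf("snapshot record \"%s\": preserving unknown field(s) %s",
              kv$variant, paste(unknown, collapse = ", "))
    )
  }

  proband <- as.integer(kv$proband_count %||% 0L)
  if (is.na(proband) || proband < 0L) {
    rlang::abort(
      sprintf("snapshot record \"%s\": proband_count must be a non-negative integer",
              kv$variant),
      class = "mtlhon_snapshot_error"
    )
  }

  tibble::tibble(
    variant = parsed$variant,
    position = parsed$position,
    mitomap_status = status,
    frequencies = list(freqs),
    apogee_score = as.numeric(kv$apogee_score %||% NA_real_),
    proband_count = proband,
    functional_strength = fstr,
    phenotype_specific_supported =
      identical(tolower(kv$phenotype_specific_supported %||% "false"), "true"),
    same_residue_pathogenic = kv$same_residue_pathogenic %||% NA_character_,
    haplogroup_tag = tag %||% NA_character_,
    genbank_frequency_table1 = as.numeric(kv$genbank_frequency_table1 %||% NA_real_),
    extra = list(kv[unknown])
  )
}

check_enum <- function(value, allowed, field, variant) {
  if (!value %in% allowed) {
    rlang::abort(
      sprintf("snapshot record \"%s\": field %s must be one of %s (got \"%s\")",
              variant, field, paste(allowed, collapse = "/"), value),
      class = "mtlhon_snapshot_error"
    )
  }
  invisible(value)
}

#' Write an evidence snapshot in canonical form
#'
#' Serialises a snapshot tibble back to the flat text format read by
#' [load_snapshot()]: records ordered by position, fields in fixed order,
#' frequency sources alphabetical.  `write(load(x))` is the canonical form
#' of `x`.
#'
#' @param snapshot A snapshot tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_snapshot <- function(snapshot, path) {
  snapshot <- dplyr::arrange(snapshot, .data$position)
  fmt_num <- function(x) formatC(x, format = "fg", digits = 15)
  out <- c(SNAPSHOT_HEADER, "")
  for (i in seq_len(nrow(snapshot))) {
    r <- snapshot[i, ]
    lines <- c(sprintf("variant: %s", r$variant),
               sprintf("mitomap_status: %s", r$mitomap_status))
    f <- r$frequencies[[1]]
    for (src in sort(names(f), method = "radix")) {
      lines <- c(lines, sprintf("freq_%s: %s", src, fmt_num(f[[src]])))
    }
    if (!is.na(r$genbank_frequency_table1)) {
      lines <- c(lines, sprintf("genbank_frequency_table1: %s",
                                fmt_num(r$genbank_frequency_table1)))
    }
    if (!is.na(r$apogee_score)) {
      lines <- c(lines, sprintf("apogee_score: %s", fmt_num(r$apogee_score)))
    }
    if (r$proband_count > 0L) {
      lines <- c(lines, sprintf("proband_count: %d", r$proband_count))
    }
    if (r$functional_strength != "none") {
      lines <- c(lines, sprintf("functional_strength: %s", r$functional_strength))
    }
    if (isTRUE(r$phenotype_specific_supported)) {
      lines <- c(lines, "phenotype_specific_supported: true")
    }
    if (!is.na(r$same_residue_pathogenic)) {
      lines <- c(lines, sprintf("same_residue_pathogenic: %s",
                                r$same_residue_pathogenic))
    }
    if (!is.na(r$haplogroup_tag)) {
      lines <- c(lines, sprintf("haplogroup_tag: %s", r$haplogroup_tag))
    }
    ex <- r$extra[[1]]
    for (k in names(ex)) lines <- c(lines, sprintf("%s: %s", k, ex[[k]]))
    out <- c(out, lines, "")
  }
  writeLines(out, path)
  invisible(path)
}

#' Export a snapshot to TSV for spreadsheet review
#'
#' One row per variant, frequency sources spread into `freq_<Source>`
#' columns.
#'
#' @param snapshot A snapshot tibble.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
export_snapshot_tsv <- function(snapshot, path) {
  freq_long <- tidyr::unnest_longer(
    dplyr::select(snapshot, "variant", "frequencies"),
    "frequencies", values_to = "percent", indices_to = "source"
  )
  freq_wide <- if (nrow(freq_long) > 0) {
    tidyr::pivot_wider(freq_long, names_from = "source",
                       values_from = "percent", names_prefix = "freq_")
  } else {
    tibble::tibble(variant = character())
  }
  flat <- dplyr::left_join(
    dplyr::select(snapshot, -"frequencies", -"extra"),
    freq_wide, by = "variant"
  )
  readr::write_tsv(flat, path)
  invisible(path)
}

#' Look up evidence for variants
#'
#' Exact-label match into a loaded snapshot.  Absence is a first-class
#' outcome: unmatched variants yield zero rows and are treated as
#' unreported downstream.
#'
#' @param snapshot A snapshot tibble from [load_snapshot()].
#' @param variant Character vector of canonical variant labels.
#' @return The matching snapshot rows (zero rows when absent).
#' @examples
#' snap <- load_snapshot(lhon_snapshot_path())
#' lookup_evidence(snap, "m.3460G>A")
#' @export
lookup_evidence <- function(snapshot, variant) {
  snapshot[snapshot$variant %in% variant, , drop = FALSE]
}

#' Maximum population frequency across sources
#'
#' @param snapshot A snapshot tibble (one or more rows).
#' @return Numeric vector of per-record maxima, in percent.  Records with
#'   no frequency sources are an error (distinct from a frequency of 0).
#' @examples
#' snap <- load_snapshot(lhon_snapshot_path())
#' max_frequency(lookup_evidence(snap, "m.11253T>C"))
#' @export
max_frequency <- function(snapshot) {
  purrr::map_dbl(seq_len(nrow(snapshot)), function(i) {
    f <- snapshot$frequencies[[i]]
    if (length(f) == 0L) {
      rlang::abort(
        sprintf("record %s has no frequency sources", snapshot$variant[i]),
        class = "mtlhon_evidence_error"
      )
    }
    max(f)
  })
}

#' Path to the bundled Argentinean-cohort evidence snapshot
#' @return File path inside the installed package.
#' @export
lhon_snapshot_path <- function() {
  system.file("extdata", "evidence_snapshot.txt", package = "mtlhon",
              mustWork = TRUE)
}

#' The bundled evidence snapshot, loaded
#'
#' Convenience wrapper: `load_snapshot(lhon_snapshot_path())`.
#' @return A snapshot tibble of 54 records.
#' @export
argentina_snapshot <- function() {
  load_snapshot(lhon_snapshot_path())
}

`%||%` <- function(a, b) if (is.null(a)) b else a
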
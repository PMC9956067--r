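#' Parse mtDNA variant notation
#'
#' Parses substitution variants written in the conventional mitochondrial
#' "m." notation, e.g. `"m.11778G>A"`, onto the rCRS coordinate frame.
#' A single optional run of spaces between the position and the reference
#' base is tolerated (`"m.14484 T>C"` is the same variant as
#' `"m.14484T>C"`); the returned `variant` label is always canonical, with
#' no internal whitespace.  Only single-nucleotide substitutions are
#' supported; indels are rejected.
#'
#' @param x Character vector of variant labels.
#' @param heteroplasmy_fraction Numeric vector (recycled) of mutant-mtDNA
#'   fractions in `[0, 1]`; `1` means homoplasmic (the default).
#' @return A tibble with one row per input: `variant` (canonical label),
#'   `position`, `ref`, `alt`, `gene`, `heteroplasmy_fraction`.
#' @examples
#' parse_mt_variants(c("m.11778G>A", "m.14484 T>C"))
#' @export
parse_mt_variants <- function(x, heteroplasmy_fraction = 1) {
  x <- as.character(x)
  m <- stringr::str_match(trimws(x), "^m\\.(\\d+) *([ACGT])>([ACGT])$")
  bad <- is.na(m[, 1])
  if (any(bad)) {
    rlang::abort(
      sprintf(
        "malformed mtDNA variant label%s: %s (expected \"m.<pos><ref>><alt>\" with single-base alleles)",
        if (sum(bad) > 1) "s" else "",
        paste(sprintf("\"%s\"", x[bad]), collapse = ", ")
      ),
      class = "mtlhon_parse_error"
    )
  }
  position <- as.integer(m[, 2])
  oor <- position < 1L | position > RCRS_LENGTH
  if (any(oor)) {
    rlang::abort(
      sprintf(
        "position out of rCRS range [1, %d] in: %s",
        RCRS_LENGTH, paste(sprintf("\"%s\"", x[oor]), collapse = ", ")
      ),
      class = "mtlhon_parse_error"
    )
  }
  same <- m[, 3] == m[, 4]
  if (any(same)) {
    rlang::abort(
      sprintf(
        "reference and alternate allele are identical in: %s",
        paste(sprintf("\"%s\"", x[same]), collapse = ", ")
      ),
      class = "mtlhon_parse_error"
    )
  }
  hf <- rep_len(as.numeric(heteroplasmy_fraction), length(x))
  if (any(!is.na(hf) & (hf < 0 | hf > 1))) {
    rlang::abort("heteroplasmy_fraction must lie in [0, 1]",
                 class = "mtlhon_parse_error")
  }
  tibble::tibble(
    variant  = sprintf("m.%d%s>%s", position, m[, 3], m[, 4]),
    position = position,
    ref      = m[, 3],
    alt      = m[, 4],
    gene     = mt_gene(position),
    heteroplasmy_fraction = hf
  )
}

#' Format parsed variants back to canonical labels
#'
#' @param variants A tibble from [parse_mt_variants()] (columns `position`,
#'   `ref`, `alt`).
#' @return Character vector of canonical `"m.<pos><ref>><alt>"` labels.
#' @examples
#' format_mt_variants(parse_mt_variants("m.3460 G>A"))
#' @export
format_mt_variants <- function(variants) {
  sprintf("m.%d%s>%s", variants$position, variants$ref, variants$alt)
}
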
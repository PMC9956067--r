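#' ACMG mtDNA engine configuration
#'
#' Thresholds used by the evidence evaluators.  Frequencies are percent
#' values (0.4 means 0.4%).  `bs1_threshold_percent` is a strict lower
#' bound for BS1; at or above `ba1_threshold_percent` the stand-alone BA1
#' applies instead.  PP3 uses a strict `>` on the APOGEE score.  The PS4
#' strength ladder maps unrelated-proband counts to strong / moderate /
#' supporting; 16 probands for PS4-strong follows the mtDNA-specific
#' ACMG/AMP specifications.
#'
#' @param bs1_threshold_percent BS1 frequency cutoff (percent), default 0.4.
#' @param ba1_threshold_percent BA1 frequency cutoff (percent), default 1.
#' @param pp3_apogee_threshold APOGEE score cutoff, default 0.5.
#' @param ps4_strong_min_probands Probands for PS4 strong, default 16.
#' @param ps4_moderate_min_probands Probands for PS4 moderate, default 4.
#' @param ps4_supporting_min_probands Probands for PS4 supporting, default 2.
#' @return An object of class `mtlhon_engine_config`.
#' @examples
#' engine_config()
#' @export
engine_config <- function(bs1_threshold_percent = 0.4,
                          ba1_threshold_percent = 1,
                          pp3_apogee_threshold = 0.5,
                          ps4_strong_min_probands = 16L,
                          ps4_moderate_min_probands = 4L,
                          ps4_supporting_min_probands = 2L) {
  cfg <- list(
    bs1_threshold_percent = as.numeric(bs1_threshold_percent),
    ba1_threshold_percent = as.numeric(ba1_threshold_percent),
    pp3_apogee_threshold = as.numeric(pp3_apogee_threshold),
    ps4_strong_min_probands = as.integer(ps4_strong_min_probands),
    ps4_moderate_min_probands = as.integer(ps4_moderate_min_probands),
    ps4_supporting_min_probands = as.integer(ps4_supporting_min_probands)
  )
  if (!(cfg$bs1_threshold_percent < cfg$ba1_threshold_percent)) {
    rlang::abort("bs1_threshold_percent must be below ba1_threshold_percent",
                 class = "mtlhon_config_error")
  }
  if (!(cfg$ps4_supporting_min_probands <= cfg$ps4_moderate_min_probands &&
        cfg$ps4_moderate_min_probands <= cfg$ps4_strong_min_probands)) {
    rlang::abort("PS4 proband thresholds must be ordered supporting <= moderate <= strong",
                 class = "mtlhon_config_error")
  }
  structure(cfg, class = "mtlhon_engine_config")
}

#' Read an engine configuration from a flat text file
#'
#' One `key: value` line per [engine_config()] field; unknown keys are
#' errors.  Missing keys keep their defaults.
#'
#' @param path Path to a config file.
#' @return An `mtlhon_engine_config` object.
#' @export
read_engine_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  m <- stringr::str_match(lines, "^([A-Za-z0-9_]+):\\s*(\\S+)\\s*$")
  if (anyNA(m[, 1])) {
    rlang::abort(sprintf("malformed config line: \"%s\"", lines[is.na(m[, 1])][1]),
                 class = "mtlhon_config_error")
  }
  known <- names(formals(engine_config))
  unknown <- setdiff(m[, 2], known)
  if (length(unknown) > 0L) {
    rlang::abort(sprintf("unknown engine config key(s): %s",
                         paste(unknown, collapse = ", ")),
                 class = "mtlhon_config_error")
  }
  do.call(engine_config, stats::setNames(as.list(as.numeric(m[, 3])), m[, 2]))
}

#' Write an engine configuration
#'
#' @param config An `mtlhon_engine_config` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_engine_config <- function(config, path) {
  writeLines(sprintf("%s: %s", names(config),
                     vapply(config, format, character(1))), path)
  invisible(path)
}

#' @export
print.mtlhon_engine_config <- function(x, ...) {
  cat("<mtlhon engine config>\n")
  for (k in names(x)) cat(sprintf("  %s: %s\n", k, format(x[[k]])))
  invisible(x)
}
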
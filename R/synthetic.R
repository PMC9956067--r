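#' Deterministic reconstruction of the Argentinean screening cohort
#'
#' Rebuilds the 100-patient cohort from the published per-variant carrier
#' counts, with no randomness:
#'
#' * per-variant carrier counts exactly as published (54 variants, 5
#'   disease-causing, 49 benign);
#' * 32 patients each carry exactly one disease-causing variant, assigned
#'   in position order to patients `P001`–`P032`;
#' * 10 patients are familial: by convention 4 of the m.3460G>A carriers,
#'   5 of the m.11778G>A carriers, and one undiagnosed patient with no
#'   detected variant (the published familial split gives only the 9/10
#'   diagnosed count, not which carriers — the assignment is a documented
#'   convention);
#' * two m.3460G>A carriers (one familial, one sporadic) are
#'   heteroplasmic at fraction 0.6 (published as "heteroplasmic state";
#'   the fraction itself is a convention), all other calls homoplasmic;
#' * the m.3395A>G carrier has the disease-specific phenotype flag set;
#' * benign variants are spread over patients `P001`–`P082` by a
#'   deterministic least-loaded greedy (variants in position order, ties
#'   by patient id), so exactly 82 patients carry at least one variant.
#'
#' @return A cohort tibble (one row per call; variant-free patients get
#'   one `NA`-variant row).  The matching evidence snapshot is
#'   [argentina_snapshot()].
#' @examples
#' fx <- fixture_argentina()
#' length(unique(fx$patient_id))
#' @export
fixture_argentina <- function() {
  tab <- lhon_variant_table()
  ids <- sprintf("P%03d", 1:100)

  dc <- tab[tab$mitomap_status == "disease_causing", ]
  dc <- dc[order(as.integer(stringr::str_match(dc$variant, "^m\\.(\\d+)")[, 2])), ]
  calls <- list()
  nxt <- 1L
  dc_carrier <- character(0)
  for (i in seq_len(nrow(dc))) {
    carriers <- ids[nxt:(nxt + dc$carriers[i] - 1L)]
    nxt <- nxt + dc$carriers[i]
    calls[[length(calls) + 1L]] <- tibble::tibble(
      patient_id = carriers, variant = dc$variant[i],
      heteroplasmy_fraction = 1
    )
    dc_carrier <- c(dc_carrier, carriers)
  }
  n_diagnosed <- nxt - 1L  # 32

  # benign variants: least-loaded greedy over patients P001..P082
  pool <- ids[1:82]
  load <- stats::setNames(rep(0L, length(pool)), pool)
  load[dc_carrier] <- 1L
  bn <- tab[tab$mitomap_status == "benign", ]
  bn <- bn[order(as.integer(stringr::str_match(bn$variant, "^m\\.(\\d+)")[, 2])), ]
  for (i in seq_len(nrow(bn))) {
    take <- names(sort(load))[seq_len(bn$carriers[i])]
    take <- pool[pool %in% take]  # deterministic id order within the pick
    calls[[length(calls) + 1L]] <- tibble::tibble(
      patient_id = take, variant = bn$variant[i], heteroplasmy_fraction = 1
    )
    load[take] <- load[take] + 1L
  }

  cohort <- dplyr::bind_rows(calls)
  cohort <- dplyr::bind_rows(
    cohort,
    tibble::tibble(patient_id = ids[83:100], variant = NA_character_,
                   heteroplasmy_fraction = NA_real_)
  )

  m3460 <- sort(cohort$patient_id[!is.na(cohort$variant) &
                                    cohort$variant == "m.3460G>A"])
  m11778 <- sort(cohort$patient_id[!is.na(cohort$variant) &
                                     cohort$variant == "m.11778G>A"])
  familial <- c(m3460[1:4], m11778[1:5], "P083")
  het <- c(m3460[1], m3460[5])  # one familial, one sporadic
  cohort$heteroplasmy_fraction[cohort$patient_id %in% het &
                                 !is.na(cohort$variant) &
                                 cohort$variant == "m.3460G>A"] <- 0.6
  m3395 <- cohort$patient_id[!is.na(cohort$variant) &
                               cohort$variant == "m.3395A>G"]
  cohort$familial <- cohort$patient_id %in% familial
  cohort$phenotype_specific <- cohort$patient_id %in% m3395

  validate_cohort(dplyr::arrange(cohort, .data$patient_id, .data$variant))
}

#' Generator parameters for synthetic screening cohorts
#'
#' Exactly one of `carrier_counts` (fixed marginal counts, placed by
#' seeded sampling without replacement) or `carrier_probs` (independent
#' per-patient carrier draws) must be given.  Defaults mirror the study
#' conditions: 100 patients, 10 familial of whom 9 carry a diagnostic
#' variant, a 0.3 Sanger detection threshold (the lower bound of the
#' 30–50% blood-heteroplasmy detectability range), and mostly homoplasmic
#' calls.
#'
#' @param n_patients Number of patients.
#' @param carrier_counts Named integer vector: variant label -> exact
#'   carrier count.
#' @param carrier_probs Named numeric vector: variant label -> carrier
#'   probability.
#' @param familial_count Patients flagged familial.
#' @param familial_diagnosed_count Familial patients that must carry a
#'   diagnostic variant.
#' @param diagnostic_variants Labels treated as diagnostic when placing
#'   familial flags; defaults to the variants flagged disease-causing in
#'   the bundled table that appear among the generated variants.
#' @param homoplasmic_prob Probability a call is homoplasmic (fraction 1).
#' @param fraction_range Length-2 numeric: uniform range for
#'   heteroplasmic fractions.
#' @param detection_threshold Sanger detection threshold carried as
#'   metadata for [apply_sanger_censoring()].
#' @param seed Integer seed; every random draw of the generator flows
#'   from it.
#' @return A validated `mtlhon_cohort_params` list.
#' @export
cohort_params <- function(n_patients = 100L,
                          carrier_counts = NULL,
                          carrier_probs = NULL,
                          familial_count = 10L,
                          familial_diagnosed_count = 9L,
                          diagnostic_variants = NULL,
                          homoplasmic_prob = 0.98,
                          fraction_range = c(0.2, 0.9),
                          detection_threshold = 0.3,
                          seed = 1L) {
  if (is.null(carrier_counts) == is.null(carrier_probs)) {
    rlang::abort("exactly one of carrier_counts or carrier_probs must be given",
                 class = "mtlhon_params_error")
  }
  n_patients <- as.integer(n_patients)
  if (n_patients < 1L) {
    rlang::abort("n_patients must be positive", class = "mtlhon_params_error")
  }
  labels <- names(carrier_counts %||% carrier_probs)
  parse_mt_variants(labels)  # labels must be well-formed
  if (!is.null(carrier_counts)) {
    carrier_counts <- stats::setNames(as.integer(carrier_counts), labels)
    if (any(carrier_counts < 0L) || any(carrier_counts > n_patients)) {
      rlang::abort(
        sprintf("carrier counts must lie in [0, n_patients = %d]", n_patients),
        class = "mtlhon_params_error"
      )
    }
  }
  if (!is.null(carrier_probs) &&
      (any(carrier_probs < 0) || any(carrier_probs > 1))) {
    rlang::abort("carrier probabilities must lie in [0, 1]",
                 class = "mtlhon_params_error")
  }
  familial_count <- as.integer(familial_count)
  familial_diagnosed_count <- as.integer(familial_diagnosed_count)
  if (familial_diagnosed_count > familial_count || familial_count > n_patients) {
    rlang::abort("need familial_diagnosed_count <= familial_count <= n_patients",
                 class = "mtlhon_params_error")
  }
  if (length(fraction_range) != 2L || fraction_range[1] > fraction_range[2] ||
      any(fraction_range < 0) || any(fraction_range > 1)) {
    rlang::abort("fraction_range must be an increasing pair in [0, 1]",
                 class = "mtlhon_params_error")
  }
  if (is.null(diagnostic_variants)) {
    tab <- lhon_variant_table()
    diagnostic_variants <- intersect(
      tab$variant[tab$mitomap_status == "disease_causing"], labels
    )
  }
  structure(
    list(
      n_patients = n_patients,
      carrier_counts = carrier_counts,
      carrier_probs = carrier_probs,
      familial_count = familial_count,
      familial_diagnosed_count = familial_diagnosed_count,
      diagnostic_variants = diagnostic_variants,
      homoplasmic_prob = as.numeric(homoplasmic_prob),
      fraction_range = as.numeric(fraction_range),
      detection_threshold = as.numeric(detection_threshold),
      seed = as.integer(seed)
    ),
    class = "mtlhon_cohort_params"
  )
}

# run code under a private RNG state derived from seed; the caller's
# global .Random.seed is untouched
with_local_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Generate a synthetic screening cohort
#'
#' Seeded and reproducible: the same parameters and seed yield an
#' identical cohort.  Fixed-count mode places each variant's carriers by
#' sampling patients without replacement, so the marginal carrier counts
#' are exact; probability mode draws carriers independently per
#' (patient, variant).  Heteroplasmy fractions are homoplasmic (1) with
#' probability `homoplasmic_prob`, otherwise uniform on `fraction_range`.
#' Familial flags go to a seeded subset honouring
#' `familial_diagnosed_count` carriers of diagnostic variants.
#'
#' @param params An [cohort_params()] object.
#' @return A cohort tibble.
#' @examples
#' p <- cohort_params(n_patients = 20,
#'                    carrier_counts = c("m.11778G>A" = 5), seed = 7)
#' generate_cohort(p)
#' @export
generate_cohort <- function(params) {
  stopifnot(inherits(params, "mtlhon_cohort_params"))
  ids <- sprintf("P%03d", seq_len(params$n_patients))
  with_local_seed(params$seed, {
    calls <- list()
    if (!is.null(params$carrier_counts)) {
      labs <- names(sort(stats::setNames(
        parse_mt_variants(names(params$carrier_counts))$position,
        names(params$carrier_counts)
      )))
      for (lab in labs) {
        k <- params$carrier_counts[[lab]]
        if (k == 0L) next
        calls[[length(calls) + 1L]] <- tibble::tibble(
          patient_id = sort(sample(ids, k)), variant = lab
        )
      }
    } else {
      labs <- names(sort(stats::setNames(
        parse_mt_variants(names(params$carrier_probs))$position,
        names(params$carrier_probs)
      )))
      for (lab in labs) {
        hit <- ids[stats::runif(params$n_patients) < params$carrier_probs[[lab]]]
        if (length(hit) == 0L) next
        calls[[length(calls) + 1L]] <- tibble::tibble(
          patient_id = hit, variant = lab
        )
      }
    }
    cohort <- if (length(calls) > 0) dplyr::bind_rows(calls) else {
      tibble::tibble(patient_id = character(), variant = character())
    }
    n <- nrow(cohort)
    homo <- stats::runif(n) < params$homoplasmic_prob
    frac <- ifelse(homo, 1,
                   stats::runif(n, params$fraction_range[1],
                                params$fraction_range[2]))
    cohort$heteroplasmy_fraction <- frac

    no_call <- setdiff(ids, cohort$patient_id)
    cohort <- dplyr::bind_rows(
      cohort,
      tibble::tibble(patient_id = no_call, variant = NA_character_,
                     heteroplasmy_fraction = NA_real_)
    )

    diagnosed_pool <- unique(
      cohort$patient_id[!is.na(cohort$variant) &
                          cohort$variant %in% params$diagnostic_variants]
    )
    if (length(diagnosed_pool) < params$familial_diagnosed_count) {
      rlang::abort(
        sprintf("infeasible familial split: %d carriers of diagnostic variants, %d required familial-diagnosed",
                length(diagnosed_pool), params$familial_diagnosed_count),
        class = "mtlhon_params_error"
      )
    }
    fam_diag <- sort(sample(diagnosed_pool, params$familial_diagnosed_count))
    rest_pool <- setdiff(ids, diagnosed_pool)
    n_rest <- params$familial_count - params$familial_diagnosed_count
    if (length(rest_pool) < n_rest) {
      rlang::abort("infeasible familial split: not enough non-diagnosed patients",
                   class = "mtlhon_params_error")
    }
    fam_rest <- sort(sample(rest_pool, n_rest))
    cohort$familial <- cohort$patient_id %in% c(fam_diag, fam_rest)
    cohort$phenotype_specific <- FALSE
    validate_cohort(dplyr::arrange(cohort, .data$patient_id, .data$variant))
  })
}

#' Censor calls below the Sanger detection threshold
#'
#' Models the blood-heteroplasmy detection floor of direct Sanger
#' sequencing (published as 30–50% mutant load): every call whose
#' heteroplasmy fraction is below `threshold` is removed, emulating an
#' obligate carrier whose variant is invisible in blood.  Homoplasmic
#' calls always survive.  Patients losing all calls remain in the cohort
#' as screened, variant-free.  The input is not modified.
#'
#' @param cohort A cohort tibble.
#' @param threshold Detection threshold in `[0, 1]`; default 0.3.
#' @return A new cohort tibble.
#' @examples
#' fx <- fixture_argentina()
#' nrow(apply_sanger_censoring(fx, 0.7)) < nrow(fx)
#' @export
apply_sanger_censoring <- function(cohort, threshold = 0.3) {
  if (threshold < 0 || threshold > 1) {
    rlang::abort("threshold must lie in [0, 1]", class = "mtlhon_params_error")
  }
  keep <- is.na(cohort$variant) | cohort$heteroplasmy_fraction >= threshold
  out <- cohort[keep, , drop = FALSE]
  lost <- setdiff(unique(cohort$patient_id), unique(out$patient_id))
  if (length(lost) > 0L) {
    flags <- dplyr::distinct(
      cohort[cohort$patient_id %in% lost,
             c("patient_id", "familial", "phenotype_specific")]
    )
    out <- dplyr::bind_rows(
      out,
      dplyr::mutate(flags, variant = NA_character_,
                    heteroplasmy_fraction = NA_real_)
    )
  }
  dplyr::arrange(out, .data$patient_id, .data$variant)
}

#' Serialise generator parameters to the flat config format
#'
#' @param params An [cohort_params()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort_params <- function(params, path) {
  num <- function(x) paste(format(x, scientific = FALSE, trim = TRUE),
                           collapse = ",")
  lines <- c(
    sprintf("n_patients: %d", params$n_patients),
    sprintf("familial_count: %d", params$familial_count),
    sprintf("familial_diagnosed_count: %d", params$familial_diagnosed_count),
    sprintf("homoplasmic_prob: %s", num(params$homoplasmic_prob)),
    sprintf("fraction_range: %s", num(params$fraction_range)),
    sprintf("detection_threshold: %s", num(params$detection_threshold)),
    sprintf("seed: %d", params$seed)
  )
  if (!is.null(params$carrier_counts)) {
    lines <- c(lines, sprintf("count_%s: %d", names(params$carrier_counts),
                              params$carrier_counts))
  }
  if (!is.null(params$carrier_probs)) {
    lines <- c(lines, sprintf("prob_%s: %s", names(params$carrier_probs),
                              vapply(params$carrier_probs, num, character(1))))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read generator parameters from the flat config format
#'
#' @param path Path written by [write_cohort_params()].
#' @return An `mtlhon_cohort_params` object.
#' @export
read_cohort_params <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  m <- stringr::str_match(lines, "^([^:]+):\\s*(.*?)\\s*$")
  kv <- stats::setNames(as.list(m[, 3]), m[, 2])
  counts <- kv[grepl("^count_", names(kv))]
  probs <- kv[grepl("^prob_", names(kv))]
  cohort_params(
    n_patients = as.integer(kv$n_patients),
    carrier_counts = if (length(counts) > 0) {
      stats::setNames(as.integer(unlist(counts)),
                      sub("^count_", "", names(counts)))
    },
    carrier_probs = if (length(probs) > 0) {
      stats::setNames(as.numeric(unlist(probs)),
                      sub("^prob_", "", names(probs)))
    },
    familial_count = as.integer(kv$familial_count),
    familial_diagnosed_count = as.integer(kv$familial_diagnosed_count),
    homoplasmic_prob = as.numeric(kv$homoplasmic_prob),
    fraction_range = as.numeric(strsplit(kv$fraction_range, ",")[[1]]),
    detection_threshold = as.numeric(kv$detection_threshold),
    seed = as.integer(kv$seed)
  )
}
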
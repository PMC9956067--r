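# Independent brute-force oracle for the ACMG evidence-combining table.
# The qualifying combinations are written as literal minimal-count rows and
# checked with elementwise >=, so the oracle shares no code with the
# engine's boolean logic.

oracle_path_rows_P <- list(
  c(S = 2, M = 0, Su = 0),
  c(S = 1, M = 3, Su = 0),
  c(S = 1, M = 2, Su = 2),
  c(S = 1, M = 1, Su = 4)
)
oracle_path_rows_LP <- list(
  c(S = 1, M = 1, Su = 0),
  c(S = 1, M = 0, Su = 2),
  c(S = 0, M = 3, Su = 0),
  c(S = 0, M = 2, Su = 2),
  c(S = 0, M = 1, Su = 4)
)

oracle_combine <- function(n_ps, n_pm, n_pp, n_bs, n_bp, ba1) {
  have <- c(S = n_ps, M = n_pm, Su = n_pp)
  meets <- function(rows) {
    any(vapply(rows, function(r) all(have >= r), logical(1)))
  }
  path <- if (meets(oracle_path_rows_P)) "pathogenic"
          else if (meets(oracle_path_rows_LP)) "likely_pathogenic"
          else NA_character_
  ben <- if (ba1 || n_bs >= 2) "benign"
         else if ((n_bs >= 1 && n_bp >= 1) || n_bp >= 2) "likely_benign"
         else NA_character_
  if (is.na(path) && is.na(ben)) return("VUS")
  if (!is.na(path) && !is.na(ben)) return("VUS")
  if (!is.na(path)) path else ben
}

# evidence-item tibble for a count pattern, in shuffled order so tests also
# exercise order invariance
items_from_counts <- function(n_ps, n_pm, n_pp, n_bs, n_bp, ba1,
                              shuffle = NULL) {
  items <- dplyr::bind_rows(
    if (n_ps > 0) evidence_item(rep("PS1", n_ps), "pathogenic", "strong"),
    if (n_pm > 0) evidence_item(rep("PM1", n_pm), "pathogenic", "moderate"),
    if (n_pp > 0) evidence_item(rep("PP1", n_pp), "pathogenic", "supporting"),
    if (n_bs > 0) evidence_item(rep("BS2", n_bs), "benign", "strong"),
    if (n_bp > 0) evidence_item(rep("BP4", n_bp), "benign", "supporting"),
    if (ba1) evidence_item("BA1", "benign", "stand_alone")
  )
  if (is.null(items)) items <- evidence_item(character(), character(), character())
  if (!is.null(shuffle) && nrow(items) > 1) {
    items <- items[sample.int(nrow(items)), ]
  }
  items
}

# a random but valid evidence record (snapshot row) for property tests
random_record <- function() {
  n_src <- sample(0:3, 1)
  freqs <- stats::setNames(round(stats::runif(n_src, 0, 2), 3),
                           c("GenBank", "gnomAD", "Helix")[seq_len(n_src)])
  tibble::tibble(
    variant = "m.1000A>G",
    position = 1000L,
    mitomap_status = sample(c("disease_causing", "benign", "unreported"), 1),
    frequencies = list(freqs),
    apogee_score = if (stats::runif(1) < 0.5) NA_real_ else round(stats::runif(1), 2),
    proband_count = sample(0:20, 1),
    functional_strength = sample(c("none", "supporting", "moderate", "strong"), 1),
    phenotype_specific_supported = stats::runif(1) < 0.5,
    same_residue_pathogenic = if (stats::runif(1) < 0.5) NA_character_ else "p.Tyr30His",
    haplogroup_tag = NA_character_,
    genbank_frequency_table1 = NA_real_,
    extra = list(list())
  )
}
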
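snap <- argentina_snapshot()
cfg <- engine_config()

test_that("frequency code BS1/BA1 applies above the configured cutoffs", {
  expect_equal(evaluate_bs1(lookup_evidence(snap, "m.11253T>C"), cfg)$code, "BS1")
  expect_equal(evaluate_bs1(lookup_evidence(snap, "m.3395A>G"), cfg)$code, "BS1")
  expect_equal(nrow(evaluate_bs1(lookup_evidence(snap, "m.11778G>A"), cfg)), 0L)
  expect_equal(nrow(evaluate_bs1(lookup_evidence(snap, "m.3460G>A"), cfg)), 0L)
  # at or above the BA1 cutoff the stand-alone code wins
  r <- lookup_evidence(snap, "m.11719G>A")
  item <- evaluate_bs1(r, cfg)
  expect_equal(item$code, "BA1")
  expect_equal(item$strength, "stand_alone")
  # boundary: exactly the BS1 cutoff does not fire (strict >)
  r$frequencies[[1]] <- c(GenBank = cfg$bs1_threshold_percent)
  expect_equal(nrow(evaluate_bs1(r, cfg)), 0L)
  r$frequencies[[1]] <- numeric()
  expect_equal(nrow(evaluate_bs1(r, cfg)), 0L)
})

test_that("PP3 uses a strict APOGEE threshold and is off without a score", {
  expect_equal(evaluate_pp3(lookup_evidence(snap, "m.11253T>C"), cfg)$code, "PP3")
  expect_equal(evaluate_pp3(lookup_evidence(snap, "m.3395A>G"), cfg)$code, "PP3")
  r <- lookup_evidence(snap, "m.11253T>C")
  r$apogee_score <- 0.50
  expect_equal(nrow(evaluate_pp3(r, cfg)), 0L)
  r$apogee_score <- NA_real_
  expect_equal(nrow(evaluate_pp3(r, cfg)), 0L)
})

test_that("PS4 strength ladder follows the proband count", {
  r <- lookup_evidence(snap, "m.11253T>C")
  ladder <- function(n) {
    r$proband_count <- n
    item <- evaluate_ps4(r, cfg)
    if (nrow(item) == 0) NA_character_ else item$strength
  }
  expect_equal(ladder(16L), "strong")
  expect_equal(ladder(10L), "moderate")
  expect_equal(ladder(4L), "moderate")
  expect_equal(ladder(3L), "supporting")
  expect_equal(ladder(2L), "supporting")
  expect_equal(ladder(1L), NA_character_)
})

test_that("PS3 passes through the curated functional strength", {
  expect_equal(evaluate_ps3(lookup_evidence(snap, "m.3395A>G"))$strength,
               "supporting")
  r <- lookup_evidence(snap, "m.3395A>G")
  r$functional_strength <- "strong"
  expect_equal(evaluate_ps3(r)$strength, "strong")
  r$functional_strength <- "none"
  expect_equal(nrow(evaluate_ps3(r)), 0L)
})

test_that("PP4 needs both the record flag and the patient flag; PM5 needs a residue match", {
  r <- lookup_evidence(snap, "m.3395A>G")
  expect_equal(evaluate_pp4(r, TRUE)$code, "PP4")
  expect_equal(nrow(evaluate_pp4(r, FALSE)), 0L)
  r$phenotype_specific_supported <- FALSE
  expect_equal(nrow(evaluate_pp4(r, TRUE)), 0L)

  expect_equal(evaluate_pm5(lookup_evidence(snap, "m.3395A>G"))$strength,
               "moderate")
  expect_equal(nrow(evaluate_pm5(lookup_evidence(snap, "m.11253T>C"))), 0L)
})

test_that("combining rules match the brute-force rule-table oracle", {
  set.seed(11)
  grid <- expand.grid(S = 0:4, M = 0:4, Su = 0:4, BS = 0:4, BP = 0:4,
                      ba1 = c(FALSE, TRUE))
  got <- character(nrow(grid))
  want <- character(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    got[i] <- combine_evidence(
      items_from_counts(g$S, g$M, g$Su, g$BS, g$BP, g$ba1, shuffle = TRUE)
    )
    want[i] <- oracle_combine(g$S, g$M, g$Su, g$BS, g$BP, g$ba1)
  }
  expect_equal(got, want)
})

test_that("worked anchor combinations and degenerate inputs classify as published", {
  expect_equal(combine_evidence(dplyr::bind_rows(
    evidence_item("BS1", "benign", "strong"),
    evidence_item("PP3", "pathogenic", "supporting"),
    evidence_item("PS4", "pathogenic", "moderate")
  )), "VUS")
  expect_equal(combine_evidence(dplyr::bind_rows(
    evidence_item("BS1", "benign", "strong"),
    evidence_item("PP3", "pathogenic", "supporting"),
    evidence_item("PS3", "pathogenic", "supporting"),
    evidence_item("PP4", "pathogenic", "supporting"),
    evidence_item("PM5", "pathogenic", "moderate"),
    evidence_item("PS4", "pathogenic", "moderate")
  )), "likely_pathogenic")
  expect_equal(combine_evidence(no_items <- evidence_item(character(), character(), character())), "VUS")
  expect_equal(combine_evidence(evidence_item("BA1", "benign", "stand_alone")),
               "benign")
  expect_equal(combine_evidence(dplyr::bind_rows(
    evidence_item("PS1", "pathogenic", "strong"),
    evidence_item("PM1", "pathogenic", "moderate")
  )), "likely_pathogenic")
})

test_that("tier is monotone under added evidence", {
  tiers <- classification_tiers()
  rank <- function(t) match(t, tiers)
  set.seed(42)
  for (rep in 1:200) {
    g <- c(sample(0:3, 3, replace = TRUE), sample(0:2, 2, replace = TRUE),
           stats::runif(1) < 0.2)
    base <- items_from_counts(g[1], g[2], g[3], g[4], g[5], g[6])
    t0 <- combine_evidence(base)
    add_p <- dplyr::bind_rows(base, evidence_item(
      "PX", "pathogenic", sample(c("supporting", "moderate", "strong"), 1)
    ))
    expect_gte(rank(combine_evidence(add_p)), rank(t0))
    add_b <- dplyr::bind_rows(base, evidence_item(
      "BX", "benign", sample(c("supporting", "strong"), 1)
    ))
    expect_lte(rank(combine_evidence(add_b)), rank(t0))
  }
})

test_that("raising the BS1 cutoff can only remove BS1 applications", {
  set.seed(7)
  for (rep in 1:100) {
    r <- random_record()
    if (length(r$frequencies[[1]]) == 0) next
    lo <- engine_config(bs1_threshold_percent = 0.2)
    hi <- engine_config(bs1_threshold_percent = 0.8)
    fired_lo <- "BS1" %in% evaluate_bs1(r, lo)$code
    fired_hi <- "BS1" %in% evaluate_bs1(r, hi)$code
    expect_false(fired_hi && !fired_lo)
  }
})

test_that("engine configuration validates and round-trips through its file format", {
  expect_error(engine_config(bs1_threshold_percent = 2),
               class = "mtlhon_config_error")
  expect_error(engine_config(ps4_moderate_min_probands = 1),
               class = "mtlhon_config_error")
  tmp <- withr::local_tempfile(fileext = ".txt")
  cfg2 <- engine_config(bs1_threshold_percent = 0.3,
                        ps4_strong_min_probands = 20)
  write_engine_config(cfg2, tmp)
  expect_equal(read_engine_config(tmp), cfg2)
  writeLines("bogus_key: 1", tmp)
  expect_error(read_engine_config(tmp), "unknown",
               class = "mtlhon_config_error")
})
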
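snap <- argentina_snapshot()

test_that("the Argentina fixture is deterministic down to its serialised bytes", {
  f1 <- fixture_argentina()
  f2 <- fixture_argentina()
  expect_identical(f1, f2)
  t1 <- withr::local_tempfile(fileext = ".tsv")
  t2 <- withr::local_tempfile(fileext = ".tsv")
  write_cohort_tsv(f1, t1)
  write_cohort_tsv(f2, t2)
  expect_identical(unname(tools::md5sum(t1)), unname(tools::md5sum(t2)))
})

test_that("the fixture satisfies its documented construction conventions", {
  fx <- fixture_argentina()
  expect_equal(length(unique(fx$patient_id)), 100L)
  expect_equal(length(unique(fx$variant[!is.na(fx$variant)])), 54L)
  # each diagnosed patient carries exactly one disease-causing variant
  dc <- snap$variant[snap$mitomap_status == "disease_causing"]
  per_patient <- table(fx$patient_id[!is.na(fx$variant) & fx$variant %in% dc])
  expect_equal(length(per_patient), 32L)
  expect_true(all(per_patient == 1))
  # familial convention: 4 m.3460G>A + 5 m.11778G>A carriers + 1 undiagnosed
  fam <- unique(fx$patient_id[fx$familial])
  expect_length(fam, 10L)
  fam_calls <- fx[fx$patient_id %in% fam & !is.na(fx$variant), ]
  expect_equal(sum(tapply(fam_calls$variant, fam_calls$patient_id,
                          function(v) "m.3460G>A" %in% v)), 4L)
  expect_equal(sum(tapply(fam_calls$variant, fam_calls$patient_id,
                          function(v) "m.11778G>A" %in% v)), 5L)
  # heteroplasmy convention: exactly two m.3460G>A carriers at 0.6
  het <- fx[!is.na(fx$variant) & fx$heteroplasmy_fraction < 1, ]
  expect_equal(nrow(het), 2L)
  expect_equal(unique(het$variant), "m.3460G>A")
  expect_equal(unique(het$heteroplasmy_fraction), 0.6)
  expect_equal(sum(het$patient_id %in% fam), 1L)
  # phenotype flag sits on the m.3395A>G carrier only
  phen <- unique(fx$patient_id[fx$phenotype_specific])
  expect_equal(phen, fx$patient_id[!is.na(fx$variant) & fx$variant == "m.3395A>G"])
})

test_that("fixed-count generation reproduces requested marginals exactly and is seeded", {
  tab <- lhon_variant_table()
  counts <- stats::setNames(tab$carriers, tab$variant)
  p <- cohort_params(n_patients = 100, carrier_counts = counts, seed = 1)
  g1 <- generate_cohort(p)
  g2 <- generate_cohort(p)
  expect_identical(g1, g2)
  sp <- spectrum_table(g1)
  expect_equal(stats::setNames(sp$carriers, sp$variant)[tab$variant],
               stats::setNames(tab$carriers, tab$variant))
  g3 <- generate_cohort(cohort_params(n_patients = 100,
                                      carrier_counts = counts, seed = 2))
  expect_false(identical(g1, g3))
  # the generator must not disturb the session RNG stream
  set.seed(99); before <- stats::runif(1)
  set.seed(99); invisible(generate_cohort(p)); after <- stats::runif(1)
  expect_identical(before, after)
})

test_that("sampling-mode carrier counts fall in the analytic binomial band", {
  p <- cohort_params(
    n_patients = 1000,
    carrier_probs = c("m.11778G>A" = 0.17),
    familial_count = 0, familial_diagnosed_count = 0, seed = 7
  )
  g <- generate_cohort(p)
  k <- sum(!is.na(g$variant) & g$variant == "m.11778G>A")
  band <- stats::qbinom(c(0.005, 0.995), 1000, 0.17)
  expect_gte(k, band[1])
  expect_lte(k, band[2])
})

test_that("infeasible parameters fail before any sampling", {
  expect_error(cohort_params(n_patients = 100,
                             carrier_counts = c("m.11778G>A" = 101)),
               class = "mtlhon_params_error")
  expect_error(cohort_params(n_patients = 100,
                             carrier_counts = c("m.11778G>A" = 5),
                             carrier_probs = c("m.11778G>A" = 0.1)),
               class = "mtlhon_params_error")
  expect_error(cohort_params(n_patients = 5, familial_count = 9),
               class = "mtlhon_params_error")
  # familial-diagnosed demand exceeding diagnostic carriers fails at run time
  p <- cohort_params(n_patients = 100,
                     carrier_counts = c("m.11778G>A" = 3),
                     familial_count = 10, familial_diagnosed_count = 9,
                     seed = 1)
  expect_error(generate_cohort(p), class = "mtlhon_params_error")
})

test_that("Sanger censoring removes sub-threshold calls, monotonically in the threshold", {
  cohort <- tibble::tibble(
    patient_id = c("A", "B", "C", "D"),
    variant = c("m.3460G>A", "m.3460G>A", "m.3460G>A", NA),
    heteroplasmy_fraction = c(0.2, 0.6, 1, NA),
    familial = c(TRUE, FALSE, FALSE, FALSE),
    phenotype_specific = FALSE
  )
  cens <- apply_sanger_censoring(cohort, 0.3)
  # the 0.2 call vanishes (the undetected obligate carrier), 0.6 and 1 remain
  expect_false("A" %in% cens$patient_id[!is.na(cens$variant)])
  expect_true(all(c("B", "C") %in% cens$patient_id[!is.na(cens$variant)]))
  # the censored patient is still a screened, variant-free row with flags kept
  expect_true("A" %in% cens$patient_id)
  expect_true(cens$familial[cens$patient_id == "A"])
  # homoplasmic calls survive any threshold
  expect_true("C" %in% apply_sanger_censoring(cohort, 1)$patient_id[
    !is.na(apply_sanger_censoring(cohort, 1)$variant)])
  # input untouched
  expect_equal(nrow(cohort), 4L)
  # monotone: higher thresholds never retain more calls
  surv <- vapply(seq(0, 1, by = 0.1), function(th) {
    sum(!is.na(apply_sanger_censoring(cohort, th)$variant))
  }, numeric(1))
  expect_true(all(diff(surv) <= 0))
})

test_that("generator parameters round-trip through the flat config format", {
  p <- cohort_params(n_patients = 50,
                     carrier_probs = c("m.11778G>A" = 0.17, "m.3460G>A" = 0.09),
                     familial_count = 5, familial_diagnosed_count = 4,
                     homoplasmic_prob = 0.9, fraction_range = c(0.1, 0.8),
                     detection_threshold = 0.4, seed = 123)
  tmp <- withr::local_tempfile(fileext = ".txt")
  write_cohort_params(p, tmp)
  expect_equal(read_cohort_params(tmp), p)
})
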
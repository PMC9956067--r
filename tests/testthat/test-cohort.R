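snap <- argentina_snapshot()
fx <- fixture_argentina()

test_that("diagnosis follows the snapshot status and breaks ties by position", {
  cohort <- tibble::tibble(
    patient_id = c("A", "A", "B", "C"),
    variant = c("m.11778G>A", "m.11719G>A", "m.11719G>A", NA),
    heteroplasmy_fraction = c(1, 1, 1, NA),
    familial = FALSE, phenotype_specific = FALSE
  )
  d <- diagnose_patients(cohort, snap)
  expect_equal(d$diagnosed, c(TRUE, FALSE, FALSE))
  expect_equal(d$causal_variant[1], "m.11778G>A")
  expect_equal(d$causal_gene[1], "MT-ND4")

  # two qualifying variants: lowest position wins
  two <- tibble::tibble(
    patient_id = "A", variant = c("m.11778G>A", "m.3460G>A"),
    heteroplasmy_fraction = 1, familial = FALSE, phenotype_specific = FALSE
  )
  expect_equal(diagnose_patients(two, snap)$causal_variant, "m.3460G>A")
  # order of the call rows is irrelevant
  expect_equal(diagnose_patients(two[2:1, ], snap)$causal_variant, "m.3460G>A")
})

test_that("acmg_tier mode excludes the VUS carriers that MitoMap status includes", {
  d_status <- diagnose_patients(fx, snap, mode = "mitomap_status")
  d_acmg <- diagnose_patients(fx, snap, mode = "acmg_tier")
  expect_equal(sum(d_status$diagnosed), 32L)
  expect_equal(sum(d_acmg$diagnosed), 29L)
  moved <- d_status$patient_id[d_status$diagnosed & !d_acmg$diagnosed]
  expect_equal(sort(unique(d_status$causal_variant[d_status$patient_id %in% moved])),
               "m.11253T>C")
})

test_that("cohort summary reproduces the published statistics", {
  s <- summarize_cohort(fx, snap)
  expect_equal(s$n_patients, 100L)
  expect_equal(s$n_diagnosed, 32L)
  expect_equal(s$yield_percent, 32L)
  att <- tidy(s)
  expect_equal(att$count[att$gene == "MT-ND4"], 20L)
  expect_equal(att$percent[att$gene == "MT-ND4"], 63L)
  expect_equal(att$count[att$gene == "MT-ND1"], 10L)
  expect_equal(att$percent[att$gene == "MT-ND1"], 31L)
  expect_equal(att$count[att$gene == "MT-ND6"], 2L)
  expect_equal(att$percent[att$gene == "MT-ND6"], 6L)
  # attribution counts cover all diagnosed patients; percents sum to 100 +- 1
  expect_equal(sum(att$count), s$n_diagnosed)
  expect_lte(abs(sum(att$percent) - 100L), 1L)
  expect_equal(s$familial_yield, c(diagnosed = 9L, total = 10L))
  expect_equal(s$sporadic_yield_percent, 26L)
  expect_equal(s$n_variant_carriers, 82L)
  g <- glance(s)
  expect_equal(g$n_variants, 54L)
  expect_equal(g$yield_percent, 32L)
})

test_that("percentage fields are invariant under cohort replication", {
  fx2 <- dplyr::mutate(fx, patient_id = paste0(patient_id, "b"))
  doubled <- dplyr::bind_rows(fx, fx2)
  s1 <- summarize_cohort(fx, snap)
  s2 <- summarize_cohort(doubled, snap)
  expect_equal(s2$yield_percent, s1$yield_percent)
  expect_equal(s2$sporadic_yield_percent, s1$sporadic_yield_percent)
  expect_equal(tidy(s2)$percent, tidy(s1)$percent)
  expect_equal(s2$n_diagnosed, 2L * s1$n_diagnosed)
})

test_that("empty cohorts and undiagnosed singletons behave as specified", {
  empty <- fx[0, ]
  expect_error(summarize_cohort(empty, snap), class = "mtlhon_cohort_error")
  one <- tibble::tibble(patient_id = "X", variant = "m.11719G>A",
                        heteroplasmy_fraction = 1, familial = FALSE,
                        phenotype_specific = FALSE)
  s <- summarize_cohort(one, snap)
  expect_equal(s$yield_percent, 0L)
  expect_equal(s$n_diagnosed, 0L)
})

test_that("spectrum counts patients, not call instances, ordered by position", {
  sp <- spectrum_table(fx)
  expect_equal(nrow(sp), 54L)
  expect_equal(sp$position, sort(sp$position))
  expect_equal(sp$carriers[sp$variant == "m.3547A>G"], 15L)
  expect_equal(sp$carriers[sp$variant == "m.14318T>C"], 14L)
  expect_equal(sp$carriers[sp$variant == "m.11719G>A"], 56L)
  # the whole fixture spectrum equals the published carrier counts
  tab <- lhon_variant_table()
  expect_equal(sp$carriers[match(tab$variant, sp$variant)], tab$carriers)
  expect_equal(nrow(spectrum_table(fx[0, ])), 0L)
})

test_that("haplogroup tagging is a pure union of marker tags", {
  cohort <- tibble::tibble(
    patient_id = c("A", "B", "B", "C", "D"),
    variant = c("m.4216T>C", "m.3552T>A", "m.14318T>C", "m.11719G>A", NA),
    heteroplasmy_fraction = c(1, 1, 1, 1, NA),
    familial = FALSE, phenotype_specific = FALSE
  )
  tags <- tag_haplogroup_markers(cohort, snap)
  expect_equal(tags$tags[tags$patient_id == "A"][[1]], "JT")
  expect_equal(tags$tags[tags$patient_id == "B"][[1]], "C")
  expect_equal(tags$tags[tags$patient_id == "C"][[1]], character())
  expect_equal(tags$tags[tags$patient_id == "D"][[1]], character())
  # fixture marker prevalences match the published percentages
  s <- summarize_cohort(fx, snap)
  hg <- s$haplogroup_counts
  expect_equal(hg$percent[hg$tag == "B2"], 15L)
  expect_equal(hg$percent[hg$tag == "AE"], 7L)
  expect_equal(hg$percent[hg$tag == "JT"], 6L)
})

test_that("duplicate calls within a patient are rejected", {
  bad <- tibble::tibble(patient_id = "A", variant = rep("m.11778G>A", 2),
                        heteroplasmy_fraction = 1, familial = FALSE,
                        phenotype_specific = FALSE)
  expect_error(diagnose_patients(bad, snap), class = "mtlhon_cohort_error")
})
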
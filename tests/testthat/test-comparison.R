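fixture_assignments <- local({
  memo <- NULL
  function() {
    if (is.null(memo)) {
      cohort <- fixture_cohort()
      memo <<- list(a17 = eln_classify(cohort, "2017", quiet = TRUE),
                    a22 = eln_classify(cohort, "2022", quiet = TRUE),
                    cohort = cohort)
    }
    memo
  }
})

test_that("self-comparison yields a diagonal table with no reclassification", {
  fx <- fixture_assignments()
  a22_as_17 <- dplyr::mutate(fx$a22, edition = "2017")
  tt <- transition_table(a22_as_17, fx$a22)
  expect_equal(sum(tt$counts) - sum(diag(tt$counts)), 0)
  expect_equal(worsened_fraction(tt), 0)
  expect_equal(improved_fraction(tt), 0)
})

test_that("transition marginals are conserved and fractions sum to 100", {
  fx <- fixture_assignments()
  tt <- transition_table(fx$a17, fx$a22)
  expect_equal(unname(rowSums(tt$counts)),
               unname(table(fx$a17$resolved)[eln_categories()]),
               ignore_attr = TRUE)
  expect_equal(unname(colSums(tt$counts)),
               unname(table(fx$a22$resolved)[eln_categories()]),
               ignore_attr = TRUE)
  stable <- 100 * sum(diag(tt$counts)) / tt$n
  expect_equal(worsened_fraction(tt) + improved_fraction(tt) +
                 round(stable, 1), 100, tolerance = 0.1)
  # reason labels mirror the published reclassification report
  expect_setequal(tt$reasons$reason, c(
    "Mutated NPM1 with low allelic ratio FLT3-ITD",
    "Biallellic mutated CEBPA (not bZIP domain) + mutated MDS genes",
    "bZIP in frame mutated CEBPA (only one CEBPA mutation)",
    "Mutated MDS genes (not RUNX1 and ASXL1)",
    "High allelic ratio FLT3-ITD",
    "Hyperdiploid karyotype + high allelic ratio FLT3-ITD",
    "Hyperdiploid karyotype"
  ))
})

test_that("id mismatch between editions is rejected", {
  fx <- fixture_assignments()
  shuffled <- fx$a22[c(2:nrow(fx$a22), 1), ]
  expect_error(transition_table(fx$a17, shuffled), "ids differ")
})

test_that("a forced all-worsening toy table reports 100%", {
  # four 2017-favorable profiles that 2022 sends to adverse:
  # NPM1 + TP53 (TP53 outranks NPM1) and biallelic non-bZIP CEBPA + MDS gene
  cohort <- tibble::tibble(
    patient_id = paste0("T", 1:4), age_years = 50L, sex = "female",
    intensive = TRUE, midostaurin = FALSE,
    mutations = c(
      replicate(2, mutation_calls(c("NPM1", "TP53"), c(0.4, 0.45)),
                simplify = FALSE),
      replicate(2, dplyr::bind_rows(
        mutation_calls("CEBPA", 0.44, cebpa_biallelic = TRUE,
                       cebpa_bzip_inframe = FALSE),
        mutation_calls("SRSF2", 0.3)), simplify = FALSE)
    ),
    karyotype = "46,XX", os_months = 10, death = FALSE
  )
  a17 <- eln_classify(cohort, "2017", quiet = TRUE)
  a22 <- eln_classify(cohort, "2022", quiet = TRUE)
  expect_true(all(a17$resolved == "favorable"))
  expect_true(all(a22$resolved == "adverse"))
  tt <- transition_table(a17, a22)
  expect_equal(worsened_fraction(tt), 100)
})

test_that("risk distribution chi-square matches the hand-computed statistic", {
  # 2x2 design {{10,0},{0,10}}: Pearson chi-square = N = 20
  cohort <- tibble::tibble(
    patient_id = paste0("C", 1:20), age_years = 50L,
    sex = rep(c("female", "male"), each = 10),
    intensive = TRUE, midostaurin = FALSE,
    mutations = c(replicate(10, mutation_calls("NPM1", 0.4),
                            simplify = FALSE),
                  replicate(10, mutation_calls("TP53", 0.5),
                            simplify = FALSE)),
    karyotype = "46,XX", os_months = 10, death = FALSE
  )
  a22 <- eln_classify(cohort, "2022", quiet = TRUE)
  sd <- subgroup_distribution(a22, cohort, by = "sex")
  expect_equal(sd$statistic, 20)
  expect_lt(sd$p, 0.001)
  # balanced identical strata: no association
  cohort2 <- dplyr::mutate(cohort, sex = rep(c("female", "male"), 10))
  a22b <- eln_classify(cohort2, "2022", quiet = TRUE)
  expect_gt(subgroup_distribution(a22b, cohort2, by = "sex")$p, 0.99)
  # an empty covariate stratum leaves the p value undefined
  cohort3 <- dplyr::mutate(cohort, age_years = 40L)
  expect_true(is.na(subgroup_distribution(a22, cohort3, by = "age65")$p))
})

test_that("Sankey export writes the documented node/link structure", {
  fx <- fixture_assignments()
  tt <- transition_table(fx$a17, fx$a22)
  path <- withr::local_tempfile(fileext = ".json")
  export_sankey(tt, path)
  j <- jsonlite::read_json(path)
  expect_length(j$nodes, 6)
  expect_length(j$links, 8)  # 3 diagonal + 5 nonzero off-diagonal cells
  expect_equal(sum(vapply(j$links, function(l) l$value, numeric(1))), 546)

  a22_as_17 <- dplyr::mutate(fx$a22, edition = "2017")
  diag_tt <- transition_table(a22_as_17, fx$a22)
  export_sankey(diag_tt, path)
  expect_length(jsonlite::read_json(path)$links, 3)

  empty <- transition_table(fx$a17[0, ], fx$a22[0, ])
  expect_error(export_sankey(empty, path), "empty")
})
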
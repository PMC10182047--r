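one_patient <- function(mutations, karyotype = "46,XX") {
  tibble::tibble(
    patient_id = "P1", age_years = 50L, sex = "female", intensive = TRUE,
    midostaurin = FALSE, mutations = list(mutations),
    karyotype = karyotype, os_months = 10, death = FALSE
  )
}

classify_one <- function(mutations, edition, karyotype = "46,XX") {
  eln_classify(one_patient(mutations, karyotype), edition, quiet = TRUE)
}

npm1_low_itd <- dplyr::bind_rows(
  mutation_calls("NPM1", 0.40),
  mutation_calls("FLT3", 0.30, itd_allelic_ratio = 0.3)
)

test_that("FLT3-ITD allelic ratio matters in 2017 but not in 2022", {
  a17 <- classify_one(npm1_low_itd, "2017")
  expect_equal(as.character(a17$resolved), "favorable")
  expect_false(a17$ambiguous)
  a22 <- classify_one(npm1_low_itd, "2022")
  expect_equal(as.character(a22$resolved), "intermediate")
  expect_match(a22$audit, "FLT3-ITD")
})

test_that("a lone MDS-gene mutation is intermediate in 2017, adverse in 2022", {
  m <- mutation_calls("SRSF2", 0.35)
  expect_equal(as.character(classify_one(m, "2017")$resolved), "intermediate")
  a22 <- classify_one(m, "2022")
  expect_equal(as.character(a22$resolved), "adverse")
  expect_match(a22$audit, "MDS-gene:SRSF2")
})

test_that("published ambiguous 2022 profiles resolve as reported", {
  # CEBPA bZIP (monoallelic) + FLT3-ITD: favorable wins, flagged ambiguous
  m <- dplyr::bind_rows(
    mutation_calls("CEBPA", 0.44, cebpa_biallelic = FALSE,
                   cebpa_bzip_inframe = TRUE),
    mutation_calls("FLT3", 0.30, itd_allelic_ratio = 0.8)
  )
  a <- classify_one(m, "2022")
  expect_equal(as.character(a$resolved), "favorable")
  expect_true(a$ambiguous)
  # adverse cytogenetics + FLT3-ITD + wild-type NPM1: adverse wins
  m <- mutation_calls("FLT3", 0.30, itd_allelic_ratio = 0.8)
  a <- classify_one(m, "2022", karyotype = "45,XX,-7")
  expect_equal(as.character(a$resolved), "adverse")
  expect_true(a$ambiguous)
})

test_that("published ambiguous 2017 profiles resolve as reported", {
  # NPM1 + high-ratio ITD + RUNX1 -> intermediate
  m <- dplyr::bind_rows(
    mutation_calls("NPM1", 0.40),
    mutation_calls("FLT3", 0.30, itd_allelic_ratio = 0.9),
    mutation_calls("RUNX1", 0.38)
  )
  a <- classify_one(m, "2017")
  expect_equal(as.character(a$resolved), "intermediate")
  expect_true(a$ambiguous)
  # high-ratio ITD + wild-type NPM1 + biallelic CEBPA -> favorable
  m <- dplyr::bind_rows(
    mutation_calls("FLT3", 0.30, itd_allelic_ratio = 0.9),
    mutation_calls("CEBPA", 0.44, cebpa_biallelic = TRUE,
                   cebpa_bzip_inframe = FALSE)
  )
  a <- classify_one(m, "2017")
  expect_equal(as.character(a$resolved), "favorable")
  expect_true(a$ambiguous)
})

test_that("suppression rules keep favorable profiles favorable", {
  # MDS gene co-occurring with NPM1 (no ITD) stays favorable in 2022
  m <- dplyr::bind_rows(mutation_calls("NPM1", 0.40),
                        mutation_calls("SRSF2", 0.30))
  a <- classify_one(m, "2022")
  expect_equal(as.character(a$resolved), "favorable")
  expect_false(a$ambiguous)
  # but NPM1 does not shield against adverse cytogenetics in 2022
  a <- classify_one(mutation_calls("NPM1", 0.40), "2022",
                    karyotype = "45,XY,-7")
  expect_equal(as.character(a$resolved), "adverse")
  expect_false(a$ambiguous)
  # NPM1 + FLT3-ITD + one MDS gene lands intermediate in 2022
  m <- dplyr::bind_rows(
    mutation_calls("NPM1", 0.40),
    mutation_calls("FLT3", 0.30, itd_allelic_ratio = 0.4),
    mutation_calls("SRSF2", 0.30)
  )
  expect_equal(as.character(classify_one(m, "2022")$resolved), "intermediate")
})

test_that("no defining lesion resolves to intermediate with audit 'other'", {
  a <- classify_one(mutation_calls("DNMT3A", 0.3), "2022")
  expect_equal(as.character(a$resolved), "intermediate")
  expect_equal(a$audit, "other")
  expect_false(a$ambiguous)
  expect_equal(nrow(eln_classify(one_patient(mutation_calls())[0, ], "2022",
                                 quiet = TRUE)), 0)
})

test_that("a policy lacking a matched lesion class is an explicit error", {
  matched <- match_defining_lesions(npm1_low_itd, "46,XX", "2022")
  broken <- dplyr::filter(eln_policy("2022"), class != "flt3_itd")
  expect_error(resolve_risk(matched, broken), "unresolvable")
})

test_that("Table 2 genetic subsets follow first-match row order", {
  a <- classify_one(mutation_calls("TP53", 0.5), "2022",
                    karyotype = "47,XX,del(12)(p13),add(21)(q22),+8")
  expect_equal(a$subset, "CK+TP53")
  expect_equal(classify_one(mutation_calls("NPM1", 0.4), "2022")$subset,
               "NPM1mut/FLT3-ITD-WT")
  expect_equal(classify_one(mutation_calls(), "2022")$subset,
               "Other abnormalities")
  # inv(3) outranks a concurrent complex karyotype
  a <- classify_one(mutation_calls(), "2022",
                    karyotype = "46,XX,inv(3)(q21q26.2)")
  expect_equal(a$subset, "inv(3)")
})

test_that("classification is deterministic and 2022 ignores the ITD ratio", {
  withr::local_seed(31)
  for (i in 1:50) {
    p <- random_profile()
    a1 <- classify_one(p$mutations, "2022", p$karyotype)
    a2 <- classify_one(p$mutations, "2022", p$karyotype)
    expect_identical(a1$resolved, a2$resolved)
    # perturb the allelic ratio of any ITD: 2022 result unchanged
    m2 <- p$mutations
    itd <- m2$gene == "FLT3" & !is.na(m2$itd_allelic_ratio)
    if (any(itd)) {
      m2$itd_allelic_ratio[itd] <- 1.4 - m2$itd_allelic_ratio[itd]
      a3 <- classify_one(m2, "2022", p$karyotype)
      expect_identical(a1$resolved, a3$resolved)
    }
  }
})

test_that("adding an MDS mutation never improves a 2022 intermediate profile", {
  withr::local_seed(32)
  rank <- function(x) match(as.character(x), eln_categories())
  n_checked <- 0
  for (i in 1:80) {
    p <- random_profile()
    base <- classify_one(p$mutations, "2022", p$karyotype)
    if (as.character(base$resolved) != "intermediate") next
    g <- sample(setdiff(mds_gene_panel(), p$mutations$gene), 1)
    m2 <- dplyr::bind_rows(p$mutations, mutation_calls(g, 0.3))
    worse <- classify_one(m2, "2022", p$karyotype)
    expect_gte(rank(worse$resolved), rank(base$resolved))
    n_checked <- n_checked + 1
  }
  expect_gt(n_checked, 5)
})

test_that("the engine agrees with a brute-force rule-row oracle on random profiles", {
  withr::local_seed(33)
  for (i in 1:500) {
    p <- random_profile()
    kept <- filter_reportable_variants(p$mutations)
    for (edition in c("2017", "2022")) {
      got <- eln_classify(one_patient(p$mutations, p$karyotype), edition,
                          quiet = TRUE)
      want <- oracle_classify(kept, p$karyotype, edition)
      expect_equal(as.character(got$resolved), want$resolved,
                   info = sprintf("%s: %s | %s", edition,
                                  paste(kept$gene, collapse = "+"),
                                  p$karyotype))
      expect_equal(got$ambiguous, want$ambiguous,
                   info = sprintf("ambiguity %s: %s | %s", edition,
                                  paste(kept$gene, collapse = "+"),
                                  p$karyotype))
    }
  }
})
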
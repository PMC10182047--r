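#' Cross-edition reclassification table
#'
#' Cross-classifies every patient by 2017 and 2022 resolved risk category
#' and labels each off-diagonal transition with the molecular feature
#' driving it, phrased as in the published reclassification report
#' ("Mutated NPM1 with low allelic ratio FLT3-ITD", "Mutated MDS genes
#' (not RUNX1 and ASXL1)", ...). Percentages are reported to 1 decimal,
#' round half up.
#'
#' @param a17,a22 Outputs of [eln_classify()] for editions 2017 and 2022
#'   on the same cohort (same patients, same order).
#' @return An object of class `eln_transition`: list with `counts` (3x3
#'   matrix, rows = 2017, columns = 2022), `n`, `reasons` (tibble with
#'   `from`, `to`, `reason`, `count`, `percent`) and `patients` (per
#'   patient from/to/reason).
#' @examples
#' cohort <- fixture_cohort()
#' tt <- transition_table(eln_classify(cohort, "2017"),
#'                        eln_classify(cohort, "2022"))
#' glance(tt)
#' @export
transition_table <- function(a17, a22) {
  if (!identical(a17$patient_id, a22$patient_id)) {
    abort("patient ids differ between the 2017 and 2022 assignments")
  }
  stopifnot(all(a17$edition == "2017"), all(a22$edition == "2022"))
  cats <- eln_categories()
  counts <- table(factor(a17$resolved, cats), factor(a22$resolved, cats))
  counts <- matrix(as.integer(counts), 3, 3,
                   dimnames = list(`2017` = cats, `2022` = cats))
  n <- nrow(a17)
  patients <- tibble(
    patient_id = a17$patient_id,
    from = as.character(a17$resolved),
    to = as.character(a22$resolved),
    reason = purrr::map_chr(seq_len(n), function(i) {
      transition_reason(a17[i, ], a22[i, ])
    })
  )
  reasons <- patients %>%
    filter(.data$from != .data$to) %>%
    count(.data$from, .data$to, .data$reason, name = "count") %>%
    mutate(percent = percent_of(.data$count, n)) %>%
    arrange(factor(.data$from, cats), factor(.data$to, cats))
  structure(list(counts = counts, n = n, reasons = reasons,
                 patients = patients),
            class = "eln_transition")
}

transition_reason <- function(p17, p22) {
  if (p17$resolved == p22$resolved) return("stable")
  itd_high <- p22$flt3_itd && !is.na(p22$itd_ratio) && p22$itd_ratio >= 0.5
  itd_low <- p22$flt3_itd && !itd_high
  from <- as.character(p17$resolved); to <- as.character(p22$resolved)
  if (from == "favorable" && to == "intermediate" && p22$npm1 && itd_low) {
    return("Mutated NPM1 with low allelic ratio FLT3-ITD")
  }
  if (from == "favorable" && to == "adverse" && p22$cebpa_biallelic &&
        !p22$cebpa_bzip && p22$n_mds_genes > 0) {
    return("Biallellic mutated CEBPA (not bZIP domain) + mutated MDS genes")
  }
  if (from == "intermediate" && to == "favorable" && p22$cebpa_bzip) {
    return("bZIP in frame mutated CEBPA (only one CEBPA mutation)")
  }
  if (from == "intermediate" && to == "adverse" && p22$n_mds_genes > 0) {
    return("Mutated MDS genes (not RUNX1 and ASXL1)")
  }
  if (from == "adverse" && to == "intermediate") {
    if (p22$hyperdiploid_trisomies_only && itd_high) {
      return("Hyperdiploid karyotype + high allelic ratio FLT3-ITD")
    }
    if (p22$hyperdiploid_trisomies_only) return("Hyperdiploid karyotype")
    if (itd_high) return("High allelic ratio FLT3-ITD")
  }
  "Other"
}

#' @export
print.eln_transition <- function(x, ...) {
  cat(sprintf("Cross-edition risk transitions, n = %d\n", x$n))
  print(x$counts)
  off <- x$n - sum(diag(x$counts))
  cat(sprintf("reclassified: %d (%.1f%%), worsened: %.1f%%\n",
              off, percent_of(off, x$n), worsened_fraction(x)))
  invisible(x)
}

#' @rdname transition_table
#' @param x An `eln_transition` object.
#' @param ... Unused.
#' @method tidy eln_transition
#' @export
tidy.eln_transition <- function(x, ...) {
  cats <- eln_categories()
  tibble(
    from = rep(cats, times = 3),
    to = rep(cats, each = 3),
    count = as.integer(x$counts[cbind(rep(1:3, times = 3),
                                      rep(1:3, each = 3))])
  ) %>%
    mutate(percent = percent_of(.data$count, x$n))
}

#' @rdname transition_table
#' @method glance eln_transition
#' @export
glance.eln_transition <- function(x, ...) {
  off <- x$n - sum(diag(x$counts))
  tibble(
    n = x$n,
    reclassified = off,
    reclassified_pct = percent_of(off, x$n),
    worsened_pct = worsened_fraction(x),
    improved_pct = improved_fraction(x)
  )
}

#' Fraction of patients moved to a worse prognosis group
#'
#' Sum of favorable-to-intermediate, favorable-to-adverse and
#' intermediate-to-adverse counts, as a percent of the cohort
#' (1 decimal, round half up).
#'
#' @param t An [transition_table()] result.
#' @return Percent (numeric scalar).
#' @export
worsened_fraction <- function(t) {
  k <- t$counts
  percent_of(k["favorable", "intermediate"] + k["favorable", "adverse"] +
               k["intermediate", "adverse"], t$n)
}

#' @rdname worsened_fraction
#' @export
improved_fraction <- function(t) {
  k <- t$counts
  percent_of(k["intermediate", "favorable"] + k["adverse", "favorable"] +
               k["adverse", "intermediate"], t$n)
}

#' Risk distribution by a covariate, with a chi-square test
#'
#' Builds the covariate x resolved-category contingency table, column
#' percents within covariate strata, and a Pearson chi-square test
#' (without continuity correction). With an empty stratum the p value is
#' undefined and reported as `NA`.
#'
#' @param assignments Output of [eln_classify()].
#' @param cohort The cohort tibble the assignments came from.
#' @param by `"age65"` (age <65 vs >=65) or `"sex"`.
#' @return A list with `table`, `percents`, `statistic`, `df`, `p`.
#' @export
subgroup_distribution <- function(assignments, cohort, by = c("age65", "sex")) {
  by <- match.arg(by)
  stopifnot(identical(assignments$patient_id, cohort$patient_id))
  strata <- if (by == "age65") {
    factor(ifelse(cohort$age_years >= 65, ">=65", "<65"),
           levels = c("<65", ">=65"))
  } else {
    factor(cohort$sex, levels = c("female", "male"))
  }
  tab <- table(strata, factor(assignments$resolved, eln_categories()))
  pct <- round_half_up(100 * prop.table(tab, margin = 1), 1)
  test_tab <- tab[, colSums(tab) > 0, drop = FALSE]
  if (any(rowSums(tab) == 0) || ncol(test_tab) < 2) {
    return(list(table = tab, percents = pct, statistic = NA_real_,
                df = NA_integer_, p = NA_real_))
  }
  ct <- suppressWarnings(chisq.test(test_tab, correct = FALSE))
  list(table = tab, percents = pct,
       statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value)
}

#' Export a transition table as Sankey flow JSON
#'
#' Writes a JSON object with `nodes` (six: one per category per edition)
#' and `links` (one per nonzero transition cell, with `source`, `target`,
#' `value` and a `reasons` breakdown for off-diagonal flows).
#'
#' @param t An [transition_table()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_sankey <- function(t, path) {
  if (t$n == 0) abort("cannot export a Sankey diagram for an empty cohort")
  cats <- eln_categories()
  nodes <- tibble(
    id = c(paste0("2017:", cats), paste0("2022:", cats)),
    edition = rep(c("2017", "2022"), each = 3),
    category = rep(cats, 2)
  )
  cells <- tidy(t) %>% filter(.data$count > 0)
  links <- purrr::pmap(cells, function(from, to, count, percent) {
    rs <- filter(t$reasons, .data$from == !!from, .data$to == !!to)
    list(
      source = paste0("2017:", from), target = paste0("2022:", to),
      value = count, percent = percent,
      reasons = if (nrow(rs) > 0) {
        purrr::pmap(rs, function(from, to, reason, count, percent) {
          list(reason = reason, count = count, percent = percent)
        })
      } else {
        list()
      }
    )
  })
  jsonlite::write_json(list(n = t$n, nodes = nodes, links = links), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
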
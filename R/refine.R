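#' Proposed refinements of the 2022 risk partition
#'
#' Two post-2022 proposals evaluated on top of a resolved 2022
#' classification:
#'
#' * **Very-adverse stratum** — patients with inv(3)/t(3;3) or a mutated
#'   TP53 (with or without complex karyotype) form a dismal-prognosis
#'   subgroup within the adverse category; `refined_category` becomes
#'   `"very-adverse"` for them. The CK+TP53 sub-case stays visible via
#'   the `subset` label of the base assignment.
#' * **MDS-burden reallocation** — an adverse patient whose ONLY
#'   adverse-defining lesions are MDS-related gene mutations, with
#'   exactly one mutated MDS gene, is reallocated to intermediate.
#'
#' Reallocation is applied before the very-adverse flag; disabling both
#' switches reproduces the base 2022 partition exactly. Reallocation can
#' only move adverse to intermediate, never the reverse.
#'
#' @param assignments Output of `eln_classify(cohort, "2022")`.
#' @param very_adverse,mds_burden Enable each refinement.
#' @return `assignments` plus columns `mds_burden` (`0`, `1`, `2+`),
#'   `very_adverse` and `refined_category` (factor with levels
#'   favorable, intermediate, adverse, very-adverse).
#' @examples
#' refine_risk(eln_classify(fixture_cohort(), "2022"))
#' @export
refine_risk <- function(assignments, very_adverse = TRUE, mds_burden = TRUE) {
  stopifnot(all(assignments$edition == "2022"))
  burden <- cut(assignments$n_mds_genes, breaks = c(-1, 0, 1, Inf),
                labels = c("0", "1", "2+"))
  only_mds_adverse <- purrr::map_lgl(assignments$matched, function(m) {
    adv <- m$label[m$category == "adverse"]
    length(adv) > 0 && all(startsWith(adv, "MDS-gene:"))
  })
  refined <- as.character(assignments$resolved)
  if (mds_burden) {
    move <- assignments$resolved == "adverse" & only_mds_adverse &
      assignments$n_mds_genes == 1
    refined[move] <- "intermediate"
  }
  va <- rep(FALSE, nrow(assignments))
  if (very_adverse) {
    va <- refined == "adverse" &
      (assignments$inv3_t3_3 | assignments$tp53)
    refined[va] <- "very-adverse"
  }
  mutate(assignments,
         mds_burden = burden,
         very_adverse = va,
         refined_category = factor(
           refined,
           levels = c(eln_categories(), "very-adverse")))
}

#' Flag the very-adverse profile of one assignment row
#'
#' True iff the patient resolved adverse under 2022 rules and carries
#' inv(3)/t(3;3) or a mutated TP53 (with or without complex karyotype).
#'
#' @param assignment One row of an `eln_classify(cohort, "2022")` result.
#' @return Logical scalar.
#' @export
flag_very_adverse <- function(assignment) {
  assignment$resolved == "adverse" &&
    (assignment$inv3_t3_3 || assignment$tp53)
}
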
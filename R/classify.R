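#' Default risk-resolution policies
#'
#' Precedence among classes of defining lesions, used when a patient
#' matches more than one risk category. Policies are data, not code: a
#' tibble with columns `class`, `category` and `rank` (1 = strongest);
#' users may reorder and pass the result to [eln_classify()].
#'
#' The 2022 default ranks adverse cytogenetic lesions above the CEBPA
#' bZIP favorable lesion, above the FLT3-ITD intermediate lesion, above
#' molecular adverse lesions, above the remaining favorable lesions.
#' This reproduces the two published resolutions of ambiguous 2022
#' profiles: adverse cytogenetics + FLT3-ITD resolves adverse, and CEBPA
#' bZIP + FLT3-ITD resolves favorable. The 2017 default reproduces the
#' published 2017 resolutions: NPM1 + high-ratio ITD + RUNX1 resolves
#' intermediate, and high-ratio ITD + biallelic CEBPA resolves favorable.
#' In both editions t(9;11) ranks above molecular adverse lesions
#' (guideline footnote: it takes precedence over rare concurrent
#' adverse-risk gene mutations).
#'
#' @param edition `"2017"` or `"2022"`.
#' @return A tibble with columns `class`, `category`, `rank`.
#' @export
eln_policy <- function(edition = c("2022", "2017")) {
  edition <- match.arg(as.character(edition), c("2022", "2017"))
  if (edition == "2022") {
    tibble(
      class = c("adverse_cytogenetic", "cebpa_bzip", "flt3_itd", "t9_11",
                "molecular_adverse", "favorable_molecular",
                "favorable_cytogenetic"),
      category = c("adverse", "favorable", "intermediate", "intermediate",
                   "adverse", "favorable", "favorable"),
      rank = 1:7
    )
  } else {
    tibble(
      class = c("adverse_cytogenetic", "favorable_cytogenetic",
                "favorable_molecular", "npm1_itd_intermediate", "t9_11",
                "molecular_adverse"),
      category = c("adverse", "favorable", "favorable", "intermediate",
                   "intermediate", "adverse"),
      rank = 1:6
    )
  }
}

# molecular + cytogenetic feature bundle for one patient
profile_features <- function(mutations, karyotype) {
  f <- derive_findings(if (inherits(karyotype, "karyotype")) karyotype
                       else parse_karyotype(karyotype))
  has <- function(g) any(mutations$gene == g)
  itd_rows <- mutations$gene == "FLT3" & !is.na(mutations$itd_allelic_ratio)
  cebpa <- filter(mutations, .data$gene == "CEBPA")
  mds <- intersect(unique(mutations$gene), mds_gene_panel())
  c(
    list(
      npm1 = has("NPM1"),
      flt3_itd = any(itd_rows),
      itd_ratio = if (any(itd_rows)) max(mutations$itd_allelic_ratio[itd_rows])
                  else NA_real_,
      cebpa_biallelic = nrow(cebpa) > 0 && isTRUE(any(cebpa$cebpa_biallelic)),
      cebpa_bzip = nrow(cebpa) > 0 && isTRUE(any(cebpa$cebpa_bzip_inframe)),
      runx1 = has("RUNX1"), asxl1 = has("ASXL1"), tp53 = has("TP53"),
      tp53_max_vaf = if (has("TP53")) max(mutations$vaf[mutations$gene == "TP53"])
                     else NA_real_,
      mds_genes = list(mds), n_mds_genes = length(mds)
    ),
    as.list(f)
  )
}

#' Match the defining lesions of a profile
#'
#' Evaluates every rule row of the requested ELN edition against one
#' patient's reportable mutations and cytogenetic findings, returning all
#' matches (possibly in more than one risk category) without resolving
#' precedence. Suppression rules applied at match time: in 2017,
#' RUNX1/ASXL1 are not used as adverse markers when a favorable-defining
#' lesion co-occurs; in 2022, the same holds for all nine MDS-related
#' genes, and NPM1 does not define favorable risk in the presence of an
#' adverse cytogenetic lesion.
#'
#' @param mutations Reportable-filtered mutation-call tibble.
#' @param karyotype Karyotype string or [parse_karyotype()] object.
#' @param edition `"2017"` or `"2022"`.
#' @param tp53_vaf_min Minimum TP53 VAF for the 2022 TP53 rule
#'   (default 0: any reportable TP53 mutation counts).
#' @return A tibble with columns `category`, `label`, `class`; zero rows
#'   when no defining lesion matches.
#' @export
match_defining_lesions <- function(mutations, karyotype,
                                   edition = c("2022", "2017"),
                                   tp53_vaf_min = 0) {
  edition <- match.arg(as.character(edition), c("2022", "2017"))
  ft <- profile_features(mutations, karyotype)
  rows <- list()
  add <- function(category, label, class) {
    rows[[length(rows) + 1]] <<- tibble(category = category, label = label,
                                        class = class)
  }
  itd_high <- ft$flt3_itd && !is.na(ft$itd_ratio) && ft$itd_ratio >= 0.5
  itd_low <- ft$flt3_itd && !itd_high

  if (edition == "2017") {
    if (ft$t_8_21) add("favorable", "t(8;21)", "favorable_cytogenetic")
    if (ft$inv16_t16_16) add("favorable", "inv(16)/t(16;16)", "favorable_cytogenetic")
    npm1_fav <- ft$npm1 && (!ft$flt3_itd || itd_low)
    if (npm1_fav) {
      add("favorable",
          if (ft$flt3_itd) "NPM1mut with low-ratio FLT3-ITD"
          else "NPM1mut without FLT3-ITD",
          "favorable_molecular")
    }
    if (ft$cebpa_biallelic) add("favorable", "biallelic CEBPA", "favorable_molecular")
    favorable_present <- ft$t_8_21 || ft$inv16_t16_16 || npm1_fav ||
      ft$cebpa_biallelic

    if (ft$npm1 && itd_high) {
      add("intermediate", "NPM1mut with high-ratio FLT3-ITD",
          "npm1_itd_intermediate")
    }
    if (ft$t_9_11) add("intermediate", "t(9;11)", "t9_11")

    adverse_cyto <- c(
      "t(6;9)" = ft$t_6_9, "t(v;11q23.3)" = ft$t_v_11q23,
      "t(9;22)" = ft$t_9_22, "inv(3)/t(3;3)" = ft$inv3_t3_3,
      "-5/del(5q)" = ft$del5_minus5, "-7" = ft$minus7,
      "-17/abn(17p)" = ft$minus17_abn17p,
      "complex karyotype" = ft$complex_2017,
      "monosomal karyotype" = ft$monosomal
    )
    for (lab in names(adverse_cyto)[adverse_cyto]) {
      add("adverse", lab, "adverse_cytogenetic")
    }
    if (!ft$npm1 && itd_high) {
      add("adverse", "FLT3-ITD high ratio with wild-type NPM1",
          "molecular_adverse")
    }
    if (ft$runx1 && !favorable_present) add("adverse", "RUNX1", "molecular_adverse")
    if (ft$asxl1 && !favorable_present) add("adverse", "ASXL1", "molecular_adverse")
    if (ft$tp53) add("adverse", "TP53", "molecular_adverse")
  } else {
    adverse_cyto <- c(
      "t(6;9)" = ft$t_6_9, "t(v;11q23.3)" = ft$t_v_11q23,
      "t(9;22)" = ft$t_9_22, "t(8;16)" = ft$t_8_16,
      "inv(3)/t(3;3)" = ft$inv3_t3_3, "t(3q26.2;v)" = ft$t_3q26_v,
      "-5/del(5q)" = ft$del5_minus5, "-7" = ft$minus7,
      "-17/abn(17p)" = ft$minus17_abn17p,
      "complex karyotype" = ft$complex_2022,
      "monosomal karyotype" = ft$monosomal
    )
    adverse_cyto_present <- any(adverse_cyto)

    if (ft$t_8_21) add("favorable", "t(8;21)", "favorable_cytogenetic")
    if (ft$inv16_t16_16) add("favorable", "inv(16)/t(16;16)", "favorable_cytogenetic")
    npm1_fav <- ft$npm1 && !ft$flt3_itd && !adverse_cyto_present
    if (npm1_fav) add("favorable", "NPM1mut without FLT3-ITD", "favorable_molecular")
    if (ft$cebpa_bzip) add("favorable", "CEBPA bZIP in-frame", "cebpa_bzip")
    favorable_present <- ft$t_8_21 || ft$inv16_t16_16 || npm1_fav || ft$cebpa_bzip

    if (ft$flt3_itd) add("intermediate", "FLT3-ITD", "flt3_itd")
    if (ft$t_9_11) add("intermediate", "t(9;11)", "t9_11")

    for (lab in names(adverse_cyto)[adverse_cyto]) {
      add("adverse", lab, "adverse_cytogenetic")
    }
    if (!favorable_present) {
      for (g in ft$mds_genes[[1]]) {
        add("adverse", paste0("MDS-gene:", g), "molecular_adverse")
      }
    }
    tp53_hit <- ft$tp53 && (tp53_vaf_min <= 0 || ft$tp53_max_vaf >= tp53_vaf_min)
    if (tp53_hit) add("adverse", "TP53", "molecular_adverse")
  }
  if (length(rows) == 0) {
    tibble(category = character(), label = character(), class = character())
  } else {
    bind_rows(rows)
  }
}

#' Resolve matched lesions into a single risk category
#'
#' Applies a precedence policy to the multi-category match table of one
#' patient. The resolved category is that of the strongest matched lesion
#' class; the ambiguity flag records whether the matches span more than
#' one category; the audit trail lists every fired rule in precedence
#' order. An empty match table resolves to intermediate with the lesion
#' label `"other"`.
#'
#' @param matched Output of [match_defining_lesions()].
#' @param policy A policy tibble, see [eln_policy()].
#' @return A list with `resolved`, `ambiguous`, `audit` (character),
#'   `matched` (the input, ranked).
#' @export
resolve_risk <- function(matched, policy) {
  if (nrow(matched) == 0) {
    return(list(resolved = "intermediate", ambiguous = FALSE,
                audit = "other", matched = matched))
  }
  unknown <- setdiff(unique(matched$class), policy$class)
  if (length(unknown) > 0) {
    cats <- paste(sort(unique(matched$category)), collapse = " vs ")
    abort(sprintf(
      "unresolvable: policy has no rank for lesion class(es) %s (categories %s)",
      paste(unknown, collapse = ", "), cats))
  }
  ranked <- arrange(left_join(matched, policy, by = c("class", "category")),
                    .data$rank)
  list(
    resolved = ranked$category[[1]],
    ambiguous = length(unique(matched$category)) > 1,
    audit = paste(ranked$label, collapse = "; "),
    matched = ranked
  )
}

# Table 2 genetic-subset label, first match in published row order
assign_subset <- function(ft, resolved) {
  itd <- ft$flt3_itd
  if (resolved == "adverse") {
    if (ft$inv3_t3_3) return("inv(3)")
    if (ft$del5_minus5 || ft$minus7 || ft$minus17_abn17p) return("(-5, -7, -17)")
    if (ft$complex_2022 && ft$tp53) return("CK+TP53")
    if (ft$tp53) return("Mutated TP53")
    if (ft$complex_2022) return("Complex karyotype")
    if (ft$n_mds_genes > 0) return("MDS-mutated genes")
    if (ft$t_v_11q23) return("t(v;11q23)")
    if (ft$t_6_9) return("t(6;9)")
    if (ft$t_9_22) return("t(9;22)")
    return("Other adverse")
  }
  if (resolved == "favorable") {
    if (ft$npm1 && !itd) return("NPM1mut/FLT3-ITD-WT")
    if (ft$cebpa_bzip) return("CEBPA-bZIP")
    if (ft$inv16_t16_16) return("inv(16)")
    if (ft$t_8_21) return("t(8;21)")
    return("Other favorable")
  }
  if (ft$npm1 && itd) return("NPM1mut/FLT3-ITD-mut")
  if (itd) return("NPM1-WT/FLT3-ITD-mut")
  if (ft$t_9_11) return("t(9;11)")
  "Other abnormalities"
}

#' Classify a cohort under an ELN edition
#'
#' Runs the variant-reporting filter, lesion matching, precedence
#' resolution and (for 2022) genetic-subset labeling over every patient,
#' preserving input order, and reports an ambiguity census to stderr.
#'
#' @param cohort A cohort tibble (see [read_cohort()]).
#' @param edition `"2017"` or `"2022"`.
#' @param policy Precedence policy; defaults to [eln_policy()] for the
#'   edition.
#' @param tp53_vaf_min Passed to [match_defining_lesions()].
#' @param quiet Suppress the ambiguity census message.
#' @return A tibble, one row per patient: `patient_id`, `edition`,
#'   `resolved` (factor favorable/intermediate/adverse), `ambiguous`,
#'   `subset` (2022 only), `audit`, a `matched` list-column, and the
#'   molecular/cytogenetic feature columns used downstream
#'   (`npm1`, `flt3_itd`, `itd_ratio`, `cebpa_biallelic`, `cebpa_bzip`,
#'   `tp53`, `n_mds_genes`, `inv3_t3_3`, `complex_2022`,
#'   `hyperdiploid_trisomies_only`).
#' @examples
#' cohort <- fixture_cohort()
#' a22 <- eln_classify(cohort, "2022")
#' table(a22$resolved)
#' @export
eln_classify <- function(cohort, edition = c("2022", "2017"), policy = NULL,
                         tp53_vaf_min = 0, quiet = FALSE) {
  edition <- match.arg(as.character(edition), c("2022", "2017"))
  policy <- policy %||% eln_policy(edition)
  rows <- purrr::map(seq_len(nrow(cohort)), function(i) {
    pid <- cohort$patient_id[[i]]
    tryCatch({
      m <- filter_reportable_variants(cohort$mutations[[i]])
      ft <- profile_features(m, cohort$karyotype[[i]])
      matched <- match_defining_lesions(m, cohort$karyotype[[i]], edition,
                                        tp53_vaf_min = tp53_vaf_min)
      res <- resolve_risk(matched, policy)
      tibble(
        patient_id = pid,
        edition = edition,
        resolved = factor(res$resolved, levels = eln_categories()),
        ambiguous = res$ambiguous,
        subset = if (edition == "2022") assign_subset(ft, res$resolved)
                 else NA_character_,
        audit = res$audit,
        matched = list(res$matched),
        npm1 = ft$npm1, flt3_itd = ft$flt3_itd, itd_ratio = ft$itd_ratio,
        cebpa_biallelic = ft$cebpa_biallelic, cebpa_bzip = ft$cebpa_bzip,
        tp53 = ft$tp53, n_mds_genes = ft$n_mds_genes,
        inv3_t3_3 = ft$inv3_t3_3, complex_2022 = ft$complex_2022,
        hyperdiploid_trisomies_only = ft$hyperdiploid_trisomies_only
      )
    }, error = function(e) {
      abort(sprintf("patient %s: %s", pid, conditionMessage(e)))
    })
  })
  out <- bind_rows(rows)
  if (!quiet && nrow(out) > 0) {
    n_amb <- sum(out$ambiguous)
    inform(sprintf(
      "%s ELN: %d/%d patients (%.1f%%) matched more than one risk category",
      edition, n_amb, nrow(out), 100 * n_amb / nrow(out)))
  }
  out
}

#' Ambiguity census of a classified cohort
#'
#' @param assignments Output of [eln_classify()].
#' @return A one-row tibble: `n`, `ambiguous`, `percent` (1 decimal).
#' @export
ambiguity_census <- function(assignments) {
  tibble(
    n = nrow(assignments),
    ambiguous = sum(assignments$ambiguous),
    percent = percent_of(sum(assignments$ambiguous), nrow(assignments))
  )
}
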
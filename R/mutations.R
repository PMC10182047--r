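#' Build a mutation-call table
#'
#' One row per reported somatic variant. `vaf` is a fraction in \[0, 1\].
#' `itd_allelic_ratio` encodes a FLT3 internal tandem duplication: a
#' non-missing value means an ITD is present with that mutant/wild-type
#' allelic ratio, and is only permitted on FLT3 rows. The CEBPA
#' annotations (`cebpa_biallelic`, `cebpa_bzip_inframe`) are input flags,
#' only permitted on CEBPA rows; bZIP domain coordinates are not modelled.
#'
#' @param gene Uppercase HGNC symbol from [eln_gene_panel()].
#' @param vaf Variant allele frequency as a fraction in \[0, 1\].
#' @param pathogenic Logical; pathogenic or probably damaging.
#' @param hotspot Logical; variant lies in a recognized hotspot region.
#' @param itd_allelic_ratio FLT3-ITD allelic ratio (`NA` = no ITD).
#' @param cebpa_biallelic,cebpa_bzip_inframe CEBPA allelic-state and
#'   bZIP in-frame annotations (`NA` on non-CEBPA rows).
#' @return A tibble with class-checked columns, one row per variant.
#' @examples
#' mutation_calls(gene = c("NPM1", "FLT3"), vaf = c(0.4, 0.3),
#'                itd_allelic_ratio = c(NA, 0.8))
#' @export
mutation_calls <- function(gene = character(), vaf = numeric(),
                           pathogenic = TRUE, hotspot = FALSE,
                           itd_allelic_ratio = NA_real_,
                           cebpa_biallelic = NA,
                           cebpa_bzip_inframe = NA) {
  m <- tibble(
    gene = toupper(as.character(gene)),
    vaf = as.numeric(vaf),
    pathogenic = as.logical(pathogenic),
    hotspot = as.logical(hotspot),
    itd_allelic_ratio = as.numeric(itd_allelic_ratio),
    cebpa_biallelic = as.logical(cebpa_biallelic),
    cebpa_bzip_inframe = as.logical(cebpa_bzip_inframe)
  )
  validate_mutations(m)
  m
}

validate_mutations <- function(m, context = "mutation table") {
  bad_gene <- setdiff(unique(m$gene), eln_gene_panel())
  if (length(bad_gene) > 0) {
    abort(sprintf("%s: unknown gene symbol(s): %s", context,
                  paste(bad_gene, collapse = ", ")))
  }
  if (any(!is.na(m$vaf) & (m$vaf < 0 | m$vaf > 1))) {
    abort(sprintf("%s: vaf out of range [0, 1]", context))
  }
  if (any(!is.na(m$itd_allelic_ratio) & m$gene != "FLT3")) {
    abort(sprintf("%s: itd_allelic_ratio only allowed on FLT3 rows", context))
  }
  if (any(!is.na(m$itd_allelic_ratio) & m$itd_allelic_ratio < 0)) {
    abort(sprintf("%s: itd_allelic_ratio must be nonnegative", context))
  }
  if (any((!is.na(m$cebpa_biallelic) | !is.na(m$cebpa_bzip_inframe)) &
            m$gene != "CEBPA")) {
    abort(sprintf("%s: cebpa_* annotations only allowed on CEBPA rows", context))
  }
  invisible(m)
}

#' Variant-reporting filter
#'
#' Applies the consensus reporting rule used at diagnosis: pathogenic or
#' probably damaging variants with VAF >= 5% are kept; variants with VAF
#' in \[1%, 5%) are kept only when flagged as hotspot. Everything else is
#' dropped. Idempotent; the result is always a subset of the input.
#'
#' @param mutations A mutation-call tibble (see [mutation_calls()]).
#' @return The retained rows, same columns.
#' @examples
#' m <- mutation_calls(gene = c("NPM1", "TET2"), vaf = c(0.40, 0.03))
#' filter_reportable_variants(m)
#' @export
filter_reportable_variants <- function(mutations) {
  filter(
    mutations,
    (.data$pathogenic & .data$vaf >= 0.05) |
      (.data$vaf >= 0.01 & .data$vaf < 0.05 & .data$hotspot)
  )
}

#' Count distinct mutated MDS-related genes
#'
#' Number of DISTINCT genes among the nine myelodysplasia-related genes
#' ([mds_gene_panel()]) carrying at least one reportable mutation.
#' Multiple variants in the same gene count once.
#'
#' @param mutations A mutation-call tibble, already reportable-filtered.
#' @return A nonnegative integer, at most 9.
#' @examples
#' count_mds_genes(mutation_calls(gene = c("SRSF2", "STAG2"), vaf = 0.3))
#' @export
count_mds_genes <- function(mutations) {
  length(intersect(unique(mutations$gene), mds_gene_panel()))
}
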
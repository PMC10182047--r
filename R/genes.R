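#' Gene panels used by the classifier
#'
#' `eln_gene_panel()` returns the 32-gene myeloid NGS panel accepted in
#' mutation tables. `mds_gene_panel()` returns the nine
#' myelodysplasia-related (MDS) genes that define adverse genetic risk in
#' the 2022 ELN classification.
#'
#' @return A character vector of uppercase HGNC gene symbols.
#' @examples
#' "SRSF2" %in% mds_gene_panel()
#' @export
eln_gene_panel <- function() {
  c(
    "ASXL1", "BCOR", "BRAF", "CALR", "CBL", "CEBPA", "CSF3R", "DNMT3A",
    "ETV6", "EZH2", "FLT3", "GATA2", "HRAS", "IDH1", "IDH2", "JAK2",
    "KIT", "KRAS", "MPL", "NPM1", "NRAS", "PTPN11", "RUNX1", "SETBP1",
    "SF3B1", "SRSF2", "STAG2", "TET2", "TP53", "U2AF1", "WT1", "ZRSR2"
  )
}

#' @rdname eln_gene_panel
#' @export
mds_gene_panel <- function() {
  c(
    "ASXL1", "BCOR", "EZH2", "RUNX1", "SF3B1", "SRSF2", "STAG2",
    "U2AF1", "ZRSR2"
  )
}

# shared category vocabulary, in display order
eln_categories <- function() c("favorable", "intermediate", "adverse")

# round half away from zero, the convention used for printed percentages
round_half_up <- function(x, digits = 1) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

percent_of <- function(count, n, digits = 1) round_half_up(100 * count / n, digits)
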
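# Independent brute-force oracles: every flag and rule row is re-checked
# with plain loops over the raw abnormality/mutation rows, with no code
# shared with the package's matching engine beyond the input containers.

oracle_findings <- function(k) {
  a <- k$abnormalities
  flags <- list(
    t_8_21 = FALSE, inv16_t16_16 = FALSE, t_9_11 = FALSE, t_v_11q23 = FALSE,
    t_6_9 = FALSE, t_9_22 = FALSE, t_8_16 = FALSE, inv3_t3_3 = FALSE,
    t_3q26_v = FALSE, del5_minus5 = FALSE, minus7 = FALSE,
    minus17_abn17p = FALSE
  )
  n_auto_mono <- 0L
  n_structural <- 0L
  for (i in seq_len(nrow(a))) {
    kind <- a$kind[i]; c1 <- a$chrom1[i]; c2 <- a$chrom2[i]
    b1 <- a$band1[i]; b2 <- a$band2[i]
    pair <- function(x, y) {
      kind == "translocation" &&
        ((c1 == x && c2 == y) || (c1 == y && c2 == x))
    }
    band_of <- function(chrom) {
      if (kind != "translocation") return(NA_character_)
      if (identical(c1, chrom)) return(b1)
      if (identical(c2, chrom)) return(b2)
      NA_character_
    }
    if (pair("8", "21")) flags$t_8_21 <- TRUE
    if ((kind == "inversion" && c1 == "16") || pair("16", "16")) {
      flags$inv16_t16_16 <- TRUE
    }
    if (pair("9", "11")) flags$t_9_11 <- TRUE
    b11 <- band_of("11")
    if (kind == "translocation" && !is.na(b11) && grepl("^q23", b11) &&
          !pair("9", "11")) {
      flags$t_v_11q23 <- TRUE
    }
    if (pair("6", "9")) flags$t_6_9 <- TRUE
    if (pair("9", "22")) flags$t_9_22 <- TRUE
    if (pair("8", "16")) flags$t_8_16 <- TRUE
    if ((kind == "inversion" && c1 == "3") || pair("3", "3")) {
      flags$inv3_t3_3 <- TRUE
    }
    b3 <- band_of("3")
    if (kind == "translocation" && !is.na(b3) && grepl("^q26", b3) &&
          !pair("3", "3")) {
      flags$t_3q26_v <- TRUE
    }
    if (kind == "monosomy" && c1 == "5") flags$del5_minus5 <- TRUE
    if (kind == "deletion" && c1 == "5" && (is.na(b1) || grepl("^q", b1))) {
      flags$del5_minus5 <- TRUE
    }
    if (kind == "monosomy" && c1 == "7") flags$minus7 <- TRUE
    if (kind == "monosomy" && c1 == "17") flags$minus17_abn17p <- TRUE
    if (kind %in% c("deletion", "addition") && c1 == "17" &&
          !is.na(b1) && grepl("^p", b1)) {
      flags$minus17_abn17p <- TRUE
    }
    b17 <- band_of("17")
    if (kind == "translocation" && !is.na(b17) && grepl("^p", b17)) {
      flags$minus17_abn17p <- TRUE
    }
    if (kind == "monosomy" && c1 %in% as.character(1:22)) {
      n_auto_mono <- n_auto_mono + 1L
    }
    if (!kind %in% c("trisomy", "monosomy")) n_structural <- n_structural + 1L
  }
  defining <- flags$t_8_21 || flags$inv16_t16_16 || flags$t_9_11 ||
    flags$t_v_11q23 || flags$t_6_9 || flags$t_9_22 || flags$t_8_16 ||
    flags$inv3_t3_3 || flags$t_3q26_v
  flags$hyperdiploid_trisomies_only <-
    nrow(a) >= 3 && all(a$kind == "trisomy")
  flags$complex_2017 <- !defining && nrow(a) >= 3
  flags$complex_2022 <- flags$complex_2017 && !flags$hyperdiploid_trisomies_only
  flags$monosomal <- n_auto_mono >= 2 ||
    (n_auto_mono == 1 && n_structural >= 1)
  flags$n_abnormalities <- nrow(a)
  flags$n_autosomal_monosomies <- n_auto_mono
  flags
}

# literal rule-row scan; returns resolved category + ambiguity flag
oracle_classify <- function(mutations, karyotype, edition) {
  f <- oracle_findings(parse_karyotype(karyotype))
  genes <- mutations$gene
  npm1 <- "NPM1" %in% genes
  itd_ratio <- NA_real_
  for (i in seq_len(nrow(mutations))) {
    if (mutations$gene[i] == "FLT3" && !is.na(mutations$itd_allelic_ratio[i])) {
      r <- mutations$itd_allelic_ratio[i]
      if (is.na(itd_ratio) || r > itd_ratio) itd_ratio <- r
    }
  }
  itd <- !is.na(itd_ratio)
  itd_high <- itd && itd_ratio >= 0.5
  cebpa_bi <- FALSE; cebpa_bzip <- FALSE
  for (i in seq_len(nrow(mutations))) {
    if (mutations$gene[i] == "CEBPA") {
      if (isTRUE(mutations$cebpa_biallelic[i])) cebpa_bi <- TRUE
      if (isTRUE(mutations$cebpa_bzip_inframe[i])) cebpa_bzip <- TRUE
    }
  }
  mds <- unique(genes[genes %in% c("ASXL1", "BCOR", "EZH2", "RUNX1", "SF3B1",
                                   "SRSF2", "STAG2", "U2AF1", "ZRSR2")])
  tp53 <- "TP53" %in% genes

  fired <- list()  # list of c(category, tier)
  hit <- function(category, tier) {
    fired[[length(fired) + 1]] <<- list(category = category, tier = tier)
  }
  if (edition == "2017") {
    adv_cyto <- f$t_6_9 || f$t_v_11q23 || f$t_9_22 || f$inv3_t3_3 ||
      f$del5_minus5 || f$minus7 || f$minus17_abn17p || f$complex_2017 ||
      f$monosomal
    npm1_fav <- npm1 && (!itd || !itd_high)
    fav <- f$t_8_21 || f$inv16_t16_16 || npm1_fav || cebpa_bi
    if (adv_cyto) hit("adverse", 1)
    if (f$t_8_21 || f$inv16_t16_16) hit("favorable", 2)
    if (npm1_fav || cebpa_bi) hit("favorable", 3)
    if (npm1 && itd_high) hit("intermediate", 4)
    if (f$t_9_11) hit("intermediate", 5)
    if (!npm1 && itd_high) hit("adverse", 6)
    if ("RUNX1" %in% genes && !fav) hit("adverse", 6)
    if ("ASXL1" %in% genes && !fav) hit("adverse", 6)
    if (tp53) hit("adverse", 6)
  } else {
    adv_cyto <- f$t_6_9 || f$t_v_11q23 || f$t_9_22 || f$t_8_16 ||
      f$inv3_t3_3 || f$t_3q26_v || f$del5_minus5 || f$minus7 ||
      f$minus17_abn17p || f$complex_2022 || f$monosomal
    npm1_fav <- npm1 && !itd && !adv_cyto
    fav <- f$t_8_21 || f$inv16_t16_16 || npm1_fav || cebpa_bzip
    if (adv_cyto) hit("adverse", 1)
    if (cebpa_bzip) hit("favorable", 2)
    if (itd) hit("intermediate", 3)
    if (f$t_9_11) hit("intermediate", 4)
    if (length(mds) > 0 && !fav) hit("adverse", 5)
    if (tp53) hit("adverse", 5)
    if (npm1_fav) hit("favorable", 6)
    if (f$t_8_21 || f$inv16_t16_16) hit("favorable", 7)
  }
  if (length(fired) == 0) {
    return(list(resolved = "intermediate", ambiguous = FALSE))
  }
  tiers <- vapply(fired, function(x) x$tier, numeric(1))
  cats <- vapply(fired, function(x) x$category, character(1))
  list(resolved = cats[which.min(tiers)],
       ambiguous = length(unique(cats)) > 1)
}

# random-profile generator for the oracle-equivalence property tests
random_profile <- function() {
  pool_genes <- c("NPM1", "FLT3", "CEBPA", "TP53", "RUNX1", "ASXL1",
                  "SRSF2", "STAG2", "BCOR", "U2AF1", "SF3B1", "DNMT3A",
                  "TET2", "IDH1", "NRAS")
  n_mut <- sample(0:4, 1)
  genes <- sample(pool_genes, n_mut)
  muts <- mutation_calls()
  for (g in genes) {
    if (g == "FLT3") {
      muts <- dplyr::bind_rows(muts, mutation_calls(
        "FLT3", runif(1, 0.06, 0.5),
        itd_allelic_ratio = if (runif(1) < 0.8) round(runif(1, 0, 1.5), 2)
                            else NA_real_))
    } else if (g == "CEBPA") {
      muts <- dplyr::bind_rows(muts, mutation_calls(
        "CEBPA", runif(1, 0.06, 0.5),
        cebpa_biallelic = runif(1) < 0.5,
        cebpa_bzip_inframe = runif(1) < 0.5))
    } else {
      muts <- dplyr::bind_rows(muts, mutation_calls(g, runif(1, 0.06, 0.5)))
    }
  }
  token_pool <- c("t(8;21)(q22;q22)", "inv(16)(p13.1q22)", "t(9;11)(p21;q23)",
                  "t(4;11)(q21;q23)", "t(6;9)(p23;q34)", "t(9;22)(q34;q11)",
                  "t(8;16)(p11.2;p13.3)", "inv(3)(q21q26.2)",
                  "t(3;21)(q26;q22)", "del(5)(q31)", "-5", "-7", "-17",
                  "del(17)(p13)", "add(17)(p13)", "+8", "+13", "+21",
                  "del(12)(p13)", "add(21)(q22)", "-18", "del(20)(q11)")
  n_abn <- sample(0:5, 1, prob = c(0.35, 0.2, 0.15, 0.15, 0.1, 0.05))
  tokens <- sample(token_pool, n_abn)
  kar <- paste(c("46", sample(c("XX", "XY"), 1), tokens), collapse = ",")
  list(mutations = muts, karyotype = kar)
}

random_karyotype <- function() {
  random_profile()$karyotype
}
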
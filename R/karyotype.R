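#' Parse a restricted ISCN karyotype string
#'
#' Accepts the dialect `modal,sex[,abn1,abn2,...]` with abnormality tokens
#' `t(a;b)(p;q)`, `inv(n)(p q)`, `del(n)(band)`, `add(n)(band)`, `+n`,
#' `-n` and `+mar`/`mar`. Band sublists are optional. This is not a full
#' ISCN 2020 grammar: no subclones, composite karyotypes or FISH
#' nomenclature. The string `"unknown"` (or `NA`) yields a karyotype with
#' unknown cytogenetics, which classifies as intermediate-by-cytogenetics
#' unless molecular markers decide otherwise.
#'
#' @param iscn Karyotype string, e.g. `"46,XY,t(8;21)(q22;q22)"`.
#' @param strict If `TRUE` an unparseable token is an error; otherwise it
#'   is recorded as an `other` structural abnormality with a warning.
#' @return An object of class `karyotype`: a list with `modal_number`,
#'   `sex_chromosomes`, `abnormalities` (tibble with columns `kind`,
#'   `chrom1`, `chrom2`, `band1`, `band2`, `token`), `normal`, `unknown`.
#' @examples
#' parse_karyotype("49,XX,+8,+13,+21")
#' @export
parse_karyotype <- function(iscn, strict = TRUE) {
  empty_abn <- tibble(
    kind = character(), chrom1 = character(), chrom2 = character(),
    band1 = character(), band2 = character(), token = character()
  )
  if (is.null(iscn) || is.na(iscn) || identical(tolower(trimws(iscn)), "unknown")) {
    return(structure(
      list(modal_number = NA_integer_, sex_chromosomes = NA_character_,
           abnormalities = empty_abn, normal = FALSE, unknown = TRUE),
      class = "karyotype"
    ))
  }
  iscn <- trimws(iscn)
  if (iscn == "") abort("empty karyotype string")
  parts <- strsplit(iscn, ",", fixed = TRUE)[[1]]
  parts <- trimws(parts)
  modal <- suppressWarnings(as.integer(parts[[1]]))
  if (is.na(modal) || modal < 30 || modal > 100) {
    abort(sprintf("malformed modal chromosome number in %s", sQuote(iscn)))
  }
  if (length(parts) < 2 || !grepl("^[XY]+$", parts[[2]])) {
    abort(sprintf("missing sex-chromosome field in %s", sQuote(iscn)))
  }
  tokens <- if (length(parts) > 2) parts[-(1:2)] else character()
  abn <- purrr::map(tokens, parse_abnormality_token, strict = strict)
  abn <- if (length(abn)) bind_rows(abn) else empty_abn
  structure(
    list(modal_number = modal, sex_chromosomes = parts[[2]],
         abnormalities = abn, normal = nrow(abn) == 0, unknown = FALSE),
    class = "karyotype"
  )
}

#' @export
print.karyotype <- function(x, ...) {
  if (x$unknown) {
    cat("<karyotype: unknown>\n")
  } else {
    cat(sprintf("<karyotype: modal %d, %s, %d abnormalit%s>\n",
                x$modal_number, x$sex_chromosomes, nrow(x$abnormalities),
                if (nrow(x$abnormalities) == 1) "y" else "ies"))
  }
  invisible(x)
}

parse_abnormality_token <- function(token, strict = TRUE) {
  row <- function(kind, chrom1 = NA, chrom2 = NA, band1 = NA, band2 = NA) {
    tibble(kind = kind, chrom1 = as.character(chrom1),
           chrom2 = as.character(chrom2), band1 = as.character(band1),
           band2 = as.character(band2), token = token)
  }
  chrom_rx <- "([0-9]{1,2}|X|Y)"
  band_rx <- "([pq][0-9.]*)"
  if (grepl(paste0("^\\+", chrom_rx, "$"), token)) {
    return(row("trisomy", chrom1 = sub("^\\+", "", token)))
  }
  if (grepl(paste0("^-", chrom_rx, "$"), token)) {
    return(row("monosomy", chrom1 = sub("^-", "", token)))
  }
  if (token %in% c("mar", "+mar")) return(row("marker"))
  m <- stringr::str_match(
    token,
    paste0("^t\\(", chrom_rx, ";", chrom_rx, "\\)",
           "(?:\\(", band_rx, ";", band_rx, "\\))?$")
  )
  if (!is.na(m[1, 1])) {
    return(row("translocation", m[1, 2], m[1, 3], m[1, 4], m[1, 5]))
  }
  m <- stringr::str_match(
    token,
    paste0("^inv\\(", chrom_rx, "\\)", "(?:\\(", band_rx, band_rx, "\\))?$")
  )
  if (!is.na(m[1, 1])) {
    return(row("inversion", m[1, 2], band1 = m[1, 3], band2 = m[1, 4]))
  }
  m <- stringr::str_match(
    token,
    paste0("^(del|add)\\(", chrom_rx, "\\)", "(?:\\(", band_rx, "\\))?$")
  )
  if (!is.na(m[1, 1])) {
    kind <- if (m[1, 2] == "del") "deletion" else "addition"
    return(row(kind, m[1, 3], band1 = m[1, 4]))
  }
  if (strict) abort(sprintf("unparseable karyotype token %s", sQuote(token)))
  warn(sprintf("karyotype token %s recorded as other-structural", sQuote(token)))
  row("other")
}

#' Build a karyotype from a structured abnormality list
#'
#' Alternative to [parse_karyotype()] for callers holding abnormalities
#' as data rather than an ISCN string (e.g. from a JSON export). Each
#' abnormality row needs a `kind` (`translocation`, `inversion`,
#' `deletion`, `monosomy`, `trisomy`, `addition`, `marker`, `other`) and,
#' where applicable, `chrom1`/`chrom2` and `band1`/`band2`.
#'
#' @param modal_number Chromosome count in \[30, 100\] (or `NA`).
#' @param sex_chromosomes e.g. `"XX"`, `"XY"`.
#' @param abnormalities A data frame of abnormality rows (default none).
#' @return A `karyotype` object, as from [parse_karyotype()].
#' @examples
#' karyotype(45, "XX",
#'           tibble::tibble(kind = "monosomy", chrom1 = "7"))
#' @export
karyotype <- function(modal_number = 46, sex_chromosomes = "XX",
                      abnormalities = NULL) {
  if (!is.na(modal_number) && (modal_number < 30 || modal_number > 100)) {
    abort("modal_number must lie in [30, 100]")
  }
  template <- tibble(
    kind = character(), chrom1 = character(), chrom2 = character(),
    band1 = character(), band2 = character(), token = character()
  )
  abn <- if (is.null(abnormalities) || nrow(abnormalities) == 0) {
    template
  } else {
    abnormalities <- as_tibble(abnormalities)
    for (col in names(template)) {
      if (!col %in% names(abnormalities)) {
        abnormalities[[col]] <- NA_character_
      }
    }
    abnormalities <- abnormalities[, names(template)]
    abnormalities[] <- lapply(abnormalities, as.character)
    abnormalities
  }
  kinds <- c("translocation", "inversion", "deletion", "monosomy",
             "trisomy", "addition", "marker", "other")
  if (!all(abn$kind %in% kinds)) {
    abort(sprintf("unknown abnormality kind(s): %s",
                  paste(setdiff(abn$kind, kinds), collapse = ", ")))
  }
  one_chrom <- abn$kind %in% c("monosomy", "trisomy")
  if (any(one_chrom & is.na(abn$chrom1))) {
    abort("monosomy/trisomy rows need exactly one chromosome in chrom1")
  }
  if (any(abn$kind %in% c("translocation", "inversion") & is.na(abn$chrom1))) {
    abort("translocation/inversion rows need at least one chromosome")
  }
  structure(
    list(modal_number = as.integer(modal_number),
         sex_chromosomes = sex_chromosomes,
         abnormalities = abn, normal = nrow(abn) == 0, unknown = FALSE),
    class = "karyotype"
  )
}

#' Derive ELN-relevant lesion flags from a karyotype
#'
#' Scans the abnormality list for the recurrent lesions the ELN risk
#' tables refer to, and evaluates complex and monosomal karyotype status.
#' Conventions: a complex karyotype (CK) requires >= 3 abnormalities in
#' the absence of any ELN-defining translocation/inversion; in the 2022
#' edition only, a karyotype consisting exclusively of >= 3 trisomies
#' (hyperdiploid, no structural abnormality) is exempted from CK.
#' Monosomal = >= 2 autosomal monosomies, or one autosomal monosomy plus
#' >= 1 structural abnormality; sex-chromosome losses are ignored.
#' abn(17p) is matched by any deletion/addition/translocation carrying a
#' 17p band, plus monosomy 17.
#'
#' @param k A [parse_karyotype()] result (or a karyotype string).
#' @return A one-row tibble of boolean lesion flags plus the counts
#'   `n_abnormalities` and `n_autosomal_monosomies`. Both editions'
#'   complex flags (`complex_2017`, `complex_2022`) are reported;
#'   `complex_2022` implies `complex_2017`.
#' @examples
#' derive_findings(parse_karyotype("49,XX,+8,+13,+21"))
#' @export
derive_findings <- function(k) {
  if (is.character(k)) k <- parse_karyotype(k)
  stopifnot(inherits(k, "karyotype"))
  a <- k$abnormalities
  tr <- filter(a, .data$kind == "translocation")
  t_pair <- function(x, y) {
    any((tr$chrom1 == x & tr$chrom2 == y) | (tr$chrom1 == y & tr$chrom2 == x))
  }
  # band on a given chromosome of a translocation, matched by prefix
  t_band <- function(chrom, prefix, exclude_pair = NULL) {
    hit <- (tr$chrom1 == chrom & startsWith(coalesce_chr(tr$band1), prefix)) |
      (tr$chrom2 == chrom & startsWith(coalesce_chr(tr$band2), prefix))
    if (!is.null(exclude_pair)) {
      same <- (tr$chrom1 == exclude_pair[1] & tr$chrom2 == exclude_pair[2]) |
        (tr$chrom1 == exclude_pair[2] & tr$chrom2 == exclude_pair[1])
      hit <- hit & !same
    }
    any(hit)
  }
  inv_chrom <- function(x) any(a$kind == "inversion" & a$chrom1 == x)
  mono <- function(x) any(a$kind == "monosomy" & a$chrom1 == x)
  autosomes <- as.character(1:22)
  n_auto_mono <- sum(a$kind == "monosomy" & a$chrom1 %in% autosomes)
  structural_kinds <- c("translocation", "inversion", "deletion",
                        "addition", "marker", "other")
  n_structural <- sum(a$kind %in% structural_kinds)

  t_8_21 <- t_pair("8", "21")
  inv16_t16_16 <- inv_chrom("16") || t_pair("16", "16")
  t_9_11 <- t_pair("9", "11")
  t_v_11q23 <- t_band("11", "q23", exclude_pair = c("9", "11"))
  t_6_9 <- t_pair("6", "9")
  t_9_22 <- t_pair("9", "22")
  t_8_16 <- t_pair("8", "16")
  inv3_t3_3 <- inv_chrom("3") || t_pair("3", "3")
  t_3q26_v <- t_band("3", "q26", exclude_pair = c("3", "3"))
  del5q <- any(a$kind == "deletion" & a$chrom1 == "5" &
                 (is.na(a$band1) | startsWith(a$band1, "q")))
  del5_minus5 <- mono("5") || del5q
  minus7 <- mono("7")
  abn17p <- any(a$kind %in% c("deletion", "addition") & a$chrom1 == "17" &
                  startsWith(coalesce_chr(a$band1), "p")) ||
    t_band("17", "p")
  minus17_abn17p <- mono("17") || abn17p

  n_abn <- nrow(a)
  hyperdiploid_trisomies_only <- n_abn >= 3 && all(a$kind == "trisomy")
  defining <- t_8_21 || inv16_t16_16 || t_9_11 || t_v_11q23 || t_6_9 ||
    t_9_22 || t_8_16 || inv3_t3_3 || t_3q26_v
  complex_2017 <- !defining && n_abn >= 3
  complex_2022 <- complex_2017 && !hyperdiploid_trisomies_only
  monosomal <- n_auto_mono >= 2 || (n_auto_mono == 1 && n_structural >= 1)

  tibble(
    t_8_21 = t_8_21, inv16_t16_16 = inv16_t16_16, t_9_11 = t_9_11,
    t_v_11q23 = t_v_11q23, t_6_9 = t_6_9, t_9_22 = t_9_22,
    t_8_16 = t_8_16, inv3_t3_3 = inv3_t3_3, t_3q26_v = t_3q26_v,
    del5_minus5 = del5_minus5, minus7 = minus7,
    minus17_abn17p = minus17_abn17p,
    hyperdiploid_trisomies_only = hyperdiploid_trisomies_only,
    monosomal = monosomal, complex_2017 = complex_2017,
    complex_2022 = complex_2022,
    n_abnormalities = n_abn, n_autosomal_monosomies = n_auto_mono,
    karyotype_unknown = isTRUE(k$unknown)
  )
}

coalesce_chr <- function(x) {
  x <- as.character(x)
  x[is.na(x)] <- ""
  x
}
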
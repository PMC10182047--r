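#' Read a per-patient cohort table
#'
#' Reads a TSV/CSV with one row per patient and the columns
#' `patient_id`, `age_years`, `sex` (`male`/`female`), `intensive`,
#' `midostaurin`, `mutations`, `karyotype`, `os_months`, `death`.
#' The `mutations` field is a semicolon-separated list of
#' `GENE:vaf:pathogenic:hotspot[:key=value...]` tokens (`.` or empty for
#' none); recognized keys are `itd_ratio` (FLT3-ITD allelic ratio),
#' `biallelic` and `bzip` (CEBPA annotations). VAF is a fraction in
#' \[0, 1\]; a trailing `%` is accepted and converted on load.
#' `karyotype` is a restricted ISCN string (see [parse_karyotype()]) or
#' `unknown`.
#'
#' In strict mode any malformed row aborts with the row number and field;
#' otherwise malformed rows are dropped (unparseable karyotypes are kept
#' with karyotype set to unknown) and each reason is logged to stderr.
#'
#' @param path Path to a `.tsv`/`.csv` file.
#' @param strict Abort on malformed rows (default) or drop-and-log.
#' @return A cohort tibble: one row per patient with a `mutations`
#'   list-column of mutation-call tibbles and `karyotype` kept as the
#'   input string.
#' @seealso [write_cohort()], [fixture_cohort()], [simulate_cohort()]
#' @export
read_cohort <- function(path, strict = TRUE) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    patient_id = readr::col_character(),
    age_years = readr::col_integer(),
    sex = readr::col_character(),
    intensive = readr::col_logical(),
    midostaurin = readr::col_logical(),
    mutations = readr::col_character(),
    karyotype = readr::col_character(),
    os_months = readr::col_double(),
    death = readr::col_logical()
  ), progress = FALSE, show_col_types = FALSE)
  required <- c("patient_id", "age_years", "sex", "intensive", "midostaurin",
                "mutations", "karyotype", "os_months", "death")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    abort(sprintf("cohort file %s lacks column(s): %s", path,
                  paste(missing_cols, collapse = ", ")))
  }

  keep <- rep(TRUE, nrow(raw))
  mut_list <- vector("list", nrow(raw))
  kary <- raw$karyotype
  for (i in seq_len(nrow(raw))) {
    res <- tryCatch(
      validate_cohort_row(raw[i, ]),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      if (strict) {
        abort(sprintf("row %d (patient_id %s): %s", i,
                      raw$patient_id[i] %||% "?", conditionMessage(res)))
      }
      message(sprintf("dropping row %d (patient_id %s): %s", i,
                      raw$patient_id[i] %||% "?", conditionMessage(res)))
      keep[i] <- FALSE
      next
    }
    mut_list[[i]] <- res
    k_ok <- tryCatch({ parse_karyotype(raw$karyotype[i]); TRUE },
                     error = function(e) e)
    if (inherits(k_ok, "error")) {
      if (strict) {
        abort(sprintf("row %d (patient_id %s): karyotype: %s", i,
                      raw$patient_id[i], conditionMessage(k_ok)))
      }
      message(sprintf("row %d (patient_id %s): karyotype set to unknown: %s",
                      i, raw$patient_id[i], conditionMessage(k_ok)))
      kary[i] <- "unknown"
    }
  }
  out <- raw[keep, ]
  out$karyotype <- kary[keep]
  out$mutations <- mut_list[keep]
  if (anyDuplicated(out$patient_id)) {
    abort(sprintf("duplicate patient_id: %s",
                  paste(unique(out$patient_id[duplicated(out$patient_id)]),
                        collapse = ", ")))
  }
  as_tibble(out)
}

validate_cohort_row <- function(r) {
  if (is.na(r$patient_id) || r$patient_id == "") abort("patient_id: missing")
  if (is.na(r$age_years) || r$age_years < 18) {
    abort("age_years: must be an integer >= 18 (pediatric patients excluded)")
  }
  if (!r$sex %in% c("male", "female")) abort("sex: must be male or female")
  if (is.na(r$os_months) || r$os_months < 0) abort("os_months: must be >= 0")
  if (is.na(r$death)) abort("death: missing")
  m <- parse_mutation_field(r$mutations)
  validate_mutations(m, context = "mutations")
  if (sum(m$gene == "FLT3" & !is.na(m$itd_allelic_ratio)) > 1) {
    abort("mutations: at most one FLT3-ITD record per patient")
  }
  if (sum(m$gene == "CEBPA") > 1) {
    abort("mutations: at most one CEBPA record per patient")
  }
  m
}

parse_mutation_field <- function(x) {
  if (is.na(x) || x == "" || x == ".") return(mutation_calls())
  tokens <- strsplit(x, ";", fixed = TRUE)[[1]]
  bind_rows(purrr::map(tokens, parse_mutation_token))
}

parse_mutation_token <- function(token) {
  parts <- strsplit(trimws(token), ":", fixed = TRUE)[[1]]
  if (length(parts) < 4) {
    abort(sprintf("mutation token %s: expected GENE:vaf:pathogenic:hotspot",
                  sQuote(token)))
  }
  vaf_str <- parts[[2]]
  vaf <- if (grepl("%$", vaf_str)) {
    suppressWarnings(as.numeric(sub("%$", "", vaf_str))) / 100
  } else {
    suppressWarnings(as.numeric(vaf_str))
  }
  if (is.na(vaf)) abort(sprintf("mutation token %s: unparseable vaf", sQuote(token)))
  if (vaf < 0 || vaf > 1) {
    abort(sprintf("mutation token %s: vaf out of range [0, 1]", sQuote(token)))
  }
  itd <- NA_real_; biallelic <- NA; bzip <- NA
  for (extra in parts[-(1:4)]) {
    kv <- strsplit(extra, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) {
      abort(sprintf("mutation token %s: malformed key=value %s",
                    sQuote(token), sQuote(extra)))
    }
    switch(kv[[1]],
      itd_ratio = { itd <- as.numeric(kv[[2]]) },
      biallelic = { biallelic <- parse_flag(kv[[2]]) },
      bzip = { bzip <- parse_flag(kv[[2]]) },
      abort(sprintf("mutation token %s: unknown key %s", sQuote(token),
                    sQuote(kv[[1]])))
    )
  }
  mutation_calls(
    gene = parts[[1]], vaf = vaf,
    pathogenic = parse_flag(parts[[3]]), hotspot = parse_flag(parts[[4]]),
    itd_allelic_ratio = itd, cebpa_biallelic = biallelic,
    cebpa_bzip_inframe = bzip
  )
}

parse_flag <- function(x) {
  if (x %in% c("1", "TRUE", "true")) return(TRUE)
  if (x %in% c("0", "FALSE", "false")) return(FALSE)
  abort(sprintf("unparseable boolean flag %s", sQuote(x)))
}

#' Write a cohort table
#'
#' Inverse of [read_cohort()]; valid rows round-trip bit-exactly.
#'
#' @param cohort A cohort tibble.
#' @param path Output `.tsv`/`.csv` path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  flat <- mutate(cohort,
                 mutations = purrr::map_chr(.data$mutations, format_mutation_field))
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  readr::write_delim(flat, path, delim = delim)
  invisible(path)
}

format_mutation_field <- function(m) {
  if (is.null(m) || nrow(m) == 0) return(".")
  fmt <- function(x) format(x, digits = 15, scientific = FALSE, trim = TRUE)
  tokens <- purrr::pmap_chr(m, function(gene, vaf, pathogenic, hotspot,
                                        itd_allelic_ratio, cebpa_biallelic,
                                        cebpa_bzip_inframe) {
    tok <- paste(gene, fmt(vaf), as.integer(pathogenic),
                 as.integer(hotspot), sep = ":")
    if (!is.na(itd_allelic_ratio)) {
      tok <- paste0(tok, ":itd_ratio=", fmt(itd_allelic_ratio))
    }
    if (!is.na(cebpa_biallelic)) {
      tok <- paste0(tok, ":biallelic=", as.integer(cebpa_biallelic))
    }
    if (!is.na(cebpa_bzip_inframe)) {
      tok <- paste0(tok, ":bzip=", as.integer(cebpa_bzip_inframe))
    }
    tok
  })
  paste(tokens, collapse = ";")
}

# assemble a cohort tibble from in-memory pieces (used by generators)
new_cohort <- function(patient_id, age_years, sex, intensive, midostaurin,
                       mutations, karyotype, os_months, death) {
  tibble(
    patient_id = patient_id,
    age_years = as.integer(age_years),
    sex = sex,
    intensive = intensive,
    midostaurin = midostaurin,
    mutations = mutations,
    karyotype = karyotype,
    os_months = os_months,
    death = death
  )
}
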
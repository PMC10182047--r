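#' Kaplan-Meier fit for one stratum
#'
#' Product-limit estimator with Greenwood variance and log-log 95%
#' confidence bands. The median is the first time the survival curve
#' drops to 0.5 or below; its confidence limits are the band crossings.
#' A median (or limit) is `NA` when the corresponding curve never
#' reaches 0.5 ("not reached").
#'
#' @param times Follow-up in months (nonnegative).
#' @param events Logical death indicator (FALSE = censored).
#' @return Object of class `km_fit`: list with `fit` (the underlying
#'   [survival::survfit()] object), `curve` (tibble: `time`, `n_risk`,
#'   `n_event`, `n_censor`, `estimate`, `conf.low`, `conf.high`), `n`,
#'   `events`, `median`, `median_lcl`, `median_ucl`.
#' @examples
#' km_fit(c(1, 2, 3, 4), c(TRUE, TRUE, TRUE, TRUE))$median
#' @export
km_fit <- function(times, events) {
  stopifnot(length(times) == length(events), all(times >= 0))
  fit <- survival::survfit(survival::Surv(times, events) ~ 1,
                           conf.type = "log-log")
  s <- summary(fit, censored = TRUE)
  curve <- tibble(
    time = s$time, n_risk = s$n.risk, n_event = s$n.event,
    n_censor = s$n.censor, estimate = s$surv,
    conf.low = s$lower, conf.high = s$upper
  )
  # first threshold crossing of the estimate / each band; NA = not reached
  crossing <- function(y) {
    hit <- which(!is.na(y) & y <= 0.5)
    if (length(hit) == 0) NA_real_ else curve$time[hit[1]]
  }
  structure(list(
    fit = fit, curve = curve,
    n = length(times), events = sum(events),
    median = crossing(curve$estimate),
    median_lcl = crossing(curve$conf.low),
    median_ucl = crossing(curve$conf.high)
  ), class = "km_fit")
}

#' @export
print.km_fit <- function(x, ...) {
  med <- if (is.na(x$median)) "not reached" else sprintf("%.1f months", x$median)
  cat(sprintf("Kaplan-Meier fit: n = %d, events = %d, median OS %s\n",
              x$n, x$events, med))
  invisible(x)
}

#' @rdname km_fit
#' @param x A `km_fit` object.
#' @param ... Unused.
#' @method tidy km_fit
#' @export
tidy.km_fit <- function(x, ...) x$curve

#' @rdname km_fit
#' @method glance km_fit
#' @export
glance.km_fit <- function(x, ...) {
  tibble(n = x$n, events = x$events, median = x$median,
         median_lcl = x$median_lcl, median_ucl = x$median_ucl)
}

#' Survival probability at fixed timepoints
#'
#' @param x A [km_fit()] object.
#' @param timepoints Months at which to evaluate the curve.
#' @return Percent surviving at each timepoint (named numeric).
#' @export
os_at <- function(x, timepoints = c(12, 24, 36)) {
  s <- summary(x$fit, times = timepoints, extend = TRUE)
  setNames(100 * s$surv, paste0("os_", timepoints))
}

#' K-group log-rank test
#'
#' @param times,events Follow-up and death indicator, as in [km_fit()].
#' @param group Stratum labels (>= 2 distinct values; >= 1 event overall).
#' @return A one-row tibble: `statistic` (chi-square), `df` (k - 1) and
#'   two-sided `p`.
#' @examples
#' logrank_test(c(1, 2, 3, 4), rep(TRUE, 4), c("a", "a", "b", "b"))
#' @export
logrank_test <- function(times, events, group) {
  group <- factor(group)
  if (nlevels(droplevels(group)) < 2) {
    abort("log-rank test needs at least two groups")
  }
  if (sum(events) == 0) abort("log-rank test needs at least one event")
  sd <- survival::survdiff(survival::Surv(times, events) ~ group)
  df <- length(sd$n) - 1
  tibble(statistic = sd$chisq, df = df,
         p = pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Cox proportional-hazards fit across strata
#'
#' Partial-likelihood fit of a single categorical covariate with Efron
#' tie handling and Wald 95% confidence intervals, each stratum versus a
#' reference. A stratum with no events makes its hazard ratio
#' unidentifiable; it is reported with `NA` estimates and a note.
#'
#' @param times,events Follow-up and death indicator.
#' @param group Stratum labels.
#' @param reference Reference stratum (default: first factor level).
#' @return A tibble, one row per non-reference stratum: `term`, `n`,
#'   `events`, `hr`, `conf.low`, `conf.high`, `p`, `note`.
#' @export
cox_hr <- function(times, events, group, reference = NULL) {
  group <- factor(group)
  if (!is.null(reference)) {
    if (!reference %in% levels(group)) {
      abort(sprintf("reference stratum %s not present", sQuote(reference)))
    }
    group <- stats::relevel(group, ref = reference)
  }
  counts <- tibble(term = as.character(group), event = events) %>%
    group_by(.data$term) %>%
    summarise(n = n(), events = sum(.data$event))
  fit <- survival::coxph(survival::Surv(times, events) ~ group,
                         ties = "efron")
  sm <- summary(fit)
  terms <- sub("^group", "", rownames(sm$coefficients))
  out <- tibble(
    term = terms,
    hr = unname(sm$coefficients[, "exp(coef)"]),
    conf.low = unname(sm$conf.int[, "lower .95"]),
    conf.high = unname(sm$conf.int[, "upper .95"]),
    p = unname(sm$coefficients[, "Pr(>|z|)"])
  ) %>%
    left_join(counts, by = "term") %>%
    mutate(note = NA_character_) %>%
    select("term", "n", "events", "hr", "conf.low", "conf.high", "p", "note")
  ref_events <- counts$events[counts$term == levels(group)[1]]
  bad <- out$events == 0 | ref_events == 0
  if (any(bad)) {
    out$hr[bad] <- NA_real_
    out$conf.low[bad] <- NA_real_
    out$conf.high[bad] <- NA_real_
    out$p[bad] <- NA_real_
    out$note[bad] <- "no events in stratum; hazard ratio unidentifiable"
  }
  out
}

#' Stratified overall-survival report
#'
#' Applies [km_fit()] per stratum, a global log-rank test, and a Cox fit
#' versus the reference stratum, mirroring the layout of published
#' per-subset outcome tables (n, median OS with 95% CI, OS rates at
#' fixed timepoints, p value). Strata smaller than `min_n` are dropped
#' with a warning before testing.
#'
#' @param data A tibble with columns `os_months` and `death`.
#' @param strata Column (bare name or string) holding the stratum label.
#' @param timepoints Months at which OS rates are reported.
#' @param reference Reference stratum for the Cox model (default: first
#'   level).
#' @param min_n Minimum stratum size retained (default 1).
#' @return Object of class `os_report`: list with `strata` (per-stratum
#'   tibble), `logrank` (one-row tibble or `NULL` with < 2 strata),
#'   `cox` (tibble or `NULL`), `curves` (named list of `km_fit`).
#' @examples
#' cohort <- fixture_cohort()
#' a22 <- eln_classify(cohort, "2022")
#' rep22 <- os_report(dplyr::mutate(cohort, risk = a22$resolved), risk)
#' tidy(rep22)
#' @export
os_report <- function(data, strata, timepoints = c(12, 24, 36),
                      reference = NULL, min_n = 1) {
  labels <- factor(pull(data, {{ strata }}))
  keep_levels <- names(which(table(labels) >= max(1, min_n)))
  dropped <- setdiff(levels(droplevels(labels)), keep_levels)
  if (length(dropped) > 0) {
    warn(sprintf("dropping strata with fewer than %d patients: %s", min_n,
                 paste(dropped, collapse = ", ")))
  }
  keep <- labels %in% keep_levels
  data <- data[keep, ]
  labels <- droplevels(labels[keep])
  if (nlevels(labels) == 0) abort("no stratum left to report")

  curves <- purrr::map(setNames(levels(labels), levels(labels)), function(l) {
    km_fit(data$os_months[labels == l], data$death[labels == l])
  })
  strata_tbl <- purrr::imap(curves, function(km, label) {
    tibble(label = label, !!!glance(km), !!!as.list(os_at(km, timepoints)))
  }) %>% bind_rows()

  lr <- NULL
  cox <- NULL
  if (nlevels(labels) >= 2 && sum(data$death) > 0) {
    lr <- logrank_test(data$os_months, data$death, labels)
    cox <- cox_hr(data$os_months, data$death, labels, reference = reference)
  }
  structure(list(strata = strata_tbl, logrank = lr, cox = cox,
                 curves = curves, timepoints = timepoints),
            class = "os_report")
}

#' @export
print.os_report <- function(x, ...) {
  cat("Overall survival by stratum\n")
  print(as.data.frame(x$strata), digits = 3)
  if (!is.null(x$logrank)) {
    cat(sprintf("log-rank chi-square %.2f on %d df, p = %.4g\n",
                x$logrank$statistic, x$logrank$df, x$logrank$p))
  }
  invisible(x)
}

#' @rdname os_report
#' @param x An `os_report` object.
#' @param ... Unused.
#' @method tidy os_report
#' @export
tidy.os_report <- function(x, ...) x$strata

#' @rdname os_report
#' @method glance os_report
#' @export
glance.os_report <- function(x, ...) {
  tibble(
    n = sum(x$strata$n), events = sum(x$strata$events),
    n_strata = nrow(x$strata),
    logrank_statistic = if (is.null(x$logrank)) NA_real_ else x$logrank$statistic,
    logrank_p = if (is.null(x$logrank)) NA_real_ else x$logrank$p
  )
}
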
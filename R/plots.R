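#' Plot methods
#'
#' `autoplot()` methods give quick ggplot2 views of the result objects:
#' Kaplan-Meier step curves (single fit or per-stratum report) and a
#' transition-matrix tile plot. `plot_risk_distribution()` shows the
#' favorable/intermediate/adverse split of one or more classified
#' cohorts as stacked bars.
#'
#' @param object A `km_fit`, `os_report` or `eln_transition` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @name elnaml-plots
NULL

km_step_data <- function(curve) {
  bind_rows(
    tibble(time = 0, estimate = 1, conf.low = 1, conf.high = 1),
    curve[, c("time", "estimate", "conf.low", "conf.high")]
  )
}

#' @rdname elnaml-plots
#' @method autoplot km_fit
#' @export
autoplot.km_fit <- function(object, ...) {
  d <- km_step_data(object$curve)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = .data$estimate)) +
    ggplot2::geom_step() +
    ggplot2::geom_step(ggplot2::aes(y = .data$conf.low), linetype = "dashed",
                       na.rm = TRUE) +
    ggplot2::geom_step(ggplot2::aes(y = .data$conf.high), linetype = "dashed",
                       na.rm = TRUE) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Months", y = "Overall survival")
}

#' @rdname elnaml-plots
#' @method autoplot os_report
#' @export
autoplot.os_report <- function(object, ...) {
  d <- purrr::imap(object$curves,
                   ~ mutate(km_step_data(.x$curve), stratum = .y)) %>%
    bind_rows()
  p_lab <- if (!is.null(object$logrank)) {
    sprintf("log-rank p = %.3g", object$logrank$p)
  } else {
    NULL
  }
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = .data$estimate,
                                  colour = .data$stratum)) +
    ggplot2::geom_step() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Months", y = "Overall survival", colour = NULL,
                  subtitle = p_lab)
}

#' @rdname elnaml-plots
#' @method autoplot eln_transition
#' @export
autoplot.eln_transition <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$to, y = .data$from,
                                  fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%d\n(%.1f%%)", .data$count, .data$percent))) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = "2022 ELN", y = "2017 ELN", fill = "n")
}

#' @rdname elnaml-plots
#' @param ... Named [eln_classify()] outputs, e.g.
#'   `plot_risk_distribution("2017" = a17, "2022" = a22)`.
#' @export
plot_risk_distribution <- function(...) {
  sets <- list(...)
  if (is.null(names(sets)) || any(names(sets) == "")) {
    names(sets) <- purrr::map_chr(sets, ~ as.character(.x$edition[[1]]))
  }
  d <- purrr::imap(sets, ~ count(.x, .data$resolved) %>%
                     mutate(set = .y)) %>%
    bind_rows() %>%
    group_by(.data$set) %>%
    mutate(pct = 100 * .data$n / sum(.data$n)) %>%
    ungroup()
  ggplot2::ggplot(d, ggplot2::aes(x = .data$set, y = .data$pct,
                                  fill = .data$resolved)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(favorable = "#4daf4a",
                                          intermediate = "#ffcc33",
                                          adverse = "#e41a1c")) +
    ggplot2::labs(x = NULL, y = "% of patients", fill = NULL)
}
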
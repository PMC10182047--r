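test_that("KM estimator reproduces hand product-limit computations", {
  # four deaths at 1,2,3,4: S = 0.75, 0.50, 0.25, 0
  km <- km_fit(c(1, 2, 3, 4), rep(TRUE, 4))
  expect_equal(km$curve$estimate, c(0.75, 0.5, 0.25, 0))
  expect_equal(km$median, 2)
  # no events: flat curve, median not reached
  km0 <- km_fit(c(5, 8, 12), rep(FALSE, 3))
  expect_true(all(km0$curve$estimate == 1))
  expect_true(is.na(km0$median))
  # single patient dying at 5: one step from 1 to 0
  km1 <- km_fit(5, TRUE)
  expect_equal(km1$curve$estimate, 0)
  expect_equal(km1$median, 5)
  # censoring: death at 2 among {2, 3+}: S(2) = 0.5 and stays
  kmc <- km_fit(c(2, 3), c(TRUE, FALSE))
  expect_equal(kmc$curve$estimate, c(0.5, 0.5))
})

test_that("KM on uncensored data equals the empirical survival function", {
  withr::local_seed(41)
  for (i in 1:10) {
    times <- round(rexp(40, 0.1), 1)
    km <- km_fit(times, rep(TRUE, 40))
    emp <- vapply(km$curve$time, function(t) mean(times > t), numeric(1))
    expect_equal(km$curve$estimate, emp)
  }
})

test_that("log-rank matches a brute-force risk-set tabulation on toy data", {
  times <- c(1, 3, 5, 2, 4, 6)
  events <- c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE)
  group <- c("a", "a", "a", "b", "b", "b")
  # brute force: observed minus expected for group a over event times
  o_minus_e <- 0; v <- 0
  for (t in sort(unique(times[events]))) {
    at_risk <- times >= t
    d <- sum(events & times == t)
    n <- sum(at_risk)
    n_a <- sum(at_risk & group == "a")
    d_a <- sum(events & times == t & group == "a")
    o_minus_e <- o_minus_e + d_a - d * n_a / n
    if (n > 1) v <- v + d * (n_a / n) * (1 - n_a / n) * (n - d) / (n - 1)
  }
  want <- o_minus_e^2 / v
  got <- logrank_test(times, events, group)
  expect_equal(got$statistic, want)
  expect_equal(got$df, 1)
  expect_equal(got$p, pchisq(want, 1, lower.tail = FALSE))
})

test_that("log-rank is symmetric, scale-invariant and null for identical groups", {
  times <- c(1, 2, 3, 4, 1, 2, 3, 4)
  events <- rep(TRUE, 8)
  group <- rep(c("a", "b"), each = 4)
  same <- logrank_test(times, events, group)
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)

  withr::local_seed(42)
  t2 <- c(rexp(30, 0.2), rexp(30, 0.6))
  e2 <- runif(60) < 0.8
  g2 <- rep(c("x", "y"), each = 30)
  a <- logrank_test(t2, e2, g2)
  # relabelling groups and rescaling time leave the statistic unchanged
  expect_equal(logrank_test(t2, e2, ifelse(g2 == "x", "y", "x"))$statistic,
               a$statistic)
  expect_equal(logrank_test(t2 * 12, e2, g2)$statistic, a$statistic)

  expect_error(logrank_test(t2, e2, rep("x", 60)), "two groups")
  expect_error(logrank_test(c(1, 2), c(FALSE, FALSE), c("a", "b")), "event")
})

test_that("three distinct exponential hazards are detected at n = 500/group", {
  withr::local_seed(43)
  times <- c(rexp(500, log(2) / 40), rexp(500, log(2) / 24),
             rexp(500, log(2) / 15))
  censor <- 36
  events <- times <= censor
  obs <- pmin(times, censor)
  group <- rep(c("f", "i", "a"), each = 500)
  lr <- logrank_test(obs, events, group)
  expect_equal(lr$df, 2)
  expect_lt(lr$p, 0.001)
})

test_that("Cox fit reproduces the closed-form toy partial likelihood", {
  # alternating events at 1..4: maximizing the partial likelihood
  # x/((2+2x)(1+2x)(1+x)) in x = exp(beta) gives 4x^2 + x - 1 = 0,
  # so the MLE hazard ratio is (sqrt(17) - 1) / 8
  fit <- cox_hr(times = c(1, 2, 3, 4), events = rep(TRUE, 4),
                group = c("ref", "alt", "ref", "alt"), reference = "ref")
  expect_equal(fit$hr, (sqrt(17) - 1) / 8, tolerance = 1e-6)
  # a duplicated-label null covariate gives HR = 1 exactly
  fit0 <- cox_hr(times = rep(c(1, 2, 3, 4), 2), events = rep(TRUE, 8),
                 group = rep(c("g1", "g2"), each = 4))
  expect_equal(fit0$hr, 1, tolerance = 1e-8)
})

test_that("Cox recovers a true hazard ratio of 2 and flags event-free strata", {
  withr::local_seed(44)
  times <- c(rexp(2000, 0.05), rexp(2000, 0.10))
  group <- rep(c("ref", "double"), each = 2000)
  fit <- cox_hr(times, rep(TRUE, 4000), group, reference = "ref")
  expect_gt(fit$hr, 1.8)
  expect_lt(fit$hr, 2.2)

  # coxph itself warns that the coefficient diverges; the wrapper reports NA
  nofit <- suppressWarnings(
    cox_hr(times = c(1, 2, 3, 4), events = c(TRUE, TRUE, FALSE, FALSE),
           group = c("ref", "ref", "dead-free", "dead-free"),
           reference = "ref"))
  expect_true(is.na(nofit$hr))
  expect_match(nofit$note, "unidentifiable")
})

test_that("stratified OS report mirrors the per-subset outcome table layout", {
  withr::local_seed(45)
  d <- tibble::tibble(
    os_months = c(rexp(150, log(2) / 40), rexp(150, log(2) / 15)),
    death = TRUE,
    risk = rep(c("favorable", "adverse"), each = 150)
  ) %>%
    dplyr::mutate(death = os_months <= 36,
                  os_months = pmin(os_months, 36))
  rep1 <- os_report(d, risk, reference = "favorable")
  expect_setequal(rep1$strata$label, c("favorable", "adverse"))
  expect_true(all(c("os_12", "os_24", "os_36") %in% names(rep1$strata)))
  expect_lt(rep1$logrank$p, 0.01)
  expect_gt(rep1$cox$hr[rep1$cox$term == "adverse"], 1)
  # OS rates are percents on a nonincreasing curve
  expect_true(all(rep1$strata$os_12 >= rep1$strata$os_24))
  # single stratum: curve only, no test
  rep2 <- os_report(d[d$risk == "adverse", ], risk)
  expect_null(rep2$logrank)
  expect_null(rep2$cox)
  # small strata are dropped with a warning
  d2 <- dplyr::bind_rows(d, tibble::tibble(os_months = 1, death = TRUE,
                                           risk = "tiny"))
  expect_warning(rep3 <- os_report(d2, risk, min_n = 5), "tiny")
  expect_false("tiny" %in% rep3$strata$label)
})
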
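test_that("vital status at a horizon follows the inclusive-death definition", {
  # death on the horizon day counts as died ("within 30 days")
  expect_equal(as.character(outcome_at_horizon(make_followup(death_day = 30), 30)),
               "died")
  expect_equal(as.character(outcome_at_horizon(make_followup(death_day = 31), 30)),
               "survived")  # death after the horizon proves survival to it
  expect_equal(as.character(outcome_at_horizon(make_followup(alive_day = 400), 365)),
               "survived")
  expect_equal(as.character(outcome_at_horizon(make_followup(alive_day = 200), 365)),
               "unknown")
  expect_equal(as.character(outcome_at_horizon(make_followup(alive_day = 365), 365)),
               "survived")
  # full definition table over every ordering of the three dates
  cases <- list(list(d = 10, a = NA, h = 30, want = "died"),
                list(d = 10, a = 5, h = 30, want = "died"),
                list(d = 40, a = NA, h = 30, want = "survived"),
                list(d = NA, a = 30, h = 30, want = "survived"),
                list(d = NA, a = 29, h = 30, want = "unknown"),
                list(d = NA, a = 0, h = 30, want = "unknown"))
  for (cs in cases)
    expect_equal(as.character(outcome_at_horizon(
      make_followup(death_day = cs$d, alive_day = cs$a), cs$h)), cs$want)
  expect_error(outcome_at_horizon(make_followup(death_day = -5), 30),
               "death before surgery")
  expect_error(outcome_at_horizon(make_followup(), 30), "death date")
})

test_that("observed mortality rates reproduce the published counts and denominators", {
  fu <- published_mortality_followup()
  r30 <- observed_mortality_rate(fu, 30)
  expect_equal(r30$deaths, 21)
  expect_equal(r30$denominator, 344)
  expect_equal(round(100 * r30$rate, 1), 6.1)
  r1y <- observed_mortality_rate(fu, 365)
  expect_equal(r1y$deaths, 65)
  expect_equal(r1y$denominator, 341)  # 3 lost before 1 year are excluded
  expect_equal(round(100 * r1y$rate, 1), 19.1)
  r8y <- observed_mortality_rate(fu, 2922)
  expect_equal(r8y$deaths, 218)
  expect_equal(r8y$denominator, 318)  # 26 lost before 8 years
  expect_equal(round(100 * r8y$rate, 1), 68.6)
  # zero deaths give rate zero; no known status at horizon is an error
  expect_equal(observed_mortality_rate(make_followup(alive_day = 40), 30)$rate, 0)
  expect_error(observed_mortality_rate(make_followup(alive_day = 10), 30),
               "undefined rate")
})

test_that("product-limit estimate matches hand computation", {
  # times {5+, 10, 15+, 20}: S(10) = 2/3, S(20) = 0
  km <- km_fit(c(5, 10, 15, 20), c(0, 1, 0, 1))
  expect_equal(km$survival[km$time == 0], 1)
  expect_equal(km$survival[km$time == 10], 2 / 3)
  expect_equal(km$survival[km$time == 20], 0)
  # no deaths: survival identically one
  expect_true(all(km_fit(rep(100, 3), rep(0, 3))$survival == 1))
  # everyone dies: survival hits zero
  expect_equal(min(km_fit(c(1, 2), c(1, 1))$survival), 0)
  expect_error(km_fit(numeric(0), numeric(0)), "empty")
})

test_that("product-limit estimate equals the empirical survival function without censoring", {
  set.seed(71)
  for (rep in 1:20) {
    n <- sample(3:40, 1)
    time <- sample(1:25, n, replace = TRUE)
    km <- km_fit(time, rep(1, n))
    emp <- vapply(km$time, function(t) mean(time > t), 0)
    expect_equal(km$survival, emp)
  }
})

test_that("product-limit estimate matches the brute-force oracle under censoring", {
  set.seed(72)
  for (rep in 1:20) {
    n <- sample(5:50, 1)
    time <- sample(1:30, n, replace = TRUE)
    event <- rbinom(n, 1, 0.7)
    if (sum(event) == 0) event[1] <- 1
    km <- km_fit(time, event)
    oracle <- km_brute(time, event)
    got <- km$survival[match(oracle$time, km$time)]
    expect_equal(got, oracle$survival)
  }
})

test_that("survival curves are valid step functions (non-increasing, shrinking risk set)", {
  cohort <- generate_cohort(cohort_config(n = 400, seed = 9))
  ft <- followup_time(cohort)
  km <- km_fit(ft$time, ft$event)
  expect_true(all(diff(km$survival) <= 0))
  expect_true(all(diff(km$n_risk) <= 0))
  expect_equal(km$survival[1], 1)
})

test_that("risk-group curves partition the cohort and degenerate correctly", {
  cfg <- cohort_config(n = 500, seed = 13,
                       outcome_mechanism = mechanism_logistic("NHFS"))
  cohort <- generate_cohort(cfg)
  km <- km_by_risk_group(cohort, "NHFS")
  expect_equal(sum(attr(km, "group_n")), nrow(cohort))
  # single-group cohort: by-group estimate equals the pooled estimate
  low_only <- cohort[score_patients(cohort, quiet = TRUE)$nhfs_group == "low", ]
  ft <- followup_time(low_only)
  w <- capture_warnings(km1 <- km_by_risk_group(low_only, "NHFS"))
  expect_true(any(grepl("empty", w)))
  expect_equal(as.data.frame(km1$low), as.data.frame(km_fit(ft$time, ft$event)))
})

test_that("a score-dependent hazard yields ordered risk-group survival curves", {
  cfg <- cohort_config(n = 4000, seed = 17,
                       outcome_mechanism = mechanism_logistic("NHFS"))
  cohort <- generate_cohort(cfg)
  km <- km_by_risk_group(cohort, "NHFS")
  # compare group survival at common time points
  probe <- c(365, 1500, 2922)
  surv_at <- function(k, t) min(k$survival[k$time <= t])
  for (t in probe) {
    expect_gt(surv_at(km$low, t), surv_at(km$intermediate, t))
    expect_gt(surv_at(km$intermediate, t), surv_at(km$high, t))
  }
})

test_that("km_table flattens curves for export", {
  cohort <- generate_cohort(cohort_config(n = 300, seed = 21))
  km <- km_by_risk_group(cohort, "HEMA")
  tab <- km_table(km)
  expect_setequal(unique(tab$group), names(km))
  expect_true(all(c("time", "survival", "n_risk", "n_event") %in% names(tab)))
})
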
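test_that("km_estimate: closed forms and basic invariants", {
  # all censored: S stays 1 (no steps)
  c0 <- km_estimate(c(3, 5, 8), c(FALSE, FALSE, FALSE))
  expect_equal(nrow(c0), 0)
  # three events, no censoring: S = 2/3, 1/3, 0
  c1 <- km_estimate(1:3, rep(TRUE, 3))
  expect_equal(c1$surv, c(2 / 3, 1 / 3, 0))
  expect_equal(c1$n_risk, 3:1)
  # record order invariance; a censored tail adds no step (but does
  # enlarge every earlier risk set: S = 3/4, 2/4, 1/4)
  c2 <- km_estimate(c(3, 1, 2), rep(TRUE, 3))
  expect_equal(c2$surv, c1$surv)
  c3 <- km_estimate(c(1, 2, 3, 99), c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(c3$time, 1:3)
  expect_equal(c3$surv, c(3 / 4, 2 / 4, 1 / 4))
  expect_error(km_estimate(c(1, -2), c(TRUE, TRUE)), "positive")
})

test_that("km_estimate matches survival::survfit (S, SE, median)", {
  skip_if_not_installed("survival")
  withr::with_seed(201, {
    for (i in 1:5) {
      t <- round(rexp(60, 0.04), 2) + 0.01
      e <- runif(60) < 0.7
      mine <- km_estimate(t, e)
      ref <- summary(survival::survfit(survival::Surv(t, e) ~ 1))
      expect_equal(mine$time, ref$time)
      expect_equal(mine$surv, ref$surv, tolerance = 1e-12)
      ok <- ref$surv > 0   # survfit reports NaN SE at S = 0; Greenwood gives 0
      expect_equal(mine$se[ok], ref$std.err[ok], tolerance = 1e-8)
      med <- unname(summary(survival::survfit(survival::Surv(t, e) ~ 1))$table["median"])
      expect_equal(median_survival(mine), med)
    }
  })
})

test_that("median_survival: exact crossing and undefined curves", {
  cv <- km_estimate(c(5, 10, 20, 30), c(TRUE, TRUE, TRUE, FALSE))
  # S = .75, .5, .25 -> first time S <= .5 is 10
  expect_equal(median_survival(cv), 10)
  high <- km_estimate(c(5, 10, 20), c(TRUE, FALSE, FALSE))  # S min = 2/3
  expect_true(is.na(median_survival(high)))
})

test_that("KM recovers exponential survival within Greenwood bands", {
  lambda <- 0.05
  cover <- with_seed(203, {
    vapply(1:20, function(i) {
      t <- rexp(200, lambda)
      cens <- rexp(200, 0.02)
      obs <- pmin(t, cens); ev <- t <= cens
      cv <- km_estimate(obs, ev)
      ok <- !is.na(cv$lower)
      mean((exp(-lambda * cv$time) >= cv$lower & exp(-lambda * cv$time) <= cv$upper)[ok])
    }, numeric(1))
  })
  # >= 90% of time points inside the 95% band, in at least 18/20 seeds
  expect_gte(mean(cover >= 0.90), 0.9)
  # median ~ ln 2 / lambda
  med <- with_seed(205, median_survival(km_estimate(rexp(2000, lambda), rep(TRUE, 2000))))
  expect_lt(abs(med - log(2) / lambda), 2)
})

test_that("logrank_test: identical groups, relabeling symmetry, group checks", {
  t <- c(2, 4, 6, 8, 10); e <- c(TRUE, TRUE, FALSE, TRUE, TRUE)
  same <- logrank_test(c(t, t), c(e, e), rep(c("a", "b"), each = 5))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  withr::with_seed(207, {
    t2 <- rexp(40, 0.1); e2 <- runif(40) < 0.8
    g <- rep(c("a", "b"), 20)
    p1 <- logrank_test(t2, e2, g)$p_value
    p2 <- logrank_test(t2, e2, ifelse(g == "a", "z", "y"))$p_value
    expect_equal(p1, p2, tolerance = 1e-12)
  })
  expect_error(logrank_test(t, e, rep("a", 5)), "2 nonempty")
})

test_that("logrank_test matches survival::survdiff and a permutation oracle", {
  skip_if_not_installed("survival")
  withr::with_seed(209, {
    for (i in 1:5) {
      t <- round(rexp(50, 0.05), 2) + 0.01
      e <- runif(50) < 0.75
      g <- sample(c("a", "b"), 50, TRUE)
      mine <- logrank_test(t, e, g)
      ref <- survival::survdiff(survival::Surv(t, e) ~ g)
      expect_equal(mine$statistic, ref$chisq, tolerance = 1e-8)
    }
    # permutation oracle on a small dataset
    t <- round(rexp(24, 0.08), 2) + 0.01
    e <- runif(24) < 0.8
    g <- rep(c("a", "b"), 12)
    obs <- logrank_test(t, e, g)
    perm <- vapply(1:2000, function(i)
      logrank_test(t, e, sample(g))$statistic, numeric(1))
    p_mc <- (sum(perm >= obs$statistic - 1e-12) + 1) / 2001
    expect_lt(abs(obs$p_value - p_mc), 4 * sqrt(p_mc * (1 - p_mc) / 2000) + 0.03)
  })
})

test_that("logrank type-I error is within [0.03, 0.07] under the null", {
  rej <- with_seed(211, {
    mean(vapply(1:3000, function(i) {
      t <- rexp(60, 0.05); e <- runif(60) < 0.8
      logrank_test(t, e, rep(c("a", "b"), 30))$p_value <= 0.05
    }, logical(1)))
  })
  expect_gte(rej, 0.03)
  expect_lte(rej, 0.07)
})

test_that("cutoff_scan: structure, quartile df, empty-group flag, degradation", {
  withr::with_seed(213, {
    n <- 80
    cases <- data.frame(
      case_id = sprintf("c%02d", 1:n),
      mtbr = runif(n, 0, 60),
      os_months = rexp(n, 0.03) + 0.1, os_event = runif(n) < 0.6,
      tss_months = rexp(n, 0.03) + 0.1, tss_event = runif(n) < 0.4)
    sc <- cutoff_scan(cases)
    expect_equal(nrow(sc), 8)  # 4 cutoffs x 2 endpoints
    expect_equal(sc$df[sc$cutoff == "quartiles"], c(3L, 3L))
    # cutoff below every mTBR: responder group empty -> flagged, p omitted
    cases2 <- cases; cases2$mtbr <- cases2$mtbr + 100  # all >> 20
    sc2 <- cutoff_scan(cases2, cutoffs = "10", endpoints = "os")
    expect_equal(sc2$flag, "empty_group")
    expect_true(is.na(sc2$p))
    # missing survival columns: endpoint skipped with warning
    expect_warning(sc3 <- cutoff_scan(cases[, c("case_id", "mtbr", "os_months", "os_event")],
                                      endpoints = c("os", "tss")), "tss")
    expect_equal(unique(sc3$endpoint), "os")
  })
})
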
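test_that("fisher_exact_2x2: published value, balance, degeneracy", {
  expect_equal(round(fisher_exact_2x2(rbind(c(35, 44), c(15, 5)))$p_value, 3), 0.023)
  expect_equal(fisher_exact_2x2(rbind(c(5, 5), c(5, 5)))$p_value, 1)
  expect_equal(fisher_exact_2x2(rbind(c(0, 0), c(3, 4)))$p_value, 1)
})

test_that("fisher_exact_2x2 equals enumeration oracle and fisher.test on random tables", {
  withr::with_seed(101, {
    for (i in 1:40) {
      tab <- matrix(rpois(4, sample(2:8, 1)) + 1, 2)
      p <- fisher_exact_2x2(tab)$p_value
      expect_equal(p, brute_force_exact_p(tab), tolerance = 1e-12)
      expect_equal(p, stats::fisher.test(tab)$p.value, tolerance = 1e-9)
      # transposition invariance
      expect_equal(p, fisher_exact_2x2(t(tab))$p_value, tolerance = 1e-12)
    }
  })
})

test_that("freeman_halton_exact: published 4x2, reduction to 2x2, oracle", {
  lauren <- rbind(c(33, 20), c(8, 15), c(10, 11), c(2, 7))
  expect_equal(round(freeman_halton_exact(lauren)$p_value, 3), 0.042)
  withr::with_seed(103, {
    for (i in 1:10) {
      t22 <- matrix(rpois(4, 6) + 1, 2)
      expect_equal(freeman_halton_exact(t22)$p_value,
                   fisher_exact_2x2(t22)$p_value, tolerance = 1e-12)
      t32 <- matrix(rpois(6, 4) + 1, 3)   # n <= ~40
      p <- freeman_halton_exact(t32)$p_value
      expect_equal(p, brute_force_exact_p(t32), tolerance = 1e-12)
      expect_equal(p, stats::fisher.test(t32)$p.value, tolerance = 1e-9)
      # row permutation invariance for nominal r x 2
      expect_equal(p, freeman_halton_exact(t32[c(2, 3, 1), ])$p_value,
                   tolerance = 1e-12)
    }
  })
  expect_error(freeman_halton_exact(matrix(200, 4, 4), max_tables = 1e3),
               "monte_carlo")
})

test_that("freeman_halton Monte-Carlo fallback approximates the exact p", {
  tab <- rbind(c(12, 3), c(4, 9), c(2, 8))
  pe <- freeman_halton_exact(tab)$p_value
  pm <- freeman_halton_exact(tab, monte_carlo = TRUE, n_sim = 2e4, seed = 9)$p_value
  expect_lt(abs(pe - pm), 3 * sqrt(pe * (1 - pe) / 2e4) + 1e-4)
})

test_that("kendall_tau_b: perfect concordance, published table, errors", {
  expect_equal(kendall_tau_b(1:10, 2 * (1:10) + 3)$statistic, 1)
  expect_equal(kendall_tau_b(1:10, -(1:10))$statistic, -1)
  b <- kendall_tau_b(rbind(c(5, 15), c(10, 9), c(35, 23)))
  expect_lt(abs(b$p_value - 0.012), 0.002)
  expect_error(kendall_tau_b(rep(1, 12), rep(1:2, 6)), "all ties")
})

test_that("kendall tau-b asymptotic p sits inside the permutation-null CI", {
  withr::with_seed(105, {
    x <- sample(1:4, 12, replace = TRUE)
    y <- x + sample(0:2, 12, replace = TRUE)   # correlated ordinal pair
    pa <- kendall_tau_b(x, y)$p_value
    pp <- kendall_tau_b(x, y, method = "permutation", n_perm = 2e4, seed = 5)$p_value
    # asymptotic approx at n = 12 should land within a generous MC window
    expect_lt(abs(pa - pp), 4 * sqrt(pp * (1 - pp) / 2e4) + 0.03)
  })
})

test_that("pearson_r: exact lines and the textbook formula", {
  expect_equal(pearson_r(1:10, 2 * (1:10) + 1)$statistic, 1)
  expect_equal(pearson_r(1:10, -(1:10))$statistic, -1)
  withr::with_seed(107, {
    x <- rnorm(25); y <- 0.4 * x + rnorm(25)
    got <- pearson_r(x, y)
    # independent direct computation
    r <- cov(x, y) / (sd(x) * sd(y))
    t <- r * sqrt(23 / (1 - r^2))
    expect_equal(got$statistic, r, tolerance = 1e-12)
    expect_equal(got$p_value, 2 * pt(-abs(t), 23), tolerance = 1e-12)
  })
  expect_error(pearson_r(rep(1, 5), 1:5), "zero variance")
})

test_that("bh_fdr: hand-computed step-up, monotonicity, m = 1", {
  expect_equal(bh_fdr(0.03)$p_adj, 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04))$p_adj, rep(0.04, 4))
  withr::with_seed(109, {
    p <- runif(20)
    a <- bh_fdr(p)
    expect_true(all(a$p_adj >= a$p))
    expect_true(all(a$p_adj <= 1))
    expect_equal(a$p_adj, stats::p.adjust(p, "BH"))  # independent reference
  })
  expect_error(bh_fdr(numeric(0)), "empty")
})

test_that("build_association_report: bookkeeping, FDR column families, null calibration", {
  withr::with_seed(111, {
    n <- 80
    cases <- data.frame(
      g1 = factor(sample(c("a", "b"), n, TRUE)),
      g2 = factor(sample(c("x", "y", "z"), n, TRUE)),
      ord = sample(1:4, n, TRUE),
      m1 = dichotomize(runif(n)), m2 = dichotomize(runif(n)))
    rep <- build_association_report(
      cases, metrics = list(M1 = "m1", M2 = "m2"),
      covariates = c("g1", "g2", "ord"), ordinal = "ord")
    expect_equal(nrow(rep), 3 * 2)  # covariates x metrics
    expect_setequal(unique(rep$test[rep$covariate == "ord"]), "kendall_tau_b_asymptotic")
    expect_true(all(rep$p_adj >= rep$p))
    # single-level covariate is skipped with a log entry
    cases$flat <- factor("only")
    expect_message(
      rep2 <- build_association_report(cases, metrics = list(M1 = "m1"),
                                       covariates = c("g1", "flat")),
      "single_level")
    expect_equal(nrow(rep2), 1)
  })
  # null calibration: shuffled labels give uniform-ish p, < 10% significant
  sig <- with_seed(113, {
    mean(vapply(1:200, function(i) {
      x <- factor(sample(c("a", "b"), 60, TRUE))
      y <- dichotomize(runif(60))
      fisher_exact_2x2(unclass(table(x, y)))$p_value <= 0.05
    }, logical(1)))
  })
  expect_lt(sig, 0.10)
})
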
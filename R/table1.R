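#' Published-cohort contingency fixtures
#'
#' The package ships the printed cross-tabulations of the 106-case
#' gastric-cancer cohort (clinicopathological covariates against the
#' four dichotomized case-wise metrics mTBR, max KiH, min KiL and KiD)
#' so the association battery can be exercised against published
#' numbers without patient-level data. The low/high columns are the
#' `<median` / `>=median` groups of each metric; for mTBR these are the
#' responder / non-responder groups.
#'
#' @return `table1_counts()`: long data.frame (covariate, level,
#'   level_order, metric, n_low, n_high). `table1_tests()`: one row per
#'   covariate x metric with the test used (`fisher` = exact test,
#'   `tau` = Kendall tau-b) and the printed p-value (character; may be
#'   a bound such as `"<0.001"`). `table1_matrix()`: the r x 2 count
#'   matrix for one covariate x metric pair, levels in printed order.
#' @export
table1_counts <- function() {
  utils::read.csv(system.file("extdata", "table1_counts.csv",
                              package = "ki67ith", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}

#' @rdname table1_counts
#' @export
table1_tests <- function() {
  utils::read.csv(system.file("extdata", "table1_tests.csv",
                              package = "ki67ith", mustWork = TRUE),
                  colClasses = c("character", "character", "character", "character"))
}

#' @rdname table1_counts
#' @param covariate,metric row / column selector, e.g.
#'   `table1_matrix("gender", "max_kih")`.
#' @export
table1_matrix <- function(covariate, metric) {
  d <- table1_counts()
  d <- d[d$covariate == covariate & d$metric == metric, ]
  if (!nrow(d)) stop("no fixture for ", covariate, " x ", metric)
  d <- d[order(d$level_order), ]
  m <- as.matrix(d[, c("n_low", "n_high")])
  dimnames(m) <- list(d$level, c("low", "high"))
  m
}

#' Run the association battery on the published fixtures
#'
#' Recomputes every covariate x metric p-value from the printed counts
#' with the test the published report used (exact test or tau-b).
#'
#' @return data.frame: covariate, metric, test, n, statistic, p,
#'   printed_p.
#' @export
table1_recompute <- function() {
  tests <- table1_tests()
  res <- lapply(seq_len(nrow(tests)), function(i) {
    m <- table1_matrix(tests$covariate[i], tests$metric[i])
    tst <- if (tests$test[i] == "tau") kendall_tau_b(m)
           else if (nrow(m) == 2L) fisher_exact_2x2(m)
           else freeman_halton_exact(m)
    data.frame(covariate = tests$covariate[i], metric = tests$metric[i],
               test = tests$test[i], n = tst$n, statistic = tst$statistic,
               p = tst$p_value, printed_p = tests$printed_p[i],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
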
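#' Exact and rank-based association tests
#'
#' The association battery used by the cohort report: point-probability
#' exact tests for 2x2 and r x c tables (the SPSS / `fisher.test`
#' two-sided definition: sum the probabilities of every
#' margin-consistent table whose point probability does not exceed the
#' observed one, with a 1 + 1e-7 guard against float-ordering
#' artifacts), Kendall's tau-b with tie-corrected asymptotic inference,
#' Pearson correlation, and Benjamini-Hochberg FDR control.
#'
#' @name cohort_stats
NULL

GUARD <- 1 + 1e-7

ith_test <- function(test, statistic, p, n) {
  structure(list(test = test, statistic = statistic,
                 p_value = min(max(p, .Machine$double.xmin), 1), n = n),
            class = "ith_test")
}

#' @export
print.ith_test <- function(x, ...) {
  cat(sprintf("<%s: statistic=%s, p=%.4g, n=%d>\n", x$test,
              if (is.na(x$statistic)) "-" else format(x$statistic, digits = 4),
              x$p_value, x$n))
  invisible(x)
}

#' Fisher's exact test for a 2x2 table
#'
#' @param tab 2x2 matrix of nonnegative integer counts.
#' @return an `ith_test` (two-sided p).
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == 2L), all(tab >= 0))
  r <- rowSums(tab); c_ <- colSums(tab); n <- sum(tab)
  if (any(r == 0) || any(c_ == 0)) return(ith_test("fisher_exact", NA_real_, 1, n))
  klo <- max(0, c_[1] - r[2]); khi <- min(r[1], c_[1])
  ks <- klo:khi
  probs <- stats::dhyper(ks, r[1], r[2], c_[1])
  pobs <- probs[ks == tab[1, 1]]
  ith_test("fisher_exact", NA_real_, sum(probs[probs <= pobs * GUARD]), n)
}

# log multivariate-hypergeometric probability of a full r x c table
log_table_prob <- function(tab, lr, lc, ln) {
  sum(lr) + sum(lc) - ln - sum(lgamma(tab + 1))
}

# enumerate all r x c tables with the given margins, calling fn(tab)
enumerate_tables <- function(rs, cs, fn) {
  r <- length(rs); cc <- length(cs)
  tab <- matrix(0L, r, cc)
  rec <- function(i, colrem) {
    if (i == r) {
      if (any(colrem < 0)) return(invisible())
      tab[r, ] <<- colrem
      fn(tab)
      return(invisible())
    }
    # enumerate compositions of rs[i] over cc cells bounded by colrem
    comp <- function(j, left, row) {
      if (j == cc) {
        if (left > colrem[cc]) return(invisible())
        row[cc] <- left
        tab[i, ] <<- row
        rec(i + 1L, colrem - row)
        return(invisible())
      }
      for (v in 0:min(left, colrem[j])) {
        row[j] <- v
        comp(j + 1L, left - v, row)
      }
    }
    comp(1L, rs[i], integer(cc))
  }
  rec(1L, cs)
}

#' Freeman-Halton exact test for an r x c table
#'
#' Generalization of the 2x2 point-probability rule: all tables with the
#' observed margins are enumerated and the multivariate-hypergeometric
#' probabilities of those no more likely than the observed table are
#' summed. Falls back on an error (suggesting the seeded Monte-Carlo
#' mode) when the enumeration would be infeasibly large.
#'
#' @param tab r x c matrix of nonnegative integer counts.
#' @param max_tables enumeration feasibility bound (upper estimate).
#' @param monte_carlo if `TRUE`, estimate p by `n_sim` seeded
#'   `r2dtable` draws instead of enumerating.
#' @param n_sim,seed Monte-Carlo draws and seed.
#' @return an `ith_test`.
#' @export
freeman_halton_exact <- function(tab, max_tables = 5e6, monte_carlo = FALSE,
                                 n_sim = 1e6, seed = 1L) {
  tab <- as.matrix(tab)
  stopifnot(all(tab >= 0), nrow(tab) >= 2L, ncol(tab) >= 2L)
  rs <- rowSums(tab); cs <- colSums(tab); n <- sum(tab)
  keep_r <- rs > 0; keep_c <- cs > 0
  tab <- tab[keep_r, keep_c, drop = FALSE]
  rs <- rs[keep_r]; cs <- cs[keep_c]
  if (nrow(tab) < 2L || ncol(tab) < 2L)
    return(ith_test("freeman_halton_exact", NA_real_, 1, n))
  lr <- lgamma(rs + 1); lc <- lgamma(cs + 1); ln <- lgamma(n + 1)
  lobs <- log_table_prob(tab, lr, lc, ln)
  if (monte_carlo) {
    p <- with_seed(seed, {
      sims <- stats::r2dtable(n_sim, rs, cs)
      hits <- sum(vapply(sims, function(s)
        log_table_prob(s, lr, lc, ln) <= lobs + log(GUARD), logical(1)))
      (hits + 1) / (n_sim + 1)
    })
    return(ith_test("freeman_halton_mc", NA_real_, p, n))
  }
  # rough upper bound on table count: compositions row by row
  bound <- prod(vapply(rs[-length(rs)], function(ri)
    choose(min(ri, n) + ncol(tab) - 1, ncol(tab) - 1), numeric(1)))
  if (!is.finite(bound) || bound > max_tables)
    stop("enumeration infeasible (~", format(bound, digits = 2),
         " tables); use monte_carlo = TRUE")
  acc <- 0
  thresh <- lobs + log(GUARD)
  enumerate_tables(rs, cs, function(t2) {
    lp <- log_table_prob(t2, lr, lc, ln)
    if (lp <= thresh) acc <<- acc + exp(lp)
  })
  ith_test("freeman_halton_exact", NA_real_, acc, n)
}

# concordance statistic and tie-corrected variance from a contingency table
taub_from_table <- function(tab) {
  r <- nrow(tab); cc <- ncol(tab); n <- sum(tab)
  C <- D <- 0
  for (i in seq_len(r)) for (j in seq_len(cc)) {
    nij <- tab[i, j]
    if (nij == 0) next
    if (i < r && j < cc) C <- C + nij * sum(tab[(i + 1):r, (j + 1):cc])
    if (i < r && j > 1)  D <- D + nij * sum(tab[(i + 1):r, 1:(j - 1)])
  }
  S <- C - D
  ti <- rowSums(tab); uj <- colSums(tab)
  n0 <- n * (n - 1) / 2
  n1 <- sum(ti * (ti - 1) / 2); n2 <- sum(uj * (uj - 1) / 2)
  denom <- sqrt(n0 - n1) * sqrt(n0 - n2)
  if (denom == 0) stop("tau-b undefined: a variable is constant (all ties)")
  v0 <- n * (n - 1) * (2 * n + 5)
  vt <- sum(ti * (ti - 1) * (2 * ti + 5)); vu <- sum(uj * (uj - 1) * (2 * uj + 5))
  v1 <- sum(ti * (ti - 1)) * sum(uj * (uj - 1)) / (2 * n * (n - 1))
  v2 <- sum(ti * (ti - 1) * (ti - 2)) * sum(uj * (uj - 1) * (uj - 2)) /
    (9 * n * (n - 1) * (n - 2))
  list(S = S, tau = S / denom, var_S = (v0 - vt - vu) / 18 + v1 + v2, n = n)
}

#' Kendall's tau-b with tie-corrected asymptotic inference
#'
#' Tau-b with the standard tie corrections in both the coefficient and
#' the variance of the concordance statistic S; the two-sided p-value
#' comes from the normal approximation (the SPSS convention), or
#' optionally from a seeded permutation null.
#'
#' @param x,y paired ordinal vectors (numeric or ordered factors), or
#'   `x` may be an r x c contingency matrix of counts (then `y` is
#'   ignored).
#' @param method `"asymptotic"` (default) or `"permutation"`.
#' @param n_perm,seed permutation count and seed.
#' @return an `ith_test` with `statistic` = tau-b.
#' @export
kendall_tau_b <- function(x, y = NULL, method = c("asymptotic", "permutation"),
                          n_perm = 1e4, seed = 1L) {
  method <- match.arg(method)
  if (is.matrix(x)) {
    tab <- x
  } else {
    keep <- !is.na(x) & !is.na(y)
    x <- x[keep]; y <- y[keep]
    if (length(x) < 3L) stop("need >= 3 complete pairs")
    tab <- table(as.integer(factor(x)), as.integer(factor(y)))
  }
  res <- taub_from_table(tab)
  if (method == "asymptotic") {
    z <- res$S / sqrt(res$var_S)
    p <- 2 * stats::pnorm(-abs(z))
  } else {
    xs <- rep(rep(seq_len(nrow(tab)), ncol(tab)), as.vector(tab))
    ys <- rep(rep(seq_len(ncol(tab)), each = nrow(tab)), as.vector(tab))
    Sobs <- abs(res$S)
    p <- with_seed(seed, {
      hits <- sum(vapply(seq_len(n_perm), function(i) {
        abs(taub_from_table(table(xs, sample(ys)))$S) >= Sobs
      }, logical(1)))
      (hits + 1) / (n_perm + 1)
    })
  }
  ith_test(paste0("kendall_tau_b_", method), res$tau, p, res$n)
}

#' Pearson correlation with a two-sided t-test
#'
#' @param x,y paired numeric vectors with nonzero variance, >= 3 pairs.
#' @return an `ith_test` with `statistic` = r.
#' @export
pearson_r <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) stop("need >= 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance")
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  p <- if (abs(r) >= 1) 0 else {
    t <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(t), df = n - 2)
  }
  ith_test("pearson", r, p, n)
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' @param p vector of raw p-values in (0, 1\].
#' @param q FDR level for the significance flags (default 0.05).
#' @return data.frame: p, p_adj, significant.
#' @export
bh_fdr <- function(p, q = 0.05) {
  if (!length(p)) stop("empty p-value family")
  stopifnot(all(p > 0 & p <= 1, na.rm = TRUE))
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  adj <- pmin(1, cummin(m / (m:1) * p[o]))[ro]
  data.frame(p = p, p_adj = adj, significant = !is.na(adj) & adj <= q)
}

#' Expand a contingency table of counts to paired label vectors
#'
#' @param tab r x c count matrix.
#' @return data.frame with integer columns `x` (row index) and `y`
#'   (column index), one row per observation.
#' @export
counts_to_pairs <- function(tab) {
  tab <- as.matrix(tab)
  data.frame(
    x = rep(rep(seq_len(nrow(tab)), ncol(tab)), as.vector(tab)),
    y = rep(rep(seq_len(ncol(tab)), each = nrow(tab)), as.vector(tab)))
}

#' Cohort association report (Table-1 style)
#'
#' Cross-tabulates every covariate against every dichotomized metric,
#' picks the test by covariate scale (exact test for nominal, tau-b for
#' ordinal), and controls the FDR per metric column with
#' Benjamini-Hochberg.
#'
#' @param cases case-level data.frame.
#' @param metrics named list: report column name -> factor column in
#'   `cases` (2 levels, low/high).
#' @param covariates character vector of covariate column names.
#' @param ordinal covariate names to treat as ordinal (tau-b).
#' @param fdr_q FDR level.
#' @return data.frame: covariate, metric, test, n, statistic, p,
#'   p_adj, significant.
#' @export
build_association_report <- function(cases, metrics, covariates,
                                     ordinal = character(0), fdr_q = 0.05) {
  rows <- list()
  for (m in names(metrics)) {
    y <- cases[[metrics[[m]]]]
    for (cv in covariates) {
      x <- cases[[cv]]
      keep <- !is.na(x) & !is.na(y)
      tab <- table(droplevels(factor(x[keep])), droplevels(factor(y[keep])))
      if (nrow(tab) < 2L || ncol(tab) < 2L) {
        message("skipping ", cv, " x ", m, ": single level [reason=single_level]")
        next
      }
      tst <- if (cv %in% ordinal) kendall_tau_b(unclass(tab))
             else if (all(dim(tab) == 2L)) fisher_exact_2x2(unclass(tab))
             else freeman_halton_exact(unclass(tab))
      rows[[length(rows) + 1L]] <- data.frame(
        covariate = cv, metric = m, test = tst$test, n = tst$n,
        statistic = tst$statistic, p = tst$p_value, stringsAsFactors = FALSE)
    }
  }
  rep <- do.call(rbind, rows)
  rep$p_adj <- NA_real_
  for (ix in split(seq_len(nrow(rep)), rep$metric))
    rep$p_adj[ix] <- bh_fdr(rep$p[ix], q = fdr_q)$p_adj
  rep$significant <- rep$p_adj <= fdr_q
  rownames(rep) <- NULL
  rep
}
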
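#' Kaplan-Meier product-limit estimate
#'
#' Standard product-limit estimator with Greenwood variance and a
#' log-log transformed pointwise 95% confidence band. Subjects censored
#' exactly at an event time are counted at risk for that event.
#'
#' @param time positive follow-up times (months).
#' @param event logical / 0-1 event indicator (death; for
#'   tumor-specific survival, tumor-related death with other deaths
#'   censored).
#' @param conf_level confidence level for the Greenwood band.
#' @return data.frame of class `km_curve`: time (event times,
#'   ascending), n_risk, n_event, surv, se (Greenwood), lower, upper;
#'   attribute `n` = number of subjects.
#' @export
km_estimate <- function(time, event, conf_level = 0.95) {
  stopifnot(length(time) == length(event), length(time) >= 1L)
  if (any(!is.finite(time) | time <= 0)) stop("times must be finite and positive")
  event <- as.logical(event)
  et <- sort(unique(time[event]))
  n <- length(time)
  if (!length(et)) {
    out <- data.frame(time = numeric(0), n_risk = integer(0), n_event = integer(0),
                      surv = numeric(0), se = numeric(0),
                      lower = numeric(0), upper = numeric(0))
    attr(out, "n") <- n
    class(out) <- c("km_curve", "data.frame")
    return(out)
  }
  n_risk <- vapply(et, function(t) sum(time >= t), integer(1))
  n_event <- vapply(et, function(t) sum(time == t & event), integer(1))
  surv <- cumprod(1 - n_event / n_risk)
  # Greenwood: var(S) = S^2 * cumsum(d / (n (n - d)))
  gw <- cumsum(n_event / (n_risk * pmax(n_risk - n_event, 1e-300)))
  se <- surv * sqrt(gw)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  # log(-log S) transformed band, defined for 0 < S < 1
  lower <- upper <- rep(NA_real_, length(surv))
  ok <- surv > 0 & surv < 1
  selog <- sqrt(gw[ok]) / abs(log(surv[ok]))
  lower[ok] <- surv[ok]^exp(z * selog)
  upper[ok] <- surv[ok]^exp(-z * selog)
  out <- data.frame(time = et, n_risk = n_risk, n_event = n_event,
                    surv = surv, se = se, lower = lower, upper = upper)
  attr(out, "n") <- n
  class(out) <- c("km_curve", "data.frame")
  out
}

#' Median survival of a Kaplan-Meier curve
#'
#' Smallest event time with S(t) <= 0.5; `NA` ("not computed") when the
#' curve never reaches 0.5.
#'
#' @param curve a [km_estimate()] result.
#' @return months, or `NA_real_`.
#' @export
median_survival <- function(curve) {
  ix <- which(curve$surv <= 0.5 + 1e-12)
  if (!length(ix)) NA_real_ else curve$time[min(ix)]
}

#' Mantel-Cox log-rank test
#'
#' Sums observed-minus-expected events over the pooled event times with
#' the hypergeometric variance; for k groups the statistic is the
#' quadratic form over the first k-1 groups, chi-square with k-1
#' degrees of freedom.
#'
#' @param time,event as in [km_estimate()].
#' @param group group labels (>= 2 nonempty groups).
#' @return an `ith_test` with `statistic` = chi-square and extra fields
#'   `df`, `observed`, `expected` per group.
#' @export
logrank_test <- function(time, event, group) {
  group <- factor(group)
  if (any(table(group) == 0L) || nlevels(group) < 2L)
    stop("log-rank needs >= 2 nonempty groups")
  event <- as.logical(event)
  k <- nlevels(group)
  et <- sort(unique(time[event]))
  gi <- as.integer(group)
  O <- E <- numeric(k)
  V <- matrix(0, k, k)
  for (t in et) {
    at <- time >= t
    n_t <- sum(at)
    n_g <- tabulate(gi[at], k)
    d_g <- tabulate(gi[time == t & event], k)
    d_t <- sum(d_g)
    O <- O + d_g
    E <- E + d_t * n_g / n_t
    # covariance at t: d(n-d)/((n-1) n^2) * (n * n_i * delta_ij - n_i n_j)
    if (n_t > 1) {
      f <- d_t * (n_t - d_t) / (n_t - 1) / n_t^2
      V <- V + f * (diag(n_t * n_g, nrow = k) - outer(n_g, n_g))
    }
  }
  U <- (O - E)[-k]
  Vk <- V[-k, -k, drop = FALSE]
  stat <- if (all(abs(U) < 1e-12)) 0 else
    as.numeric(t(U) %*% solve(Vk, U))
  res <- ith_test("logrank", stat, stats::pchisq(stat, df = k - 1,
                                                 lower.tail = FALSE),
                  length(time))
  res$df <- k - 1L
  res$observed <- O
  res$expected <- E
  res
}

#' Survival cut-off scan over the case mTBR
#'
#' One row per (cutoff, endpoint): the cohort is split at the cohort
#' median, at 10%, at 20%, and into quartiles, and overall / tumor-
#' specific survival are compared by log-rank. Cutoffs producing an
#' empty group are flagged and their p omitted.
#'
#' @param cases case-level data.frame with `mtbr`, `os_months`,
#'   `os_event` and (optionally) `tss_months`, `tss_event` columns.
#' @param cutoffs subset of `c("median", "10", "20", "quartiles")`.
#' @param endpoints subset of `c("os", "tss")`.
#' @return data.frame: cutoff, endpoint, n_groups, group sizes/events
#'   (semicolon-joined), medians, chi-square, df, p, flag.
#' @export
cutoff_scan <- function(cases, cutoffs = c("median", "10", "20", "quartiles"),
                        endpoints = c("os", "tss")) {
  rows <- list()
  for (ep in endpoints) {
    tcol <- paste0(ep, "_months"); ecol <- paste0(ep, "_event")
    if (!all(c(tcol, ecol) %in% names(cases))) {
      warning("endpoint ", ep, " skipped: columns missing")
      next
    }
    keep <- !is.na(cases[[tcol]]) & !is.na(cases[[ecol]]) & !is.na(cases$mtbr)
    d <- cases[keep, ]
    for (co in cutoffs) {
      grp <- switch(co,
        median = responder_label(d$mtbr, stats::median(d$mtbr)),
        "10" = responder_label(d$mtbr, 10),
        "20" = responder_label(d$mtbr, 20),
        quartiles = mtbr_quartiles(d$mtbr))
      empty <- any(table(grp) == 0L) || nlevels(droplevels(grp)) < 2L
      sizes <- table(grp)
      evts <- tapply(as.logical(d[[ecol]]), grp, sum)
      meds <- vapply(levels(grp), function(l) {
        ix <- which(grp == l)
        if (!length(ix)) NA_real_
        else median_survival(km_estimate(d[[tcol]][ix], d[[ecol]][ix]))
      }, numeric(1))
      if (empty) {
        rows[[length(rows) + 1L]] <- data.frame(
          cutoff = co, endpoint = ep, n_groups = nlevels(grp),
          n = paste(sizes, collapse = ";"),
          events = paste(evts, collapse = ";"),
          medians = paste(round(meds, 1), collapse = ";"),
          chisq = NA_real_, df = NA_integer_, p = NA_real_,
          flag = "empty_group", stringsAsFactors = FALSE)
      } else {
        lr <- logrank_test(d[[tcol]], d[[ecol]], grp)
        rows[[length(rows) + 1L]] <- data.frame(
          cutoff = co, endpoint = ep, n_groups = nlevels(grp),
          n = paste(sizes, collapse = ";"),
          events = paste(evts, collapse = ";"),
          medians = paste(round(meds, 1), collapse = ";"),
          chisq = lr$statistic, df = lr$df, p = lr$p_value,
          flag = "", stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}
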
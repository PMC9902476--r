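#' Aggregate block metrics to one case
#'
#' Case-wise parameters: `max_kih` = maximum block KiH, `min_kil` =
#' minimum block KiL, `case_kid` = max KiH - min KiL, `mtbr` = median of
#' the included blocks' TBRs (even counts average the two central
#' values). The case Becker grade is derived from the mTBR. Only
#' included blocks contribute.
#'
#' @param blocks data.frame of block metrics (rows of [score_block()])
#'   sharing one `case_id`.
#' @return one-row data.frame, or `NULL` (with a message) when no block
#'   is included.
#' @export
aggregate_case <- function(blocks) {
  stopifnot(length(unique(blocks$case_id)) == 1L)
  inc <- blocks[blocks$included, , drop = FALSE]
  if (!nrow(inc)) {
    message("case ", blocks$case_id[1], " excluded: no included blocks [reason=no_included_blocks]")
    return(NULL)
  }
  maxk <- if (all(is.na(inc$kih))) NA_real_ else max(inc$kih, na.rm = TRUE)
  mink <- if (all(is.na(inc$kil))) NA_real_ else min(inc$kil, na.rm = TRUE)
  kid <- if (is.na(maxk) || is.na(mink)) NA_real_ else maxk - mink
  mtbr <- stats::median(inc$tbr)
  data.frame(case_id = inc$case_id[1], n_blocks = nrow(inc),
             max_kih = maxk, min_kil = mink, case_kid = kid, mtbr = mtbr,
             becker = becker_trg(mtbr), stringsAsFactors = FALSE)
}

#' Aggregate a whole block table to cases
#'
#' @param blocks data.frame of block metrics (any number of cases).
#' @param cases optional data.frame of case-level covariates / survival,
#'   joined on `case_id`.
#' @return data.frame, one row per case with at least one included block.
#' @export
aggregate_cases <- function(blocks, cases = NULL) {
  out <- do.call(rbind, lapply(split(blocks, blocks$case_id), aggregate_case))
  rownames(out) <- NULL
  if (!is.null(cases)) out <- merge(out, cases, by = "case_id", sort = TRUE)
  out
}

#' Dichotomize a cohort vector at its median
#'
#' Values below the cutoff are labelled `"<median"`, values at or above
#' `">=median"` (ties at the median go to the high / non-responder
#' group, matching the `<median` / `>=median` column pairs of the
#' cohort report). Missing values stay missing.
#'
#' @param x numeric cohort vector.
#' @param cutoff cutoff; defaults to `median(x, na.rm = TRUE)`.
#' @return factor with levels `<median`, `>=median` and attribute
#'   `cutoff`.
#' @export
dichotomize <- function(x, cutoff = NULL) {
  if (all(is.na(x))) stop("cannot dichotomize an all-missing vector")
  if (sum(!is.na(x)) < 2L) stop("need >= 2 non-missing values")
  if (is.null(cutoff)) cutoff <- stats::median(x, na.rm = TRUE)
  f <- factor(ifelse(x < cutoff, "<median", ">=median"),
              levels = c("<median", ">=median"))
  attr(f, "cutoff") <- cutoff
  f
}

#' Responder labelling at a mTBR cutoff
#'
#' A case is a responder iff its mTBR lies strictly below the cutoff
#' (cohort median, 10% or 20%).
#'
#' @param mtbr numeric vector of case mTBRs.
#' @param cutoff percentage cutoff.
#' @return factor with levels `responder`, `non-responder`.
#' @export
responder_label <- function(mtbr, cutoff) {
  factor(ifelse(is.na(mtbr), NA_character_,
                ifelse(mtbr < cutoff, "responder", "non-responder")),
         levels = c("responder", "non-responder"))
}

#' mTBR quartile grouping
#'
#' Quartile boundaries are the cohort's type-7 quantiles; groups are the
#' half-open intervals Q1 = \[0, q1\], Q2 = (q1, q2\], Q3 = (q2, q3\],
#' Q4 = (q3, 100\].
#'
#' @param mtbr numeric vector.
#' @param boundaries optional explicit boundaries `c(q1, q2, q3)`.
#' @return factor Q1..Q4 with attribute `boundaries`.
#' @export
mtbr_quartiles <- function(mtbr, boundaries = NULL) {
  if (is.null(boundaries))
    boundaries <- stats::quantile(mtbr, c(.25, .5, .75), na.rm = TRUE, type = 7)
  f <- cut(mtbr, breaks = c(-Inf, boundaries, Inf),
           labels = c("Q1", "Q2", "Q3", "Q4"), right = TRUE)
  attr(f, "boundaries") <- unname(boundaries)
  f
}

#' Cohort bookkeeping summary
#'
#' @param blocks data.frame of block metrics with `case_id` and
#'   `included` columns; excluded blocks count toward the screening
#'   total only.
#' @return list: n_cases, n_blocks (included), n_blocks_screened,
#'   n_excluded, pct_excluded, mean_blocks_per_case, and
#'   `blocks_per_case` (data.frame n_blocks / n_cases / pct).
#' @export
cohort_summary <- function(blocks) {
  if (!nrow(blocks)) stop("empty block table")
  inc <- blocks[blocks$included, , drop = FALSE]
  per_case <- table(factor(tapply(rep(1L, nrow(inc)), inc$case_id, sum),
                           levels = 1:5))
  n_cases <- length(unique(inc$case_id))
  dist <- data.frame(n_blocks = as.integer(names(per_case)),
                     n_cases = as.integer(per_case),
                     pct = round(100 * as.integer(per_case) / n_cases, 1))
  list(n_cases = n_cases,
       n_blocks = nrow(inc),
       n_blocks_screened = nrow(blocks),
       n_excluded = sum(!blocks$included),
       pct_excluded = round(100 * sum(!blocks$included) / nrow(blocks), 1),
       mean_blocks_per_case = round(nrow(inc) / n_cases, 1),
       blocks_per_case = dist)
}
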
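#' Block-wise analysis
#'
#' Dichotomizes all block TBRs at the cohort median into responder /
#' non-responder blocks, dichotomizes each block Ki67 index (KiH, KiL,
#' KiD) at its own median, and tests each index against responder-block
#' status with the exact test. The block-wise median TBR is a property
#' of the dataset and is recomputed, never assumed.
#'
#' @param blocks data.frame of block metrics ([score_blocks()]).
#' @param fdr_q FDR level for the report flags.
#' @return list: `median_tbr`, `blocks` (with `tbr_group` column),
#'   `report` (one row per Ki67 index: test, p, group medians).
#' @export
run_blockwise <- function(blocks, fdr_q = 0.05) {
  inc <- blocks[blocks$included, , drop = FALSE]
  if (!nrow(inc)) stop("no included blocks")
  grp <- dichotomize(inc$tbr)
  inc$tbr_group <- grp
  rows <- lapply(c("kih", "kil", "kid"), function(v) {
    x <- inc[[v]]
    keep <- !is.na(x)
    if (sum(keep) < 2L) return(NULL)
    xg <- dichotomize(x[keep])
    tab <- table(xg, grp[keep])
    tst <- if (all(dim(tab) == 2L) && all(rowSums(tab) > 0) && all(colSums(tab) > 0))
      fisher_exact_2x2(unclass(tab)) else ith_test("fisher_exact", NA_real_, 1, sum(keep))
    data.frame(index = v, n = sum(keep),
               median_responder = stats::median(x[keep & grp == "<median"]),
               median_nonresponder = stats::median(x[keep & grp == ">=median"]),
               p = tst$p_value, stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, rows)
  report$p_adj <- bh_fdr(report$p, q = fdr_q)$p_adj
  list(median_tbr = attr(grp, "cutoff"), blocks = inc, report = report)
}

#' Case-wise analysis
#'
#' Aggregates blocks to cases, dichotomizes the four case-wise
#' parameters at their cohort medians, builds the covariate association
#' report, and (when survival columns are present) runs the mTBR
#' cut-off scan.
#'
#' @param blocks data.frame of block metrics.
#' @param cases optional case-level covariate / survival table joined
#'   on `case_id`.
#' @param covariates covariate columns for the association report
#'   (defaults to those present among the published-cohort set).
#' @param ordinal covariates treated as ordinal (tau-b).
#' @param fdr_q FDR level.
#' @return list: `cases` (aggregated, with `*_group` columns),
#'   `report`, `scan` (or `NULL` if survival columns are absent).
#' @export
run_casewise <- function(blocks, cases = NULL,
                         covariates = NULL,
                         ordinal = c("ypT", "ypN", "uicc", "becker"),
                         fdr_q = 0.05) {
  agg <- aggregate_cases(blocks, cases)
  agg$mtbr_group <- dichotomize(agg$mtbr)
  agg$max_kih_group <- if (sum(!is.na(agg$max_kih)) >= 2) dichotomize(agg$max_kih) else NA
  agg$min_kil_group <- if (sum(!is.na(agg$min_kil)) >= 2) dichotomize(agg$min_kil) else NA
  agg$kid_group <- if (sum(!is.na(agg$case_kid)) >= 2) dichotomize(agg$case_kid) else NA
  if (is.null(covariates)) {
    covariates <- intersect(c(names(COVARIATE_MARGINALS), "becker"), names(agg))
  }
  report <- build_association_report(
    agg,
    metrics = list(mtbr = "mtbr_group", max_kih = "max_kih_group",
                   min_kil = "min_kil_group", kid = "kid_group"),
    covariates = covariates, ordinal = ordinal, fdr_q = fdr_q)
  scan <- if (all(c("os_months", "os_event") %in% names(agg))) {
    eps <- c("os", if (all(c("tss_months", "tss_event") %in% names(agg))) "tss")
    cutoff_scan(agg, endpoints = eps)
  } else {
    warning("survival columns missing; cut-off scan skipped")
    NULL
  }
  list(cases = agg, report = report, scan = scan)
}

#' End-to-end pipeline
#'
#' Runs either execution mode: `annotations` (read / simulate GeoJSON
#' blocks, score the geometry, then aggregate) or `tables` (start from
#' an existing block-metrics CSV). Writes block metrics, case table,
#' association report and survival scan as CSV when `out_dir` is given.
#'
#' @param annotations_dir directory of `.geojson` block annotations.
#' @param blocks_csv alternatively, a block-metrics CSV.
#' @param cases_csv optional case-level covariate/survival CSV.
#' @param sim_config alternatively, a [sim_config()]: simulate, then run.
#' @param out_dir optional output directory.
#' @param fdr_q FDR level.
#' @return list: `blocks`, `blockwise`, `casewise`.
#' @export
run_pipeline <- function(annotations_dir = NULL, blocks_csv = NULL,
                         cases_csv = NULL, sim_config = NULL,
                         out_dir = NULL, fdr_q = 0.05) {
  modes <- c(!is.null(annotations_dir), !is.null(blocks_csv), !is.null(sim_config))
  if (sum(modes) != 1L)
    stop("give exactly one of annotations_dir, blocks_csv, sim_config")
  cases <- if (!is.null(cases_csv)) utils::read.csv(cases_csv) else NULL
  if (!is.null(sim_config)) {
    sim <- simulate_cohort(sim_config)
    blocks <- score_blocks(sim$annotations, window_cells = sim_config$window_cells)
    cases <- sim$cases
  } else if (!is.null(annotations_dir)) {
    blocks <- score_blocks(annotations_dir)
  } else {
    blocks <- utils::read.csv(blocks_csv)
  }
  bw <- run_blockwise(blocks, fdr_q = fdr_q)
  cw <- run_casewise(blocks, cases, fdr_q = fdr_q)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(blocks, file.path(out_dir, "block_metrics.csv"), row.names = FALSE)
    utils::write.csv(bw$report, file.path(out_dir, "blockwise_report.csv"), row.names = FALSE)
    cw_out <- cw$cases
    utils::write.csv(cw_out, file.path(out_dir, "case_summary.csv"), row.names = FALSE)
    utils::write.csv(cw$report, file.path(out_dir, "association_report.csv"), row.names = FALSE)
    if (!is.null(cw$scan))
      utils::write.csv(cw$scan, file.path(out_dir, "survival_scan.csv"), row.names = FALSE)
  }
  list(blocks = blocks, blockwise = bw, casewise = cw)
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (write a synthetic cohort), `score` (score
#' an annotations directory to a block CSV), `report` (block CSV ->
#' reports), `all` (simulate + score + reports), `table1` (recompute
#' the published contingency-table statistics). Invoke via
#' `Rscript -e 'ki67ith::ith_cli()' <subcommand> [options]`.
#'
#' @param args character vector (defaults to `commandArgs(TRUE)`).
#' @return invisibly, the result object of the subcommand.
#' @export
ith_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: ith <simulate|score|report|all|table1> [--seed N] [--n-cases N]",
    "           [--in DIR|CSV] [--cases CSV] [--out DIR]", sep = "\n")
  if (!length(args)) { cat(usage, "\n"); return(invisible(NULL)) }
  cmd <- args[1]
  opt <- function(name, default = NULL) {
    i <- which(args == name)
    if (length(i) && i < length(args)) args[i + 1L] else default
  }
  seed <- as.integer(opt("--seed", "1"))
  out <- opt("--out", "ith_out")
  res <- switch(cmd,
    simulate = {
      cfg <- sim_config(n_cases = as.integer(opt("--n-cases", "106")), seed = seed)
      simulate_cohort(cfg, dir = out)
    },
    score = {
      b <- score_blocks(opt("--in"))
      dir.create(out, recursive = TRUE, showWarnings = FALSE)
      utils::write.csv(b, file.path(out, "block_metrics.csv"), row.names = FALSE)
      b
    },
    report = run_pipeline(blocks_csv = opt("--in"), cases_csv = opt("--cases"),
                          out_dir = out),
    all = run_pipeline(sim_config = sim_config(
      n_cases = as.integer(opt("--n-cases", "106")), seed = seed), out_dir = out),
    table1 = {
      t1 <- table1_recompute()
      dir.create(out, recursive = TRUE, showWarnings = FALSE)
      utils::write.csv(t1, file.path(out, "table1_recomputed.csv"), row.names = FALSE)
      print(t1)
      t1
    },
    stop(usage))
  invisible(res)
}
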
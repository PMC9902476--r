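#' Simulation configuration
#'
#' Parameters of the subclonal chemotherapy-selection generator. The
#' generative model: each case carries a pool of subclones, each with a
#' pre-therapy Ki67 positivity probability and a chemotherapy survival
#' probability; chemotherapy erases the fraction `1 - survival_k` of
#' subclone k's spatial footprint (residual tumor persists as compact
#' nests around the territory center at unchanged cell density),
#' survival being lower for highly proliferative subclones (cytotoxic
#' agents preferentially hit cycling cells); where
#' the surviving cell fraction of a block falls below the
#' competitive-release threshold, surviving subclones gain an additive
#' positivity boost (release from competition by fitter, chemo-
#' sensitive neighbours). Blocks are spatial: a blob-shaped tumor-bed
#' polygon partitioned into nearest-seed (Voronoi-style) subclone
#' territories with homogeneous-Poisson cell placement; the residual
#' tumor is annotated as convex hulls of surviving territory cells,
#' which introduces realistic annotation slop.
#'
#' Defaults state the emulated cohort: 106 cases; 1-5 blocks/case with
#' the published availability frequencies (5 blocks in 54.7% of cases,
#' then 17.9/11.3/9.4/6.6%); 0.26 um pixels; responders defined at the
#' 10% mTBR cutoff; exponential survival with responder median 32
#' months (the published responder median OS) and hazard ratio 2.5 for
#' non-responders; light independent exponential censoring (rate
#' 0.004/month) plus administrative censoring at 120 months — light so
#' the generator meets its documented log-rank power surface; the
#' published cohort censors more heavily (~46%).
#'
#' @param n_cases number of cases.
#' @param blocks_per_case_prob probabilities of 1..5 blocks per case.
#' @param subclones_range inclusive range of subclones per case.
#' @param pre_positivity_range pre-therapy positivity drawn uniformly
#'   from this range per subclone.
#' @param resistance_beta shape1/shape2 of the Beta prior on the
#'   case-level chemo-survival scale.
#' @param prolif_sensitivity exponent tilt: subclone survival =
#'   theta^(1 + prolif_sensitivity * pre_positivity).
#' @param release_threshold surviving-fraction threshold below which
#'   competitive release applies.
#' @param release_boost additive positivity boost on release.
#' @param cell_density cells per pixel^2 of tumor bed.
#' @param bed_radius_px range of the bed blob radius (pixels).
#' @param bed_irregularity relative radial noise of the bed outline.
#' @param pixel_size_um pixel pitch (um).
#' @param window_cells hot/cold-spot window size.
#' @param responder_cutoff mTBR percentage defining true responders.
#' @param median_responder_os responder median OS in months
#'   (exponential).
#' @param hazard_ratio hazard ratio of true non-responders.
#' @param censor_rate exponential censoring hazard per month.
#' @param admin_censor_months administrative censoring horizon.
#' @param tumor_death_prob probability a death is tumor-related (TSS).
#' @param seed mandatory RNG seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_cases = 106L,
                       blocks_per_case_prob = c(0.066, 0.094, 0.113, 0.179, 0.547),
                       subclones_range = c(3L, 6L),
                       pre_positivity_range = c(0.05, 0.85),
                       resistance_beta = c(1.1, 2.2),
                       prolif_sensitivity = 1.5,
                       release_threshold = 0.5,
                       release_boost = 0.15,
                       cell_density = 0.25,
                       bed_radius_px = c(90, 130),
                       bed_irregularity = 0.12,
                       pixel_size_um = 0.26,
                       window_cells = 500L,
                       responder_cutoff = 10,
                       median_responder_os = 32,
                       hazard_ratio = 2.5,
                       censor_rate = 0.004,
                       admin_censor_months = 120,
                       tumor_death_prob = 0.8,
                       seed) {
  if (missing(seed)) stop("seed is mandatory")
  # published availability percentages sum to 99.9 (rounding); renormalize
  stopifnot(length(blocks_per_case_prob) == 5L,
            abs(sum(blocks_per_case_prob) - 1) < 0.01)
  blocks_per_case_prob <- blocks_per_case_prob / sum(blocks_per_case_prob)
  stopifnot(
            release_threshold >= 0, release_threshold <= 1,
            release_boost >= 0, release_boost <= 1,
            diff(pre_positivity_range) >= 0,
            max(pre_positivity_range) + release_boost <= 1 + 1e-9,
            cell_density > 0, pixel_size_um > 0, hazard_ratio > 0)
  structure(as.list(environment()), class = "sim_config")
}

# blob-shaped simple polygon: radial noise around a circle
make_bed_polygon <- function(radius, irregularity, n_vertices = 28L) {
  th <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  r <- radius * (1 + irregularity * stats::runif(n_vertices, -1, 1))
  polygon_region(cbind(r * cos(th), r * sin(th)), "tumor_bed", check = FALSE)
}

# uniform points inside a polygon by bbox rejection sampling
sample_in_polygon <- function(n, poly) {
  v <- poly$vertices
  xr <- range(v[, 1]); yr <- range(v[, 2])
  xs <- ys <- numeric(0)
  while (length(xs) < n) {
    m <- max(64L, ceiling((n - length(xs)) * 2))
    cx <- stats::runif(m, xr[1], xr[2]); cy <- stats::runif(m, yr[1], yr[2])
    ok <- point_in_polygon(cx, cy, poly)
    xs <- c(xs, cx[ok]); ys <- c(ys, cy[ok])
  }
  cbind(xs[seq_len(n)], ys[seq_len(n)])
}

# area fraction of each seed's nearest-seed territory inside the bed,
# estimated on a deterministic lattice
territory_fractions <- function(poly, seeds, n_grid = 4000L) {
  v <- poly$vertices
  xr <- range(v[, 1]); yr <- range(v[, 2])
  step <- sqrt(diff(xr) * diff(yr) / n_grid)
  gx <- seq(xr[1], xr[2], by = step); gy <- seq(yr[1], yr[2], by = step)
  g <- expand.grid(x = gx, y = gy)
  ok <- point_in_polygon(g$x, g$y, poly)
  g <- g[ok, ]
  d2 <- outer(g$x, seeds[, 1], "-")^2 + outer(g$y, seeds[, 2], "-")^2
  near <- max.col(-d2, ties.method = "first")
  tabulate(near, nrow(seeds)) / nrow(g)
}

#' Simulate one tumor block
#'
#' Draws the spatial block for a case-level subclone pool and applies
#' the chemotherapy-selection model; see [sim_config()] for the model.
#' Consumes the current RNG stream (callers seed once per cohort).
#'
#' @param subclones data.frame with `pre_positivity` and `survival`
#'   columns (one row per subclone of the case).
#' @param config a [sim_config()].
#' @param case_id,block_id identifiers for the emitted annotation.
#' @param geometry if `FALSE`, skip the spatial layer: territory
#'   weights are Dirichlet(1) draws and no annotation is produced
#'   (fast path for cohort-scale survival statistics).
#' @return list with `annotation` ([block_annotation()] or `NULL`) and
#'   `truth` (one-row data.frame: true_tbr, true_kih, true_kil,
#'   n_cells, n_survivors, released).
#' @export
simulate_block <- function(subclones, config, case_id = "case", block_id = "b1",
                           geometry = TRUE) {
  k <- nrow(subclones)
  if (!geometry) {
    w <- stats::rgamma(k, 1); w <- w / sum(w)
    surv_frac <- sum(w * subclones$survival)
    released <- surv_frac < config$release_threshold
    post <- pmin(1, subclones$pre_positivity + if (released) config$release_boost else 0)
    present <- w * subclones$survival > 1e-4  # subclones with surviving mass
    truth <- data.frame(case_id = case_id, block_id = block_id,
                        true_tbr = 100 * surv_frac,
                        true_kih = if (any(present)) 100 * max(post[present]) else NA_real_,
                        true_kil = if (any(present)) 100 * min(post[present]) else NA_real_,
                        n_cells = NA_integer_, n_survivors = NA_integer_,
                        released = released, stringsAsFactors = FALSE)
    return(list(annotation = NULL, truth = truth))
  }
  for (try in 1:5) {
    bed <- make_bed_polygon(stats::runif(1, config$bed_radius_px[1],
                                         config$bed_radius_px[2]),
                            config$bed_irregularity)
    bed_area_px <- polygon_area(bed)
    n_cells <- stats::rpois(1, config$cell_density * bed_area_px)
    if (n_cells >= k) break
  }
  if (n_cells < k) stop("degenerate bed polygon: too few cells after retries")
  seeds <- sample_in_polygon(k, bed)
  cells <- sample_in_polygon(n_cells, bed)
  d2 <- outer(cells[, 1], seeds[, 1], "-")^2 + outer(cells[, 2], seeds[, 2], "-")^2
  terr <- max.col(-d2, ties.method = "first")
  f <- territory_fractions(bed, seeds)
  # regression contracts each clone's footprint: the surviving fraction of a
  # territory is the sub-region nearest its seed, at unchanged cell density
  # (residual tumor forms compact nests, not a uniform thinning)
  alive <- logical(n_cells)
  for (j in seq_len(k)) {
    ix <- which(terr == j)
    keep_n <- round(subclones$survival[j] * length(ix))
    if (keep_n > 0L)
      alive[ix[order(d2[ix, j])][seq_len(keep_n)]] <- TRUE
  }
  surv_frac_cells <- mean(alive)
  released <- surv_frac_cells < config$release_threshold
  post <- pmin(1, subclones$pre_positivity + if (released) config$release_boost else 0)
  positive <- stats::runif(n_cells) < post[terr]
  marks <- cell_marks(cells[alive, 1], cells[alive, 2], positive[alive])

  # residual tumor: convex hull of surviving cells per territory
  regions <- list(bed)
  for (j in seq_len(k)) {
    ix <- which(alive & terr == j)
    if (length(ix) >= 3L) {
      h <- grDevices::chull(cells[ix, 1], cells[ix, 2])
      regions[[length(regions) + 1L]] <-
        polygon_region(cells[ix[h], , drop = FALSE], "residual_tumor", check = FALSE)
    }
  }
  # delineated Ki67 regions, as a pathologist would draw them
  n_surv <- sum(alive)
  if (n_surv >= 2L * config$window_cells) {
    sel <- select_extreme_regions(marks, window_cells = config$window_cells)
    regions <- c(regions, list(sel$hotspot, sel$coldspot))
  } else if (n_surv >= 100L) {
    h <- grDevices::chull(marks$x, marks$y)
    ctr <- c(mean(marks$x), mean(marks$y))
    hull <- t(t(marks[h, c("x", "y")]) - ctr) * 1.001
    regions[[length(regions) + 1L]] <-
      polygon_region(t(t(hull) + ctr), "ki67_region", check = FALSE)
  }
  ann <- block_annotation(case_id, block_id, regions = regions, marks = marks,
                          pck_tumor_cell_count = n_surv,
                          pixel_size_um = config$pixel_size_um)
  # territory presence for ground-truth extremes: >= 100 surviving cells
  n_surv_terr <- tabulate(terr[alive], k)
  present <- n_surv_terr >= 100L
  truth <- data.frame(case_id = case_id, block_id = block_id,
                      true_tbr = 100 * sum(f * subclones$survival),
                      true_kih = if (any(present)) 100 * max(post[present]) else NA_real_,
                      true_kil = if (any(present)) 100 * min(post[present]) else NA_real_,
                      n_cells = n_cells, n_survivors = n_surv,
                      released = released, stringsAsFactors = FALSE)
  list(annotation = ann, truth = truth)
}

# published covariate marginals used to decorate simulated cases
COVARIATE_MARGINALS <- list(
  gender = c(Male = 85, Female = 21),
  age_group = c("<64" = 49, ">=64" = 57),
  localization = c(Proximal = 75, Distal = 31),
  lauren = c(Intestinal = 53, Diffuse = 23, Mixed = 21, Unclassifiable = 9),
  ypT = c(ypT1 = 17, ypT2 = 16, ypT3 = 63, ypT4 = 10),
  ypN = c(ypN0 = 35, ypN1 = 23, ypN2 = 28, ypN3 = 20),
  uicc = c(I = 17, II = 16, III = 60, IV = 13),
  ypL = c(ypL0 = 74, ypL1 = 32),
  ypV = c(ypV0 = 97, ypV1 = 9),
  ypPn = c(ypPn0 = 79, ypPn1 = 27),
  r_status = c(pR0 = 92, pR1 = 12))

draw_covariates <- function(n) {
  as.data.frame(lapply(COVARIATE_MARGINALS, function(m) {
    factor(sample(names(m), n, replace = TRUE, prob = m / sum(m)),
           levels = names(m))
  }), stringsAsFactors = TRUE)
}

#' Simulate one case
#'
#' Draws the case-level subclone pool (shared across blocks; per-block
#' territory layouts create between-block heterogeneity), the number of
#' blocks, covariates, and survival keyed to the true responder status
#' at the configured cutoff. Consumes the current RNG stream.
#'
#' @inheritParams simulate_block
#' @param case_id identifier.
#' @return list: `annotations` (list, possibly of NULLs), `truth_blocks`
#'   (data.frame), `case` (one-row data.frame with true_mtbr,
#'   true_responder, covariates and survival).
#' @export
simulate_case <- function(config, case_id = "case1", geometry = TRUE) {
  k <- sample(config$subclones_range[1]:config$subclones_range[2], 1L)
  theta <- stats::rbeta(1, config$resistance_beta[1], config$resistance_beta[2])
  pre <- stats::runif(k, config$pre_positivity_range[1], config$pre_positivity_range[2])
  subclones <- data.frame(
    pre_positivity = pre,
    survival = theta^(1 + config$prolif_sensitivity * pre))
  n_blocks <- sample(1:5, 1L, prob = config$blocks_per_case_prob)
  sims <- lapply(seq_len(n_blocks), function(b)
    simulate_block(subclones, config, case_id = case_id,
                   block_id = sprintf("b%d", b), geometry = geometry))
  truth <- do.call(rbind, lapply(sims, `[[`, "truth"))
  true_mtbr <- stats::median(truth$true_tbr)
  responder <- true_mtbr < config$responder_cutoff
  lambda <- log(2) / config$median_responder_os *
    if (responder) 1 else config$hazard_ratio
  t_death <- stats::rexp(1, lambda)
  t_cens <- min(stats::rexp(1, config$censor_rate), config$admin_censor_months)
  os_months <- max(min(t_death, t_cens), 0.03)
  os_event <- t_death <= t_cens
  tumor_death <- stats::runif(1) < config$tumor_death_prob
  case <- cbind(
    data.frame(case_id = case_id, true_mtbr = true_mtbr,
               true_responder = responder,
               os_months = os_months, os_event = os_event,
               tss_months = os_months, tss_event = os_event && tumor_death,
               stringsAsFactors = FALSE),
    draw_covariates(1L))
  list(annotations = lapply(sims, `[[`, "annotation"),
       truth_blocks = truth, case = case)
}

#' Simulate a cohort
#'
#' Seeded end-to-end generation: annotations (optional), ground-truth
#' block table and case table. Deterministic for a fixed
#' `config$seed`; when `dir` is given, the annotation GeoJSON files,
#' `cases.csv`, `ground_truth.csv` and a `config.json` echo are
#' written there (byte-identical across runs).
#'
#' @inheritParams simulate_case
#' @param dir optional output directory.
#' @return list: `annotations` (flat list), `truth_blocks`, `cases`.
#' @export
simulate_cohort <- function(config, dir = NULL, geometry = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  res <- with_seed(config$seed, {
    sims <- lapply(seq_len(config$n_cases), function(i)
      simulate_case(config, case_id = sprintf("case%03d", i), geometry = geometry))
    list(annotations = unlist(lapply(sims, `[[`, "annotations"), recursive = FALSE),
         truth_blocks = do.call(rbind, lapply(sims, `[[`, "truth_blocks")),
         cases = do.call(rbind, lapply(sims, `[[`, "case")))
  })
  res$annotations <- Filter(Negate(is.null), res$annotations)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (ann in res$annotations)
      write_annotation(ann, file.path(dir, sprintf("%s_%s.geojson",
                                                   ann$case_id, ann$block_id)))
    utils::write.csv(res$cases, file.path(dir, "cases.csv"), row.names = FALSE)
    utils::write.csv(res$truth_blocks, file.path(dir, "ground_truth.csv"),
                     row.names = FALSE)
    cfg <- config; class(cfg) <- NULL
    writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA),
               file.path(dir, "config.json"))
  }
  res
}
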
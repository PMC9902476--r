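#' Ki67 proliferation index of one delineated region
#'
#' PI = 100 x (red dots / all dots) within a delineated polygon. At
#' least 100 counted tumor cells are required for a region to be
#' evaluable; regions below that threshold are *not evaluable*, which is
#' distinct from a PI of 0. More than 500 dots triggers a warning (the
#' 500-cell cap is a manual-counting constraint, not a statistical one)
#' but all dots are used.
#'
#' @param positive logical vector, one element per counted cell
#'   (`TRUE` = Ki67-positive).
#' @param min_cells minimum cells for evaluability (default 100).
#' @param soft_cap counting cap that triggers a warning (default 500).
#' @return PI in percent, in \[0, 100\]; not rounded.
#' @export
ki67_pi <- function(positive, min_cells = 100L, soft_cap = 500L) {
  n <- length(positive)
  if (n < min_cells)
    stop_not_evaluable(sprintf(
      "Ki67 PI not evaluable: %d cells counted, minimum is %d", n, min_cells))
  if (n > soft_cap)
    warning(sprintf("%d cells counted exceeds the %d-cell counting cap; using all",
                    n, soft_cap))
  100 * sum(positive) / n
}

#' Derive KiH / KiL / KiD from region PIs
#'
#' KiH is the maximum and KiL the minimum evaluable region PI of a
#' slide; KiD = KiH - KiL is the heterogeneity span. When the tumor
#' mass suffices for a single PI only, that value is reported as KiH
#' with KiL and KiD missing; with no evaluable PI all three are missing.
#'
#' @param pis numeric vector of region PIs; `NA` = not evaluable.
#' @return list with `kih`, `kil`, `kid` (each may be `NA`).
#' @export
classify_block_pis <- function(pis) {
  p <- pis[!is.na(pis)]
  if (length(p) == 0L) return(list(kih = NA_real_, kil = NA_real_, kid = NA_real_))
  if (length(p) == 1L) return(list(kih = p[[1]], kil = NA_real_, kid = NA_real_))
  list(kih = max(p), kil = min(p), kid = max(p) - min(p))
}

#' Tumor bed ratio of one block
#'
#' TBR = 100 x residual pan-cytokeratin-positive tumor area / former
#' tumor-bed area. Values marginally above 100 (annotation slop) are
#' clipped to 100 with a warning.
#'
#' @param residual_area,bed_area areas in consistent units (um^2).
#' @return TBR in percent, in \[0, 100\].
#' @export
tumor_bed_ratio <- function(residual_area, bed_area) {
  if (!is.finite(bed_area) || bed_area <= 0)
    stop("invalid annotation: tumor bed area must be positive")
  if (!is.finite(residual_area) || residual_area < 0)
    stop("invalid annotation: residual tumor area must be nonnegative")
  tbr <- 100 * residual_area / bed_area
  if (tbr > 100) {
    warning(sprintf("TBR %.2f%% > 100%% clipped to 100 (annotation slop)", tbr))
    tbr <- 100
  }
  tbr
}

#' Block inclusion rule
#'
#' A slide enters the study iff at least 50 tumor cells were counted on
#' the pan-cytokeratin screening slide.
#'
#' @param pck_tumor_cell_count nonnegative integer (vectorized).
#' @return logical.
#' @export
block_inclusion <- function(pck_tumor_cell_count) {
  stopifnot(all(pck_tumor_cell_count >= 0))
  pck_tumor_cell_count >= 50
}

#' Becker tumor regression grade
#'
#' Maps the percentage of residual vital tumor to the Becker grade:
#' 1a = complete regression (exactly 0%), 1b = below 10%, 2 = 10-50%
#' (both bounds included), 3 = above 50%.
#'
#' @param residual_pct residual vital tumor in percent, in \[0, 100\]
#'   (vectorized); typically a TBR or case mTBR.
#' @return factor with ordered levels `1a < 1b < 2 < 3`.
#' @export
becker_trg <- function(residual_pct) {
  x <- as.numeric(residual_pct)
  bad <- !is.na(x) & (x < 0 | x > 100)
  if (any(bad)) stop("residual percentage out of [0, 100]")
  g <- ifelse(is.na(x), NA_character_,
       ifelse(x == 0, "1a",
       ifelse(x < 10, "1b",
       ifelse(x <= 50, "2", "3"))))
  factor(g, levels = c("1a", "1b", "2", "3"), ordered = TRUE)
}

#' Automatic hotspot / coldspot selection on a cell point pattern
#'
#' Emulates the pathologist's delineation on simulated slides: over
#' circular windows centered on marks and containing each center's
#' `window_cells` nearest marks, picks the windows with the highest and
#' lowest Ki67-positive fraction. Ties break to the lowest center index.
#' With many marks, centers may be thinned to an even index-spaced
#' subset (`max_centers`) for speed; thinning is deterministic.
#'
#' @param marks data.frame from [cell_marks()].
#' @param window_cells cells per window (default 500, the counting cap).
#' @param max_centers maximum candidate centers (default 200).
#' @return list with `hotspot` and `coldspot` [polygon_region()]s
#'   (circle approximations), and `hot_pi`, `cold_pi`, `hot_center`,
#'   `cold_center`.
#' @export
select_extreme_regions <- function(marks, window_cells = 500L, max_centers = 200L) {
  n <- nrow(marks)
  if (n < 2L * window_cells)
    stop_not_evaluable(sprintf(
      "hot/cold-spot selection needs >= %d marks, got %d", 2L * window_cells, n))
  centers <- if (n > max_centers)
    unique(round(seq(1L, n, length.out = max_centers))) else seq_len(n)
  best <- list(hi = -Inf, hi_i = NA, hi_r = NA, lo = Inf, lo_i = NA, lo_r = NA)
  x <- marks$x; y <- marks$y; pos <- marks$positive
  for (i in centers) {
    d2 <- (x - x[i])^2 + (y - y[i])^2
    # partial sort; exact distance ties (measure zero for continuous
    # coordinates) fall back to lowest mark index
    th <- sort(d2, partial = window_cells)[window_cells]
    ord <- which(d2 <= th)
    if (length(ord) > window_cells)
      ord <- ord[order(d2[ord], ord)][seq_len(window_cells)]
    frac <- mean(pos[ord])
    r <- sqrt(max(d2[ord]))
    if (frac > best$hi) { best$hi <- frac; best$hi_i <- i; best$hi_r <- r }
    if (frac < best$lo) { best$lo <- frac; best$lo_i <- i; best$lo_r <- r }
  }
  circle <- function(cx, cy, r, role) {
    th <- seq(0, 2 * pi, length.out = 49L)[-49L]
    rr <- r / cos(pi / 48) + 1e-9  # circumscribed polygon contains the disc
    polygon_region(cbind(cx + rr * cos(th), cy + rr * sin(th)),
                   "ki67_region", role = role, check = FALSE)
  }
  list(hotspot = circle(x[best$hi_i], y[best$hi_i], best$hi_r, "hotspot"),
       coldspot = circle(x[best$lo_i], y[best$lo_i], best$lo_r, "coldspot"),
       hot_pi = 100 * best$hi, cold_pi = 100 * best$lo,
       hot_center = c(x[best$hi_i], y[best$hi_i]),
       cold_center = c(x[best$lo_i], y[best$lo_i]))
}

#' Score one annotated block
#'
#' Computes the full per-block metric set: tumor bed ratio from the
#' tumor-bed and residual-tumor polygon areas, KiH/KiL/KiD from the
#' delineated Ki67 regions (or, absent those, from automatic
#' hotspot/coldspot selection; with 100 to 2 x `window_cells` marks a
#' single whole-slide PI is reported as KiH), and the 50-cell inclusion
#' flag.
#'
#' @param ann a [block_annotation()].
#' @param window_cells window size for automatic region selection.
#' @param min_cells minimum cells per evaluable PI.
#' @return one-row data.frame: case_id, block_id, included, tbr, kih,
#'   kil, kid, n_cells_hot, n_cells_cold, residual_area_um2,
#'   bed_area_um2.
#' @export
score_block <- function(ann, window_cells = 500L, min_cells = 100L) {
  stopifnot(inherits(ann, "block_annotation"))
  labs <- vapply(ann$regions, function(r) r$label, character(1))
  px <- ann$pixel_size_um
  area_of <- function(lab) {
    ix <- which(labs == lab)
    if (!length(ix)) 0 else sum(vapply(ann$regions[ix], polygon_area,
                                       numeric(1), pixel_size_um = px))
  }
  bed_area <- area_of("tumor_bed")
  residual_area <- area_of("residual_tumor")
  tbr <- tumor_bed_ratio(residual_area, bed_area)

  kregs <- ann$regions[labs == "ki67_region"]
  n_hot <- n_cold <- NA_integer_
  if (length(kregs)) {
    assign <- assign_marks_to_regions(ann$marks, kregs)
    pis <- vapply(assign, function(ix) eval_or_na(ki67_pi(ann$marks$positive[ix],
                                                          min_cells = min_cells)),
                  numeric(1))
    roles <- vapply(kregs, function(r) r$role %||% "", character(1))
    if (any(roles == "hotspot")) n_hot <- length(assign[[which(roles == "hotspot")[1]]])
    if (any(roles == "coldspot")) n_cold <- length(assign[[which(roles == "coldspot")[1]]])
    cls <- classify_block_pis(pis)
  } else if (nrow(ann$marks) >= 2L * window_cells) {
    sel <- select_extreme_regions(ann$marks, window_cells = window_cells)
    cls <- list(kih = sel$hot_pi, kil = sel$cold_pi, kid = sel$hot_pi - sel$cold_pi)
    n_hot <- n_cold <- as.integer(window_cells)
  } else if (nrow(ann$marks) >= min_cells) {
    # tumor mass sufficient for one PI only: report it as KiH
    cls <- list(kih = ki67_pi(ann$marks$positive, min_cells = min_cells,
                              soft_cap = Inf),
                kil = NA_real_, kid = NA_real_)
    n_hot <- nrow(ann$marks); n_cold <- NA_integer_
  } else {
    cls <- list(kih = NA_real_, kil = NA_real_, kid = NA_real_)
  }
  data.frame(case_id = ann$case_id, block_id = ann$block_id,
             included = block_inclusion(ann$pck_tumor_cell_count),
             tbr = tbr, kih = cls$kih, kil = cls$kil, kid = cls$kid,
             n_cells_hot = n_hot, n_cells_cold = n_cold,
             residual_area_um2 = residual_area, bed_area_um2 = bed_area,
             stringsAsFactors = FALSE)
}

#' Score a set of annotations
#'
#' @param anns list of [block_annotation()]s, or a directory containing
#'   `.geojson` annotation files.
#' @inheritParams score_block
#' @return data.frame of per-block metrics (one row per block).
#' @export
score_blocks <- function(anns, window_cells = 500L, min_cells = 100L) {
  if (is.character(anns)) {
    paths <- sort(list.files(anns, pattern = "\\.geojson$", full.names = TRUE))
    anns <- lapply(paths, read_annotation)
  }
  do.call(rbind, lapply(anns, score_block, window_cells = window_cells,
                        min_cells = min_cells))
}
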
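#' Slide-annotation geometry
#'
#' Annotations live in the pixel coordinate frame of the digitalized
#' whole-mount tissue section (0-based pixel units, default pixel pitch
#' 0.26 um). A region is a simple closed polygon with a semantic label;
#' cell marks are classified points (Ki67-positive / Ki67-negative).
#'
#' @name geometry
NULL

REGION_LABELS <- c("tumor_bed", "residual_tumor", "ki67_region")
REGION_ROLES  <- c("hotspot", "coldspot")

as_vertex_matrix <- function(vertices) {
  v <- as.matrix(vertices)
  storage.mode(v) <- "double"
  if (ncol(v) != 2L) stop("vertices must be an n x 2 matrix")
  v
}

# segment intersection test used by the simplicity check; proper crossings only
segments_cross <- function(p1, p2, q1, q2) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(q1, q2, p1); d2 <- d(q1, q2, p2)
  d3 <- d(p1, p2, q1); d4 <- d(p1, p2, q2)
  (d1 * d2 < 0) && (d3 * d4 < 0)
}

is_simple_polygon <- function(v) {
  n <- nrow(v)
  if (n < 3L) return(FALSE)
  idx <- function(i) ((i - 1L) %% n) + 1L
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i + 1L || (i == 1L && j == n)) next
      if (segments_cross(v[i, ], v[idx(i + 1L), ], v[j, ], v[idx(j + 1L), ]))
        return(FALSE)
    }
  }
  TRUE
}

#' Construct a polygon region
#'
#' @param vertices numeric n x 2 matrix of pixel coordinates; closed ring
#'   stored open (first vertex not repeated).
#' @param label one of `"tumor_bed"`, `"residual_tumor"`, `"ki67_region"`.
#' @param role for `ki67_region` polygons, optionally `"hotspot"` or
#'   `"coldspot"`.
#' @param check if `TRUE` (default) reject self-intersecting rings.
#' @return an object of class `polygon_region`.
#' @export
polygon_region <- function(vertices, label, role = NULL, check = TRUE) {
  v <- as_vertex_matrix(vertices)
  if (nrow(v) < 3L) stop("invalid polygon: fewer than 3 vertices")
  if (any(!is.finite(v))) stop("invalid polygon: non-finite vertex coordinates")
  label <- match.arg(label, REGION_LABELS)
  if (!is.null(role)) role <- match.arg(role, REGION_ROLES)
  if (check && !is_simple_polygon(v))
    stop("invalid polygon: self-intersecting ring")
  structure(list(vertices = v, label = label, role = role),
            class = "polygon_region")
}

#' Polygon area by the shoelace formula
#'
#' @param region a [polygon_region()] or a bare n x 2 vertex matrix.
#' @param pixel_size_um physical pixel pitch; the result is in um^2
#'   (`pixel_size_um = 1` gives pixel^2).
#' @return nonnegative area, orientation-independent.
#' @export
polygon_area <- function(region, pixel_size_um = 1) {
  v <- if (inherits(region, "polygon_region")) region$vertices else as_vertex_matrix(region)
  if (nrow(v) < 3L) stop("invalid polygon: fewer than 3 vertices")
  x <- v[, 1]; y <- v[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  abs(sum(x * ys - xs * y)) / 2 * pixel_size_um^2
}

#' Point-in-polygon test (even-odd rule, boundary counts as inside)
#'
#' Vectorized over points. Points on an edge or vertex are classified
#' inside: dots placed exactly on the drawn line belong to the region.
#'
#' @param x,y point coordinates (equal-length vectors).
#' @param region a [polygon_region()] or vertex matrix.
#' @param tol absolute tolerance for the boundary test.
#' @return logical vector.
#' @export
point_in_polygon <- function(x, y, region, tol = 1e-9) {
  v <- if (inherits(region, "polygon_region")) region$vertices else as_vertex_matrix(region)
  n <- nrow(v)
  if (n < 3L) stop("invalid polygon: fewer than 3 vertices")
  inside <- logical(length(x))
  xi <- v[, 1]; yi <- v[, 2]
  xj <- c(xi[n], xi[-n]); yj <- c(yi[n], yi[-n])
  for (k in seq_len(n)) {
    x1 <- xj[k]; y1 <- yj[k]; x2 <- xi[k]; y2 <- yi[k]
    # even-odd ray cast (horizontal ray to +infinity)
    crosses <- ((y1 > y) != (y2 > y)) &
      (x < (x2 - x1) * (y - y1) / (y2 - y1) + x1)
    inside <- xor(inside, crosses)
  }
  # boundary pass only for points the ray cast called outside and that
  # lie inside the (tol-expanded) bounding box
  cand <- which(!inside &
                  x >= min(xi) - tol & x <= max(xi) + tol &
                  y >= min(yi) - tol & y <= max(yi) + tol)
  if (length(cand)) {
    cx <- x[cand]; cy <- y[cand]
    boundary <- logical(length(cand))
    for (k in seq_len(n)) {
      x1 <- xj[k]; y1 <- yj[k]; x2 <- xi[k]; y2 <- yi[k]
      dx <- x2 - x1; dy <- y2 - y1
      len2 <- dx * dx + dy * dy
      t <- if (len2 > 0) pmin(1, pmax(0, ((cx - x1) * dx + (cy - y1) * dy) / len2)) else 0
      px <- x1 + t * dx; py <- y1 + t * dy
      boundary <- boundary | ((cx - px)^2 + (cy - py)^2 <= tol^2)
    }
    inside[cand[boundary]] <- TRUE
  }
  inside
}

#' Construct a classified cell mark table
#'
#' @param x,y coordinates; `positive` logical (Ki67-positive = red dot).
#' @return data.frame with columns x, y, positive.
#' @export
cell_marks <- function(x, y, positive) {
  stopifnot(length(x) == length(y), length(x) == length(positive))
  if (length(x) && any(!is.finite(x) | !is.finite(y)))
    stop("cell marks must have finite coordinates")
  data.frame(x = as.numeric(x), y = as.numeric(y), positive = as.logical(positive))
}

#' Assign cell marks to Ki67 regions
#'
#' Each mark is assigned to every `ki67_region` polygon containing it
#' (boundary inclusive); marks outside all regions are ignored. If
#' regions overlap, a warning is emitted and marks in the overlap are
#' counted in both regions.
#'
#' @param marks a data.frame as returned by [cell_marks()].
#' @param regions list of [polygon_region()] objects; non-`ki67_region`
#'   entries are skipped.
#' @return named list (one element per ki67 region, in input order) of
#'   integer index vectors into `marks`.
#' @export
assign_marks_to_regions <- function(marks, regions) {
  kregs <- Filter(function(r) r$label == "ki67_region", regions)
  if (!length(kregs)) return(list())
  out <- vector("list", length(kregs))
  names(out) <- vapply(seq_along(kregs), function(i)
    kregs[[i]]$role %||% paste0("region", i), character(1))
  hit <- integer(nrow(marks))
  for (i in seq_along(kregs)) {
    idx <- integer(0)
    if (nrow(marks)) {
      v <- kregs[[i]]$vertices  # bbox prefilter before the exact test
      cand <- which(marks$x >= min(v[, 1]) & marks$x <= max(v[, 1]) &
                      marks$y >= min(v[, 2]) & marks$y <= max(v[, 2]))
      if (length(cand))
        idx <- cand[point_in_polygon(marks$x[cand], marks$y[cand], kregs[[i]])]
    }
    out[[i]] <- idx
    hit[idx] <- hit[idx] + 1L
  }
  if (any(hit > 1L))
    warning(sum(hit > 1L), " mark(s) fall in overlapping ki67 regions; counted in each")
  out
}

#' Construct a block annotation
#'
#' One annotated paraffin block / whole-mount tissue section: the former
#' tumor bed and residual tumor outlines, delineated Ki67 regions, the
#' classified cell marks, and the pan-cytokeratin screening cell count
#' used by the 50-cell inclusion rule.
#'
#' @param case_id,block_id nonempty identifiers.
#' @param regions list of [polygon_region()] objects; multi-part tumor
#'   bed / residual tumor sets are allowed (several polygons sharing a
#'   label, summed by area).
#' @param marks data.frame from [cell_marks()].
#' @param pck_tumor_cell_count nonnegative integer.
#' @param pixel_size_um physical pixel pitch in um (scanner default 0.26).
#' @return object of class `block_annotation`.
#' @export
block_annotation <- function(case_id, block_id, regions = list(),
                             marks = cell_marks(numeric(0), numeric(0), logical(0)),
                             pck_tumor_cell_count = 0L,
                             pixel_size_um = 0.26) {
  stopifnot(is.character(case_id), nzchar(case_id),
            is.character(block_id), nzchar(block_id),
            pixel_size_um > 0, pck_tumor_cell_count >= 0)
  labs <- vapply(regions, function(r) r$label, character(1))
  if (length(labs)) stopifnot(all(labs %in% REGION_LABELS))
  structure(list(case_id = case_id, block_id = block_id,
                 pixel_size_um = pixel_size_um, regions = regions,
                 marks = marks,
                 pck_tumor_cell_count = as.integer(pck_tumor_cell_count)),
            class = "block_annotation")
}

#' @export
print.block_annotation <- function(x, ...) {
  labs <- vapply(x$regions, function(r) r$label, character(1))
  cat(sprintf("<block_annotation %s/%s: %d region(s) [%s], %d mark(s), PCK count %d>\n",
              x$case_id, x$block_id, length(x$regions),
              paste(unique(labs), collapse = ","), nrow(x$marks),
              x$pck_tumor_cell_count))
  invisible(x)
}
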
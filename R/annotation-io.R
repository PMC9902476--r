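#' Read and write block annotations as GeoJSON
#'
#' One file per block: a `FeatureCollection` whose Polygon features carry
#' `properties$label` (`tumor_bed` / `residual_tumor` / `ki67_region`,
#' the latter optionally with `properties$role` hotspot/coldspot) and
#' whose Point features carry `properties$mark`
#' (`ki67_pos` / `ki67_neg`). Block metadata travel as top-level foreign
#' members: `case_id`, `block_id`, `pixel_size_um`,
#' `pck_tumor_cell_count`. Write-then-read is the identity on all
#' fields.
#'
#' @param ann a [block_annotation()].
#' @param path file path (`.geojson`).
#' @return `read_annotation()` returns a [block_annotation()];
#'   `write_annotation()` returns `path` invisibly.
#' @export
write_annotation <- function(ann, path) {
  stopifnot(inherits(ann, "block_annotation"))
  feat_poly <- lapply(ann$regions, function(r) {
    ring <- rbind(r$vertices, r$vertices[1, , drop = FALSE])  # GeoJSON closes rings
    list(type = "Feature",
         geometry = list(type = "Polygon",
                         coordinates = list(unname(split(ring, row(ring)[, 1])))),
         properties = list(label = r$label, role = r$role))
  })
  feat_pt <- if (nrow(ann$marks)) lapply(seq_len(nrow(ann$marks)), function(i) {
    list(type = "Feature",
         geometry = list(type = "Point",
                         coordinates = c(ann$marks$x[i], ann$marks$y[i])),
         properties = list(mark = if (ann$marks$positive[i]) "ki67_pos" else "ki67_neg"))
  }) else list()
  obj <- list(type = "FeatureCollection",
              case_id = ann$case_id, block_id = ann$block_id,
              pixel_size_um = ann$pixel_size_um,
              pck_tumor_cell_count = ann$pck_tumor_cell_count,
              features = c(feat_poly, feat_pt))
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null",
                           pretty = FALSE)
  writeLines(json, path)
  invisible(path)
}

#' @rdname write_annotation
#' @export
read_annotation <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(obj$type, "FeatureCollection"))
    stop("annotation parse error: not a GeoJSON FeatureCollection")
  for (fld in c("case_id", "block_id", "pixel_size_um", "pck_tumor_cell_count"))
    if (is.null(obj[[fld]]))
      stop("annotation parse error: foreign member '", fld, "' missing")
  regions <- list()
  xs <- ys <- numeric(0); pos <- logical(0)
  for (f in obj$features) {
    g <- f$geometry
    if (identical(g$type, "Polygon")) {
      ring <- do.call(rbind, lapply(g$coordinates[[1]], function(p) unlist(p)[1:2]))
      if (nrow(ring) > 1 && all(ring[1, ] == ring[nrow(ring), ]))
        ring <- ring[-nrow(ring), , drop = FALSE]
      lab <- f$properties$label
      if (is.null(lab) || !lab %in% REGION_LABELS)
        stop("annotation parse error: polygon with missing/unknown label")
      regions[[length(regions) + 1L]] <-
        polygon_region(ring, lab, role = f$properties$role)
    } else if (identical(g$type, "Point")) {
      mk <- f$properties$mark
      if (is.null(mk) || !mk %in% c("ki67_pos", "ki67_neg"))
        stop("annotation parse error: point with missing/unknown mark")
      co <- unlist(g$coordinates)
      xs <- c(xs, co[1]); ys <- c(ys, co[2]); pos <- c(pos, mk == "ki67_pos")
    } else stop("annotation parse error: unsupported geometry type ", g$type)
  }
  labs <- vapply(regions, function(r) r$label, character(1))
  if (!any(labs == "tumor_bed"))
    stop("annotation parse error: tumor_bed missing")
  block_annotation(case_id = obj$case_id, block_id = obj$block_id,
                   regions = regions, marks = cell_marks(xs, ys, pos),
                   pck_tumor_cell_count = obj$pck_tumor_cell_count,
                   pixel_size_um = obj$pixel_size_um)
}
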
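#' Detect inflammatory cell clusters (alpha-shape regions of interest)
#'
#' Computes the alpha-shape over all annotated cell x-y positions with a
#' tuned alpha (default 0.1 per micrometre, i.e. triangles with circumradius
#' above 10 micrometres are discarded); every disjoint region of the
#' resulting complex is a candidate cluster. Membership is every cell lying
#' inside or on the region; candidates with fewer than `min_cells` members
#' (default 15, the minimum cluster size seen in inflamed but not healthy
#' tissue) are removed. Survivors carry their polygon, area, member cells,
#' per-label composition and centroid (unweighted mean of member
#' coordinates). Cells in no surviving region are unclustered; a cell on a
#' boundary shared by two regions joins the lower region id.
#'
#' @param table a [cell_table()].
#' @param annotation an `annotation` aligned with `table`.
#' @param alpha alpha parameter (1/micrometres).
#' @param min_cells minimum member count for a retained cluster.
#' @return An object of class `alpha_roi_set`: list of clusters (each with
#'   `roi_id`, `polygon`, `area`, `member_cell_ids`, `n_cells`,
#'   `composition`, `center`) plus the underlying `shape` and the
#'   `unclustered` cell ids.
#' @export
detect_alpha_rois <- function(table, annotation, alpha = 0.1, min_cells = 15) {
  stopifnot(inherits(table, "cell_table"), inherits(annotation, "annotation"),
            min_cells >= 1)
  if (!identical(annotation$cell_id, table$cells$cell_id)) {
    ps_stop("annotation is not aligned with the cell table")
  }
  if (n_cells(table) < 3) ps_stop("need at least 3 cells to detect clusters")
  xy <- as.matrix(table$cells[, c("x", "y")])
  shape <- suppressWarnings(alpha_shape(xy, alpha = alpha))
  rois <- list()
  if (shape$n_components > 0) {
    comp <- locate_points(shape, xy)
    keep <- which(tabulate(comp, nbins = shape$n_components) >= min_cells)
    for (k in seq_along(keep)) {
      cidx <- keep[k]
      members <- which(!is.na(comp) & comp == cidx)
      polys <- Filter(function(p) p$component == cidx, shape$polygons)
      counts <- table(annotation$label[members])
      rois[[k]] <- list(
        roi_id = k,
        polygon = polys,
        area = shape$component_areas[cidx],
        member_cell_ids = table$cells$cell_id[members],
        n_cells = length(members),
        composition = data.frame(label = names(counts),
                                 count = as.integer(counts),
                                 proportion = as.integer(counts) / length(members),
                                 stringsAsFactors = FALSE),
        center = c(x = mean(xy[members, 1]), y = mean(xy[members, 2]))
      )
    }
  }
  clustered <- unlist(lapply(rois, `[[`, "member_cell_ids"))
  structure(list(rois = rois, shape = shape,
                 unclustered = setdiff(table$cells$cell_id, clustered),
                 alpha = alpha, min_cells = as.integer(min_cells),
                 sample_id = table$sample_id,
                 labels = attr(annotation, "labels")),
            class = "alpha_roi_set")
}

#' @export
print.alpha_roi_set <- function(x, ...) {
  cat(sprintf("<alpha_roi_set> sample '%s': %d cluster(s) (alpha = %g, min %d cells), %d unclustered cells\n",
              x$sample_id, length(x$rois), x$alpha, x$min_cells,
              length(x$unclustered)))
  for (r in x$rois) {
    cat(sprintf("  roi %d: %d cells, area %.1f um^2, center (%.1f, %.1f)\n",
                r$roi_id, r$n_cells, r$area, r$center[1], r$center[2]))
  }
  invisible(x)
}

#' Number of detected clusters
#' @param x an `alpha_roi_set`.
#' @return integer count.
#' @export
n_rois <- function(x) length(x$rois)

#' Summarise detected clusters for one sample
#'
#' Cluster count and density (per square millimetre of section area or per
#' cubic millimetre of imaged volume), together with one composition row per
#' cluster and label, suitable for cross-sample heatmaps.
#'
#' @param rois an [detect_alpha_rois()] result.
#' @param area_mm2 section area denominator (square millimetres).
#' @param volume_mm3 alternative volume denominator (cubic millimetres).
#'   Exactly one denominator must be supplied and positive.
#' @return list with `n_rois`, `density`, `denominator`, `per_roi`
#'   (id, area, n_cells, centroid) and `composition` (long table of
#'   proportions).
#' @export
roi_summary <- function(rois, area_mm2 = NULL, volume_mm3 = NULL) {
  stopifnot(inherits(rois, "alpha_roi_set"))
  if (is.null(area_mm2) == is.null(volume_mm3)) {
    ps_stop("supply exactly one of area_mm2 or volume_mm3")
  }
  denom <- if (is.null(area_mm2)) volume_mm3 else area_mm2
  if (denom <= 0) ps_stop("density denominator must be positive")
  per_roi <- do.call(rbind, lapply(rois$rois, function(r) {
    data.frame(roi_id = r$roi_id, area_um2 = r$area, n_cells = r$n_cells,
               center_x = r$center[1], center_y = r$center[2],
               row.names = NULL)
  }))
  comp <- do.call(rbind, lapply(rois$rois, function(r) {
    cbind(roi_id = r$roi_id, r$composition)
  }))
  list(n_rois = length(rois$rois),
       density = length(rois$rois) / denom,
       denominator = if (is.null(area_mm2)) "per_mm3" else "per_mm2",
       per_roi = per_roi,
       composition = comp)
}

#' Write a cluster table to CSV
#'
#' One row per cluster: id, area, member count, centroid, and one column per
#' label proportion over the annotation's label vocabulary.
#'
#' @param rois an `alpha_roi_set`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_roi_table <- function(rois, path) {
  stopifnot(inherits(rois, "alpha_roi_set"))
  labs <- rois$labels
  rows <- lapply(rois$rois, function(r) {
    props <- stats::setNames(rep(0, length(labs)), labs)
    hit <- r$composition$label %in% labs
    props[r$composition$label[hit]] <- r$composition$proportion[hit]
    cbind(data.frame(roi_id = r$roi_id, area_um2 = r$area,
                     n_cells = r$n_cells, center_x = r$center[1],
                     center_y = r$center[2], row.names = NULL),
          as.data.frame(as.list(props), check.names = FALSE))
  })
  out <- if (length(rows) > 0) do.call(rbind, rows) else {
    data.frame(roi_id = integer(0), area_um2 = numeric(0),
               n_cells = integer(0), center_x = numeric(0),
               center_y = numeric(0))
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
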
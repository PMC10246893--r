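#' Per-label cell densities
#'
#' Cell counts per label divided by the region-of-interest volume. The
#' default volume is the standard acquisition box, 0.6 x 0.4 x 0.02 mm =
#' 0.0048 mm^3. The "Other" sink label is kept in totals but excluded from
#' per-label densities unless explicitly requested.
#'
#' @param annotation an `annotation` object.
#' @param roi_volume_mm3 positive volume denominator (cubic millimetres).
#' @param labels labels to report (zero-count labels are reported as density
#'   0); defaults to the annotation's label vocabulary without "Other".
#' @return named numeric vector of densities (cells per cubic millimetre).
#' @export
cell_density <- function(annotation, roi_volume_mm3 = 0.0048, labels = NULL) {
  stopifnot(inherits(annotation, "annotation"))
  if (roi_volume_mm3 <= 0) ps_stop("roi_volume_mm3 must be positive")
  if (is.null(labels)) {
    labels <- setdiff(union(attr(annotation, "labels"),
                            unique(annotation$label)), "Other")
  }
  counts <- table(factor(annotation$label, levels = labels))
  stats::setNames(as.numeric(counts) / roi_volume_mm3, labels)
}

#' Mean distance to the epidermis per label
#'
#' Arithmetic mean of each cell's distance r to the epidermis model, grouped
#' by annotated label; labels with no cells are omitted.
#'
#' @param annotation an `annotation` object.
#' @param distances a `distance_table` from [distance_to_structure()] over
#'   the same cells.
#' @return data.frame with columns `label`, `n`, `mean_distance_um`.
#' @export
distance_summary <- function(annotation, distances) {
  stopifnot(inherits(annotation, "annotation"),
            inherits(distances, "distance_table"))
  if (!identical(annotation$cell_id, distances$cell_id)) {
    ps_stop("annotation and distance table are not aligned on cell_id")
  }
  sp <- split(distances$distance, annotation$label)
  data.frame(label = names(sp),
             n = lengths(sp),
             mean_distance_um = vapply(sp, mean, numeric(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Export the per-cell feature matrix for external embedding tools
#'
#' Writes (or returns) the per-cell MFI matrix plus the annotated label
#' column, the input consumed by off-the-shelf t-SNE / PCA / heatmap
#' tooling. No embedding is computed here.
#'
#' @param annotation an `annotation` object.
#' @param table the matching [cell_table()].
#' @param path optional output CSV path.
#' @return data.frame `cell_id` + one column per channel + `label`
#'   (invisibly when `path` is given).
#' @export
export_embedding_inputs <- function(annotation, table, path = NULL) {
  stopifnot(inherits(annotation, "annotation"), inherits(table, "cell_table"))
  if (!identical(annotation$cell_id, table$cells$cell_id)) {
    ps_stop("annotation is not aligned with the cell table")
  }
  out <- cbind(data.frame(cell_id = table$cells$cell_id),
               as.data.frame(table$mfi, check.names = FALSE),
               label = annotation$label)
  if (!is.null(path)) {
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
    return(invisible(out))
  }
  out
}

#' Sample-level summary
#'
#' Collects the per-label counts, densities and mean epidermis distances and
#' the cluster count/density for one sample into a single object.
#'
#' @param annotation an `annotation` object.
#' @param roi_volume_mm3 imaged-box volume (cubic millimetres).
#' @param distances optional `distance_table`.
#' @param rois optional `alpha_roi_set`.
#' @return A list of class `sample_summary`.
#' @export
sample_summary <- function(annotation, roi_volume_mm3 = 0.0048,
                           distances = NULL, rois = NULL) {
  stopifnot(inherits(annotation, "annotation"))
  if (roi_volume_mm3 <= 0) ps_stop("roi_volume_mm3 must be positive")
  labels <- setdiff(union(attr(annotation, "labels"),
                          unique(annotation$label)), "Other")
  counts <- table(factor(annotation$label, levels = labels))
  per_label <- data.frame(label = labels, count = as.integer(counts),
                          density_mm3 = as.integer(counts) / roi_volume_mm3,
                          stringsAsFactors = FALSE)
  if (!is.null(distances)) {
    ds <- distance_summary(annotation, distances)
    per_label$mean_distance_um <-
      ds$mean_distance_um[match(per_label$label, ds$label)]
  }
  out <- list(sample_id = attr(annotation, "sample_id"),
              roi_volume_mm3 = roi_volume_mm3,
              n_cells = nrow(annotation),
              n_other = sum(annotation$label == "Other"),
              per_label = per_label)
  if (!is.null(rois)) {
    out$n_rois <- n_rois(rois)
    out$roi_density_mm3 <- n_rois(rois) / roi_volume_mm3
  }
  structure(out, class = "sample_summary")
}

#' @export
print.sample_summary <- function(x, ...) {
  cat(sprintf("<sample_summary> sample '%s': %d cells (%d Other) in %.4f mm^3\n",
              x$sample_id, x$n_cells, x$n_other, x$roi_volume_mm3))
  print(x$per_label, row.names = FALSE)
  if (!is.null(x$n_rois)) {
    cat(sprintf("  clusters: %d (%.1f per mm^3)\n", x$n_rois,
                x$roi_density_mm3))
  }
  invisible(x)
}
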
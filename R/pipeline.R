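#' Run the full phenotyping pipeline on one sample
#'
#' Convenience wrapper tying the stages together: dynamic matrix adaptation,
#' Spearman annotation, activation splitting, cluster detection, optional
#' epidermis distances, and the sample summary.
#'
#' @param table a [cell_table()].
#' @param panel an [attribution_matrix()].
#' @param config a [run_config()].
#' @param contour optional epidermis vertex matrix (or path readable by
#'   [read_epidermis_contour()]).
#' @param activation an [activation_config()]; the default picks the
#'   panel's own targets for the packaged panels. `NULL` skips the split.
#' @param roi_volume_mm3 density denominator.
#' @return An object of class `phenoshape_run` with elements `table`,
#'   `annotation`, `rois`, `distances` (or NULL), `epidermis` (or NULL) and
#'   `summary`.
#' @export
run_sample <- function(table, panel, config = run_config(), contour = NULL,
                       activation = NULL,
                       roi_volume_mm3 = 0.0048) {
  stopifnot(inherits(table, "cell_table"), inherits(panel, "attribution_matrix"),
            inherits(config, "run_config"))
  if (is.null(activation) && !missing(activation)) {
    # explicit NULL: skip the split
  } else if (is.null(activation)) {
    tg <- if (panel$panel_name %in% c("lymphoid", "myeloid")) {
      default_activation_targets(panel$panel_name)
    } else {
      default_activation_targets("both")
    }
    activation <- activation_config(tg[tg$label %in% unique(panel$labels), ,
                                       drop = FALSE])
  }
  check <- validate_panel(table, panel)
  if (!check$ok) {
    ps_stop("panel markers missing from the cell table: %s",
            paste(check$missing_in_table, collapse = ", "))
  }
  ann <- annotate_cells(table, adapt_matrix(panel, table))
  if (!is.null(activation)) {
    ann <- split_activation(ann, table, activation)
  }
  distances <- NULL
  model <- NULL
  if (!is.null(contour)) {
    if (is.character(contour)) contour <- read_epidermis_contour(contour)
    model <- build_epidermis_model(contour, alpha = config$alpha_epidermis)
    distances <- distance_to_structure(table, model)
  }
  rois <- detect_alpha_rois(table, ann, alpha = config$alpha_roi,
                            min_cells = config$min_roi_cells)
  structure(list(table = table, annotation = ann, rois = rois,
                 distances = distances, epidermis = model,
                 summary = sample_summary(ann, roi_volume_mm3,
                                          distances = distances, rois = rois),
                 config = config),
            class = "phenoshape_run")
}

#' @export
print.phenoshape_run <- function(x, ...) {
  print(x$summary)
  invisible(x)
}

#' @export
summary.phenoshape_run <- function(object, ...) object$summary

#' Digital map of an annotated sample
#'
#' Plots cell positions coloured by label, overlaying cluster polygons and
#' the epidermis outline when available.
#'
#' @param x a `phenoshape_run`.
#' @param ... passed to [plot()].
#' @export
plot.phenoshape_run <- function(x, ...) {
  xy <- x$table$cells[, c("x", "y")]
  labs <- factor(x$annotation$label)
  pal <- grDevices::hcl.colors(max(3, nlevels(labs)), "Dark 3")
  plot(xy, col = pal[as.integer(labs)], pch = 16, cex = 0.6, asp = 1,
       xlab = "x (um)", ylab = "y (um)",
       main = sprintf("sample '%s'", x$table$sample_id), ...)
  if (!is.null(x$epidermis)) {
    for (p in x$epidermis$shape$polygons) {
      graphics::polygon(p$vertices, border = "grey40", lwd = 2)
    }
  }
  for (r in x$rois$rois) {
    for (p in r$polygon) graphics::polygon(p$vertices, border = "red", lwd = 2)
  }
  graphics::legend("topright", legend = levels(labs), col = pal[seq_len(nlevels(labs))],
                   pch = 16, cex = 0.6, bg = "white")
  invisible(x)
}
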
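#' Positivity threshold at the first peak of an MFI density curve
#'
#' Estimates a Gaussian kernel density (Silverman's rule-of-thumb bandwidth
#' by default) on an evenly spaced grid spanning the observed MFI range and
#' returns the grid location of the first local maximum scanning from low
#' MFI. Cells with MFI strictly above this value are considered positive for
#' the marker. A monotone-decreasing curve peaks at the first grid point; a
#' monotone-increasing one at the last.
#'
#' @param values non-negative MFI vector (at least 10 values with nonzero
#'   spread).
#' @param grid_points number of KDE grid points (default 512).
#' @param bandwidth bandwidth rule or numeric bandwidth passed to
#'   [stats::density()] (default "nrd0", Silverman's rule).
#' @return The threshold MFI (numeric scalar) with attributes `bandwidth`
#'   and `n`.
#' @export
activation_threshold <- function(values, grid_points = 512,
                                 bandwidth = "nrd0") {
  values <- values[!is.na(values)]
  if (length(values) < 10) {
    ps_stop("population too small to threshold (%d values, need >= 10)",
            length(values))
  }
  if (max(values) == min(values)) {
    ps_stop("zero spread: cannot estimate a density curve")
  }
  d <- stats::density(values, bw = bandwidth, kernel = "gaussian",
                      n = grid_points, from = min(values), to = max(values))
  y <- d$y
  k <- length(y)
  peaks <- which(y[-c(1, k)] > y[-c(k - 1, k)] & y[-c(1, k)] > y[-c(1, 2)]) + 1L
  if (y[1] > y[2]) peaks <- c(1L, peaks)
  first <- if (length(peaks) > 0) peaks[1] else which.max(y)
  structure(d$x[first], bandwidth = d$bw, n = length(values))
}

#' Activation-split configuration
#'
#' Which populations get a low/high split on which activation marker, and the
#' KDE settings used to derive the per-population threshold.
#'
#' @param targets data.frame with columns `label`, `marker`; defaults to the
#'   packaged targets of both panels (CD57 on CD4/CD8 T cells, HLA-DR on dDC,
#'   LC and CD207+ dDC).
#' @param grid_points KDE grid points (>= 64).
#' @param bandwidth KDE bandwidth rule.
#' @param min_population smallest population that is split; smaller target
#'   populations are left unsplit with a warning.
#' @return A list of class `activation_config`.
#' @export
activation_config <- function(targets = default_activation_targets("both"),
                              grid_points = 512, bandwidth = "nrd0",
                              min_population = 10) {
  stopifnot(is.data.frame(targets),
            all(c("label", "marker") %in% names(targets)),
            grid_points >= 64)
  structure(list(targets = targets, grid_points = as.integer(grid_points),
                 bandwidth = bandwidth,
                 min_population = as.integer(min_population)),
            class = "activation_config")
}

#' Split target populations into activation-low/high variants
#'
#' For each configured (population, marker) target, the marker's MFI density
#' curve is computed within the annotated population and thresholded at its
#' first peak; member cells with MFI strictly above the threshold receive the
#' "high" variant label (e.g. "CD8 T CD57high"), the rest the "low" variant.
#' Non-target populations are untouched. Populations below the minimum size
#' or with degenerate MFI spread are left unsplit with a warning.
#'
#' @param annotation an `annotation` object.
#' @param table the [cell_table()] the annotation was computed from.
#' @param config an [activation_config()].
#' @return A new `annotation`; the per-population thresholds are attached as
#'   `attr(, "activation_thresholds")` (population, marker, threshold, n,
#'   bandwidth).
#' @export
split_activation <- function(annotation, table,
                             config = activation_config()) {
  stopifnot(inherits(annotation, "annotation"), inherits(table, "cell_table"),
            inherits(config, "activation_config"))
  if (!identical(annotation$cell_id, table$cells$cell_id)) {
    ps_stop("annotation is not aligned with the cell table")
  }
  label <- annotation$label
  vocab <- attr(annotation, "labels")
  report <- NULL
  for (i in seq_len(nrow(config$targets))) {
    pop <- config$targets$label[i]
    mk <- config$targets$marker[i]
    lo <- paste0(pop, " ", mk, "low")
    hi <- paste0(pop, " ", mk, "high")
    vocab <- c(setdiff(vocab, pop), lo, hi)
    idx <- which(label == pop)
    if (length(idx) == 0) next
    if (!mk %in% channels(table)) {
      ps_warn("activation marker '%s' absent from table; '%s' left unsplit",
              mk, pop)
      next
    }
    v <- table$mfi[idx, mk]
    if (length(idx) < config$min_population || max(v) == min(v)) {
      ps_warn("population '%s' too small or degenerate to split (n = %d)",
              pop, length(idx))
      next
    }
    thr <- activation_threshold(v, grid_points = config$grid_points,
                                bandwidth = config$bandwidth)
    label[idx] <- ifelse(v > as.numeric(thr), hi, lo)
    report <- rbind(report,
                    data.frame(population = pop, marker = mk,
                               threshold = as.numeric(thr), n = length(idx),
                               bandwidth = attr(thr, "bandwidth"),
                               stringsAsFactors = FALSE))
  }
  out <- new_annotation(annotation$cell_id, label, annotation$rho_best,
                        annotation$rho_runner_up, annotation$tied,
                        labels = unique(vocab),
                        sample_id = attr(annotation, "sample_id"),
                        method = attr(annotation, "method"))
  attr(out, "activation_thresholds") <- report
  out
}

#' Write the activation-threshold report to CSV
#' @param annotation an annotation produced by [split_activation()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_threshold_report <- function(annotation, path) {
  rep <- attr(annotation, "activation_thresholds")
  if (is.null(rep)) {
    rep <- data.frame(population = character(0), marker = character(0),
                      threshold = numeric(0), n = integer(0),
                      bandwidth = numeric(0))
  }
  utils::write.csv(rep, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' MFI z-scores within a population
#'
#' Descriptive standardisation of marker intensities across the supplied cell
#' set: `(value - mean) / sd`. Grouping (per sample, per population, cohort)
#' is left to the caller. The resulting scores have mean 0 and standard
#' deviation 1.
#'
#' @param values MFI vector (>= 2 values, nonzero spread).
#' @return numeric z-score vector.
#' @export
mfi_zscore <- function(values) {
  if (length(values) < 2) ps_stop("need at least 2 values for a z-score")
  s <- stats::sd(values)
  if (s == 0) ps_stop("zero standard deviation: z-scores undefined")
  (values - mean(values)) / s
}
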
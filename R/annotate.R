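#' Dynamically adapt an attribution matrix to a sample
#'
#' Acquisition parameters (laser power, gain) differ between samples, so the
#' binary reference table is rescaled per sample: every 1-entry of marker m is
#' replaced by the maximum MFI observed for m across the sample's cells;
#' 0-entries stay 0. Rank correlation against the adapted columns is then
#' comparable across samples.
#'
#' @param matrix an [attribution_matrix()].
#' @param table a [cell_table()]; its channels must cover the matrix markers.
#' @return An object of class `adapted_matrix` with elements `markers`,
#'   `labels`, `column_id`, `values` (numeric matrix markers x columns) and
#'   `max_mfi`.
#' @export
adapt_matrix <- function(matrix, table) {
  stopifnot(inherits(matrix, "attribution_matrix"), inherits(table, "cell_table"))
  if (n_cells(table) == 0) ps_stop("cannot adapt a matrix to an empty cell table")
  miss <- setdiff(matrix$markers, channels(table))
  if (length(miss) > 0) {
    ps_stop("matrix marker(s) absent from table channels: %s",
            paste(miss, collapse = ", "))
  }
  max_mfi <- apply(table$mfi[, matrix$markers, drop = FALSE], 2, max)
  zero <- max_mfi == 0 & rowSums(matrix$signatures) > 0
  if (any(zero)) {
    ps_warn("marker(s) with maximum MFI of 0, column(s) degenerate: %s",
            paste(matrix$markers[zero], collapse = ", "))
  }
  values <- matrix$signatures * max_mfi
  structure(
    list(markers = matrix$markers,
         labels = matrix$labels,
         column_id = matrix$column_id,
         values = values,
         max_mfi = max_mfi,
         panel_name = matrix$panel_name),
    class = "adapted_matrix"
  )
}

#' @export
print.adapted_matrix <- function(x, ...) {
  cat(sprintf("<adapted_matrix> panel '%s': %d markers, %d columns\n",
              x$panel_name, length(x$markers), ncol(x$values)))
  invisible(x)
}

#' Spearman rank correlation coefficient
#'
#' Spearman's rho with average ranks for ties. Returns `NA` (undefined) when
#' either vector is constant, rather than erroring: downstream annotation
#' treats undefined correlations as non-candidates.
#'
#' @param a,b numeric vectors of equal length (at least 2).
#' @return rho in \[-1, 1\], or `NA_real_` if undefined.
#' @export
spearman_rho <- function(a, b) {
  if (length(a) != length(b)) {
    ps_stop("vector length mismatch (%d vs %d)", length(a), length(b))
  }
  if (length(a) < 2) ps_stop("need at least 2 paired observations")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  unname(stats::cor(a, b, method = "spearman"))
}

# Column-standardised ranks: rank each column with average ties.
.rank_cols <- function(m) apply(m, 2, rank)

#' Annotate cells by rank correlation against an adapted matrix
#'
#' Each cell's MFI vector over the matrix's marker set is correlated
#' (Spearman, average-rank ties) against every adapted signature column. The
#' cell receives the label of the best-correlated column. Columns sharing a
#' label are optional-marker variants and compete as one candidate: the best
#' of a label's columns represents the label, and a tie between two columns
#' of the *same* label is not ambiguous. An exact tie (correlations equal
#' after rounding to 12 significant digits) between *different* labels, or an
#' all-undefined correlation profile (e.g. a constant MFI vector), assigns
#' the conservative sink label "Other".
#'
#' @param table a [cell_table()].
#' @param adapted an [adapt_matrix()] result.
#' @return An object of class `annotation`: a data.frame with columns
#'   `cell_id`, `label`, `rho_best`, `rho_runner_up`, `tied`, carrying the
#'   full label vocabulary in `attr(, "labels")`.
#' @export
annotate_cells <- function(table, adapted) {
  stopifnot(inherits(table, "cell_table"), inherits(adapted, "adapted_matrix"))
  miss <- setdiff(adapted$markers, channels(table))
  if (length(miss) > 0) {
    ps_stop("adapted marker(s) absent from table channels: %s",
            paste(miss, collapse = ", "))
  }
  X <- table$mfi[, adapted$markers, drop = FALSE]
  n <- nrow(X)
  # Spearman = Pearson on average ranks; rank cells (rows) and columns once.
  rx <- t(apply(X, 1, rank))              # n x m
  ry <- .rank_cols(adapted$values)        # m x k
  sdx <- apply(rx, 1, stats::sd)
  sdy <- apply(ry, 2, stats::sd)
  rho <- suppressWarnings(stats::cor(t(rx), ry))   # n x k, NaN where constant
  rho[, sdy == 0] <- NA_real_
  rho[sdx == 0, ] <- NA_real_
  rho[is.nan(rho)] <- NA_real_
  rho <- signif(rho, 12)

  labs <- adapted$labels
  ulabs <- unique(labs)
  # best column per label (optional-marker variants compete within the label)
  per_label <- matrix(NA_real_, n, length(ulabs),
                      dimnames = list(NULL, ulabs))
  for (j in seq_along(ulabs)) {
    cols <- which(labs == ulabs[j])
    per_label[, j] <- do.call(pmax, c(lapply(cols, function(cc) rho[, cc]),
                                      list(na.rm = TRUE)))
  }
  per_label[is.infinite(per_label)] <- NA_real_

  label <- character(n)
  rho_best <- rep(NA_real_, n)
  rho_runner <- rep(NA_real_, n)
  tied <- logical(n)
  for (i in seq_len(n)) {
    v <- per_label[i, ]
    if (all(is.na(v))) {
      label[i] <- "Other"
      next
    }
    best <- max(v, na.rm = TRUE)
    winners <- which(!is.na(v) & v == best)
    rho_best[i] <- best
    srt <- sort(v[!is.na(v)], decreasing = TRUE)
    if (length(srt) > 1) rho_runner[i] <- srt[2]
    if (length(winners) > 1) {
      tied[i] <- TRUE
      label[i] <- "Other"
    } else {
      label[i] <- ulabs[winners]
    }
  }
  new_annotation(table$cells$cell_id, label, rho_best, rho_runner, tied,
                 labels = ulabs, sample_id = table$sample_id,
                 method = "spearman")
}

new_annotation <- function(cell_id, label, rho_best, rho_runner_up, tied,
                           labels, sample_id, method) {
  out <- data.frame(cell_id = cell_id, label = label, rho_best = rho_best,
                    rho_runner_up = rho_runner_up, tied = tied,
                    stringsAsFactors = FALSE)
  structure(out, class = c("annotation", "data.frame"),
            labels = labels, sample_id = sample_id, method = method)
}

#' @export
print.annotation <- function(x, ...) {
  cat(sprintf("<annotation> sample '%s' (%s): %d cells\n",
              attr(x, "sample_id"), attr(x, "method"), nrow(x)))
  print(sort(table(x$label), decreasing = TRUE))
  invisible(x)
}

#' @export
summary.annotation <- function(object, ...) {
  tab <- table(factor(object$label,
                      levels = union(attr(object, "labels"),
                                     unique(object$label))))
  data.frame(label = names(tab), n = as.integer(tab),
             proportion = as.numeric(tab) / nrow(object),
             stringsAsFactors = FALSE)
}

#' Write an annotated cell table to CSV
#'
#' Appends the annotation columns (label, rho_best, tied, and the epidermis
#' distance when supplied) to the cell table export.
#'
#' @param table a [cell_table()].
#' @param annotation an `annotation` for the same cells.
#' @param path output CSV path.
#' @param distances optional `distance_table` aligned on `cell_id`; adds a
#'   `distance_to_epidermis_um` column.
#' @return `path`, invisibly.
#' @export
write_annotated_table <- function(table, annotation, path, distances = NULL) {
  stopifnot(inherits(table, "cell_table"), inherits(annotation, "annotation"))
  if (!identical(table$cells$cell_id, annotation$cell_id)) {
    ps_stop("annotation is not aligned with the cell table (cell_id mismatch)")
  }
  out <- cbind(table$cells, as.data.frame(table$mfi, check.names = FALSE),
               label = annotation$label, rho_best = annotation$rho_best,
               tied = annotation$tied)
  if (!is.null(distances)) {
    if (!identical(distances$cell_id, table$cells$cell_id)) {
      ps_stop("distance table is not aligned with the cell table")
    }
    out$distance_to_epidermis_um <- distances$distance
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
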
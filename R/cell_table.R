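#' Per-cell segmentation statistics for one sample
#'
#' A `cell_table` holds the single-cell database exported after 3D
#' segmentation of an imaged tissue region: one row per segmented CD45+ cell
#' with its position (micrometres), morphology (volume, sphericity, area) and
#' the mean fluorescence intensity (MFI) of every acquired channel.
#'
#' @param cells data.frame with columns `cell_id`, `x`, `y`, `z`, `volume`,
#'   `sphericity`, `area` (micrometre-based units).
#' @param mfi numeric matrix, one row per cell, one named column per channel;
#'   all values must be finite and non-negative.
#' @param sample_id character scalar identifying the sample.
#' @return An object of class `cell_table` with elements `sample_id`, `cells`
#'   and `mfi`.
#' @export
cell_table <- function(cells, mfi, sample_id = "sample") {
  stopifnot(is.data.frame(cells), is.matrix(mfi))
  req <- c("cell_id", "x", "y", "z", "volume", "sphericity", "area")
  miss <- setdiff(req, names(cells))
  if (length(miss) > 0) {
    ps_stop("cell table is missing required column(s): %s",
            paste(miss, collapse = ", "))
  }
  if (nrow(cells) != nrow(mfi)) {
    ps_stop("morphology table (%d rows) and MFI matrix (%d rows) disagree",
            nrow(cells), nrow(mfi))
  }
  if (is.null(colnames(mfi)) || any(!nzchar(colnames(mfi)))) {
    ps_stop("MFI matrix must have channel names as column names")
  }
  if (anyDuplicated(colnames(mfi))) {
    ps_stop("duplicate channel name(s): %s",
            paste(unique(colnames(mfi)[duplicated(colnames(mfi))]), collapse = ", "))
  }
  if (anyDuplicated(cells$cell_id)) {
    ps_stop("duplicate cell_id(s): %s",
            paste(unique(cells$cell_id[duplicated(cells$cell_id)])[1:3], collapse = ", "))
  }
  coord <- as.matrix(cells[, c("x", "y", "z", "volume", "sphericity", "area")])
  if (any(!is.finite(coord))) {
    ps_stop("non-finite coordinate or morphology value in validated cell table")
  }
  if (any(!is.finite(mfi)) || any(mfi < 0)) {
    ps_stop("MFI values must be finite and non-negative in validated cell table")
  }
  structure(
    list(sample_id = as.character(sample_id),
         cells = cells[, req],
         mfi = mfi),
    class = "cell_table"
  )
}

#' @export
print.cell_table <- function(x, ...) {
  cat(sprintf("<cell_table> sample '%s': %d cells, %d channels\n",
              x$sample_id, nrow(x$cells), ncol(x$mfi)))
  cat("  channels:", paste(colnames(x$mfi), collapse = ", "), "\n")
  invisible(x)
}

#' Number of cells in a cell table
#' @param x a `cell_table`.
#' @return integer cell count.
#' @export
n_cells <- function(x) nrow(x$cells)

#' Channel names of a cell table
#' @param x a `cell_table`.
#' @return character vector of channel names.
#' @export
channels <- function(x) colnames(x$mfi)

#' Read a per-cell statistics table from CSV
#'
#' Reads the comma-separated single-cell export (header row, decimal point,
#' UTF-8). Required columns are `cell_id`, `x`, `y`, `z`, `volume`,
#' `sphericity`, `area`; every remaining numeric column is treated as an MFI
#' channel. Vendor column names are absorbed through `channel_map`. Rows with
#' any non-finite coordinate/morphology value or a non-finite or negative MFI
#' are segmentation artifacts: they are dropped with a logged count rather
#' than aborting the run.
#'
#' @param path path to the CSV file.
#' @param channel_map optional named character vector mapping raw column names
#'   to canonical names, e.g. `c("Intensity Mean Ch1" = "CD45")`.
#' @param sample_id sample identifier; defaults to the file name without
#'   extension.
#' @return A validated [cell_table()].
#' @export
read_cell_table <- function(path, channel_map = NULL, sample_id = NULL) {
  if (!file.exists(path)) ps_stop("file not found: %s", path)
  raw <- utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8")
  if (!is.null(channel_map)) {
    hit <- names(raw) %in% names(channel_map)
    names(raw)[hit] <- unname(channel_map[names(raw)[hit]])
  }
  req <- c("cell_id", "x", "y", "z", "volume", "sphericity", "area")
  miss <- setdiff(req, names(raw))
  if (length(miss) > 0) {
    ps_stop("missing required column(s) in %s: %s", path,
            paste(miss, collapse = ", "))
  }
  chan <- setdiff(names(raw), req)
  chan <- chan[vapply(raw[chan], is.numeric, logical(1))]
  if (length(chan) == 0) ps_stop("no numeric MFI channel columns found in %s", path)
  if (anyDuplicated(raw$cell_id)) {
    ps_stop("duplicate cell_id(s) in %s: %s", path,
            paste(unique(raw$cell_id[duplicated(raw$cell_id)])[1:3], collapse = ", "))
  }
  num <- as.matrix(raw[, c(req[-1], chan)])
  mfi <- as.matrix(raw[, chan, drop = FALSE])
  bad <- rowSums(!is.finite(num)) > 0 | rowSums(mfi < 0, na.rm = TRUE) > 0
  if (any(bad)) {
    ps_warn("%d row(s) rejected in %s (non-finite values or negative MFI)",
            sum(bad), basename(path))
    ps_log("rejected %d of %d rows from %s", sum(bad), nrow(raw), path,
           level = "WARN")
    raw <- raw[!bad, , drop = FALSE]
  }
  if (is.null(sample_id)) {
    sample_id <- tools::file_path_sans_ext(basename(path))
  }
  cell_table(cells = raw[, req],
             mfi = as.matrix(raw[, chan, drop = FALSE]),
             sample_id = sample_id)
}

#' Write a cell table to CSV
#'
#' Inverse of [read_cell_table()]: writes one row per cell with the
#' morphology columns followed by one column per MFI channel.
#'
#' @param x a `cell_table`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cell_table <- function(x, path) {
  stopifnot(inherits(x, "cell_table"))
  out <- cbind(x$cells, as.data.frame(x$mfi, check.names = FALSE))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Check marker/channel consistency between a cell table and a panel
#'
#' Report-only consistency check: which matrix markers are absent from the
#' table's channels (these block a run) and which table channels are unused by
#' the matrix (e.g. a nuclear stain; harmless).
#'
#' @param table a `cell_table`.
#' @param matrix an [attribution_matrix()].
#' @return A list of class `panel_validation` with elements
#'   `missing_in_table`, `unused_channels` and logical `ok`.
#' @export
validate_panel <- function(table, matrix) {
  stopifnot(inherits(table, "cell_table"), inherits(matrix, "attribution_matrix"))
  missing_in_table <- setdiff(matrix$markers, channels(table))
  unused_channels <- setdiff(channels(table), matrix$markers)
  structure(
    list(missing_in_table = missing_in_table,
         unused_channels = unused_channels,
         ok = length(missing_in_table) == 0),
    class = "panel_validation"
  )
}

#' @export
print.panel_validation <- function(x, ...) {
  cat("<panel_validation>", if (x$ok) "OK" else "NOT RUNNABLE", "\n")
  if (length(x$missing_in_table) > 0) {
    cat("  markers missing from table:",
        paste(x$missing_in_table, collapse = ", "), "\n")
  }
  if (length(x$unused_channels) > 0) {
    cat("  unused table channels:",
        paste(x$unused_channels, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Run configuration
#'
#' Holds the tunable parameters of the spatial pipeline: the alpha parameter
#' used for inflammatory-cluster detection (`alpha_roi`, default 0.1), the
#' alpha parameter for the epidermis model (`alpha_epidermis`, default 0.4),
#' the minimum cluster membership (`min_roi_cells`, default 15 cells) and the
#' kernel-density grid resolution for activation thresholds.
#'
#' @param alpha_roi alpha (1/micrometre) for cluster detection.
#' @param alpha_epidermis alpha (1/micrometre) for the epidermis model.
#' @param min_roi_cells minimum member count for a retained cluster.
#' @param kde_grid_points grid points for activation-threshold density curves.
#' @param seed optional integer seed for stochastic steps.
#' @return A list of class `run_config`.
#' @export
run_config <- function(alpha_roi = 0.1, alpha_epidermis = 0.4,
                       min_roi_cells = 15, kde_grid_points = 512,
                       seed = NULL) {
  stopifnot(alpha_roi >= 0, alpha_epidermis >= 0, min_roi_cells >= 1,
            kde_grid_points >= 64)
  structure(list(alpha_roi = alpha_roi,
                 alpha_epidermis = alpha_epidermis,
                 min_roi_cells = as.integer(min_roi_cells),
                 kde_grid_points = as.integer(kde_grid_points),
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from a flat key = value text file
#' @param path path to the config file; lines of the form `key = value`,
#'   `#` comments allowed.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) ps_stop("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- lengths(kv) != 2
  if (any(bad)) ps_stop("malformed config line: '%s'", lines[bad][1])
  vals <- stats::setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
  args <- list()
  for (k in c("alpha_roi", "alpha_epidermis", "min_roi_cells",
              "kde_grid_points", "seed")) {
    if (k %in% names(vals)) args[[k]] <- as.numeric(vals[[k]])
  }
  do.call(run_config, args)
}

#' Write a run configuration as flat key = value text
#' @param config a [run_config()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  keep <- !vapply(config, is.null, logical(1))
  writeLines(sprintf("%s = %s", names(config)[keep],
                     unlist(config[keep], use.names = FALSE)), path)
  invisible(path)
}
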
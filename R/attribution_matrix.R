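#' Binary phenotype attribution matrix
#'
#' The reference table driving automatic cell-type annotation: one row per
#' marker, one column per cell-type variant, entries strictly 0/1 encoding the
#' literature-based theoretical signature of each immune subset. A population
#' that *can* express a marker is expanded into two columns sharing the same
#' label, one with the entry set to 1 and one with 0 (e.g. gamma-delta T cells
#' may or may not express CD4).
#'
#' @param signatures integer 0/1 matrix, markers as rows (rownames), one
#'   column per cell-type variant.
#' @param labels character vector of cell-type labels, one per column;
#'   repeated labels mark optional-marker variants of the same subset.
#' @param panel_name name of the panel ("lymphoid", "myeloid" or custom).
#' @return An object of class `attribution_matrix` with elements
#'   `panel_name`, `markers`, `labels`, `column_id` and `signatures`.
#' @export
attribution_matrix <- function(signatures, labels,
                               panel_name = "custom") {
  signatures <- as.matrix(signatures)
  if (is.null(rownames(signatures))) {
    ps_stop("signature matrix must carry marker names as rownames")
  }
  if (length(labels) != ncol(signatures)) {
    ps_stop("need one label per signature column (%d labels, %d columns)",
            length(labels), ncol(signatures))
  }
  if (!all(signatures %in% c(0, 1))) {
    ps_stop("attribution matrix entries must be exactly 0 or 1")
  }
  empty <- colSums(signatures) == 0
  if (any(empty)) {
    ps_stop("empty signature column(s) (no marker set to 1): %s",
            paste(labels[empty], collapse = ", "))
  }
  storage.mode(signatures) <- "integer"
  column_id <- paste0(labels, "#", stats::ave(seq_along(labels), labels,
                                              FUN = seq_along))
  colnames(signatures) <- column_id
  structure(
    list(panel_name = as.character(panel_name),
         markers = rownames(signatures),
         labels = as.character(labels),
         column_id = column_id,
         signatures = signatures),
    class = "attribution_matrix"
  )
}

#' @export
print.attribution_matrix <- function(x, ...) {
  cat(sprintf("<attribution_matrix> panel '%s': %d markers, %d columns, %d labels\n",
              x$panel_name, length(x$markers), length(x$labels),
              length(unique(x$labels))))
  cat("  markers:", paste(x$markers, collapse = ", "), "\n")
  cat("  labels: ", paste(unique(x$labels), collapse = ", "), "\n")
  invisible(x)
}

#' Read an attribution matrix from CSV/TSV
#'
#' Expects markers as rows (first column named `marker`) and one column per
#' cell-type variant; the header holds the cell-type label, repeated for
#' optional-marker variants. Entries must be strictly binary.
#'
#' @param path path to the CSV (comma) or TSV (tab) file.
#' @param panel_name panel name stored on the result; defaults to the file
#'   name without extension.
#' @return An [attribution_matrix()].
#' @export
read_attribution_matrix <- function(path, panel_name = NULL) {
  if (!file.exists(path)) ps_stop("file not found: %s", path)
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  # read.table uniquifies duplicate headers even with check.names = FALSE,
  # but repeated labels mark optional-marker variants: parse the header apart
  header <- strsplit(readLines(path, n = 1)[1], sep, fixed = TRUE)[[1]]
  raw <- utils::read.table(path, sep = sep, header = FALSE, skip = 1,
                           fileEncoding = "UTF-8", stringsAsFactors = FALSE)
  names(raw) <- header
  if (header[1] != "marker") {
    ps_stop("first column of %s must be named 'marker'", path)
  }
  mat <- as.matrix(raw[, -1, drop = FALSE])
  colnames(mat) <- header[-1]
  if (!is.numeric(mat) || !all(mat %in% c(0, 1))) {
    ps_stop("non-binary entry in attribution matrix %s", path)
  }
  rownames(mat) <- raw$marker
  if (is.null(panel_name)) {
    panel_name <- tools::file_path_sans_ext(basename(path))
  }
  attribution_matrix(mat, labels = colnames(mat), panel_name = panel_name)
}

#' Write an attribution matrix to CSV
#' @param x an [attribution_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_attribution_matrix <- function(x, path) {
  stopifnot(inherits(x, "attribution_matrix"))
  out <- data.frame(marker = x$markers, check.names = FALSE)
  sig <- x$signatures
  colnames(sig) <- x$labels
  out <- cbind(out, as.data.frame(sig, check.names = FALSE))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Packaged default attribution panels
#'
#' Loads the packaged reference panels. The lymphoid panel covers B cells, NK
#' cells, CD4/CD8 T cells, gamma-delta T cells and double-negative/positive T
#' cells over CD45, CD20, CD3, TCRgd, CD4, CD8 and CD57; the myeloid panel
#' covers mast cells, neutrophils, eosinophils, basophils, dermal dendritic
#' cells (dDC), Langerhans cells (LC) and CD207+ dDC over CD45, CD1c, CD207,
#' HLA-DR, Tryptase, MPO, Siglec8 and CD123. Optional markers (CD57 on
#' alpha-beta T cells, CD4 on gamma-delta T cells, HLA-DR on dendritic
#' subsets) are expanded into paired 0/1 columns.
#'
#' @param panel "lymphoid" or "myeloid".
#' @return An [attribution_matrix()].
#' @export
default_panel <- function(panel = c("lymphoid", "myeloid")) {
  panel <- match.arg(panel)
  path <- system.file("extdata", paste0(panel, "_panel.csv"),
                      package = "phenoshape", mustWork = TRUE)
  read_attribution_matrix(path, panel_name = panel)
}

#' Default activation-marker targets for a panel
#'
#' The populations whose activation status is read out by density-curve
#' thresholding: CD57 on CD4 and CD8 T cells (lymphoid panel), HLA-DR on dDC,
#' LC and CD207+ dDC (myeloid panel).
#'
#' @param panel "lymphoid", "myeloid", or "both".
#' @return data.frame with columns `label` and `marker`.
#' @export
default_activation_targets <- function(panel = c("lymphoid", "myeloid", "both")) {
  panel <- match.arg(panel)
  lym <- data.frame(label = c("CD4 T", "CD8 T"), marker = "CD57",
                    stringsAsFactors = FALSE)
  mye <- data.frame(label = c("dDC", "LC", "CD207+ dDC"), marker = "HLA-DR",
                    stringsAsFactors = FALSE)
  switch(panel, lymphoid = lym, myeloid = mye, both = rbind(lym, mye))
}

#' Enumerate the final label vocabulary of one or more panels
#'
#' Base cell-type labels from the attribution matrices, with every
#' activation-target population expanded into its low/high variants (e.g.
#' "CD4 T" becomes "CD4 T CD57low" and "CD4 T CD57high"). With both packaged
#' default panels this vocabulary has 19 labels: 9 lymphoid and 10 myeloid
#' immune subsets.
#'
#' @param panels an [attribution_matrix()] or list of them; defaults to both
#'   packaged panels.
#' @param targets activation targets as from [default_activation_targets()];
#'   `NULL` keeps base labels unexpanded.
#' @return character vector of distinct labels.
#' @export
panel_labels <- function(panels = list(default_panel("lymphoid"),
                                       default_panel("myeloid")),
                         targets = default_activation_targets("both")) {
  if (inherits(panels, "attribution_matrix")) panels <- list(panels)
  out <- character(0)
  for (p in panels) {
    for (lab in unique(p$labels)) {
      hit <- !is.null(targets) && lab %in% targets$label
      if (hit) {
        mk <- targets$marker[match(lab, targets$label)]
        out <- c(out, paste0(lab, " ", mk, "low"), paste0(lab, " ", mk, "high"))
      } else {
        out <- c(out, lab)
      }
    }
  }
  unique(out)
}
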
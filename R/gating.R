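#' Rule-based histo-cytometry gating
#'
#' A `gating_rules` object mirrors a manual flow-cytometry-style gating
#' strategy applied to per-cell image statistics: an ordered list of rules,
#' each requiring named markers to be positive or negative relative to a
#' per-marker cutoff; unnamed markers are unconstrained. Cells are assigned
#' to the first rule they satisfy; cells failing every rule become "Other".
#' Used as the supervised validation oracle for the correlation-based
#' annotation.
#'
#' @param rules data.frame: column `label` plus one column per marker with
#'   entries in `pos`, `neg`, `any`. Row order is the gating order.
#' @return An object of class `gating_rules`.
#' @export
gating_rules <- function(rules) {
  stopifnot(is.data.frame(rules), "label" %in% names(rules))
  markers <- setdiff(names(rules), "label")
  req <- as.matrix(rules[, markers, drop = FALSE])
  if (!all(req %in% c("pos", "neg", "any"))) {
    ps_stop("gating requirements must be 'pos', 'neg' or 'any'")
  }
  structure(list(labels = rules$label, markers = markers, requirements = req),
            class = "gating_rules")
}

#' @export
print.gating_rules <- function(x, ...) {
  cat(sprintf("<gating_rules> %d rules over %d markers\n",
              length(x$labels), length(x$markers)))
  for (i in seq_along(x$labels)) {
    r <- x$requirements[i, ]
    used <- r != "any"
    cat(sprintf("  %-12s %s\n", x$labels[i],
                paste0(x$markers[used], ifelse(r[used] == "pos", "+", "-"),
                       collapse = " ")))
  }
  invisible(x)
}

#' Packaged default gating strategies
#'
#' The hierarchical marker gates for the lymphoid panel (B, NK, CD4 T, CD8 T,
#' gamma-delta T, double-negative and double-positive T cells) and the
#' myeloid panel (mast cells, dDC, LC, CD207+ dDC, neutrophils, eosinophils,
#' basophils), as used for supervised histo-cytometry validation. CD57 and
#' HLA-DR low/high splits are applied afterwards by [split_activation()].
#'
#' @param panel "lymphoid" or "myeloid".
#' @return A [gating_rules()] object.
#' @export
default_gating <- function(panel = c("lymphoid", "myeloid")) {
  panel <- match.arg(panel)
  path <- system.file("extdata", paste0(panel, "_gating.csv"),
                      package = "phenoshape", mustWork = TRUE)
  gating_rules(utils::read.csv(path, check.names = FALSE,
                               stringsAsFactors = FALSE))
}

#' Gate cells with a rule set
#'
#' Deterministic hierarchical gating: for each cell, markers are compared to
#' their positivity cutoffs (strictly greater than the cutoff counts as
#' positive) and the first satisfied rule assigns the label. When no cutoffs
#' are supplied they default to the first-density-peak threshold of each used
#' marker computed over the whole sample (see [activation_threshold()]).
#'
#' @param table a [cell_table()].
#' @param rules a [gating_rules()] object.
#' @param thresholds named numeric vector of per-marker positivity cutoffs;
#'   markers missing from it are derived from the sample. An underivable
#'   cutoff for a used marker is an error.
#' @return An `annotation` object (no correlation scores are set).
#' @export
gate_cells <- function(table, rules, thresholds = NULL) {
  stopifnot(inherits(table, "cell_table"), inherits(rules, "gating_rules"))
  used <- rules$markers[colSums(rules$requirements != "any") > 0]
  miss <- setdiff(used, channels(table))
  if (length(miss) > 0) {
    ps_stop("gating marker(s) absent from table channels: %s",
            paste(miss, collapse = ", "))
  }
  thr <- stats::setNames(rep(NA_real_, length(used)), used)
  if (!is.null(thresholds)) {
    hit <- intersect(names(thresholds), used)
    thr[hit] <- thresholds[hit]
  }
  for (m in used[is.na(thr)]) {
    t_m <- tryCatch(activation_threshold(table$mfi[, m]),
                    error = function(e) NA_real_)
    if (is.na(t_m)) {
      ps_stop("no threshold supplied for marker '%s' and none derivable", m)
    }
    thr[m] <- as.numeric(t_m)
  }
  pos <- sweep(table$mfi[, used, drop = FALSE], 2, thr[used], `>`)
  n <- n_cells(table)
  label <- rep("Other", n)
  unassigned <- rep(TRUE, n)
  for (i in seq_along(rules$labels)) {
    r <- rules$requirements[i, used]
    need_pos <- used[r == "pos"]
    need_neg <- used[r == "neg"]
    ok <- unassigned
    if (length(need_pos) > 0) {
      ok <- ok & rowSums(pos[, need_pos, drop = FALSE]) == length(need_pos)
    }
    if (length(need_neg) > 0) {
      ok <- ok & rowSums(pos[, need_neg, drop = FALSE]) == 0
    }
    label[ok] <- rules$labels[i]
    unassigned <- unassigned & !ok
  }
  ann <- new_annotation(table$cells$cell_id, label,
                        rho_best = rep(NA_real_, n),
                        rho_runner_up = rep(NA_real_, n),
                        tied = rep(FALSE, n),
                        labels = unique(rules$labels),
                        sample_id = table$sample_id, method = "gating")
  attr(ann, "thresholds") <- thr
  ann
}

#' Least-squares regression coefficient across paired label densities
#'
#' Fits per-label density pairs (method A vs method B) by ordinary least
#' squares and returns the regression coefficient R, i.e. the signed
#' correlation coefficient of the fit (`sign(slope) * sqrt(R^2)`), which is
#' bounded by \[-1, 1\].
#'
#' @param pairs data.frame with columns `density_a` and `density_b`.
#' @return list with `R`, `slope`, `intercept`.
#' @export
density_regression <- function(pairs) {
  stopifnot(all(c("density_a", "density_b") %in% names(pairs)))
  if (nrow(pairs) < 3) ps_stop("regression needs at least 3 label pairs")
  fit <- stats::lm(density_b ~ density_a, data = pairs)
  tss <- sum((pairs$density_b - mean(pairs$density_b))^2)
  if (tss == 0) ps_stop("density_b is constant; regression ill-posed")
  r2 <- 1 - sum(stats::residuals(fit)^2) / tss
  r2 <- min(max(r2, 0), 1)
  slope <- unname(stats::coef(fit)[2])
  list(R = sign(slope) * sqrt(r2), slope = slope,
       intercept = unname(stats::coef(fit)[1]))
}

#' Compare two annotations of the same sample by density regression
#'
#' Accuracy-validation step: per-label cell densities are computed for both
#' annotation methods (counts over the region-of-interest volume) and a
#' least-squares linear regression is fitted across labels. A regression
#' coefficient R between 0.75 and 1 indicates method agreement.
#'
#' @param a,b `annotation` objects over the same cells.
#' @param labels labels to compare; defaults to the union of both label
#'   vocabularies, excluding "Other".
#' @param roi_volume_mm3 shared density denominator (default: the 0.6 x 0.4 x
#'   0.02 mm acquisition box, 0.0048 mm^3). A shared denominator makes R
#'   invariant to its choice.
#' @return An object of class `annotation_comparison`: list with `R`,
#'   `slope`, `intercept`, `pairs` (per-label density table) and `agreement`
#'   (fraction of cells with identical labels).
#' @export
compare_annotations <- function(a, b, labels = NULL, roi_volume_mm3 = 0.0048) {
  stopifnot(inherits(a, "annotation"), inherits(b, "annotation"))
  if (nrow(a) != nrow(b) || !identical(a$cell_id, b$cell_id)) {
    ps_stop("annotations do not cover the same cells")
  }
  if (is.null(labels)) {
    labels <- setdiff(union(attr(a, "labels"), attr(b, "labels")), "Other")
  }
  da <- cell_density(a, roi_volume_mm3 = roi_volume_mm3, labels = labels)
  db <- cell_density(b, roi_volume_mm3 = roi_volume_mm3, labels = labels)
  if (sum(da > 0) < 3 || sum(db > 0) < 3) {
    ps_stop("fewer than 3 labels with nonzero density; regression ill-posed")
  }
  pairs <- data.frame(label = labels, density_a = unname(da),
                      density_b = unname(db), stringsAsFactors = FALSE)
  fit <- density_regression(pairs)
  structure(list(R = fit$R, slope = fit$slope, intercept = fit$intercept,
                 pairs = pairs, agreement = mean(a$label == b$label)),
            class = "annotation_comparison")
}

#' @export
print.annotation_comparison <- function(x, ...) {
  cat(sprintf("<annotation_comparison> %d labels, R = %.4f, per-cell agreement = %.1f%%\n",
              nrow(x$pairs), x$R, 100 * x$agreement))
  invisible(x)
}
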
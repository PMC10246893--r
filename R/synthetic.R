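#' Specification of a synthetic single-cell sample
#'
#' Defines everything needed to simulate the statistical structure that the
#' annotation, activation, clustering and distance stages consume: a panel,
#' exact subset counts, a log-normal marker intensity model (right-skewed and
#' non-negative, like fluorescence), activation mixing fractions, a spatial
#' layout (Gaussian blobs and/or pinned positions over a uniform background)
#' inside the imaged box, and an optional epidermis band. The default box is
#' 600 x 400 x 20 micrometres (0.0048 mm^3).
#'
#' @param panel an [attribution_matrix()] (defaults to the packaged lymphoid
#'   panel).
#' @param subset_counts named integer vector: cells per base label. Labels
#'   must exist in the panel.
#' @param intensity_model list with elements `negative = c(meanlog, sdlog)`,
#'   `positive = c(meanlog, sdlog)` and optionally `per_marker` (named list
#'   of such pairs overriding individual markers) and `brightness` (named
#'   per-channel scale factors multiplying both distributions; defaults to a
#'   log-spaced ladder over one decade across the panel's markers, emulating
#'   the different laser/gain/fluorophore scales of real channels that the
#'   dynamic matrix adaptation exists to absorb). `sdlog = 0` makes a
#'   distribution degenerate at `exp(meanlog)` (use `meanlog = -Inf` for an
#'   exact-zero background).
#' @param activation_mix data.frame with columns `label`, `marker`,
#'   `high_fraction`: within each target population, exactly
#'   `round(high_fraction * n)` cells draw the marker from the positive
#'   distribution ("high"), the rest from the background ("low").
#' @param layout list with optional elements `blobs` (list of
#'   `list(center = c(x, y), sd, n, labels = NULL)`) and `fixed` (list of
#'   `list(label, x, y)` pinning cells of one label to given coordinates).
#'   Cells not claimed by a blob or pin are spread uniformly over the box.
#' @param roi_box numeric length-3: box extents in micrometres.
#' @param epidermis_band optional numeric length-2 y-range of the epidermis
#'   band; when set, a jittered grid of surface vertices is emitted.
#' @param epidermis_spacing vertex grid spacing of the band (micrometres).
#' @param seed integer seed; the whole sample is a pure function of the spec.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(panel = default_panel("lymphoid"),
                           subset_counts,
                           intensity_model = list(
                             negative = c(meanlog = log(10), sdlog = 0.35),
                             positive = c(meanlog = log(150), sdlog = 0.35)),
                           activation_mix = NULL,
                           layout = list(),
                           roi_box = c(x = 600, y = 400, z = 20),
                           epidermis_band = NULL,
                           epidermis_spacing = 5,
                           seed = 1L) {
  stopifnot(inherits(panel, "attribution_matrix"),
            !is.null(names(subset_counts)), all(subset_counts >= 0))
  unknown <- setdiff(names(subset_counts), unique(panel$labels))
  if (length(unknown) > 0) {
    ps_stop("subset label(s) not in panel: %s", paste(unknown, collapse = ", "))
  }
  if (intensity_model$positive["meanlog"] <= intensity_model$negative["meanlog"]) {
    ps_stop("positive meanlog must exceed negative meanlog")
  }
  if (is.null(intensity_model$brightness)) {
    k <- length(panel$markers)
    # half-decade ladder: real channel-scale variation for the adaptation
    # step to absorb, while keeping every positive distribution at least
    # ~4 sdlog above every channel's background (well-separated signatures)
    intensity_model$brightness <- stats::setNames(
      10^(seq(0, 0.5, length.out = max(k, 2)))[seq_len(k)], panel$markers)
  }
  if (is.null(activation_mix)) {
    tg <- default_activation_targets(
      if (panel$panel_name %in% c("lymphoid", "myeloid")) panel$panel_name else "both")
    tg <- tg[tg$label %in% names(subset_counts), , drop = FALSE]
    activation_mix <- if (nrow(tg) > 0) cbind(tg, high_fraction = 0.5) else NULL
  }
  for (b in layout$blobs) {
    if (any(b$center < 0) || b$center[1] > roi_box[1] || b$center[2] > roi_box[2]) {
      ps_stop("infeasible layout: blob center (%g, %g) outside the box",
              b$center[1], b$center[2])
    }
  }
  if (!is.null(epidermis_band) &&
      (epidermis_band[1] < 0 || epidermis_band[2] > roi_box[2])) {
    ps_stop("epidermis band outside the box")
  }
  structure(list(panel = panel,
                 subset_counts = subset_counts,
                 intensity_model = intensity_model,
                 activation_mix = activation_mix,
                 layout = layout,
                 roi_box = roi_box,
                 epidermis_band = epidermis_band,
                 epidermis_spacing = epidermis_spacing,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

.marker_params <- function(model, marker, positive) {
  p <- model$per_marker[[marker]]
  par <- if (!is.null(p)) {
    if (positive) p$positive else p$negative
  } else if (positive) model$positive else model$negative
  b <- model$brightness[marker]
  if (!is.null(model$brightness) && !is.na(b)) {
    par["meanlog"] <- par["meanlog"] + log(unname(b))
  }
  par
}

.draw_lnorm <- function(n, par) {
  if (n == 0) return(numeric(0))
  if (par["sdlog"] == 0) rep(exp(par["meanlog"]), n)
  else stats::rlnorm(n, par["meanlog"], par["sdlog"])
}

#' Generate a synthetic sample with ground truth
#'
#' Draws a full single-cell database from a [synthetic_spec()]: marker MFIs
#' from the positive/negative distributions dictated by each cell's
#' ground-truth signature (activation mixing controls the activation-marker
#' draw), positions from the layout, morphology from generic log-normal /
#' beta models, and the epidermis band vertices when requested. Ground truth
#' is returned alongside, never inside, the cell table.
#'
#' @param spec a [synthetic_spec()].
#' @return A list of class `synthetic_sample` with elements `table`
#'   (a [cell_table()]), `truth` (data.frame: cell_id, label, activation,
#'   final_label), `contour` (epidermis vertex matrix or NULL) and `spec`.
#' @export
generate_sample <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    panel <- spec$panel
    counts <- spec$subset_counts
    labels <- rep(names(counts), counts)
    n <- length(labels)
    if (n == 0) ps_stop("spec yields zero cells")
    markers <- panel$markers

    # base generating signature: the first matrix column of each label
    first_col <- match(unique(panel$labels), panel$labels)
    base_sig <- panel$signatures[, first_col, drop = FALSE]
    colnames(base_sig) <- panel$labels[first_col]
    sig <- base_sig[, labels, drop = FALSE]  # markers x cells

    # activation ground truth: exact high counts per target population
    activation <- rep(NA_character_, n)
    mix <- spec$activation_mix
    if (!is.null(mix)) {
      for (i in seq_len(nrow(mix))) {
        idx <- which(labels == mix$label[i])
        if (length(idx) == 0) next
        n_high <- round(mix$high_fraction[i] * length(idx))
        hi <- idx[sample.int(length(idx), n_high)]
        activation[idx] <- "low"
        activation[hi] <- "high"
        sig[mix$marker[i], idx] <- 0L
        sig[mix$marker[i], hi] <- 1L
      }
    }

    mfi <- matrix(0, n, length(markers), dimnames = list(NULL, markers))
    for (m in markers) {
      posi <- sig[m, ] == 1L
      mfi[posi, m] <- .draw_lnorm(sum(posi),
                                  .marker_params(spec$intensity_model, m, TRUE))
      mfi[!posi, m] <- .draw_lnorm(sum(!posi),
                                   .marker_params(spec$intensity_model, m, FALSE))
    }

    # positions: pinned cells, then blobs, then uniform background
    bx <- spec$roi_box[1]; by <- spec$roi_box[2]; bz <- spec$roi_box[3]
    pos <- matrix(NA_real_, n, 2)
    pool <- seq_len(n)
    for (f in spec$layout$fixed) {
      cand <- pool[labels[pool] == f$label]
      if (length(cand) < length(f$x)) {
        ps_stop("infeasible layout: %d pinned positions for label '%s' but only %d cells",
                length(f$x), f$label, length(cand))
      }
      take <- cand[seq_along(f$x)]
      pos[take, 1] <- f$x
      pos[take, 2] <- f$y
      pool <- setdiff(pool, take)
    }
    for (b in spec$layout$blobs) {
      cand <- if (is.null(b$labels)) pool else pool[labels[pool] %in% b$labels]
      if (length(cand) < b$n) {
        ps_stop("infeasible layout: blob wants %d cells, %d available", b$n,
                length(cand))
      }
      take <- cand[sample.int(length(cand), b$n)]
      pos[take, 1] <- pmin(pmax(b$center[1] + stats::rnorm(b$n, 0, b$sd), 0), bx)
      pos[take, 2] <- pmin(pmax(b$center[2] + stats::rnorm(b$n, 0, b$sd), 0), by)
      pool <- setdiff(pool, take)
    }
    if (length(pool) > 0) {
      pos[pool, 1] <- stats::runif(length(pool), 0, bx)
      pos[pool, 2] <- stats::runif(length(pool), 0, by)
    }

    cells <- data.frame(
      cell_id = seq_len(n),
      x = pos[, 1], y = pos[, 2],
      z = stats::runif(n, 0, bz),
      volume = stats::rlnorm(n, log(300), 0.3),
      sphericity = stats::rbeta(n, 5, 2),
      area = stats::rlnorm(n, log(120), 0.3)
    )

    contour <- NULL
    if (!is.null(spec$epidermis_band)) {
      gx <- seq(0, bx, by = spec$epidermis_spacing)
      gy <- seq(spec$epidermis_band[1], spec$epidermis_band[2],
                by = spec$epidermis_spacing)
      g <- expand.grid(x = gx, y = gy)
      jit <- 0.15 * spec$epidermis_spacing
      g$x <- pmin(pmax(g$x + stats::runif(nrow(g), -jit, jit), 0), bx)
      g$y <- pmin(pmax(g$y + stats::runif(nrow(g), -jit, jit),
                       spec$epidermis_band[1]), spec$epidermis_band[2])
      contour <- cbind(x = g$x, y = g$y, z = stats::runif(nrow(g), 0, bz))
    }

    final <- labels
    if (!is.null(mix)) {
      tgt <- !is.na(activation)
      mk <- mix$marker[match(labels[tgt], mix$label)]
      final[tgt] <- paste0(labels[tgt], " ", mk, activation[tgt])
    }

    list2 <- list(
      table = cell_table(cells, mfi, sample_id = sprintf("synthetic_seed%d", spec$seed)),
      truth = data.frame(cell_id = cells$cell_id, label = labels,
                         activation = activation, final_label = final,
                         stringsAsFactors = FALSE),
      contour = contour,
      spec = spec
    )
    structure(list2, class = "synthetic_sample")
  })
}

#' @export
print.synthetic_sample <- function(x, ...) {
  cat(sprintf("<synthetic_sample> %d cells, %d subsets, seed %d%s\n",
              n_cells(x$table), length(x$spec$subset_counts), x$spec$seed,
              if (is.null(x$contour)) "" else
                sprintf(", epidermis band of %d vertices", nrow(x$contour))))
  invisible(x)
}

#' Ground-truth annotation of a synthetic sample
#'
#' Wraps the generator's planted labels in an `annotation` object so that
#' downstream stages (clusters, densities, distances) can be run against the
#' truth.
#'
#' @param sample a [generate_sample()] result.
#' @param final use the activation-split (`final_label`) vocabulary rather
#'   than base labels.
#' @return An `annotation` object.
#' @export
truth_annotation <- function(sample, final = FALSE) {
  stopifnot(inherits(sample, "synthetic_sample"))
  lab <- if (final) sample$truth$final_label else sample$truth$label
  n <- length(lab)
  new_annotation(sample$truth$cell_id, lab,
                 rho_best = rep(NA_real_, n),
                 rho_runner_up = rep(NA_real_, n),
                 tied = rep(FALSE, n),
                 labels = unique(lab),
                 sample_id = sample$table$sample_id, method = "truth")
}

#' Expert-style gating cutoffs implied by an intensity model
#'
#' The per-marker positivity cutoff halfway (on the log scale) between the
#' negative and positive distributions of a synthetic spec — the desk-scale
#' analogue of manually drawn flow-cytometry gates, used to drive the gating
#' oracle on synthetic benchmarks.
#'
#' @param spec a [synthetic_spec()].
#' @return named numeric vector of cutoffs per marker.
#' @export
midpoint_thresholds <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  vapply(spec$panel$markers, function(m) {
    lo <- .marker_params(spec$intensity_model, m, FALSE)["meanlog"]
    hi <- .marker_params(spec$intensity_model, m, TRUE)["meanlog"]
    if (!is.finite(lo)) lo <- hi - 20  # exact-zero background
    exp((lo + hi) / 2)
  }, numeric(1))
}

#' Fixed benchmark fixture set
#'
#' The seeded synthetic fixtures exercised by the package's validation suite:
#' \describe{
#'   \item{lymphoid, myeloid}{well-separated annotation benchmarks (600 and
#'     627 cells; 1227 in total, every base subset of both panels present,
#'     activation mixing 50/50) plus the midpoint gating cutoffs.}
#'   \item{activation}{a 2000-cell CD4 T population whose CD57 values are a
#'     50/50 mixture of the background and positive log-normals.}
#'   \item{roi_sweep}{30 isolated Gaussian blobs of sizes exactly 1..30
#'     (sd 3 micrometres, pairwise separations of at least 80 micrometres,
#'     more than 10 blob sd), no background cells.}
#'   \item{epidermis}{an epidermis band in y = \[360, 400\] with CD8 T cells
#'     pinned 10 micrometres below the band edge, B cells 100 micrometres
#'     below, and NK cells inside the band.}
#' }
#'
#' @param seed integer master seed; fixture sub-seeds are derived from it.
#' @return named list of fixtures; each holds `spec` plus fixture-specific
#'   expectations (gating `thresholds`, planted `high_fraction`, planted
#'   `blob_sizes`, planted distances).
#' @export
generate_benchmark_suite <- function(seed = 1L) {
  seed <- as.integer(seed)
  lym_counts <- c("B" = 60, "NK" = 60, "CD4 T" = 140, "CD8 T" = 140,
                  "gd T" = 70, "dn T" = 60, "dp T" = 70)
  mye_counts <- c("mast" = 70, "neutrophil" = 70, "eosinophil" = 60,
                  "basophil" = 47, "dDC" = 140, "LC" = 160,
                  "CD207+ dDC" = 80)
  lym_spec <- synthetic_spec(default_panel("lymphoid"), lym_counts,
                             seed = seed + 1L)
  mye_spec <- synthetic_spec(default_panel("myeloid"), mye_counts,
                             seed = seed + 2L)

  act_spec <- synthetic_spec(default_panel("lymphoid"),
                             c("CD4 T" = 2000),
                             activation_mix = data.frame(
                               label = "CD4 T", marker = "CD57",
                               high_fraction = 0.5),
                             seed = seed + 3L)

  sizes <- 1:30
  centers_x <- 50 + 100 * ((sizes - 1) %% 6)
  centers_y <- 40 + 80 * ((sizes - 1) %/% 6)
  blobs <- lapply(sizes, function(k) {
    list(center = c(centers_x[k], centers_y[k]), sd = 3, n = k)
  })
  sweep_spec <- synthetic_spec(default_panel("lymphoid"),
                               c("CD4 T" = sum(sizes)),
                               activation_mix = NULL,
                               layout = list(blobs = blobs),
                               seed = seed + 4L)

  epi_spec <- synthetic_spec(
    default_panel("lymphoid"),
    c("CD8 T" = 60, "B" = 60, "NK" = 40),
    layout = list(fixed = list(
      list(label = "CD8 T", x = seq(5, 595, length.out = 60), y = rep(350, 60)),
      list(label = "B", x = seq(5, 595, length.out = 60), y = rep(260, 60)),
      list(label = "NK", x = seq(10, 590, length.out = 40), y = rep(380, 40))
    )),
    epidermis_band = c(360, 400),
    epidermis_spacing = 5,
    seed = seed + 5L)

  list(
    lymphoid = list(spec = lym_spec, thresholds = midpoint_thresholds(lym_spec)),
    myeloid = list(spec = mye_spec, thresholds = midpoint_thresholds(mye_spec)),
    activation = list(spec = act_spec, high_fraction = 0.5, marker = "CD57",
                      population = "CD4 T"),
    roi_sweep = list(spec = sweep_spec, blob_sizes = sizes, blob_sd = 3,
                     min_separation = 80),
    epidermis = list(spec = epi_spec, alpha_epidermis = 0.1,
                     planted_distance = c("CD8 T" = 10, "B" = 100, "NK" = 0))
  )
}
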
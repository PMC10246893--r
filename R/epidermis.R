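# Epidermis modelling and cell-to-structure distances.
#
# The epidermis surface coordinates (exported as a vertex list) are projected
# to the x-y plane and modelled as an alpha-shape; its boundary vertices are
# loaded into a k-d tree so each cell's nearest contour vertex can be found
# quickly. Cells inside the epidermis shape get distance 0.

#' Build a 2D k-d tree over a point set
#'
#' Static median-split k-d tree used as the nearest-vertex spatial index of
#' the epidermis model.
#'
#' @param points two-column matrix of x-y coordinates.
#' @return An object of class `kd_tree`.
#' @export
kd_tree <- function(points) {
  pts <- as.matrix(points)[, 1:2, drop = FALSE]
  storage.mode(pts) <- "double"
  if (nrow(pts) == 0) ps_stop("cannot index an empty point set")
  build <- function(idx, depth) {
    if (length(idx) == 0) return(NULL)
    axis <- depth %% 2L + 1L
    ord <- idx[order(pts[idx, axis])]
    med <- (length(ord) + 1L) %/% 2L
    list(point = ord[med], axis = axis, split = pts[ord[med], axis],
         left = build(ord[seq_len(med - 1L)], depth + 1L),
         right = build(ord[seq_len(length(ord) - med) + med], depth + 1L))
  }
  structure(list(root = build(seq_len(nrow(pts)), 0L), points = pts),
            class = "kd_tree")
}

#' Nearest neighbours from a k-d tree
#'
#' For each query point, the index of the nearest indexed point and the
#' Euclidean distance to it (standard branch-and-bound descent).
#'
#' @param tree a [kd_tree()].
#' @param query two-column matrix of query x-y coordinates.
#' @return list with integer vector `index` and numeric vector `distance`.
#' @export
kd_nearest <- function(tree, query) {
  stopifnot(inherits(tree, "kd_tree"))
  q <- as.matrix(query)[, 1:2, drop = FALSE]
  pts <- tree$points
  n <- nrow(q)
  best_i <- integer(n)
  best_d2 <- numeric(n)
  for (k in seq_len(n)) {
    qx <- q[k, 1]; qy <- q[k, 2]
    bi <- 0L; bd2 <- Inf
    search <- function(node) {
      if (is.null(node)) return(invisible(NULL))
      p <- pts[node$point, ]
      d2 <- (p[1] - qx)^2 + (p[2] - qy)^2
      if (d2 < bd2) { bd2 <<- d2; bi <<- node$point }
      qv <- if (node$axis == 1L) qx else qy
      delta <- qv - node$split
      first <- if (delta <= 0) node$left else node$right
      second <- if (delta <= 0) node$right else node$left
      search(first)
      if (delta^2 <= bd2) search(second)
      invisible(NULL)
    }
    search(tree$root)
    best_i[k] <- bi
    best_d2[k] <- bd2
  }
  list(index = best_i, distance = sqrt(best_d2))
}

#' Read epidermis surface coordinates from CSV
#'
#' Expects columns `x`, `y` and optionally `z` (micrometres), one row per
#' exported surface vertex.
#'
#' @param path path to the CSV file.
#' @return numeric matrix with columns x, y, z.
#' @export
read_epidermis_contour <- function(path) {
  if (!file.exists(path)) ps_stop("file not found: %s", path)
  raw <- utils::read.csv(path, check.names = FALSE)
  if (!all(c("x", "y") %in% names(raw))) {
    ps_stop("epidermis contour CSV must have columns x and y")
  }
  if (!"z" %in% names(raw)) raw$z <- 0
  m <- as.matrix(raw[, c("x", "y", "z")])
  if (nrow(m) < 3) ps_stop("epidermis contour needs at least 3 vertices")
  if (any(!is.finite(m))) ps_stop("non-finite epidermis coordinates")
  m
}

#' Write epidermis surface coordinates to CSV
#' @param contour matrix with columns x, y (and optionally z).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_epidermis_contour <- function(contour, path) {
  m <- as.matrix(contour)
  df <- data.frame(x = m[, 1], y = m[, 2],
                   z = if (ncol(m) >= 3) m[, 3] else 0)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Model the epidermis as an alpha-shape with a nearest-vertex index
#'
#' Projects the exported surface vertices to the x-y plane, computes the
#' alpha-shape, and loads the boundary contour vertices into a k-d tree for
#' nearest-neighbour queries.
#'
#' @param contour matrix of surface vertices (columns x, y\[, z\]) or the
#'   result of [read_epidermis_contour()].
#' @param alpha alpha parameter of the epidermis shape (default 0.4 per
#'   micrometre).
#' @return An object of class `epidermis_model` with elements `shape`
#'   (an [alpha_shape()]), `contour_vertices` (boundary x-y coordinates) and
#'   `index` (a [kd_tree()]).
#' @export
build_epidermis_model <- function(contour, alpha = 0.4) {
  m <- as.matrix(contour)
  if (nrow(m) < 3) ps_stop("epidermis contour needs at least 3 vertices")
  xy <- m[, 1:2, drop = FALSE]
  shape <- alpha_shape(xy, alpha = alpha)
  if (shape$n_components == 0) {
    ps_stop("degenerate epidermis projection: no alpha-shape could be built")
  }
  vidx <- sort(unique(unlist(lapply(shape$polygons, `[[`, "vertex_index"))))
  verts <- shape$points[vidx, , drop = FALSE]
  structure(list(shape = shape, contour_vertices = verts,
                 index = kd_tree(verts), alpha = alpha),
            class = "epidermis_model")
}

#' @export
print.epidermis_model <- function(x, ...) {
  cat(sprintf("<epidermis_model> alpha = %g: %d contour vertices, area = %.1f um^2\n",
              x$alpha, nrow(x$contour_vertices), x$shape$total_area))
  invisible(x)
}

#' Distance from each cell to the epidermis
#'
#' Cells whose x-y position lies inside or on the epidermis alpha-shape get
#' distance 0; every other cell gets the distance r to its nearest epidermis
#' contour vertex, found through the model's k-d tree.
#'
#' @param table a [cell_table()].
#' @param model an [build_epidermis_model()] result.
#' @return An object of class `distance_table`: data.frame with columns
#'   `cell_id`, `distance` (micrometres) and `inside_epidermis`.
#' @export
distance_to_structure <- function(table, model) {
  stopifnot(inherits(table, "cell_table"), inherits(model, "epidermis_model"))
  xy <- as.matrix(table$cells[, c("x", "y")])
  inside <- !is.na(locate_points(model$shape, xy))
  r <- numeric(nrow(xy))
  if (any(!inside)) {
    nn <- kd_nearest(model$index, xy[!inside, , drop = FALSE])
    r[!inside] <- nn$distance
  }
  structure(data.frame(cell_id = table$cells$cell_id, distance = r,
                       inside_epidermis = inside, stringsAsFactors = FALSE),
            class = c("distance_table", "data.frame"))
}
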
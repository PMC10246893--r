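# Alpha-shapes from planar point sets.
#
# The alpha-complex is built from a Delaunay triangulation by keeping every
# triangle whose circumradius is at most 1/alpha (a circle of radius 1/alpha
# can roll around the point set; alpha = 0 keeps everything and yields the
# convex hull). Disjoint groups of kept triangles become separate polygons.

# Circumcentres and squared circumradii of triangles `tri` (rows of vertex
# indices) over points P. Collinear triangles get an infinite radius.
.circum <- function(P, tri) {
  ax <- P[tri[, 1], 1]; ay <- P[tri[, 1], 2]
  bx <- P[tri[, 2], 1]; by <- P[tri[, 2], 2]
  cx <- P[tri[, 3], 1]; cy <- P[tri[, 3], 2]
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  a2 <- ax^2 + ay^2; b2 <- bx^2 + by^2; c2 <- cx^2 + cy^2
  ux <- (a2 * (by - cy) + b2 * (cy - ay) + c2 * (ay - by)) / d
  uy <- (a2 * (cx - bx) + b2 * (ax - cx) + c2 * (bx - ax)) / d
  r2 <- (ux - ax)^2 + (uy - ay)^2
  bad <- !is.finite(d) | abs(d) < .Machine$double.eps * (abs(a2) + abs(b2) + abs(c2) + 1)
  r2[bad] <- Inf
  cbind(ux, uy, r2)
}

.tri_area <- function(P, tri) {
  abs((P[tri[, 2], 1] - P[tri[, 1], 1]) * (P[tri[, 3], 2] - P[tri[, 1], 2]) -
      (P[tri[, 3], 1] - P[tri[, 1], 1]) * (P[tri[, 2], 2] - P[tri[, 1], 2])) / 2
}

# Bowyer-Watson incremental Delaunay triangulation. Points must be deduped.
# Returns a matrix of vertex-index triples (rows), or NULL when degenerate.
.delaunay <- function(pts) {
  n <- nrow(pts)
  if (n < 3) return(NULL)
  rx <- range(pts[, 1]); ry <- range(pts[, 2])
  span <- max(diff(rx), diff(ry), 1)
  cx <- mean(rx); cy <- mean(ry)
  # far enough out that even flat boundary slivers' circumcircles
  # (radius can be orders of magnitude above the data span) stay clear
  big <- 1e5 * span
  sup <- rbind(c(cx - 2 * big, cy - big),
               c(cx + 2 * big, cy - big),
               c(cx, cy + 2 * big))
  P <- rbind(sup, pts)
  tri <- matrix(c(1L, 2L, 3L), nrow = 1)
  cc <- .circum(P, tri)
  for (i in seq_len(n)) {
    v <- i + 3L
    px <- P[v, 1]; py <- P[v, 2]
    # strictly-inside circumcircle test; cocircular points stay outside so
    # degenerate quads keep whichever diagonal was built first
    d2 <- (px - cc[, 1])^2 + (py - cc[, 2])^2
    bad <- which(d2 < cc[, 3] * (1 - 1e-12))
    if (length(bad) == 0) {
      # numerical safety net: force the nearest circumcircle open
      bad <- which.min(d2 / cc[, 3])
    }
    eg <- rbind(tri[bad, c(1, 2), drop = FALSE],
                tri[bad, c(2, 3), drop = FALSE],
                tri[bad, c(3, 1), drop = FALSE])
    lo <- pmin(eg[, 1], eg[, 2]); hi <- pmax(eg[, 1], eg[, 2])
    key <- lo * (n + 4) + hi
    once <- !(key %in% key[duplicated(key)])
    eg <- eg[once, , drop = FALSE]
    newtri <- cbind(eg, v)
    tri <- rbind(tri[-bad, , drop = FALSE], newtri)
    cc <- rbind(cc[-bad, , drop = FALSE], .circum(P, newtri))
  }
  keep <- rowSums(tri <= 3L) == 0
  tri <- tri[keep, , drop = FALSE] - 3L
  if (nrow(tri) == 0) NULL else tri
}

# Union-find over triangle adjacency (shared edges) -> component ids.
.components <- function(tri, n_points) {
  nt <- nrow(tri)
  parent <- seq_len(nt)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  eg <- rbind(tri[, c(1, 2)], tri[, c(2, 3)], tri[, c(3, 1)])
  key <- pmin(eg[, 1], eg[, 2]) * (n_points + 1) + pmax(eg[, 1], eg[, 2])
  owner <- rep(seq_len(nt), 3)
  ord <- order(key)
  key <- key[ord]; owner <- owner[ord]
  same <- which(key[-1] == key[-length(key)])
  for (s in same) {
    a <- find(owner[s]); b <- find(owner[s + 1])
    if (a != b) parent[a] <- b
  }
  comp <- vapply(seq_len(nt), find, integer(1))
  match(comp, unique(comp))
}

# Boundary polygons (vertex cycles) of a set of triangles.
.boundary_polygons <- function(P, tri, comp) {
  eg <- rbind(tri[, c(1, 2)], tri[, c(2, 3)], tri[, c(3, 1)])
  ecomp <- rep(comp, 3)
  key <- pmin(eg[, 1], eg[, 2]) * (nrow(P) + 1) + pmax(eg[, 1], eg[, 2])
  boundary <- !(key %in% key[duplicated(key)])
  eg <- eg[boundary, , drop = FALSE]
  ecomp <- ecomp[boundary]
  polys <- list()
  for (cset in split(seq_len(nrow(eg)), ecomp)) {
    sub <- eg[cset, , drop = FALSE]
    used <- rep(FALSE, nrow(sub))
    # adjacency: vertex -> edge rows
    adj <- split(rep(seq_len(nrow(sub)), 2), c(sub[, 1], sub[, 2]))
    while (any(!used)) {
      e0 <- which(!used)[1]
      used[e0] <- TRUE
      cyc <- c(sub[e0, 1], sub[e0, 2])
      repeat {
        last <- cyc[length(cyc)]
        cand <- adj[[as.character(last)]]
        cand <- cand[!used[cand]]
        if (length(cand) == 0) break
        e <- cand[1]
        used[e] <- TRUE
        nxt <- if (sub[e, 1] == last) sub[e, 2] else sub[e, 1]
        if (nxt == cyc[1]) break
        cyc <- c(cyc, nxt)
      }
      verts <- P[cyc, , drop = FALSE]
      sa <- sum(verts[, 1] * c(verts[-1, 2], verts[1, 2]) -
                c(verts[-1, 1], verts[1, 1]) * verts[, 2]) / 2
      if (sa < 0) {  # orient counter-clockwise
        cyc <- rev(cyc)
        verts <- P[cyc, , drop = FALSE]
      }
      polys[[length(polys) + 1]] <- list(vertices = verts,
                                         vertex_index = cyc,
                                         area = abs(sa),
                                         component = ecomp[cset][1])
    }
  }
  polys
}

#' Alpha-shape of a planar point set
#'
#' Computes the Delaunay triangulation of the x-y points, keeps the triangles
#' whose circumradius is at most `1/alpha` (all of them for `alpha = 0`,
#' giving the convex hull), and dissolves shared edges into boundary
#' polygons. Disconnected groups of kept triangles yield disjoint polygons.
#' Duplicate points are removed with a logged count; fewer than 3 distinct
#' non-collinear points yield an empty shape with a warning.
#'
#' @param points two-column matrix/data.frame of x-y coordinates
#'   (micrometres).
#' @param alpha alpha parameter (1/micrometres); `1/alpha` is the
#'   circumradius cut-off.
#' @return An object of class `alpha_shape`: list with `points` (deduplicated
#'   coordinates), `triangles` (kept triangle vertex indices), `component`
#'   (component id per kept triangle), `polygons` (boundary vertex cycles
#'   with areas), `component_areas` (triangle-sum area per component),
#'   `total_area`, `n_components` and `alpha`.
#' @export
alpha_shape <- function(points, alpha = 0) {
  stopifnot(alpha >= 0)
  pts <- as.matrix(points)[, 1:2, drop = FALSE]
  storage.mode(pts) <- "double"
  if (any(!is.finite(pts))) ps_stop("non-finite coordinates in point set")
  dup <- duplicated(pts)
  if (any(dup)) {
    ps_log("removed %d duplicate point(s) before triangulation", sum(dup))
    pts <- pts[!dup, , drop = FALSE]
  }
  empty <- structure(list(points = pts, triangles = NULL,
                          component = integer(0), polygons = list(),
                          component_areas = numeric(0), total_area = 0,
                          n_components = 0L, alpha = alpha),
                     class = "alpha_shape")
  if (nrow(pts) < 3) {
    ps_warn("fewer than 3 distinct points: empty alpha-shape")
    return(empty)
  }
  tri <- .delaunay(pts)
  if (is.null(tri)) {
    ps_warn("degenerate (collinear) point set: empty alpha-shape")
    return(empty)
  }
  if (alpha > 0) {
    r2 <- .circum(pts, tri)[, 3]
    tri <- tri[r2 <= (1 / alpha)^2 * (1 + 1e-9), , drop = FALSE]
    if (nrow(tri) == 0) return(empty)
  }
  comp <- .components(tri, nrow(pts))
  areas <- .tri_area(pts, tri)
  comp_area <- as.numeric(tapply(areas, comp, sum))
  polys <- .boundary_polygons(pts, tri, comp)
  structure(list(points = pts, triangles = tri, component = comp,
                 polygons = polys, component_areas = comp_area,
                 total_area = sum(areas), n_components = max(comp),
                 alpha = alpha),
            class = "alpha_shape")
}

#' @export
print.alpha_shape <- function(x, ...) {
  cat(sprintf("<alpha_shape> alpha = %g: %d points, %d triangles, %d component(s), area = %.1f\n",
              x$alpha, nrow(x$points),
              if (is.null(x$triangles)) 0 else nrow(x$triangles),
              x$n_components, x$total_area))
  invisible(x)
}

#' Locate points in an alpha-shape
#'
#' Returns, for each query point, the component id of the alpha-shape region
#' containing it (boundary counts as inside), or `NA` when outside. A point
#' on a boundary shared by two components reports the lower component id.
#'
#' @param shape an [alpha_shape()].
#' @param points two-column matrix of query x-y coordinates.
#' @return integer vector of component ids (`NA` = outside).
#' @export
locate_points <- function(shape, points) {
  stopifnot(inherits(shape, "alpha_shape"))
  q <- as.matrix(points)[, 1:2, drop = FALSE]
  res <- rep(NA_integer_, nrow(q))
  if (is.null(shape$triangles) || nrow(q) == 0) return(res)
  P <- shape$points
  tri <- shape$triangles
  ord <- order(shape$component)  # lower component ids claim boundary points
  eps <- 1e-9 * max(abs(P), 1)
  for (t in ord) {
    open <- which(is.na(res))
    if (length(open) == 0) break
    a <- P[tri[t, 1], ]; b <- P[tri[t, 2], ]; c <- P[tri[t, 3], ]
    inbox <- q[open, 1] >= min(a[1], b[1], c[1]) - eps &
             q[open, 1] <= max(a[1], b[1], c[1]) + eps &
             q[open, 2] >= min(a[2], b[2], c[2]) - eps &
             q[open, 2] <= max(a[2], b[2], c[2]) + eps
    open <- open[inbox]
    if (length(open) == 0) next
    qx <- q[open, 1]; qy <- q[open, 2]
    d1 <- (b[1] - a[1]) * (qy - a[2]) - (b[2] - a[2]) * (qx - a[1])
    d2 <- (c[1] - b[1]) * (qy - b[2]) - (c[2] - b[2]) * (qx - b[1])
    d3 <- (a[1] - c[1]) * (qy - c[2]) - (a[2] - c[2]) * (qx - c[1])
    scale <- abs((b[1] - a[1]) * (c[2] - a[2]) - (c[1] - a[1]) * (b[2] - a[2]))
    tol <- 1e-9 * max(scale, 1)
    inside <- (d1 >= -tol & d2 >= -tol & d3 >= -tol) |
              (d1 <= tol & d2 <= tol & d3 <= tol)
    res[open[inside]] <- shape$component[t]
  }
  res
}

#' Export alpha-shape polygons as well-known text (WKT)
#'
#' One `POLYGON ((...))` per boundary polygon, or a single
#' `MULTIPOLYGON` when `collapse = TRUE`.
#'
#' @param shape an [alpha_shape()].
#' @param path optional output path; when given, one WKT string per line is
#'   written there.
#' @param collapse emit a single MULTIPOLYGON string.
#' @return character vector of WKT strings (invisibly when `path` is given).
#' @export
shape_wkt <- function(shape, path = NULL, collapse = FALSE) {
  stopifnot(inherits(shape, "alpha_shape"))
  ring <- function(v) {
    v <- rbind(v, v[1, , drop = FALSE])  # close the ring
    paste0("(", paste(sprintf("%.6g %.6g", v[, 1], v[, 2]), collapse = ", "), ")")
  }
  rings <- vapply(shape$polygons, function(p) ring(p$vertices), "")
  out <- if (collapse) {
    if (length(rings) == 0) "MULTIPOLYGON EMPTY"
    else paste0("MULTIPOLYGON (", paste0("(", rings, ")", collapse = ", "), ")")
  } else {
    if (length(rings) == 0) character(0) else paste0("POLYGON (", rings, ")")
  }
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}

#' @export
plot.alpha_shape <- function(x, add = FALSE, col = "grey70", border = "black",
                             pch = 16, cex = 0.4, ...) {
  if (!add) {
    plot(x$points, asp = 1, pch = pch, cex = cex, xlab = "x (um)",
         ylab = "y (um)", ...)
  }
  for (p in x$polygons) {
    graphics::polygon(p$vertices, col = grDevices::adjustcolor(col, 0.3),
                      border = border)
  }
  invisible(x)
}
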
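# Shared fixtures and independent oracles used across the test files.

# Build a small cell_table directly from a marker-value matrix.
make_table <- function(mfi, xy = NULL, sample_id = "test") {
  n <- nrow(mfi)
  if (is.null(xy)) xy <- cbind(seq_len(n) * 10, rep(5, n))
  cells <- data.frame(cell_id = seq_len(n), x = xy[, 1], y = xy[, 2],
                      z = rep(1, n), volume = rep(300, n),
                      sphericity = rep(0.8, n), area = rep(120, n))
  cell_table(cells, mfi, sample_id = sample_id)
}

# Wrap arbitrary labels in an annotation object (through a synthetic sample
# so only exported API is used).
make_annotation <- function(labels, xy = NULL) {
  k <- length(labels)
  mfi <- matrix(rep(1:k, 2), k, 2, dimnames = list(NULL, c("CD45", "CD3")))
  tab <- make_table(mfi, xy = xy)
  ann <- gate_cells(tab, gating_rules(data.frame(label = "x", CD45 = "any",
                                                 CD3 = "any")))
  ann$label <- labels
  attr(ann, "labels") <- unique(labels)
  list(table = tab, annotation = ann)
}

# Independent average-rank computation (counting smaller/equal values), used
# by the Spearman oracle; deliberately avoids base rank().
midranks <- function(x) {
  vapply(x, function(v) sum(x < v) + (sum(x == v) + 1) / 2, numeric(1))
}

# Spearman oracle: Pearson product-moment formula applied to midranks.
oracle_spearman <- function(a, b) {
  ra <- midranks(a); rb <- midranks(b)
  da <- ra - mean(ra); db <- rb - mean(rb)
  sum(da * db) / sqrt(sum(da^2) * sum(db^2))
}

# Brute-force Delaunay triangulation by empty-circumcircle enumeration of
# all point triples (small n only).
oracle_delaunay <- function(pts) {
  n <- nrow(pts)
  out <- NULL
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    a <- pts[i, ]; b <- pts[j, ]; c <- pts[k, ]
    d <- 2 * (a[1] * (b[2] - c[2]) + b[1] * (c[2] - a[2]) + c[1] * (a[2] - b[2]))
    if (abs(d) < 1e-12) next
    ux <- (sum(a^2) * (b[2] - c[2]) + sum(b^2) * (c[2] - a[2]) +
           sum(c^2) * (a[2] - b[2])) / d
    uy <- (sum(a^2) * (c[1] - b[1]) + sum(b^2) * (a[1] - c[1]) +
           sum(c^2) * (b[1] - a[1])) / d
    r2 <- sum((a - c(ux, uy))^2)
    others <- setdiff(seq_len(n), c(i, j, k))
    d2 <- (pts[others, 1] - ux)^2 + (pts[others, 2] - uy)^2
    if (all(d2 >= r2 * (1 - 1e-12))) out <- rbind(out, c(i, j, k))
  }
  out
}

tri_keys <- function(tri) {
  apply(tri, 1, function(t) paste(sort(t), collapse = "-"))
}

# Shoelace area of the polygon over a chull() index cycle.
hull_area <- function(pts) {
  h <- grDevices::chull(pts)
  hp <- pts[h, , drop = FALSE]
  abs(sum(hp[, 1] * c(hp[-1, 2], hp[1, 2]) -
          c(hp[-1, 1], hp[1, 1]) * hp[, 2])) / 2
}

# All-pairs nearest-neighbour scan.
oracle_nn <- function(P, q) {
  d <- sqrt((P[, 1] - q[1])^2 + (P[, 2] - q[2])^2)
  i <- which.min(d)
  c(index = i, distance = d[i])
}

# The zero-noise study condition: both intensity distributions degenerate
# (background exactly 0, positives exactly at their channel scale).
zero_noise_spec <- function(seed = 11) {
  synthetic_spec(
    default_panel("lymphoid"),
    c("B" = 40, "NK" = 40, "CD4 T" = 60, "CD8 T" = 60, "gd T" = 40,
      "dn T" = 30, "dp T" = 30),
    intensity_model = list(negative = c(meanlog = -Inf, sdlog = 0),
                           positive = c(meanlog = log(150), sdlog = 0)),
    seed = seed)
}
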
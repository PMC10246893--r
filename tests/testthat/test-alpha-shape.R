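test_that("alpha = 0 reproduces the convex hull", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  sh <- alpha_shape(sq, 0)
  expect_identical(sh$n_components, 1L)
  expect_length(sh$polygons, 1)
  expect_equal(sh$total_area, 1, tolerance = 1e-12)
  expect_equal(sh$polygons[[1]]$area, 1, tolerance = 1e-12)

  set.seed(31)
  for (i in 1:5) {
    pts <- matrix(runif(2 * 150, 0, 500), ncol = 2)
    sh <- alpha_shape(pts, 0)
    expect_equal(sh$total_area, hull_area(pts), tolerance = 1e-9)
    # every input point lies inside or on the hull
    expect_false(anyNA(locate_points(sh, pts)))
  }
})

test_that("the triangulation matches empty-circumcircle enumeration", {
  set.seed(32)
  for (i in 1:12) {
    n <- sample(6:20, 1)
    pts <- matrix(runif(2 * n, 0, 100), ncol = 2)
    sh <- alpha_shape(pts, 0)
    expect_setequal(tri_keys(sh$triangles), tri_keys(oracle_delaunay(pts)))
  }
})

test_that("alpha filtering matches explicit circumradius filtering", {
  set.seed(33)
  pts <- matrix(runif(2 * 40, 0, 100), ncol = 2)
  alpha <- 0.08
  sh0 <- alpha_shape(pts, 0)
  sh <- alpha_shape(pts, alpha)
  # oracle: filter the full Delaunay triangle set by circumradius <= 1/alpha
  keep <- vapply(seq_len(nrow(sh0$triangles)), function(t) {
    tri <- sh0$triangles[t, ]
    a <- pts[tri[1], ]; b <- pts[tri[2], ]; c <- pts[tri[3], ]
    la <- sqrt(sum((b - c)^2)); lb <- sqrt(sum((a - c)^2)); lc <- sqrt(sum((a - b)^2))
    ar <- abs((b[1] - a[1]) * (c[2] - a[2]) - (c[1] - a[1]) * (b[2] - a[2])) / 2
    la * lb * lc / (4 * ar) <= 1 / alpha
  }, logical(1))
  expect_setequal(tri_keys(sh$triangles), tri_keys(sh0$triangles[keep, , drop = FALSE]))
})

test_that("distant point groups dissolve into disjoint polygons", {
  set.seed(34)
  blob1 <- cbind(runif(30, 0, 20), runif(30, 0, 20))
  blob2 <- cbind(runif(30, 120, 140), runif(30, 0, 20))
  sh <- alpha_shape(rbind(blob1, blob2), alpha = 1 / 30)  # 1/alpha = 30 < 100
  expect_identical(sh$n_components, 2L)
  expect_length(sh$component_areas, 2)
  comp <- locate_points(sh, rbind(blob1, blob2))
  expect_identical(length(unique(comp[1:30])), 1L)
  expect_identical(length(unique(comp[31:60])), 1L)
  expect_false(comp[1] == comp[31])
})

test_that("alpha-shape area is non-increasing in alpha", {
  set.seed(35)
  pts <- matrix(runif(2 * 200, 0, 300), ncol = 2)
  alphas <- c(0, 0.02, 0.05, 0.1, 0.3)
  areas <- vapply(alphas, function(a) alpha_shape(pts, a)$total_area,
                  numeric(1))
  expect_true(all(diff(areas) <= 1e-9))
})

test_that("translation moves polygons rigidly and keeps areas", {
  set.seed(36)
  pts <- matrix(runif(2 * 80, 0, 100), ncol = 2)
  sh1 <- alpha_shape(pts, 0.05)
  shift <- c(1234.5, -678.9)
  sh2 <- alpha_shape(sweep(pts, 2, -shift), 0.05)
  expect_equal(sh2$total_area, sh1$total_area, tolerance = 1e-6)
  expect_identical(sh2$n_components, sh1$n_components)
  expect_equal(sh2$polygons[[1]]$vertices,
               sweep(sh1$polygons[[1]]$vertices, 2, -shift),
               tolerance = 1e-9)
})

test_that("degenerate inputs yield an empty shape with a warning", {
  expect_warning(sh <- alpha_shape(rbind(c(0, 0), c(1, 1)), 0), "fewer than 3")
  expect_identical(sh$n_components, 0L)
  expect_warning(sh2 <- alpha_shape(cbind(1:5, 2 * (1:5)), 0), "collinear")
  expect_identical(sh2$total_area, 0)
  # duplicated points are deduplicated, not fatal
  pts <- rbind(c(0, 0), c(0, 0), c(1, 0), c(0, 1))
  sh3 <- alpha_shape(pts, 0)
  expect_identical(nrow(sh3$points), 3L)
})

test_that("WKT export writes one valid polygon per boundary ring", {
  sq <- rbind(c(0, 0), c(2, 0), c(2, 2), c(0, 2))
  sh <- alpha_shape(sq, 0)
  wkt <- shape_wkt(sh)
  expect_length(wkt, 1)
  expect_match(wkt, "^POLYGON \\(\\(")
  # ring is closed: first and last coordinate pair coincide
  nums <- strsplit(gsub("[A-Z()]", "", wkt), ",")[[1]]
  expect_identical(trimws(nums[1]), trimws(nums[length(nums)]))
  expect_match(shape_wkt(sh, collapse = TRUE), "^MULTIPOLYGON")
})
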
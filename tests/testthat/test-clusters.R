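blob_spec <- function(sizes, seed = 50, sd = 3) {
  centers_x <- 50 + 100 * ((seq_along(sizes) - 1) %% 6)
  centers_y <- 40 + 80 * ((seq_along(sizes) - 1) %/% 6)
  blobs <- lapply(seq_along(sizes), function(k) {
    list(center = c(centers_x[k], centers_y[k]), sd = sd, n = sizes[k])
  })
  synthetic_spec(default_panel("lymphoid"),
                 c("CD4 T" = sum(sizes)),
                 activation_mix = NULL,
                 layout = list(blobs = blobs),
                 seed = seed)
}

test_that("an isolated 14-cell blob is below the membership filter", {
  s <- generate_sample(blob_spec(14))
  rois <- detect_alpha_rois(s$table, truth_annotation(s), alpha = 0.1,
                            min_cells = 15)
  expect_identical(n_rois(rois), 0L)
  expect_length(rois$unclustered, 14)
})

test_that("blob sizes {15, 30, 14} yield exactly two clusters", {
  s <- generate_sample(blob_spec(c(15, 30, 14)))
  rois <- detect_alpha_rois(s$table, truth_annotation(s), alpha = 0.1,
                            min_cells = 15)
  expect_identical(n_rois(rois), 2L)
  expect_setequal(vapply(rois$rois, `[[`, integer(1), "n_cells"), c(15L, 30L))
})

test_that("a 20-cell blob over a sparse background is one exact cluster", {
  spec <- synthetic_spec(default_panel("lymphoid"), c("CD4 T" = 30),
                         activation_mix = NULL,
                         layout = list(blobs = list(
                           list(center = c(300, 200), sd = 3, n = 20))),
                         seed = 51)
  s <- generate_sample(spec)  # 10 cells left as uniform background
  rois <- detect_alpha_rois(s$table, truth_annotation(s), alpha = 0.1,
                            min_cells = 15)
  expect_identical(n_rois(rois), 1L)
  expect_identical(rois$rois[[1]]$n_cells, 20L)
  # membership equals the planted blob cells
  xy <- s$table$cells
  blob_ids <- xy$cell_id[sqrt((xy$x - 300)^2 + (xy$y - 200)^2) < 20]
  expect_setequal(rois$rois[[1]]$member_cell_ids, blob_ids)
})

test_that("cluster statistics are internally consistent", {
  s <- generate_sample(blob_spec(c(20, 25), seed = 52))
  ann <- annotate_cells(s$table, adapt_matrix(default_panel("lymphoid"), s$table))
  rois <- detect_alpha_rois(s$table, ann, alpha = 0.1, min_cells = 15)
  for (r in rois$rois) {
    expect_identical(sum(r$composition$count), r$n_cells)
    expect_equal(sum(r$composition$proportion), 1, tolerance = 1e-9)
    expect_identical(length(r$member_cell_ids), r$n_cells)
    expect_gt(r$area, 0)
    # every member lies inside or on the cluster region
    idx <- match(r$member_cell_ids, s$table$cells$cell_id)
    comp <- locate_points(rois$shape, as.matrix(s$table$cells[idx, c("x", "y")]))
    expect_false(anyNA(comp))
    # centroid is the unweighted member mean
    expect_equal(unname(r$center),
                 c(mean(s$table$cells$x[idx]), mean(s$table$cells$y[idx])),
                 tolerance = 1e-9)
  }
})

test_that("lowering min_cells never loses clusters and reruns are identical", {
  s <- generate_sample(blob_spec(c(5, 12, 18, 24), seed = 53))
  ta <- truth_annotation(s)
  n15 <- n_rois(detect_alpha_rois(s$table, ta, alpha = 0.1, min_cells = 15))
  n10 <- n_rois(detect_alpha_rois(s$table, ta, alpha = 0.1, min_cells = 10))
  n3 <- n_rois(detect_alpha_rois(s$table, ta, alpha = 0.1, min_cells = 3))
  expect_true(n3 >= n10 && n10 >= n15)
  r1 <- detect_alpha_rois(s$table, ta, alpha = 0.1, min_cells = 15)
  r2 <- detect_alpha_rois(s$table, ta, alpha = 0.1, min_cells = 15)
  expect_identical(lapply(r1$rois, `[[`, "member_cell_ids"),
                   lapply(r2$rois, `[[`, "member_cell_ids"))
})

test_that("cluster summaries report density per chosen denominator", {
  s <- generate_sample(blob_spec(c(20, 20, 20, 20), seed = 54))
  ta <- truth_annotation(s)
  rois <- detect_alpha_rois(s$table, ta, alpha = 0.1, min_cells = 15)
  expect_identical(n_rois(rois), 4L)
  sm <- roi_summary(rois, area_mm2 = 2)
  expect_equal(sm$density, 2)
  expect_identical(sm$denominator, "per_mm2")
  agg <- tapply(sm$composition$proportion, sm$composition$roi_id, sum)
  expect_equal(unname(as.numeric(agg)), rep(1, 4), tolerance = 1e-9)
  expect_error(roi_summary(rois, area_mm2 = 0), "positive")
  expect_error(roi_summary(rois), "exactly one")
  # empty set: density zero, not an error
  s2 <- generate_sample(blob_spec(5, seed = 55))
  r0 <- detect_alpha_rois(s2$table, truth_annotation(s2), min_cells = 15)
  expect_equal(roi_summary(r0, volume_mm3 = 0.0048)$density, 0)
})

test_that("cluster tables export one proportion column per label", {
  s <- generate_sample(blob_spec(c(18, 22), seed = 56))
  ann <- annotate_cells(s$table, adapt_matrix(default_panel("lymphoid"), s$table))
  rois <- detect_alpha_rois(s$table, ann, alpha = 0.1, min_cells = 15)
  path <- withr::local_tempfile(fileext = ".csv")
  write_roi_table(rois, path)
  out <- read.csv(path, check.names = FALSE)
  expect_identical(nrow(out), 2L)
  lab_cols <- setdiff(names(out), c("roi_id", "area_um2", "n_cells",
                                    "center_x", "center_y"))
  expect_true(all(attr(ann, "labels") %in% lab_cols))
  expect_equal(unname(rowSums(out[, lab_cols])), rep(1, 2), tolerance = 1e-9)
})
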
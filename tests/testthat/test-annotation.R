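test_that("dynamic adaptation replaces ones with per-channel maxima", {
  mfi <- matrix(c(812.5, 100, 3, 40, 7, 2), 2, 3,
                dimnames = list(NULL, c("CD3", "CD20", "CD45")))
  tab <- make_table(mfi)
  sig <- matrix(c(1L, 0L, 1L, 0L, 1L, 1L), 3, 2,
                dimnames = list(c("CD3", "CD20", "CD45"), NULL))
  m <- attribution_matrix(sig, labels = c("T", "B"))
  ad <- adapt_matrix(m, tab)
  # brute-force column maxima by direct scan
  expect_equal(unname(ad$max_mfi), c(812.5, 40, 7))
  expect_equal(unname(ad$values[, 1]), c(812.5, 0, 7))
  expect_equal(unname(ad$values[, 2]), c(0, 40, 7))
})

test_that("adaptation flags degenerate markers and empty tables", {
  mfi <- matrix(c(5, 2, 0, 0), 2, 2, dimnames = list(NULL, c("CD45", "CD3")))
  tab <- make_table(mfi)
  sig <- matrix(c(1L, 1L), 2, 1, dimnames = list(c("CD45", "CD3"), NULL))
  m <- attribution_matrix(sig, labels = "T")
  expect_warning(adapt_matrix(m, tab), "degenerate")
})

test_that("spearman_rho matches the rank-formula oracle to 1e-12", {
  expect_equal(spearman_rho(c(1, 5, 9), c(1, 5, 9)), 1)
  expect_equal(spearman_rho(c(1, 5, 9), c(9, 5, 1)), -1)
  expect_true(is.na(spearman_rho(c(2, 2, 2), c(1, 2, 3))))
  expect_error(spearman_rho(1:3, 1:4), "mismatch")
  set.seed(101)
  for (i in 1:200) {
    a <- sample(0:4, 6, replace = TRUE) + ifelse(i %% 2 == 0, 0, runif(6))
    b <- sample(0:4, 6, replace = TRUE) + runif(6) * (i %% 3)
    if (sd(a) == 0 || sd(b) == 0) next
    expect_equal(spearman_rho(a, b), oracle_spearman(a, b), tolerance = 1e-12)
  }
})

test_that("a perfect-signature cell gets its column's label with rho 1", {
  lym <- default_panel("lymphoid")
  # cell 1's MFI vector equals the adapted B column exactly; cell 2 keeps
  # every channel maximum positive so no column degenerates
  base <- matrix(c(100, 80, 0, 0, 0, 0, 0,
                   100, 1, 50, 40, 30, 20, 10), 2, 7, byrow = TRUE,
                 dimnames = list(NULL, lym$markers))
  tab <- make_table(base)
  ad <- adapt_matrix(lym, tab)
  ann <- annotate_cells(tab, ad)
  expect_identical(ann$label[1], "B")
  expect_equal(ann$rho_best[1], 1)
  expect_false(ann$tied[1])
})

test_that("exact ties across labels and constant cells sink to Other", {
  mk <- c("CD45", "CD3", "CD20")
  sig <- matrix(c(1L, 0L, 0L, 0L, 0L, 1L), 3, 2, dimnames = list(mk, NULL))
  m <- attribution_matrix(sig, labels = c("A", "B"))
  mfi <- matrix(c(10, 5, 10,   # mirror-symmetric: exact tie A vs B
                  20, 5, 1,    # clear A
                  7, 7, 7),    # constant vector: rho undefined
                3, 3, byrow = TRUE, dimnames = list(NULL, mk))
  tab <- make_table(mfi)
  ann <- annotate_cells(tab, adapt_matrix(m, tab))
  expect_identical(ann$label[1], "Other")
  expect_true(ann$tied[1])
  expect_equal(ann$rho_best[1], ann$rho_runner_up[1])
  expect_identical(ann$label[2], "A")
  expect_identical(ann$label[3], "Other")
  expect_true(is.na(ann$rho_best[3]))
})

test_that("tie between variant columns of the same label is not ambiguous", {
  lym <- default_panel("lymphoid")
  suite <- generate_benchmark_suite(5)
  s <- generate_sample(suite$lymphoid$spec)
  ann <- annotate_cells(s$table, adapt_matrix(lym, s$table))
  # gd T has two CD4 variants; gd T cells must not be flagged tied en masse
  gd <- s$truth$label == "gd T"
  expect_gt(mean(ann$label[gd] == "gd T"), 0.9)
})

test_that("annotation agrees with a per-cell brute-force argmax oracle", {
  suite <- generate_benchmark_suite(2)
  s <- generate_sample(suite$lymphoid$spec)
  sub <- 1:200
  lym <- default_panel("lymphoid")
  ad <- adapt_matrix(lym, s$table)
  ann <- annotate_cells(s$table, ad)
  oracle_label <- vapply(sub, function(i) {
    rho <- vapply(seq_along(ad$column_id), function(j) {
      suppressWarnings(cor(s$table$mfi[i, ad$markers], ad$values[, j],
                           method = "spearman"))
    }, numeric(1))
    rho <- signif(rho, 12)
    per_label <- tapply(rho, ad$labels, max, na.rm = TRUE)
    best <- max(per_label)
    winners <- names(per_label)[per_label == best]
    if (length(winners) > 1) "Other" else winners
  }, character(1))
  expect_identical(ann$label[sub], oracle_label)
})

test_that("annotation is rank-invariant to positive rescaling of a cell", {
  suite <- generate_benchmark_suite(3)
  s <- generate_sample(suite$lymphoid$spec)
  lym <- default_panel("lymphoid")
  ad <- adapt_matrix(lym, s$table)
  ann1 <- annotate_cells(s$table, ad)
  scaled <- s$table
  scaled$mfi <- scaled$mfi * 37.5
  ann2 <- annotate_cells(scaled, ad)
  expect_identical(ann1$label, ann2$label)
  expect_equal(ann1$rho_best, ann2$rho_best)
})

test_that("permuting cell order permutes labels identically", {
  suite <- generate_benchmark_suite(4)
  s <- generate_sample(suite$lymphoid$spec)
  lym <- default_panel("lymphoid")
  ann1 <- annotate_cells(s$table, adapt_matrix(lym, s$table))
  set.seed(9)
  perm <- sample(n_cells(s$table))
  tab2 <- s$table
  tab2$cells <- tab2$cells[perm, ]
  tab2$mfi <- tab2$mfi[perm, , drop = FALSE]
  ann2 <- annotate_cells(tab2, adapt_matrix(lym, tab2))
  expect_identical(ann2$label, ann1$label[perm])
})

test_that("every cell gets exactly one label and counts are conserved", {
  suite <- generate_benchmark_suite(6)
  s <- generate_sample(suite$myeloid$spec)
  ann <- annotate_cells(s$table, adapt_matrix(default_panel("myeloid"), s$table))
  expect_identical(nrow(ann), n_cells(s$table))
  expect_identical(sum(table(ann$label)), n_cells(s$table))
  expect_true(all(ann$label == "Other" | !ann$tied))
  both <- !is.na(ann$rho_best) & !is.na(ann$rho_runner_up)
  expect_true(all(ann$rho_best[both] >= ann$rho_runner_up[both]))
})
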
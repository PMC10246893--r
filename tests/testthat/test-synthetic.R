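test_that("the same spec and seed reproduce byte-identical samples", {
  spec <- synthetic_spec(subset_counts = c("B" = 30, "NK" = 20, "dn T" = 10),
                         epidermis_band = c(360, 400), seed = 77)
  s1 <- generate_sample(spec)
  s2 <- generate_sample(spec)
  expect_identical(s1$table, s2$table)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$contour, s2$contour)
  # and the generator does not disturb the caller's RNG stream
  set.seed(1); before <- rnorm(1)
  set.seed(1); invisible(generate_sample(spec)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("subset counts are honoured exactly", {
  counts <- c("B" = 200, "NK" = 300, "CD4 T" = 400, "CD8 T" = 327)
  s <- generate_sample(synthetic_spec(subset_counts = counts, seed = 5))
  expect_identical(n_cells(s$table), 1227L)
  expect_identical(as.integer(table(s$truth$label)[names(counts)]),
                   unname(as.integer(counts)))
})

test_that("positive marker intensities stochastically dominate background", {
  s <- generate_sample(synthetic_spec(
    subset_counts = c("B" = 1000, "dn T" = 1000), seed = 6))
  pos <- s$table$mfi[s$truth$label == "B", "CD20"]
  neg <- s$table$mfi[s$truth$label == "dn T", "CD20"]
  w <- wilcox.test(pos, neg, alternative = "greater")
  expect_lt(w$p.value, 1e-6)
})

test_that("ground truth is recoverable by gating at 4-sdlog separation", {
  suite <- generate_benchmark_suite(12)
  s <- generate_sample(suite$lymphoid$spec)
  g <- gate_cells(s$table, default_gating("lymphoid"), suite$lymphoid$thresholds)
  expect_gte(mean(g$label == s$truth$label), 0.99)
})

test_that("planted activation fractions are exact by construction", {
  spec <- synthetic_spec(subset_counts = c("CD4 T" = 500),
                         activation_mix = data.frame(label = "CD4 T",
                                                     marker = "CD57",
                                                     high_fraction = 0.3),
                         seed = 8)
  s <- generate_sample(spec)
  expect_identical(sum(s$truth$activation == "high"), 150L)
  expect_setequal(unique(s$truth$final_label),
                  c("CD4 T CD57low", "CD4 T CD57high"))
})

test_that("infeasible layouts are rejected", {
  expect_error(synthetic_spec(subset_counts = c("B" = 10),
                              layout = list(blobs = list(
                                list(center = c(900, 100), sd = 3, n = 5)))),
               "infeasible")
  spec <- synthetic_spec(subset_counts = c("B" = 4),
                         layout = list(blobs = list(
                           list(center = c(100, 100), sd = 3, n = 10))))
  expect_error(generate_sample(spec), "infeasible")
})

test_that("the benchmark suite is reproducible and matches its contract", {
  s1 <- generate_benchmark_suite(99)
  s2 <- generate_benchmark_suite(99)
  expect_identical(lapply(s1, `[[`, "spec"), lapply(s2, `[[`, "spec"))
  expect_setequal(names(s1), c("lymphoid", "myeloid", "activation",
                               "roi_sweep", "epidermis"))
  # ~1200 cells across both panels, spanning every base subset
  n_lym <- sum(s1$lymphoid$spec$subset_counts)
  n_mye <- sum(s1$myeloid$spec$subset_counts)
  expect_identical(n_lym + n_mye, 1227)
  expect_length(s1$lymphoid$spec$subset_counts, 7)
  expect_length(s1$myeloid$spec$subset_counts, 7)
  # filter sweep: blob sizes exactly 1..30, separations > 10 x blob sd
  sizes <- vapply(s1$roi_sweep$spec$layout$blobs, `[[`, numeric(1), "n")
  expect_identical(as.integer(sizes), 1:30)
  centers <- t(vapply(s1$roi_sweep$spec$layout$blobs, `[[`, numeric(2),
                      "center"))
  expect_gt(min(dist(centers)), 10 * s1$roi_sweep$blob_sd)
})

test_that("zero-noise samples are annotated perfectly", {
  s <- generate_sample(zero_noise_spec(13))
  ann <- annotate_cells(s$table, adapt_matrix(default_panel("lymphoid"),
                                              s$table))
  expect_identical(mean(ann$label == s$truth$label), 1)
})
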
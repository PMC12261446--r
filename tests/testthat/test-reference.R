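test_that("generation is bitwise-reproducible given (config, seed)", {
  cfg <- reference_config(n_cells = 100, n_genes = 60, n_peaks = 80,
                          n_cell_types = 3, markers_per_type = 5)
  a <- generate_reference(cfg, seed = 42)
  b <- generate_reference(cfg, seed = 42)
  expect_identical(as.matrix(rna_counts(a)), as.matrix(rna_counts(b)))
  expect_identical(as.matrix(atac_counts(a)), as.matrix(atac_counts(b)))
  expect_identical(cell_types(a), cell_types(b))
  c <- generate_reference(cfg, seed = 43)
  expect_false(identical(as.matrix(rna_counts(a)),
                         as.matrix(rna_counts(c))))
})

test_that("counts are nonnegative integers and dimensions are coherent", {
  ref <- small_reference()
  for (m in list(rna_counts(ref), atac_counts(ref))) {
    expect_true(all(m@x >= 0))
    expect_identical(m@x, floor(m@x))
    expect_equal(ncol(m), 200)
  }
  expect_length(cell_types(ref), 200)
  expect_gte(length(unique(cell_types(ref))), 2)
})

test_that("marker fold change is recovered from generated counts", {
  cfg <- reference_config(n_cells = 3000, n_genes = 300, n_peaks = 300,
                          n_cell_types = 12, markers_per_type = 10,
                          marker_fold_change = 8, library_size_sigma = 0)
  ref <- generate_reference(cfg, seed = 5)
  labels <- cell_types(ref)
  marker_of <- SummarizedExperiment::rowData(ref)$marker_type
  rna <- rna_counts(ref)
  ratios <- vapply(sort(unique(labels)), function(t) {
    own <- Matrix::rowMeans(rna[which(marker_of == t),
                                labels == t, drop = FALSE])
    bg <- Matrix::rowMeans(rna[which(is.na(marker_of)),
                               labels == t, drop = FALSE])
    mean(own) / mean(bg)
  }, numeric(1))
  expect_true(all(ratios > 1))
  expect_equal(mean(ratios), 8, tolerance = 0.1)
})

test_that("fold change 1 leaves marker genes indistinguishable", {
  cfg <- reference_config(n_cells = 2000, n_genes = 200, n_peaks = 200,
                          n_cell_types = 4, markers_per_type = 10,
                          marker_fold_change = 1, library_size_sigma = 0)
  ref <- generate_reference(cfg, seed = 6)
  labels <- cell_types(ref)
  marker_of <- SummarizedExperiment::rowData(ref)$marker_type
  rna <- rna_counts(ref)
  own <- as.numeric(rna[which(marker_of == "type01"), labels == "type01"])
  other <- as.numeric(rna[which(marker_of == "type01"),
                          labels == "type02"])
  # two-sample mean difference within Monte-Carlo error
  expect_gt(t.test(own, other)$p.value, 1e-4)
})

test_that("method-of-moments recovers overdispersion and size spread", {
  cfg <- reference_config(n_cells = 3000, n_genes = 200, n_peaks = 100,
                          n_cell_types = 2, markers_per_type = 1,
                          marker_fold_change = 1, baseline_rna_mean = 5,
                          rna_overdispersion = 2, library_size_sigma = 0)
  ref <- generate_reference(cfg, seed = 8)
  rna <- rna_counts(ref)
  mu <- Matrix::rowMeans(rna)
  v <- apply(as.matrix(rna), 1, var)
  theta_hat <- mu^2 / (v - mu)
  expect_equal(median(theta_hat), 2, tolerance = 0.15)

  cfg2 <- reference_config(n_cells = 3000, n_genes = 200, n_peaks = 100,
                           n_cell_types = 2, markers_per_type = 1,
                           marker_fold_change = 1, baseline_rna_mean = 5,
                           rna_overdispersion = 50,
                           library_size_sigma = 0.4)
  ref2 <- generate_reference(cfg2, seed = 9)
  depth <- Matrix::colSums(rna_counts(ref2))
  expect_equal(sd(log(depth)), 0.4, tolerance = 0.12)
})

test_that("lowering baseline means increases sparsity", {
  mk <- function(base) generate_reference(
    reference_config(n_cells = 300, n_genes = 150, n_peaks = 150,
                     n_cell_types = 3, markers_per_type = 5,
                     baseline_rna_mean = base,
                     baseline_atac_mean = base), seed = 3)
  zfrac <- function(m) 1 - length(m@x) / prod(dim(m))
  hi <- mk(2); lo <- mk(0.2)
  expect_gt(zfrac(rna_counts(lo)), zfrac(rna_counts(hi)))
  expect_gt(zfrac(atac_counts(lo)), zfrac(atac_counts(hi)))
})

test_that("invalid configurations are rejected", {
  expect_error(reference_config(n_cells = 0), "positive integer")
  expect_error(reference_config(n_cells = 100, n_genes = 20,
                                n_cell_types = 5, markers_per_type = 10),
               "marker allocation")
  expect_error(reference_config(marker_fold_change = -1), "positive")
  expect_error(reference_config(n_cell_types = 1), "at least 2")
  expect_error(reference_config(cell_type_props = c(0.5, 0.5)),
               "cell_type_props")
})

test_that("unbalanced cell-type proportions are honoured", {
  cfg <- reference_config(n_cells = 200, n_genes = 60, n_peaks = 80,
                          n_cell_types = 2, markers_per_type = 5,
                          cell_type_props = c(0.8, 0.2))
  tab <- table(cell_types(generate_reference(cfg, seed = 1)))
  expect_equal(as.integer(tab), c(160, 40))
})

test_that("targeted layouts place cells as configured", {
  unif <- small_targeted(layout = "uniform")
  xy <- spatial_coords(unif)
  expect_true(all(xy >= 0 & xy <= 1))
  # per-type coordinate means statistically equal under uniform layout
  fit <- summary(aov(xy[, 1] ~ factor(cell_types(unif))))
  expect_gt(fit[[1]][["Pr(>F)"]][1], 1e-4)

  centers <- rbind(c(0.1, 0.1), c(0.9, 0.9), c(0.5, 0.5))
  clus <- small_targeted(layout = "clustered", centers = centers,
                         dispersion = 0.02)
  cxy <- spatial_coords(clus)
  types <- sort(unique(cell_types(clus)))
  for (i in seq_along(types)) {
    mu <- colMeans(cxy[cell_types(clus) == types[i], , drop = FALSE])
    expect_equal(unname(mu), unname(centers[i, ]), tolerance = 0.02)
  }
  # degenerate limit: zero dispersion puts every cell at its center
  degen <- small_targeted(layout = "clustered", centers = centers,
                          dispersion = 0)
  dxy <- spatial_coords(degen)
  expect_equal(unname(dxy[cell_types(degen) == types[1], ][1, ]),
               c(0.1, 0.1))
  expect_equal(max(abs(dxy - centers[match(cell_types(degen), types), ])),
               0)
})

test_that("reference expansion is nested with exact sizes", {
  cfg <- reference_config(n_cells = 900, n_genes = 40, n_peaks = 50,
                          n_cell_types = 3, markers_per_type = 5)
  pool <- generate_reference(cfg, seed = 2)
  base <- pool[, 1:50]
  series <- expand_reference_series(base, pool, factors = c(2, 4, 8, 16),
                                    seed = 4)
  expect_equal(unname(vapply(series, ncol, 1L)), c(100, 200, 400, 800))
  ids <- lapply(series, colnames)
  for (i in 2:4) expect_true(all(ids[[i - 1]] %in% ids[[i]]))
  for (id in ids) expect_false(anyDuplicated(id) > 0)
  # factor 1 returns the base unchanged
  expect_identical(expand_reference_series(base, pool, factors = 1)[[1]],
                   base)
  expect_error(expand_reference_series(base, pool, factors = 32),
               "pool has only")
})
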
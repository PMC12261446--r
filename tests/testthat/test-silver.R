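test_that("the spot grid covers the unit square with exact counts", {
  g4 <- lay_spot_grid(4)
  expect_equal(nrow(g4), 4)
  expect_setequal(unique(g4[, "x"]), c(0.25, 0.75))
  expect_setequal(unique(g4[, "y"]), c(0.25, 0.75))
  # 5 spots on a 3-column grid: bottom row full, second row partial
  g5 <- lay_spot_grid(5)
  expect_equal(nrow(g5), 5)
  expect_equal(sum(g5[, "y"] == g5[1, "y"]), 3)
  expect_equal(sum(g5[, "y"] != g5[1, "y"]), 2)
  g1000 <- lay_spot_grid(1000)
  expect_equal(nrow(g1000), 1000)
  expect_true(all(g1000 >= 0 & g1000 <= 1))
})

test_that("zone assignment follows the documented geometries", {
  g <- lay_spot_grid(1000)
  expect_identical(assign_zones(g, "uniform", 1), integer(1000))
  z <- assign_zones(g, "stripes", 4)
  expect_setequal(unique(z), 0:3)
  counts <- table(z)
  # each band holds 250 spots give or take one grid column
  expect_true(all(abs(counts - 250) <= ceiling(sqrt(1000))))
  # agreement with direct x-binning
  expect_identical(z, pmin(as.integer(floor(g[, "x"] * 4)), 3L))

  zc <- assign_zones(g, "circles", 4)
  expect_true(all(zc %in% 0:3))
  expect_gt(sum(zc == 0), 0)
  # discs sit on the diagonal: spots at the centers get the disc label
  centers <- cbind(c(0.25, 0.5, 0.75), c(0.25, 0.5, 0.75))
  expect_identical(assign_zones(centers, "circles", 4), 1:3)
  # degenerate radius: everything is background
  expect_identical(assign_zones(g, "circles", 4, radius = 0),
                   integer(1000))
  expect_error(assign_zones(g, "stripes", 1), "n_regions")
})

test_that("spot membership honours type counts and allocation rules", {
  ref <- small_reference()
  m1 <- sample_spot_members(ref, k_types = 1, n_cells = 6, seed = 1)
  labels <- cell_types(ref)[match(m1, colnames(ref))]
  expect_length(m1, 6)
  expect_equal(length(unique(labels)), 1)

  # pigeonhole: k types and k cells means exactly one cell per type
  m3 <- sample_spot_members(ref, k_types = 3, n_cells = 3, seed = 2)
  labels3 <- cell_types(ref)[match(m3, colnames(ref))]
  expect_equal(sort(table(labels3))[[1]], 1)
  expect_equal(length(unique(labels3)), 3)

  expect_error(sample_spot_members(ref, k_types = 9, n_cells = 5),
               "between 1 and")
})

test_that("type pairs are chosen uniformly over combinations", {
  ref <- small_reference(n_cells = 120, n_types = 4)
  pairs <- replicate(3000, {
    m <- sample_spot_members(ref, k_types = 2, n_cells = 2)
    paste(sort(unique(cell_types(ref)[match(m, colnames(ref))])),
          collapse = "+")
  })
  tab <- table(pairs)
  expect_length(tab, choose(4, 2))
  expect_gt(chisq.test(tab)$p.value, 1e-4)
})

test_that("spot counts are the exact sum of member-cell profiles", {
  ref <- small_reference()
  spots <- simulate_spots(ref, simulation_config(n_spots = 30), seed = 3)
  mem <- member_cells(spots)
  for (s in c(1, 7, 30)) {
    idx <- match(mem[[s]], colnames(ref))
    expect_identical(as.numeric(rna_counts(spots)[, s]),
                     unname(Matrix::rowSums(rna_counts(ref)[, idx,
                                                            drop = FALSE])))
    expect_identical(as.numeric(atac_counts(spots)[, s]),
                     unname(Matrix::rowSums(atac_counts(ref)[, idx,
                                                             drop = FALSE])))
  }
  # global conservation per modality
  all_idx <- match(unlist(mem), colnames(ref))
  expect_equal(sum(rna_counts(spots)),
               sum(Matrix::colSums(rna_counts(ref))[all_idx]))
  expect_equal(sum(atac_counts(spots)),
               sum(Matrix::colSums(atac_counts(ref))[all_idx]))
})

test_that("true proportions are member-type frequencies summing to 1", {
  ref <- small_reference()
  spots <- simulate_spots(ref, simulation_config(n_spots = 25), seed = 4)
  p <- true_proportions(spots)
  expect_equal(unname(rowSums(p)), rep(1, 25), tolerance = 1e-12)
  mem <- member_cells(spots)
  labels <- cell_types(ref)
  for (s in c(2, 25)) {
    tab <- table(factor(labels[match(mem[[s]], colnames(ref))],
                        levels = colnames(p)))
    expect_equal(unname(p[s, ]), as.numeric(tab) / length(mem[[s]]))
  }
})

test_that("per-spot composition follows the clamped Poisson-Gamma law", {
  ref <- generate_reference(
    reference_config(n_cells = 1200, n_genes = 50, n_peaks = 60,
                     n_cell_types = 12, markers_per_type = 4), seed = 10)
  spots <- simulate_spots(ref, simulation_config(n_spots = 1000,
                                                 mean_cell_types = 3,
                                                 mean_cells = 5), seed = 1)
  cd <- SummarizedExperiment::colData(spots)
  n_cells <- cd$n_cells
  n_types <- cd$n_types
  m_cells <- nb_clamp_mean_oracle(5, 20, lower = 1)
  m_types <- nb_clamp_mean_oracle(3, 20, lower = 1, upper = 12)
  expect_lt(abs(mean(n_cells) - m_cells),
            3 * sd(n_cells) / sqrt(1000) + 1e-12)
  expect_lt(abs(mean(n_types) - m_types),
            3 * sd(n_types) / sqrt(1000) + 1e-12)
  # a spot never holds fewer cells than distinct types
  expect_true(all(n_cells >= n_types))
})

test_that("zonated simulations differ across zones as configured", {
  ref <- small_reference(n_cells = 600, n_types = 12)
  cfg <- simulation_config(n_spots = 400, zonation = "stripes",
                           n_regions = 4,
                           mean_cell_types = c(10, 5, 10, 5),
                           mean_cells = c(15, 10, 15, 5))
  spots <- simulate_spots(ref, cfg, seed = 6)
  cd <- SummarizedExperiment::colData(spots)
  expect_setequal(unique(cd$zone), 0:3)
  mean_by_zone <- tapply(cd$n_cells, cd$zone, mean)
  expect_gt(mean_by_zone[["0"]], mean_by_zone[["3"]])
  expect_gt(mean_by_zone[["2"]], mean_by_zone[["3"]])
  types_by_zone <- tapply(cd$n_types, cd$zone, mean)
  expect_gt(types_by_zone[["0"]], types_by_zone[["1"]])
})

test_that("silver simulation is seed-deterministic and prefix-stable", {
  ref <- small_reference()
  a <- simulate_spots(ref, simulation_config(n_spots = 20), seed = 5)
  b <- simulate_spots(ref, simulation_config(n_spots = 20), seed = 5)
  expect_identical(as.matrix(rna_counts(a)), as.matrix(rna_counts(b)))
  expect_identical(member_cells(a), member_cells(b))
  # adding spots does not perturb the earlier ones
  big <- simulate_spots(ref, simulation_config(n_spots = 35), seed = 5)
  expect_identical(member_cells(big)[1:20], member_cells(a))
})

test_that("a single-type reference yields one-hot proportions", {
  ref <- small_reference()
  one <- ref[, cell_types(ref) == "type01"]
  spots <- suppressMessages(
    simulate_spots(one, simulation_config(n_spots = 10), seed = 7))
  p <- true_proportions(spots)
  expect_true(all(p[, "type01"] == 1))
})
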
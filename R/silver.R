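#' Configuration of a silver-standard spot simulation
#'
#' A silver-standard dataset is simulated from a dissociated single-cell
#' reference: per spot, the number of distinct cell types (tissue
#' heterogeneity) and the number of cells (spot density) are drawn from a
#' Poisson-Gamma -- i.e. negative binomial -- distribution with the region's
#' configured mean and a shared overdispersion shape `theta` (variance
#' `mu + mu^2 / theta`).  Composition can vary spatially ("zonation"):
#' `"uniform"` uses one region, `"stripes"` splits the unit square into
#' equal-width vertical bands, and `"circles"` places discs along the
#' square's diagonal with a background region.
#'
#' @param n_spots number of spots, laid on a near-square grid.
#' @param zonation `"uniform"`, `"stripes"` or `"circles"`.
#' @param n_regions number of composition regions (1 for uniform).
#' @param mean_cell_types per-region mean number of distinct cell types
#'   per spot (length `n_regions`, recycled if scalar).
#' @param mean_cells per-region mean number of cells per spot.
#' @param overdispersion Poisson-Gamma shape `theta`; default 20.
#' @return A validated list of class `"simulation_config"`.
#' @seealso [simulate_spots()], [silver_presets()]
#' @export
simulation_config <- function(n_spots = 1000,
                              zonation = c("uniform", "stripes", "circles"),
                              n_regions = 1,
                              mean_cell_types = 3,
                              mean_cells = 5,
                              overdispersion = 20) {
  zonation <- match.arg(zonation)
  if (n_spots < 1 || n_spots != floor(n_spots)) {
    stop("'n_spots' must be a positive integer")
  }
  if (zonation == "uniform" && n_regions != 1) {
    stop("uniform zonation requires n_regions = 1")
  }
  if (zonation != "uniform" && n_regions < 2) {
    stop("zonated simulations require n_regions >= 2")
  }
  recycle <- function(v, name) {
    if (length(v) == 1) v <- rep(v, n_regions)
    if (length(v) != n_regions) {
      stop("'", name, "' must have length n_regions (", n_regions, ")")
    }
    if (any(v <= 0)) stop("'", name, "' must be positive")
    v
  }
  .assert_positive_scalar(overdispersion, "overdispersion")
  structure(list(
    n_spots = as.integer(n_spots), zonation = zonation,
    n_regions = as.integer(n_regions),
    mean_cell_types = recycle(mean_cell_types, "mean_cell_types"),
    mean_cells = recycle(mean_cells, "mean_cells"),
    overdispersion = overdispersion
  ), class = "simulation_config")
}

#' Standard silver-standard parameter sets
#'
#' The four stock simulation designs used throughout the package: two
#' uniform designs probing sparse versus dense, homogeneous versus
#' heterogeneous spots (means of 3 types / 5 cells and 10 types / 15
#' cells), and two four-region zonated designs mixing those regimes across
#' stripes.  All use 1000 spots and overdispersion 20.
#'
#' @return Named list of [simulation_config()] objects:
#'   `sparse_uniform`, `dense_uniform`, `zonated_dense_mix`,
#'   `zonated_sparse_mix`.
#' @export
silver_presets <- function() {
  list(
    sparse_uniform = simulation_config(1000, "uniform", 1, 3, 5),
    dense_uniform = simulation_config(1000, "uniform", 1, 10, 15),
    zonated_dense_mix = simulation_config(1000, "stripes", 4,
                                          c(10, 5, 10, 5),
                                          c(15, 10, 15, 5)),
    zonated_sparse_mix = simulation_config(1000, "stripes", 4,
                                           c(3, 5, 3, 5),
                                           c(15, 10, 15, 5))
  )
}

#' Sample clamped Poisson-Gamma composition sizes
#'
#' Draws `n` variates from a negative binomial with mean `mean` and shape
#' `overdispersion` (the Poisson-Gamma mixture), then clamps each draw into
#' `[lower, upper]`.  Clamping rather than rejection keeps the mean bias
#' small and analytically tractable: with `lower = 1` the expectation is
#' `mean + P(X = 0)`.
#'
#' Draws are generated by inverting the negative binomial CDF on uniform
#' quantiles, so passing the same `quantiles` to two calls with different
#' means yields comonotone (rank-coupled) samples -- used by
#' [simulate_spots()] to guarantee a spot never has fewer cells than
#' distinct cell types without biasing either marginal.
#'
#' @param n number of draws.
#' @param mean positive negative binomial mean.
#' @param overdispersion shape `theta` (> 0); variance is
#'   `mean + mean^2 / overdispersion`.
#' @param lower,upper clamp bounds; `lower >= 1`, `upper = NULL` for none.
#' @param seed optional integer seed; `NULL` uses the current RNG stream.
#' @param quantiles optional vector of `n` uniforms overriding the RNG.
#' @return integer vector of length `n`.
#' @examples
#' x <- sample_composition_size(1e4, mean = 5, overdispersion = 20, seed = 1)
#' mean(x)  # ~ 5 + 0.8^20
#' @export
sample_composition_size <- function(n, mean, overdispersion = 20,
                                    lower = 1L, upper = NULL,
                                    seed = NULL, quantiles = NULL) {
  .assert_positive_scalar(mean, "mean")
  .assert_positive_scalar(overdispersion, "overdispersion")
  if (lower < 1) stop("'lower' must be >= 1")
  if (!is.null(upper) && upper < lower) stop("'upper' must be >= 'lower'")
  u <- if (is.null(quantiles)) with_seed(seed, runif(n)) else {
    stopifnot(length(quantiles) == n)
    quantiles
  }
  x <- qnbinom(u, mu = mean, size = overdispersion)
  x <- pmax(x, lower)
  if (!is.null(upper)) x <- pmin(x, upper)
  as.integer(x)
}

# Closed-form mean of the clamped negative binomial, by pmf summation.
# Test oracle and documentation aid for the clamp bias.
clamped_nb_mean <- function(mean, overdispersion, lower = 1L,
                            upper = NULL) {
  kmax <- max(qnbinom(1 - 1e-12, mu = mean, size = overdispersion),
              if (is.null(upper)) 0 else upper) + 10
  k <- 0:kmax
  p <- dnbinom(k, mu = mean, size = overdispersion)
  v <- pmax(k, lower)
  if (!is.null(upper)) v <- pmin(v, upper)
  sum(p * v) + (1 - sum(p)) * if (is.null(upper)) kmax else upper
}

#' Lay spots on a regular grid over the unit square
#'
#' Places `n_spots` spot centers on a near-square grid: `ceiling(sqrt(n))`
#' columns, rows filled left-to-right bottom-to-top, the last row possibly
#' partial.  Deterministic.
#'
#' @param n_spots number of spots.
#' @return `n_spots` x 2 matrix of (x, y) centers in `[0, 1]^2`.
#' @export
lay_spot_grid <- function(n_spots) {
  if (n_spots < 1 || n_spots != floor(n_spots)) {
    stop("'n_spots' must be a positive integer")
  }
  ncols <- ceiling(sqrt(n_spots))
  nrows <- ceiling(n_spots / ncols)
  i <- seq_len(n_spots) - 1L
  col <- i %% ncols
  row <- i %/% ncols
  cbind(x = (col + 0.5) / ncols, y = (row + 0.5) / nrows)
}

#' Assign spatial zone labels to spot coordinates
#'
#' Implements the package's fixed zonation geometries on the unit square:
#' `"uniform"` labels every spot 0; `"stripes"` cuts `n_regions`
#' equal-width vertical bands labelled 0 to `n_regions - 1` by the spot's
#' x coordinate; `"circles"` places `n_regions - 1` disc centers equally
#' spaced along the square's diagonal with radius `1 / (2 * n_regions)`,
#' labels spots inside disc `i` as region `i` (ties to the lowest index)
#' and everything else as background region 0.
#'
#' @param coords two-column coordinate matrix.
#' @param zonation `"uniform"`, `"stripes"` or `"circles"`.
#' @param n_regions number of regions.
#' @param radius disc radius for `"circles"`; default
#'   `1 / (2 * n_regions)`.
#' @return integer vector of zone labels, one per spot.
#' @export
assign_zones <- function(coords, zonation = c("uniform", "stripes",
                                              "circles"),
                         n_regions = 1, radius = NULL) {
  zonation <- match.arg(zonation)
  coords <- as.matrix(coords)
  n <- nrow(coords)
  switch(zonation,
    uniform = integer(n),
    stripes = {
      if (n_regions < 2) stop("stripes require n_regions >= 2")
      as.integer(pmin(floor(coords[, 1] * n_regions), n_regions - 1))
    },
    circles = {
      if (n_regions < 2) stop("circles require n_regions >= 2")
      if (is.null(radius)) radius <- 1 / (2 * n_regions)
      centers <- seq_len(n_regions - 1) / n_regions
      zone <- integer(n)
      for (i in rev(seq_along(centers))) {
        d2 <- (coords[, 1] - centers[i])^2 + (coords[, 2] - centers[i])^2
        zone[d2 <= radius^2] <- i
      }
      zone
    })
}

#' Sample the member cells of one simulated spot
#'
#' Chooses `k_types` distinct cell types uniformly without replacement,
#' allocates `n_cells` among them by uniform multinomial -- guaranteeing
#' every chosen type at least one cell whenever `n_cells >= k_types` -- and
#' samples cells within each type uniformly, with replacement only when a
#' type's demand exceeds its pool.  Operates on the current RNG stream
#' unless `seed` is given.
#'
#' @param reference a multiome `SingleCellExperiment` with cell-type
#'   labels.
#' @param k_types number of distinct types for the spot.
#' @param n_cells number of member cells.
#' @param seed optional integer seed.
#' @return character vector of `n_cells` member cell barcodes (possibly
#'   with duplicates when a pool was exhausted).
#' @export
sample_spot_members <- function(reference, k_types, n_cells, seed = NULL) {
  labels <- cell_types(reference)
  type_labels <- sort(unique(labels))
  if (k_types < 1 || k_types > length(type_labels)) {
    stop("'k_types' must be between 1 and the number of types (",
         length(type_labels), ")")
  }
  if (n_cells < 1) stop("'n_cells' must be >= 1")
  barcodes <- colnames(reference)
  with_seed(seed, {
    chosen <- sample(type_labels, k_types)
    alloc <- .allocate_cells(as.integer(n_cells), as.integer(k_types))
    unlist(lapply(seq_len(k_types), function(i) {
      if (alloc[i] == 0L) return(character(0))
      pool <- barcodes[labels == chosen[i]]
      sample(pool, alloc[i], replace = alloc[i] > length(pool))
    }), use.names = FALSE)
  })
}

# n cells among k chosen types: one guaranteed cell per type when n >= k,
# remainder (or everything, when n < k) split uniform-multinomially.
.allocate_cells <- function(n, k) {
  if (n >= k) {
    base <- rep(1L, k)
    extra <- n - k
  } else {
    base <- rep(0L, k)
    extra <- n
  }
  if (extra > 0) {
    base + as.integer(rmultinom(1, extra, rep(1 / k, k))[, 1])
  } else base
}

#' Simulate silver-standard spots from a dissociated reference
#'
#' For each spot on a regular grid: determine its zone, draw the number of
#' distinct cell types and the number of cells from the zone's clamped
#' Poisson-Gamma distributions (see [sample_composition_size()]; the two
#' draws are rank-coupled and the type count upper-clamped to the types
#' available, so every chosen type contributes at least one cell), sample
#' member cells, and sum their RNA and ATAC profiles.  True proportions
#' are the member-cell type frequencies.  Per-spot seeds are derived
#' prefix-stably from `seed`, so enlarging `n_spots` reproduces the
#' original spots unchanged.
#'
#' @param reference a multiome `SingleCellExperiment`
#'   ([generate_reference()] or a loaded real reference).
#' @param config a [simulation_config()].
#' @param seed integer RNG seed.
#' @return A spot-level multiome `SingleCellExperiment`: summed counts per
#'   modality; `colData` columns `x`, `y`, `zone`, `n_cells`, `n_types`,
#'   matrix column `true_proportions` and list column `member_cells`.
#' @examples
#' ref <- generate_reference(reference_config(n_cells = 120, n_genes = 40,
#'   n_peaks = 60, n_cell_types = 4, markers_per_type = 5), seed = 1)
#' spots <- simulate_spots(ref, simulation_config(n_spots = 25), seed = 1)
#' all(Matrix::colSums(rna_counts(spots)) > 0)
#' @export
simulate_spots <- function(reference, config, seed = 1L) {
  stopifnot(inherits(config, "simulation_config"))
  labels <- cell_types(reference)
  type_labels <- sort(unique(labels))
  n_types <- length(type_labels)
  if (n_types < max(config$mean_cell_types)) {
    message("reference has ", n_types, " cell types; per-spot type counts ",
            "will be clamped to that maximum")
  }
  coords <- lay_spot_grid(config$n_spots)
  zone <- assign_zones(coords, config$zonation, config$n_regions)
  spot_seeds <- derive_seeds(seed, config$n_spots)

  members <- vector("list", config$n_spots)
  for (s in seq_len(config$n_spots)) {
    z <- zone[s] + 1L
    members[[s]] <- with_seed(spot_seeds[s], {
      u <- runif(1)
      k <- sample_composition_size(1, config$mean_cell_types[z],
                                   config$overdispersion,
                                   lower = 1L, upper = n_types,
                                   quantiles = u)
      nc <- sample_composition_size(1, config$mean_cells[z],
                                    config$overdispersion,
                                    lower = 1L, quantiles = u)
      nc <- max(nc, k)
      sample_spot_members(reference, k, nc)
    })
  }

  .build_spot_dataset(reference, members, coords, zone,
                      spot_prefix = "spot", extra = list(config = config))
}

# Shared assembly of a spot-level dataset from member barcode lists.
.build_spot_dataset <- function(reference, members, coords, zone,
                                spot_prefix = "spot", extra = list()) {
  labels <- cell_types(reference)
  type_labels <- sort(unique(labels))
  n_spots <- length(members)
  idx <- lapply(members, match, table = colnames(reference))

  # cells x spots incidence with multiplicity; spot counts = counts %*% M
  mi <- unlist(idx, use.names = FALSE)
  mj <- rep(seq_len(n_spots), lengths(idx))
  M <- sparseMatrix(i = mi, j = mj, x = 1,
                    dims = c(ncol(reference), n_spots))
  rna <- drop0(rna_counts(reference) %*% M)
  at <- drop0(atac_counts(reference) %*% M)
  spot_ids <- sprintf("%s%04d", spot_prefix, seq_len(n_spots))
  colnames(rna) <- colnames(at) <- spot_ids

  prop <- matrix(0, n_spots, length(type_labels),
                 dimnames = list(spot_ids, type_labels))
  for (s in seq_len(n_spots)) {
    tab <- table(factor(labels[idx[[s]]], levels = type_labels))
    prop[s, ] <- as.numeric(tab) / length(idx[[s]])
  }
  validate_proportions(prop)

  cd <- DataFrame(row.names = spot_ids)
  cd$x <- coords[, 1]
  cd$y <- coords[, 2]
  cd$zone <- as.integer(zone)
  cd$n_cells <- lengths(members)
  cd$n_types <- vapply(idx, function(i) length(unique(labels[i])), 1L)
  cd$true_proportions <- prop
  cd$member_cells <- CharacterList(members)

  sce <- SingleCellExperiment(assays = list(counts = rna), colData = cd)
  altExp(sce, "ATAC") <- SingleCellExperiment(
    assays = list(counts = at))
  for (nm in names(extra)) metadata(sce)[[nm]] <- extra[[nm]]
  sce
}
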
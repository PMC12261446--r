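#' Configuration for the synthetic multiome reference generator
#'
#' Describes a dissociated single-cell multiome reference with
#' block-structured cell-type identity: each cell type owns a disjoint set
#' of marker genes and marker peaks whose mean signal is
#' `marker_fold_change` times the baseline.  RNA counts are negative
#' binomial (mean/shape parameterization, variance
#' `mu + mu^2 / rna_overdispersion`) with a log-normal per-cell size
#' factor; ATAC counts are Poisson by default, reflecting that peak-level
#' fragment counts are typically well described without extra
#' overdispersion, with a negative binomial option.
#'
#' @param n_cells,n_genes,n_peaks,n_cell_types dataset dimensions.
#' @param markers_per_type number of marker genes (and marker peaks) per
#'   cell type; `markers_per_type * n_cell_types` may not exceed the
#'   feature count of either modality.
#' @param marker_fold_change mean fold change of a type's markers over
#'   baseline in cells of that type.
#' @param baseline_rna_mean,baseline_atac_mean baseline per-feature mean
#'   counts at size factor 1.
#' @param rna_overdispersion negative binomial shape for RNA counts.
#' @param library_size_sigma standard deviation (log scale) of the
#'   log-normal per-cell size factor; the factor is mean-centred so the
#'   expected depth is unchanged.
#' @param cell_type_props optional proportion vector (length
#'   `n_cell_types`, summing to 1); default balanced.
#' @param atac_distribution `"poisson"` (default) or `"nb"`.
#' @param atac_overdispersion shape used when `atac_distribution = "nb"`.
#' @return A validated list of class `"reference_config"`.
#' @seealso [generate_reference()], [generate_targeted()]
#' @export
reference_config <- function(n_cells = 2000, n_genes = 1000, n_peaks = 2000,
                             n_cell_types = 12, markers_per_type = 10,
                             marker_fold_change = 8,
                             baseline_rna_mean = 0.5,
                             baseline_atac_mean = 0.2,
                             rna_overdispersion = 2,
                             library_size_sigma = 0.3,
                             cell_type_props = NULL,
                             atac_distribution = c("poisson", "nb"),
                             atac_overdispersion = 20) {
  for (d in c("n_cells", "n_genes", "n_peaks", "n_cell_types",
              "markers_per_type")) {
    v <- get(d)
    if (!is.numeric(v) || length(v) != 1 || v < 1 || v != floor(v)) {
      stop("'", d, "' must be a positive integer")
    }
  }
  if (n_cell_types < 2) stop("'n_cell_types' must be at least 2")
  if (markers_per_type * n_cell_types > n_genes) {
    stop("marker allocation exceeds the number of genes")
  }
  if (markers_per_type * n_cell_types > n_peaks) {
    stop("marker allocation exceeds the number of peaks")
  }
  .assert_positive_scalar(marker_fold_change, "marker_fold_change")
  .assert_positive_scalar(baseline_rna_mean, "baseline_rna_mean")
  .assert_positive_scalar(baseline_atac_mean, "baseline_atac_mean")
  .assert_positive_scalar(rna_overdispersion, "rna_overdispersion")
  if (library_size_sigma < 0) stop("'library_size_sigma' must be >= 0")
  if (!is.null(cell_type_props)) {
    if (length(cell_type_props) != n_cell_types ||
        any(cell_type_props <= 0) ||
        abs(sum(cell_type_props) - 1) > 1e-8) {
      stop("'cell_type_props' must be ", n_cell_types,
           " positive values summing to 1")
    }
  }
  structure(list(
    n_cells = as.integer(n_cells), n_genes = as.integer(n_genes),
    n_peaks = as.integer(n_peaks), n_cell_types = as.integer(n_cell_types),
    markers_per_type = as.integer(markers_per_type),
    marker_fold_change = marker_fold_change,
    baseline_rna_mean = baseline_rna_mean,
    baseline_atac_mean = baseline_atac_mean,
    rna_overdispersion = rna_overdispersion,
    library_size_sigma = library_size_sigma,
    cell_type_props = cell_type_props,
    atac_distribution = match.arg(atac_distribution),
    atac_overdispersion = atac_overdispersion
  ), class = "reference_config")
}

# Per-type cell counts: balanced (or proportional) with largest-remainder
# rounding so counts sum exactly to n_cells.
.type_counts <- function(config) {
  p <- config$cell_type_props
  if (is.null(p)) p <- rep(1 / config$n_cell_types, config$n_cell_types)
  raw <- p * config$n_cells
  k <- floor(raw)
  rem <- config$n_cells - sum(k)
  if (rem > 0) {
    bump <- order(-(raw - k), seq_along(k))[seq_len(rem)]
    k[bump] <- k[bump] + 1
  }
  as.integer(k)
}

# Feature-by-type mean matrix with a block-diagonal marker structure.
.type_means <- function(n_features, n_types, markers_per_type, baseline,
                        fold_change) {
  mu <- matrix(baseline, nrow = n_features, ncol = n_types)
  for (t in seq_len(n_types)) {
    idx <- (t - 1) * markers_per_type + seq_len(markers_per_type)
    mu[idx, t] <- baseline * fold_change
  }
  mu
}

#' Generate a dissociated synthetic multiome reference
#'
#' Draws a cells x features multiome dataset under a [reference_config()]:
#' cells are assigned to types (balanced unless `cell_type_props` is set),
#' RNA counts come from a negative binomial whose per-type mean is scaled
#' by `marker_fold_change` on that type's marker genes and by a per-cell
#' log-normal size factor, and ATAC counts come from a Poisson (or negative
#' binomial) with the analogous per-type peak means.  The output is
#' bitwise-reproducible given `(config, seed)`.
#'
#' @param config a [reference_config()].
#' @param seed integer RNG seed.
#' @return A multiome `SingleCellExperiment` (see [multiome_dataset()]);
#'   `rowData` of each modality records which type, if any, each feature
#'   marks.
#' @examples
#' ref <- generate_reference(reference_config(n_cells = 60, n_genes = 50,
#'   n_peaks = 80, n_cell_types = 3, markers_per_type = 5), seed = 1)
#' table(cell_types(ref))
#' @export
generate_reference <- function(config, seed = 1L) {
  stopifnot(inherits(config, "reference_config"))
  with_seed(seed, .generate_reference_impl(config))
}

.generate_reference_impl <- function(config) {
  n <- config$n_cells
  type_labels <- sprintf("type%02d", seq_len(config$n_cell_types))
  counts_per_type <- .type_counts(config)
  type_idx <- rep(seq_len(config$n_cell_types), counts_per_type)

  sf <- exp(rnorm(n, 0, config$library_size_sigma) -
              config$library_size_sigma^2 / 2)

  mu_rna <- .type_means(config$n_genes, config$n_cell_types,
                        config$markers_per_type, config$baseline_rna_mean,
                        config$marker_fold_change)
  mu_atac <- .type_means(config$n_peaks, config$n_cell_types,
                         config$markers_per_type, config$baseline_atac_mean,
                         config$marker_fold_change)

  mu_cells_rna <- mu_rna[, type_idx, drop = FALSE] *
    rep(sf, each = config$n_genes)
  rna <- matrix(rnbinom(length(mu_cells_rna),
                        size = config$rna_overdispersion,
                        mu = as.vector(mu_cells_rna)),
                nrow = config$n_genes)

  mu_cells_atac <- mu_atac[, type_idx, drop = FALSE] *
    rep(sf, each = config$n_peaks)
  atac <- if (config$atac_distribution == "poisson") {
    matrix(rpois(length(mu_cells_atac), as.vector(mu_cells_atac)),
           nrow = config$n_peaks)
  } else {
    matrix(rnbinom(length(mu_cells_atac),
                   size = config$atac_overdispersion,
                   mu = as.vector(mu_cells_atac)),
           nrow = config$n_peaks)
  }

  rownames(rna) <- sprintf("gene%05d", seq_len(config$n_genes))
  rownames(atac) <- sprintf("peak%05d", seq_len(config$n_peaks))
  sce <- multiome_dataset(rna, atac, type_labels[type_idx])
  marker_of <- function(n_features) {
    m <- rep(NA_character_, n_features)
    idx <- seq_len(config$markers_per_type * config$n_cell_types)
    m[idx] <- rep(type_labels, each = config$markers_per_type)
    m
  }
  SummarizedExperiment::rowData(sce)$marker_type <- marker_of(config$n_genes)
  SummarizedExperiment::rowData(altExp(sce, "ATAC"))$marker_type <-
    marker_of(config$n_peaks)
  colData(sce)$size_factor <- sf
  metadata(sce)$reference_config <- config
  sce
}

#' Generate a spatially tagged synthetic multiome dataset
#'
#' As [generate_reference()], but every cell additionally receives a 2-D
#' coordinate in the unit square, emulating a targeted spatial multiome
#' assay in which transcriptome and accessibility are measured per cell
#' together with its position.  Under the `"uniform"` layout positions are
#' independent of cell type; under `"clustered"`, cells scatter normally
#' (sd `dispersion`) around a type-specific center, then are clipped to the
#' unit square.
#'
#' @inheritParams generate_reference
#' @param layout `"uniform"` or `"clustered"`.
#' @param centers optional `n_cell_types` x 2 matrix of cluster centers in
#'   the unit square (clustered layout); default centers are drawn
#'   uniformly in `[0.15, 0.85]^2`.
#' @param dispersion normal sd of cell positions around their type center.
#' @return A multiome `SingleCellExperiment` with `x`/`y` columns in its
#'   `colData`.
#' @export
generate_targeted <- function(config, layout = c("uniform", "clustered"),
                              centers = NULL, dispersion = 0.08,
                              seed = 1L) {
  layout <- match.arg(layout)
  if (dispersion < 0) stop("'dispersion' must be >= 0")
  seeds <- derive_seeds(seed, 2)
  sce <- generate_reference(config, seed = seeds[1])
  types <- cell_types(sce)
  type_labels <- sort(unique(types))
  n <- ncol(sce)
  coords <- with_seed(seeds[2], {
    if (layout == "uniform") {
      cbind(runif(n), runif(n))
    } else {
      if (is.null(centers)) {
        centers <- cbind(runif(length(type_labels), 0.15, 0.85),
                         runif(length(type_labels), 0.15, 0.85))
      }
      centers <- as.matrix(centers)
      if (nrow(centers) != length(type_labels) || ncol(centers) != 2) {
        stop("'centers' must be an n_cell_types x 2 matrix")
      }
      ti <- match(types, type_labels)
      xy <- centers[ti, , drop = FALSE] +
        matrix(rnorm(2 * n, 0, dispersion), ncol = 2)
      pmin(pmax(xy, 0), 1)
    }
  })
  colData(sce)$x <- as.numeric(coords[, 1])
  colData(sce)$y <- as.numeric(coords[, 2])
  metadata(sce)$layout <- layout
  sce
}

#' Expand a reference by sampling extra cells from a pool
#'
#' Builds a nested series of references whose sizes are multiples of the
#' base: the element for factor `f` contains all cells of the previous
#' element plus cells sampled without replacement from `pool` (cells not
#' already in `base`), for a total of `f * ncol(base)` cells.  Used to
#' study how deconvolution methods respond to reference size.
#'
#' @param base the smallest reference (a multiome `SingleCellExperiment`).
#' @param pool a larger dataset with the same features; cells of `base`
#'   are excluded from sampling by barcode.
#' @param factors integer expansion factors, e.g. `c(2, 4, 8, 16)`;
#'   a factor of 1 returns `base` itself.
#' @param seed integer RNG seed.
#' @return Named list of `SingleCellExperiment`s, one per factor.
#' @export
expand_reference_series <- function(base, pool, factors = c(2, 4, 8, 16),
                                    seed = 1L) {
  if (any(factors < 1 | factors != floor(factors))) {
    stop("'factors' must be positive integers")
  }
  if (!identical(rownames(base), rownames(pool))) {
    stop("'base' and 'pool' must share an identical feature space")
  }
  factors <- sort(unique(as.integer(factors)))
  nb <- ncol(base)
  avail <- setdiff(colnames(pool), colnames(base))
  need <- (max(factors) - 1L) * nb
  if (length(avail) < need) {
    stop("pool has only ", length(avail), " cells outside the base; ",
         need, " needed for factor ", max(factors))
  }
  extra_order <- with_seed(seed, sample(avail, need))
  out <- lapply(factors, function(f) {
    if (f == 1L) return(base)
    extra <- extra_order[seq_len((f - 1L) * nb)]
    BiocGenerics::cbind(base, pool[, extra])
  })
  names(out) <- paste0("factor_", factors)
  out
}
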
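#' Feature-selection strategies for deconvolution
#'
#' Deconvolution methods built for transcriptomics use a few thousand
#' informative genes, while chromatin accessibility matrices carry far
#' more peaks than is practical; selection is therefore performed on the
#' reference and the identical feature space is then imposed on the
#' spatial dataset.  Three strategies are provided:
#'
#' * `select_highly_accessible()` -- peaks ranked by total fragment count
#'   across all reference cells (option: by the fraction of cells with a
#'   nonzero count), capturing common, robust signals.
#' * `select_highly_variable_peaks()` -- peaks ranked by the variance of
#'   their per-cell-type mean accessibility, computed on median-depth
#'   normalized, `log1p`-transformed counts with cell types as the
#'   predefined clusters, capturing type-discriminating signals.
#' * `select_hvg_seurat()` -- dispersion-based highly variable genes:
#'   counts are depth-normalized to the mean total, the per-gene
#'   dispersion (variance/mean of the normalized counts) is z-scored
#'   within 20 bins of genes with similar mean, and genes are ranked by
#'   normalized dispersion.
#'
#' All selections are deterministic; score ties are broken by ascending
#' feature index.
#'
#' @param x a features x cells count matrix, or a multiome
#'   `SingleCellExperiment` from which the relevant modality is taken.
#' @param n number of features to keep; larger than the feature count
#'   selects everything (with a message).
#' @param method ranking statistic for accessibility: `"total"` fragment
#'   count or `"prevalence"` (fraction of cells nonzero).
#' @return An object of class `"feature_selection"`: list with `modality`,
#'   `strategy`, `n_features` (requested), `selected` (ordered feature
#'   names) and `scores` (full named score vector).
#' @name feature_selection
NULL

.as_modality_matrix <- function(x, modality) {
  if (is(x, "SingleCellExperiment")) modality_counts(x, modality)
  else as(x, "CsparseMatrix")
}

.make_selection <- function(scores, n, modality, strategy) {
  if (is.null(names(scores))) names(scores) <- seq_along(scores)
  n_avail <- length(scores)
  if (n > n_avail) {
    message("requested ", n, " features but only ", n_avail,
            " available; returning all")
  }
  # scores compared at 1e-9 resolution so that structurally tied scores
  # (e.g. z-scores in two-member bins) rank by feature index, not by
  # floating-point noise
  keep <- order_desc_stable(round(scores, 9))[seq_len(min(n, n_avail))]
  structure(list(modality = modality, strategy = strategy,
                 n_features = as.integer(n),
                 selected = names(scores)[keep],
                 scores = scores),
            class = "feature_selection")
}

#' @rdname feature_selection
#' @export
select_highly_accessible <- function(x, n = 20000,
                                     method = c("total", "prevalence")) {
  method <- match.arg(method)
  m <- .as_modality_matrix(x, "atac")
  if (n < 1) stop("'n' must be >= 1")
  scores <- if (method == "total") rowSums(m) else rowSums(m > 0) / ncol(m)
  .make_selection(scores, n, "atac", "highly_accessible")
}

#' @rdname feature_selection
#' @param cell_types cluster labels, one per cell; taken from the
#'   `SingleCellExperiment` when omitted.
#' @export
select_highly_variable_peaks <- function(x, cell_types = NULL, n = 20000) {
  m <- .as_modality_matrix(x, "atac")
  if (is.null(cell_types) && is(x, "SingleCellExperiment")) {
    cell_types <- colData(x)$cell_type
  }
  if (is.null(cell_types) || length(cell_types) != ncol(m)) {
    stop("'cell_types' must provide one label per cell")
  }
  types <- sort(unique(as.character(cell_types)))
  if (length(types) < 2) {
    stop("highly variable peak selection needs at least 2 cell types")
  }
  if (n < 1) stop("'n' must be >= 1")
  depth <- colSums(m)
  depth[depth == 0] <- 1
  lognorm <- log1p(m %*% Diagonal(x = median(colSums(m)) / depth))
  # peaks x types matrix of per-type means
  grp <- sparseMatrix(i = seq_len(ncol(m)),
                      j = match(as.character(cell_types), types),
                      x = 1 / as.numeric(table(factor(cell_types,
                                                      levels = types)))[
                        match(as.character(cell_types), types)],
                      dims = c(ncol(m), length(types)))
  tm <- as.matrix(lognorm %*% grp)
  mu <- rowMeans(tm)
  scores <- rowSums((tm - mu)^2) / (length(types) - 1)
  names(scores) <- rownames(m)
  .make_selection(scores, n, "atac", "highly_variable_peaks")
}

#' @rdname feature_selection
#' @param n_bins number of gene-mean bins for dispersion normalization.
#' @export
select_hvg_seurat <- function(x, n = 4000, n_bins = 20) {
  m <- .as_modality_matrix(x, "rna")
  if (nrow(m) < 2) stop("need at least 2 genes")
  if (n < 1) stop("'n' must be >= 1")
  depth <- colSums(m)
  depth[depth == 0] <- 1
  norm <- m %*% Diagonal(x = mean(colSums(m)) / depth)
  # mean/dispersion on the normalized-count (expm1-of-log) scale
  mu <- rowMeans(norm)
  ex2 <- rowSums(norm^2) / ncol(norm)
  v <- (ex2 - mu^2) * ncol(norm) / max(1, ncol(norm) - 1)
  disp <- ifelse(mu > 0, v / mu, 0)
  zs <- .bin_zscore(log1p(mu), disp, n_bins)
  names(zs) <- rownames(m)
  .make_selection(zs, n, "rna", "hvg_seurat")
}

# z-score `value` within equal-width bins of `key`; degenerate bins
# (single member or zero spread) get z = 0.
.bin_zscore <- function(key, value, n_bins) {
  brk <- seq(min(key), max(key), length.out = n_bins + 1)
  brk[1] <- brk[1] - 1e-9
  bin <- cut(key, breaks = unique(c(brk, max(key) + 1e-9)),
             include.lowest = TRUE)
  z <- numeric(length(value))
  for (b in levels(bin)) {
    i <- which(bin == b)
    if (length(i) < 2) { z[i] <- 0; next }
    s <- sd(value[i])
    z[i] <- if (is.na(s) || s == 0) 0 else (value[i] - mean(value[i])) / s
  }
  z
}

#' Restrict a spatial dataset to a reference-derived feature selection
#'
#' Applies a [feature_selection] computed on the reference to a spot (or
#' cell) dataset, keeping exactly the selected features of that modality
#' in selection order.  Features absent from the dataset raise an error
#' naming them.
#'
#' @param spatial a multiome `SingleCellExperiment`.
#' @param sel a `"feature_selection"` object.
#' @return The dataset with the selected modality subset to
#'   `sel$selected`.
#' @export
apply_selection <- function(spatial, sel) {
  stopifnot(inherits(sel, "feature_selection"))
  current <- rownames(.as_modality_matrix(spatial, sel$modality))
  missing <- setdiff(sel$selected, current)
  if (length(missing)) {
    stop("selected features absent from dataset: ",
         paste(head(missing, 5), collapse = ", "),
         if (length(missing) > 5) sprintf(" ... (%d total)",
                                          length(missing)))
  }
  if (sel$modality == "rna") {
    spatial[sel$selected, ]
  } else {
    altExp(spatial, "ATAC") <- altExp(spatial, "ATAC")[sel$selected, ]
    spatial
  }
}
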
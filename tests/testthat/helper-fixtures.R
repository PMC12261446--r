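## Shared fixtures and independent oracles for the test suite.

# Small multiome reference used by most module tests.
small_reference <- function(n_cells = 200, n_types = 4, seed = 11,
                            fold = 8, ...) {
  generate_reference(
    reference_config(n_cells = n_cells, n_genes = 100, n_peaks = 150,
                     n_cell_types = n_types, markers_per_type = 8,
                     marker_fold_change = fold, ...),
    seed = seed)
}

small_targeted <- function(n_cells = 150, n_types = 3, layout = "uniform",
                           seed = 7, ...) {
  generate_targeted(
    reference_config(n_cells = n_cells, n_genes = 60, n_peaks = 80,
                     n_cell_types = n_types, markers_per_type = 5),
    layout = layout, seed = seed, ...)
}

# Wrap an ATAC spot matrix (features x spots) as a minimal multiome spot
# dataset compatible with nnls_deconvolve(); the RNA slot is a dummy.
mixture_spot_sce <- function(ref, atac_matrix) {
  k <- ncol(atac_matrix)
  ids <- sprintf("mix%03d", seq_len(k))
  rna <- rna_counts(ref)[, seq_len(k), drop = FALSE]
  colnames(rna) <- ids
  atac_matrix <- methods::as(atac_matrix, "CsparseMatrix")
  colnames(atac_matrix) <- ids
  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = rna))
  SingleCellExperiment::altExp(sce, "ATAC") <-
    SingleCellExperiment::SingleCellExperiment(
      assays = list(counts = atac_matrix))
  sce
}

# Independent oracle: mean of a negative binomial (mean mu, shape theta)
# clamped into [lower, upper], by direct pmf summation.
nb_clamp_mean_oracle <- function(mu, theta, lower = 1, upper = Inf) {
  kmax <- 2000
  k <- 0:kmax
  p <- dnbinom(k, mu = mu, size = theta)
  sum(p * pmin(pmax(k, lower), upper)) + (1 - sum(p)) * min(kmax, upper)
}

nb_clamp_var_oracle <- function(mu, theta, lower = 1, upper = Inf) {
  kmax <- 2000
  k <- 0:kmax
  p <- dnbinom(k, mu = mu, size = theta)
  v <- pmin(pmax(k, lower), upper)
  m <- sum(p * v)
  sum(p * (v - m)^2)
}

# Brute-force entropy/mutual-information oracle for NMI.
nmi_oracle <- function(a, b) {
  if (identical(as.character(a), as.character(b))) return(1)
  n <- length(a)
  pa <- table(a) / n
  pb <- table(b) / n
  h <- function(p) -sum(p[p > 0] * log(p[p > 0]))
  ha <- h(pa); hb <- h(pb)
  if (ha == 0 || hb == 0) return(0)
  mi <- 0
  for (x in names(pa)) for (y in names(pb)) {
    pxy <- sum(a == x & b == y) / n
    if (pxy > 0) mi <- mi + pxy * log(pxy / (pa[[x]] * pb[[y]]))
  }
  mi / ((ha + hb) / 2)
}

# Naive per-spot Jensen-Shannon divergence (base 2) oracle.
jsd_oracle <- function(p, q) {
  p <- p / sum(p); q <- q / sum(q)
  m <- (p + q) / 2
  kl <- function(a) sum(ifelse(a > 0, a * log2(a / m), 0))
  (kl(p) + kl(q)) / 2
}
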
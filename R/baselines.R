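#' Naive majority-cell-type baseline
#'
#' Predicts a single cell type with probability 1 for every spot.  Two
#' readings of "majority" are provided: `"oracle_spot"` uses each spot's
#' true majority type (an informed baseline that upper-bounds what
#' majority-only prediction can achieve), while `"global_reference"`
#' predicts the reference's most abundant cell type for all spots.
#'
#' @param true spots x cell-types true proportion matrix (required for
#'   `"oracle_spot"`; also supplies the column labels).
#' @param mode `"oracle_spot"` or `"global_reference"`.
#' @param reference_labels per-cell labels of the reference (required for
#'   `"global_reference"`).
#' @return A `"deconvolution_result"`: list with `method`, `proportions`
#'   (one-hot rows) and `provenance`.
#' @examples
#' tr <- rbind(c(0.5, 0.3, 0.2), c(0.1, 0.2, 0.7))
#' colnames(tr) <- c("A", "B", "C")
#' majority_baseline(tr)$proportions
#' @export
majority_baseline <- function(true = NULL,
                              mode = c("oracle_spot", "global_reference"),
                              reference_labels = NULL) {
  mode <- match.arg(mode)
  if (is.null(true)) stop("'true' proportions are required")
  true <- as.matrix(true)
  labs <- colnames(true)
  if (is.null(labs)) labs <- as.character(seq_len(ncol(true)))
  hot <- if (mode == "oracle_spot") {
    majority_labels(true)
  } else {
    if (is.null(reference_labels)) {
      stop("'reference_labels' required for mode = 'global_reference'")
    }
    tab <- table(as.character(reference_labels))
    top <- sort(names(tab)[tab == max(tab)])[1]
    if (!(top %in% labs)) {
      stop("reference majority type '", top, "' absent from proportion ",
           "columns")
    }
    rep(top, nrow(true))
  }
  p <- matrix(0, nrow(true), ncol(true),
              dimnames = list(rownames(true), labs))
  p[cbind(seq_len(nrow(p)), match(hot, labs))] <- 1
  structure(list(method = paste0("majority_", mode),
                 proportions = validate_proportions(p),
                 provenance = list(mode = mode)),
            class = "deconvolution_result")
}

#' Non-negative least-squares reference deconvolver
#'
#' A lightweight deconvolution method so the benchmarking pipeline runs
#' end-to-end without external tools: each cell type's signature is the
#' arithmetic mean of its depth-normalized reference profiles (each cell
#' scaled to unit total), each spot profile is normalized the same way,
#' and per-spot coefficients are found by Lawson-Hanson non-negative
#' least squares and renormalized to sum to one.  A spot solved as
#' all-zero falls back to a uniform row (with a message).
#'
#' @param reference multiome `SingleCellExperiment` with cell-type labels.
#' @param spots spot-level dataset sharing the reference feature space
#'   (after [apply_selection()] on both, or unselected).
#' @param selection optional [feature_selection] applied to both datasets
#'   before fitting.
#' @param modality `"rna"` or `"atac"`; defaults to the selection's
#'   modality, else `"rna"`.
#' @return A `"deconvolution_result"` with the spots x types proportion
#'   matrix.
#' @export
nnls_deconvolve <- function(reference, spots, selection = NULL,
                            modality = NULL) {
  if (is.null(modality)) {
    modality <- if (is.null(selection)) "rna" else selection$modality
  }
  if (!is.null(selection)) {
    reference <- apply_selection(reference, selection)
    spots <- apply_selection(spots, selection)
  }
  refm <- modality_counts(reference, modality)
  spotm <- modality_counts(spots, modality)
  if (!identical(rownames(refm), rownames(spotm))) {
    stop("reference and spots must share an identical ", modality,
         " feature space")
  }
  labels <- cell_types(reference)
  types <- sort(unique(labels))
  sig <- .signature_matrix(refm, labels, types)
  if (qr(sig)$rank < ncol(sig)) {
    warning("signature matrix is rank-deficient; proportions may not be ",
            "identifiable")
  }
  depth <- colSums(spotm)
  depth[depth == 0] <- 1
  y <- as.matrix(spotm %*% Diagonal(x = 1 / depth))
  prop <- matrix(0, ncol(spotm), length(types),
                 dimnames = list(colnames(spotm), types))
  n_zero <- 0L
  for (s in seq_len(ncol(spotm))) {
    w <- pracma::lsqnonneg(sig, y[, s])$x
    if (sum(w) == 0) {
      n_zero <- n_zero + 1L
      prop[s, ] <- 1 / length(types)
    } else {
      prop[s, ] <- w / sum(w)
    }
  }
  if (n_zero > 0) {
    message(n_zero, " spot(s) had an all-zero NNLS solution; set uniform")
  }
  structure(list(method = "nnls",
                 proportions = validate_proportions(prop),
                 provenance = list(modality = modality,
                                   strategy = if (is.null(selection))
                                     NA_character_ else selection$strategy)),
            class = "deconvolution_result")
}

# types-signature: mean of unit-total cell profiles per type (dense,
# features x types)
.signature_matrix <- function(m, labels, types) {
  depth <- colSums(m)
  depth[depth == 0] <- 1
  normed <- m %*% Diagonal(x = 1 / depth)
  sig <- vapply(types, function(t) {
    rowMeans(as.matrix(normed[, labels == t, drop = FALSE]))
  }, numeric(nrow(m)))
  dimnames(sig) <- list(rownames(m), types)
  sig
}
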
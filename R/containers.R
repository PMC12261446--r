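#' Multiome dataset containers
#'
#' spotbench stores every dataset -- dissociated references, spatially
#' tagged references, and aggregated spots -- as a
#' [SingleCellExperiment::SingleCellExperiment] whose main experiment holds
#' the RNA count matrix (genes x cells, assay `"counts"`) and whose
#' `"ATAC"` alternative experiment holds the peak count matrix
#' (peaks x cells).  Column metadata carries per-cell (or per-spot)
#' annotation: `cell_type`, spatial coordinates `x`/`y`, and for spot
#' datasets the `zone` label, a `true_proportions` matrix column and a
#' `member_cells` list column naming the reference cells summed into each
#' spot.
#'
#' `multiome_dataset()` assembles and validates such an object from raw
#' matrices; the accessors below extract the pieces.
#'
#' @param rna_counts sparse or dense integer matrix, genes x cells.
#' @param atac_counts sparse or dense integer matrix, peaks x cells, with
#'   the same columns as `rna_counts`.
#' @param cell_types character or factor of length `ncol(rna_counts)`.
#' @param coords optional two-column matrix or data.frame of (x, y)
#'   positions, one row per cell.
#' @param colnames_prefix prefix used to synthesize cell barcodes when the
#'   matrices are unnamed.
#' @return A `SingleCellExperiment` with an `"ATAC"` altExp.
#' @examples
#' rna <- matrix(rpois(40, 1), nrow = 4,
#'               dimnames = list(paste0("g", 1:4), NULL))
#' atac <- matrix(rpois(60, 1), nrow = 6,
#'                dimnames = list(paste0("p", 1:6), NULL))
#' ds <- multiome_dataset(rna, atac, rep(c("A", "B"), each = 5))
#' dim(rna_counts(ds))
#' table(cell_types(ds))
#' @export
multiome_dataset <- function(rna_counts, atac_counts, cell_types,
                             coords = NULL, colnames_prefix = "cell") {
  rna_counts <- as(as(rna_counts, "CsparseMatrix"), "dMatrix")
  atac_counts <- as(as(atac_counts, "CsparseMatrix"), "dMatrix")
  n <- ncol(rna_counts)
  if (ncol(atac_counts) != n) {
    stop("RNA and ATAC matrices must have the same number of cells (",
         n, " vs ", ncol(atac_counts), ")")
  }
  if (length(cell_types) != n) {
    stop("'cell_types' must have one label per cell")
  }
  .check_counts(rna_counts, "rna_counts")
  .check_counts(atac_counts, "atac_counts")
  if (is.null(colnames(rna_counts))) {
    colnames(rna_counts) <- sprintf("%s%d", colnames_prefix, seq_len(n))
  }
  colnames(atac_counts) <- colnames(rna_counts)
  if (is.null(rownames(rna_counts))) {
    rownames(rna_counts) <- sprintf("gene%d", seq_len(nrow(rna_counts)))
  }
  if (is.null(rownames(atac_counts))) {
    rownames(atac_counts) <- sprintf("peak%d", seq_len(nrow(atac_counts)))
  }
  cd <- DataFrame(cell_type = as.character(cell_types),
                  row.names = colnames(rna_counts))
  if (!is.null(coords)) {
    coords <- as.matrix(coords)
    if (nrow(coords) != n || ncol(coords) != 2) {
      stop("'coords' must be an n_cells x 2 matrix")
    }
    if (!all(is.finite(coords))) stop("coordinates must be finite")
    cd$x <- as.numeric(coords[, 1])
    cd$y <- as.numeric(coords[, 2])
  }
  sce <- SingleCellExperiment(assays = list(counts = rna_counts),
                              colData = cd)
  altExp(sce, "ATAC") <- SingleCellExperiment(
    assays = list(counts = atac_counts))
  sce
}

.check_counts <- function(m, what) {
  x <- if (is(m, "sparseMatrix")) m@x else as.numeric(m)
  if (length(x) && (any(x < 0) || any(x != floor(x)))) {
    stop("'", what, "' must contain nonnegative integer counts")
  }
  invisible(TRUE)
}

#' @rdname multiome_dataset
#' @param x a multiome `SingleCellExperiment`.
#' @export
rna_counts <- function(x) assay(x, "counts")

#' @rdname multiome_dataset
#' @export
atac_counts <- function(x) assay(altExp(x, "ATAC"), "counts")

#' @rdname multiome_dataset
#' @param modality `"rna"` or `"atac"`.
#' @export
modality_counts <- function(x, modality = c("rna", "atac")) {
  switch(match.arg(modality), rna = rna_counts(x), atac = atac_counts(x))
}

#' @rdname multiome_dataset
#' @export
cell_types <- function(x) colData(x)$cell_type

#' @rdname multiome_dataset
#' @export
spatial_coords <- function(x) {
  cd <- colData(x)
  if (is.null(cd$x)) stop("dataset has no spatial coordinates")
  cbind(x = cd$x, y = cd$y)
}

#' @rdname multiome_dataset
#' @export
spot_zones <- function(x) colData(x)$zone

#' Ground-truth spot composition
#'
#' Extracts the spots x cell-types matrix of true proportions attached to a
#' simulated or aggregated spot dataset.  Every row is nonnegative and sums
#' to one.
#'
#' @param x a spot `SingleCellExperiment` produced by [simulate_spots()] or
#'   [aggregate_pseudo_spots()].
#' @return numeric matrix, spots x cell types.
#' @export
true_proportions <- function(x) {
  p <- colData(x)$true_proportions
  if (is.null(p)) stop("dataset has no 'true_proportions' column")
  m <- as.matrix(p)
  rownames(m) <- colnames(x)
  m
}

#' @rdname true_proportions
#' @export
member_cells <- function(x) {
  mc <- colData(x)$member_cells
  if (is.null(mc)) stop("dataset has no 'member_cells' column")
  as.list(mc)
}

#' Validate a proportion matrix
#'
#' Checks that rows are probability vectors: entries in \[0, 1\] and each
#' row summing to one within `tol`.
#'
#' @param p numeric matrix with cell-type column names.
#' @param tol row-sum tolerance.
#' @return `p`, invisibly, after validation.
#' @export
validate_proportions <- function(p, tol = 1e-9) {
  p <- as.matrix(p)
  if (any(p < 0) || any(p > 1 + tol)) {
    stop("proportions must lie in [0, 1]")
  }
  rs <- rowSums(p)
  if (any(abs(rs - 1) > tol)) {
    stop("proportion rows must sum to 1 (max deviation ",
         format(max(abs(rs - 1))), ")")
  }
  invisible(p)
}
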
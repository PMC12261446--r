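#' Read and write multiome datasets as Matrix Market / TSV bundles
#'
#' A dataset directory holds one Matrix Market file per modality
#' (`rna.mtx`, `atac.mtx`, features x cells, 1-based indices per the MTX
#' standard), a features TSV per modality (`rna_features.tsv`,
#' `atac_features.tsv`), and a `cells.tsv` with one row per cell or spot
#' (`barcode`, `cell_type` where applicable, coordinates `x`/`y`, `zone`,
#' and a semicolon-joined `member_cells` column for spot datasets).  Spot
#' datasets additionally carry `true_proportions.tsv` (spots x types, tab
#' separated, header of type labels).  Counts, labels and coordinates
#' round-trip losslessly; all writes are atomic (temp file + rename).
#'
#' @param x a multiome `SingleCellExperiment`.
#' @param dir bundle directory (created if needed).
#' @return `write_dataset()` returns `dir` invisibly; `read_dataset()`
#'   returns the reconstructed `SingleCellExperiment`.
#' @export
write_dataset <- function(x, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wtsv <- function(df, file) {
    atomic_write(function(tmp) {
      write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
    }, file.path(dir, file))
  }
  wmtx <- function(m, file) {
    atomic_write(function(tmp) writeMM(m, tmp), file.path(dir, file))
  }
  wmtx(rna_counts(x), "rna.mtx")
  wmtx(atac_counts(x), "atac.mtx")
  fd <- function(sce_part) {
    rd <- as.data.frame(SummarizedExperiment::rowData(sce_part))
    cbind(data.frame(feature_id = rownames(sce_part)), rd)
  }
  wtsv(fd(x), "rna_features.tsv")
  wtsv(fd(altExp(x, "ATAC")), "atac_features.tsv")

  cd <- colData(x)
  cells <- data.frame(barcode = colnames(x))
  for (col in c("cell_type", "x", "y", "zone", "n_cells", "n_types",
                "size_factor", "ix", "iy")) {
    if (!is.null(cd[[col]])) {
      v <- cd[[col]]
      if (is.double(v)) v <- sprintf("%.17g", v)
      cells[[col]] <- v
    }
  }
  if (!is.null(cd$member_cells)) {
    cells$member_cells <- vapply(as.list(cd$member_cells),
                                 paste, "", collapse = ";")
  }
  wtsv(cells, "cells.tsv")
  if (!is.null(cd$true_proportions)) {
    p <- as.matrix(cd$true_proportions)
    wtsv(cbind(data.frame(barcode = colnames(x)),
               as.data.frame(.full_precision(p))),
         "true_proportions.tsv")
  }
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  need <- function(file) {
    path <- file.path(dir, file)
    if (!file.exists(path)) {
      stop("dataset bundle ", dir, " is missing required file '", file, "'")
    }
    path
  }
  rmtx <- function(file) as(readMM(need(file)), "CsparseMatrix")
  rna <- rmtx("rna.mtx")
  at <- rmtx("atac.mtx")
  rfeat <- read.delim(need("rna_features.tsv"))
  afeat <- read.delim(need("atac_features.tsv"))
  cells <- read.delim(need("cells.tsv"),
                      colClasses = c(barcode = "character"))
  if (nrow(rfeat) != nrow(rna) || nrow(afeat) != nrow(at)) {
    stop("feature table and matrix dimensions disagree")
  }
  if (nrow(cells) != ncol(rna) || ncol(rna) != ncol(at)) {
    stop("cells.tsv rows and matrix columns disagree")
  }
  rownames(rna) <- rfeat$feature_id
  rownames(at) <- afeat$feature_id
  colnames(rna) <- colnames(at) <- cells$barcode

  cd <- DataFrame(row.names = cells$barcode)
  for (col in setdiff(names(cells), c("barcode", "member_cells"))) {
    cd[[col]] <- cells[[col]]
  }
  if (!is.null(cells$member_cells)) {
    cd$member_cells <- CharacterList(strsplit(cells$member_cells, ";",
                                              fixed = TRUE))
  }
  pp <- file.path(dir, "true_proportions.tsv")
  if (file.exists(pp)) {
    tp <- read.delim(pp, check.names = FALSE,
                     colClasses = c(barcode = "character"))
    p <- as.matrix(tp[, -1, drop = FALSE])
    rownames(p) <- tp$barcode
    cd$true_proportions <- p[cells$barcode, , drop = FALSE]
  }
  sce <- SingleCellExperiment(assays = list(counts = rna), colData = cd)
  altExp(sce, "ATAC") <- SingleCellExperiment(assays = list(counts = at))
  if (ncol(rfeat) > 1) {
    SummarizedExperiment::rowData(sce) <-
      cbind(SummarizedExperiment::rowData(sce),
            rfeat[, -1, drop = FALSE])
  }
  if (ncol(afeat) > 1) {
    SummarizedExperiment::rowData(altExp(sce, "ATAC")) <-
      cbind(SummarizedExperiment::rowData(altExp(sce, "ATAC")),
            afeat[, -1, drop = FALSE])
  }
  sce
}

#' Read and write proportion matrices as TSV
#'
#' The interchange contract for deconvolution outputs: a tab-separated
#' table whose first column (`spot_id`) names the spot and whose remaining
#' header names are cell-type labels, one row per spot.  Any external
#' tool's predictions written in this form can be scored with
#' [evaluate()].
#'
#' @param p spots x cell-types matrix.
#' @param path TSV file path.
#' @return `write_proportions()` returns `path` invisibly;
#'   `read_proportions()` returns a numeric matrix with spot rownames.
#' @export
write_proportions <- function(p, path) {
  p <- as.matrix(p)
  df <- cbind(data.frame(spot_id = if (is.null(rownames(p)))
    sprintf("spot%04d", seq_len(nrow(p))) else rownames(p)),
    as.data.frame(.full_precision(p)))
  atomic_write(function(tmp) {
    write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  }, path)
}

# full-roundtrip decimal rendering of a numeric matrix ("%.17g")
.full_precision <- function(p) {
  q <- matrix(sprintf("%.17g", p), nrow(p), dimnames = dimnames(p))
  q
}

#' @rdname write_proportions
#' @export
read_proportions <- function(path) {
  if (!file.exists(path)) stop("no such proportions file: ", path)
  # first column is the spot identifier, whatever its header says
  id_col <- names(read.delim(path, nrows = 1))[1]
  df <- read.delim(path, check.names = FALSE,
                   colClasses = setNames("character", id_col))
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
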
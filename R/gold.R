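#' Bin spatially tagged cells onto a square spot grid
#'
#' Partitions the plane into half-open squares
#' `[x0 + i*s, x0 + (i+1)*s) x [y0 + j*s, y0 + (j+1)*s)` and assigns every
#' cell to the unique square containing it.  This is the first step of the
#' gold-standard simulation, which turns single-cell spatial data into
#' spot-like aggregates with known composition.
#'
#' @param coords two-column matrix of cell (x, y) positions.
#' @param spot_side side length `s` of a square pseudo-spot, in the length
#'   units of `coords`.
#' @param origin grid origin `(x0, y0)`.
#' @return An object of class `"spot_grid"`: list with `spot_side`,
#'   `origin`, and a per-cell data.frame `assignment` (`ix`, `iy`,
#'   `spot` key).
#' @examples
#' g <- grid_assign(cbind(c(0.1, 0.9), c(0.1, 0.9)), spot_side = 0.5)
#' g$assignment
#' @export
grid_assign <- function(coords, spot_side, origin = c(0, 0)) {
  .assert_positive_scalar(spot_side, "spot_side")
  coords <- as.matrix(coords)
  if (!all(is.finite(coords))) stop("coordinates must be finite")
  ix <- floor((coords[, 1] - origin[1]) / spot_side)
  iy <- floor((coords[, 2] - origin[2]) / spot_side)
  structure(list(
    spot_side = spot_side,
    origin = as.numeric(origin),
    assignment = data.frame(ix = as.integer(ix), iy = as.integer(iy),
                            spot = paste(ix, iy, sep = "_"))
  ), class = "spot_grid")
}

#' Aggregate spatially tagged cells into pseudo-spots
#'
#' Sums the RNA and ATAC profiles of all cells falling into each occupied
#' grid square, yielding gold-standard spots whose true cell-type
#' proportions are the member-label frequencies.  Squares with fewer than
#' `min_cells` cells are dropped (and reported via a message).  The spot
#' coordinate is the square's centroid.
#'
#' @param data a spatially tagged multiome `SingleCellExperiment`
#'   ([generate_targeted()] or a loaded real dataset).
#' @param grid a [grid_assign()] result computed on `spatial_coords(data)`.
#' @param min_cells minimum member cells for a square to become a spot.
#' @return A spot-level multiome `SingleCellExperiment`, as for
#'   [simulate_spots()] (zone column absent; `colData` keeps the grid
#'   indices `ix`, `iy`).
#' @export
aggregate_pseudo_spots <- function(data, grid, min_cells = 1L) {
  stopifnot(inherits(grid, "spot_grid"))
  asg <- grid$assignment
  if (nrow(asg) != ncol(data)) {
    stop("grid assignment covers ", nrow(asg), " cells but the dataset ",
         "has ", ncol(data))
  }
  if (min_cells < 1) stop("'min_cells' must be >= 1")
  keys <- split(seq_len(ncol(data)), asg$spot)
  sizes <- lengths(keys)
  dropped <- sum(sizes < min_cells)
  keys <- keys[sizes >= min_cells]
  if (length(keys) == 0) {
    stop("no grid square holds at least min_cells = ", min_cells, " cells")
  }
  if (dropped > 0) {
    message(dropped, " square(s) below min_cells = ", min_cells,
            " dropped (", sum(sizes[sizes < min_cells]), " cells)")
  }
  # order spots by (iy, ix) for a reproducible layout
  first <- vapply(keys, `[`, 1L, 1L)
  ord <- order(asg$iy[first], asg$ix[first])
  keys <- keys[ord]

  members <- lapply(keys, function(i) colnames(data)[i])
  ix <- asg$ix[vapply(keys, `[`, 1L, 1L)]
  iy <- asg$iy[vapply(keys, `[`, 1L, 1L)]
  centroids <- cbind(grid$origin[1] + (ix + 0.5) * grid$spot_side,
                     grid$origin[2] + (iy + 0.5) * grid$spot_side)
  sce <- .build_spot_dataset(data, members, centroids,
                             zone = rep(0L, length(members)),
                             spot_prefix = "pseudospot",
                             extra = list(spot_grid = grid[c("spot_side",
                                                             "origin")],
                                          min_cells = min_cells))
  colData(sce)$zone <- NULL
  colData(sce)$ix <- as.integer(ix)
  colData(sce)$iy <- as.integer(iy)
  sce
}
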
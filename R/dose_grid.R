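#' Dose distribution on a uniform grid
#'
#' The common currency of all comparisons in the package: dose values on a
#' regular 1-, 2- or 3-dimensional grid with physical node spacing and origin
#' in millimetres. Coordinates are node-centred; the physical coordinate of
#' node `i` (1-based) on axis `a` is `origin[a] + (i - 1) * spacing[a]`.
#'
#' @param values numeric vector (1D) or array (2D/3D) of dose values.
#'   All values must be finite and non-negative; every axis needs at least
#'   two nodes. Units are Gy unless `is_relative = TRUE`.
#' @param spacing numeric vector of per-axis node spacing in mm (all > 0),
#'   one entry per axis of `values`.
#' @param origin numeric vector, physical coordinate (mm) of the first node
#'   on each axis. Defaults to 0 on every axis.
#' @param axes character vector of axis names (e.g. `c("z", "y", "x")` or
#'   `"depth"`). Defaults to `x`/`y`/`z` style names by dimensionality.
#' @param is_relative logical; `TRUE` marks normalised (relative) dose.
#'
#' @return An object of class `dose_grid`: a list with elements `values`
#'   (always stored as an array), `spacing`, `origin`, `axes`, `is_relative`.
#' @examples
#' g <- dose_grid(matrix(1:12, 3, 4), spacing = c(2, 2))
#' grid_axis_coords(g, 1)
#' @export
dose_grid <- function(values, spacing, origin = NULL, axes = NULL,
                      is_relative = FALSE) {
  if (is.null(dim(values))) values <- array(as.numeric(values), dim = length(values))
  values <- as.array(values)
  storage.mode(values) <- "double"
  nd <- length(dim(values))
  if (nd < 1L || nd > 3L) {
    stop("dose_grid supports 1 to 3 axes, got ", nd)
  }
  if (any(dim(values) < 2L)) {
    stop("every axis must have at least 2 nodes (dims: ",
         paste(dim(values), collapse = "x"), ")")
  }
  if (any(!is.finite(values))) stop("dose values must all be finite")
  if (any(values < 0)) stop("dose values must be non-negative")
  spacing <- as.numeric(spacing)
  if (length(spacing) != nd) stop("spacing must have one entry per axis")
  if (any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("spacing must be positive and finite")
  }
  if (is.null(origin)) origin <- rep(0, nd)
  origin <- as.numeric(origin)
  if (length(origin) != nd) stop("origin must have one entry per axis")
  if (any(!is.finite(origin))) stop("origin must be finite")
  if (is.null(axes)) {
    axes <- switch(nd, "x", c("y", "x"), c("z", "y", "x"))
  }
  axes <- as.character(axes)
  if (length(axes) != nd) stop("axes must have one name per axis")
  structure(
    list(values = values, spacing = spacing, origin = origin,
         axes = axes, is_relative = isTRUE(is_relative)),
    class = "dose_grid"
  )
}

#' @export
print.dose_grid <- function(x, ...) {
  cat(sprintf(
    "<dose_grid> %s [%s] spacing %s mm, origin %s mm, %s dose\n",
    paste(dim(x$values), collapse = "x"),
    paste(x$axes, collapse = ","),
    paste(format(x$spacing), collapse = "x"),
    paste(format(x$origin), collapse = ","),
    if (x$is_relative) "relative" else "absolute"
  ))
  invisible(x)
}

#' Number of axes of a dose grid
#' @param grid a [dose_grid()].
#' @return integer dimensionality (1, 2 or 3).
#' @export
grid_ndim <- function(grid) length(dim(grid$values))

#' Physical node coordinates along one axis
#' @param grid a [dose_grid()].
#' @param axis axis index (1-based).
#' @return numeric vector of node coordinates in mm.
#' @export
grid_axis_coords <- function(grid, axis) {
  n <- dim(grid$values)[axis]
  grid$origin[axis] + (seq_len(n) - 1) * grid$spacing[axis]
}

#' Physical extent of a grid
#' @param grid a [dose_grid()].
#' @return a 2 x ndim matrix; row 1 the lower, row 2 the upper bound (mm).
#' @export
grid_extent <- function(grid) {
  nd <- grid_ndim(grid)
  lo <- grid$origin
  hi <- grid$origin + (dim(grid$values) - 1) * grid$spacing
  rbind(lo = lo, hi = hi)
}

#' Matrix of all node coordinates
#'
#' Returns the physical coordinates of every grid node, in the storage order
#' of `as.vector(grid$values)` (first axis fastest, R column-major order).
#'
#' @param grid a [dose_grid()].
#' @return an N x ndim numeric matrix of coordinates (mm).
#' @export
grid_node_coords <- function(grid) {
  coords <- lapply(seq_len(grid_ndim(grid)), function(a) grid_axis_coords(grid, a))
  as.matrix(expand.grid(coords, KEEP.OUT.ATTRS = FALSE))
}

#' Resample a dose grid at arbitrary physical positions
#'
#' Multilinear (linear/bilinear/trilinear) interpolation of the dose at each
#' query position. Interpolation is exact at grid nodes and reproduces any
#' multilinear function of the coordinates exactly. No extrapolation is
#' performed.
#'
#' @param grid a [dose_grid()].
#' @param positions an N x ndim matrix (or a vector for 1D grids) of physical
#'   coordinates in mm.
#' @param outside how to treat positions outside the grid extent: `"error"`
#'   (default) or `"na"` to return `NA` for those positions.
#' @return numeric vector of interpolated dose values, one per position.
#' @export
resample_to <- function(grid, positions, outside = c("error", "na")) {
  outside <- match.arg(outside)
  nd <- grid_ndim(grid)
  if (is.null(dim(positions))) {
    if (nd == 1L) positions <- matrix(positions, ncol = 1L)
    else positions <- matrix(positions, ncol = nd, byrow = TRUE)
  }
  if (ncol(positions) != nd) {
    stop("positions must have ", nd, " columns to match the grid")
  }
  out <- grid_interp(grid, positions)
  if (outside == "error" && anyNA(out)) {
    stop("position outside grid extent (", sum(is.na(out)), " of ",
         length(out), " queries)")
  }
  out
}

#' Monte Carlo batch statistical uncertainty
#'
#' Per voxel, the standard error of the mean dose across independent batches,
#' expressed as a percentage of that voxel's mean dose; the reported figure is
#' the average of this quantity over all voxels whose mean dose exceeds 70% of
#' the maximum mean dose. This is the batch-based statistical-uncertainty
#' definition used when commissioning Monte Carlo dose engines.
#'
#' @param batches a list of [dose_grid()] objects on identical grids
#'   (same dims, spacing, origin); at least 2.
#' @param threshold_fraction voxels with mean dose above this fraction of the
#'   maximum mean dose enter the average (default 0.7).
#' @return the mean relative standard error, in percent.
#' @export
batch_uncertainty <- function(batches, threshold_fraction = 0.7) {
  if (!is.list(batches) || length(batches) < 2L) {
    stop("need at least 2 batches")
  }
  ref <- batches[[1L]]
  for (b in batches[-1L]) {
    if (!identical(dim(b$values), dim(ref$values)) ||
        !isTRUE(all.equal(b$spacing, ref$spacing)) ||
        !isTRUE(all.equal(b$origin, ref$origin))) {
      stop("all batches must share an identical grid")
    }
  }
  m <- vapply(batches, function(b) as.vector(b$values),
              numeric(length(ref$values)))
  mu <- rowMeans(m)
  mx <- max(mu)
  if (mx <= 0) stop("maximum mean dose is zero; uncertainty undefined")
  sel <- mu > threshold_fraction * mx
  sem <- apply(m[sel, , drop = FALSE], 1L, stats::sd) / sqrt(ncol(m))
  mean(100 * sem / mu[sel])
}
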
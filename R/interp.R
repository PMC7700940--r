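# Vectorised multilinear interpolation on uniform grids (d = 1..3).
# Returns NA for queries outside [first node, last node] on any axis.
# Queries exactly on the upper boundary are clamped into the last cell so the
# boundary node value is reproduced exactly.
grid_interp <- function(grid, pts) {
  v <- grid$values
  dims <- dim(v)
  nd <- length(dims)
  n <- nrow(pts)
  if (n == 0L) return(numeric(0))

  i0 <- matrix(0L, n, nd)   # lower cell index, 0-based
  fr <- matrix(0, n, nd)    # fractional position within cell
  ok <- rep(TRUE, n)
  tol <- 1e-9
  for (a in seq_len(nd)) {
    t_a <- (pts[, a] - grid$origin[a]) / grid$spacing[a]
    ok <- ok & t_a >= -tol & t_a <= (dims[a] - 1) + tol
    t_a <- pmin(pmax(t_a, 0), dims[a] - 1)
    ia <- floor(t_a)
    ia[ia > dims[a] - 2] <- dims[a] - 2   # clamp upper boundary into last cell
    i0[, a] <- as.integer(ia)
    fr[, a] <- t_a - ia
  }

  # linear index of the lower corner (0-based), strides in storage order
  stride <- cumprod(c(1L, dims[-nd]))
  base <- rep(0, n)
  for (a in seq_len(nd)) base <- base + i0[, a] * stride[a]

  out <- rep(0, n)
  vv <- as.vector(v)
  # accumulate over the 2^nd corners
  for (corner in seq_len(2L^nd) - 1L) {
    w <- rep(1, n)
    off <- 0
    for (a in seq_len(nd)) {
      bit <- bitwAnd(corner, bitwShiftL(1L, a - 1L)) > 0L
      if (bit) {
        w <- w * fr[, a]
        off <- off + stride[a]
      } else {
        w <- w * (1 - fr[, a])
      }
    }
    out <- out + w * vv[base + off + 1]
  }
  out[!ok] <- NA_real_
  out
}
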
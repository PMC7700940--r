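# Smooth random dose pairs for oracle-equivalence and property sweeps.
# Fields are sums of broad Gaussians (sigma 15-25 mm), so the gamma surface
# is well resolved by the engine's search lattice; perturbations are a small
# global scaling plus a sub-voxel rigid shift of the underlying pattern.
smooth_random_pair <- function(nd, seed, shape, spacing = 3,
                               shift_max = 0.5, scale_max = 1.5) {
  set.seed(seed)
  shape <- rep(shape, length.out = nd)
  ext <- (shape - 1) * spacing
  g <- dose_grid(array(0, dim = if (nd == 1L) shape[1L] else shape),
                 spacing = rep(spacing, nd), origin = -ext / 2)
  pts <- grid_node_coords(g)
  cs <- lapply(1:3, function(j) stats::runif(nd, -4, 4))
  sg <- stats::runif(3, 15, 25)
  am <- stats::runif(3, 2, 5)
  field <- function(p) {
    v <- rep(2, nrow(p))
    for (j in 1:3) {
      v <- v + am[j] * exp(-rowSums(sweep(p, 2, cs[[j]])^2) / (2 * sg[j]^2))
    }
    v
  }
  shift <- stats::runif(nd, -shift_max, shift_max)
  scale <- 1 + stats::runif(1, -scale_max, scale_max) / 100
  ref <- g
  ref$values[] <- field(pts)
  ev <- g
  ev$values[] <- scale * field(sweep(pts, 2, shift, "-"))
  list(reference = ref, evaluated = ev)
}

# correlated Gaussian pair with given population correlation
correlated_series <- function(n, rho, seed) {
  set.seed(seed)
  z1 <- stats::rnorm(n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
  list(a = qa_series(90 + 2 * z1, metric_name = "pass_rate"),
       b = qa_series(90 + 2 * z2, metric_name = "pass_rate"))
}
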
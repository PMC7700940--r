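#' Gamma evaluation criteria
#'
#' Settings for a gamma-index comparison, written in the usual shorthand
#' as a dose-difference / distance-to-agreement pair, e.g. `Γ(2,1)` for 2%
#' dose difference and 1 mm DTA.
#'
#' @param dose_diff_percent dose-difference criterion ΔD, in percent of the
#'   normalization dose (> 0).
#' @param dta_mm distance-to-agreement criterion Δd, in mm (> 0).
#' @param normalization `"global-max"`: ΔD is a percentage of the maximum of
#'   the reference distribution; `"local"`: of the local reference dose.
#' @param cutoff_percent reference points below this percentage of the global
#'   reference maximum are excluded from the statistics (0 = no cutoff).
#' @param search_radius_factor spatial search extends to this multiple of Δd
#'   around each reference point (>= 1). Beyond 3·Δd the distance term alone
#'   gives γ > 3, so the default loses nothing in practice.
#' @param search_step_fraction coarse search step as a fraction of Δd
#'   (0 < f <= 1). The engine refines the coarse optimum locally, so the
#'   default Δd/10 grid governs cost, not final accuracy.
#' @return object of class `gamma_criteria`.
#' @export
gamma_criteria <- function(dose_diff_percent = 2, dta_mm = 1,
                           normalization = c("global-max", "local"),
                           cutoff_percent = 10,
                           search_radius_factor = 3,
                           search_step_fraction = 0.1) {
  normalization <- match.arg(normalization)
  stopifnot(dose_diff_percent > 0, dta_mm > 0,
            cutoff_percent >= 0, cutoff_percent < 100,
            search_radius_factor >= 1,
            search_step_fraction > 0, search_step_fraction <= 1)
  structure(
    list(dose_diff_percent = dose_diff_percent, dta_mm = dta_mm,
         normalization = normalization, cutoff_percent = cutoff_percent,
         search_radius_factor = search_radius_factor,
         search_step_fraction = search_step_fraction),
    class = "gamma_criteria"
  )
}

#' @export
print.gamma_criteria <- function(x, ...) {
  cat(sprintf("<gamma_criteria> Gamma(%g%%, %g mm), %s normalization, %g%% cutoff\n",
              x$dose_diff_percent, x$dta_mm, x$normalization, x$cutoff_percent))
  invisible(x)
}

# a point passes iff gamma <= 1 + GAMMA_PASS_TOL (deterministic boundary case)
GAMMA_PASS_TOL <- 1e-9

new_gamma_result <- function(gamma_vec, mask, dims, criteria, n_boundary) {
  gm <- rep(NA_real_, prod(dims))
  gm[mask] <- gamma_vec
  gamma_map <- array(gm, dim = dims)
  structure(
    list(gamma_map = gamma_map, evaluated_mask = array(mask, dim = dims),
         pass_rate = 100 * mean(gamma_vec <= 1 + GAMMA_PASS_TOL),
         mean_gamma = mean(gamma_vec),
         n_evaluated = length(gamma_vec), n_boundary = n_boundary,
         criteria = criteria),
    class = "gamma_result"
  )
}

#' @export
print.gamma_result <- function(x, ...) {
  cat(sprintf(
    "<gamma_result> Gamma(%g%%, %g mm): pass rate %.2f%%, mean gamma %.3f (%d points, %d at search boundary)\n",
    x$criteria$dose_diff_percent, x$criteria$dta_mm,
    x$pass_rate, x$mean_gamma, x$n_evaluated, x$n_boundary))
  invisible(x)
}

# shared setup: cutoff mask, normalization dose, boundary-point count
gamma_setup <- function(reference, evaluated, criteria) {
  stopifnot(inherits(reference, "dose_grid"), inherits(evaluated, "dose_grid"),
            inherits(criteria, "gamma_criteria"))
  if (grid_ndim(reference) != grid_ndim(evaluated)) {
    stop("reference and evaluated grids must have the same dimensionality")
  }
  ref_vals <- as.vector(reference$values)
  gmax <- max(ref_vals)
  if (gmax <= 0) stop("reference distribution has no positive dose")
  mask <- ref_vals >= criteria$cutoff_percent / 100 * gmax
  if (!any(mask)) stop("no evaluable points: every reference point is below the dose cutoff")
  pts <- grid_node_coords(reference)[mask, , drop = FALSE]
  dd_abs <- if (criteria$normalization == "global-max") {
    rep(criteria$dose_diff_percent / 100 * gmax, sum(mask))
  } else {
    criteria$dose_diff_percent / 100 * ref_vals[mask]
  }
  radius <- criteria$search_radius_factor * criteria$dta_mm
  ext <- grid_extent(evaluated)
  inside_ball <- rep(TRUE, nrow(pts))
  for (a in seq_len(ncol(pts))) {
    inside_ball <- inside_ball &
      (pts[, a] - radius >= ext[1L, a] - 1e-9) &
      (pts[, a] + radius <= ext[2L, a] + 1e-9)
  }
  list(ref = ref_vals[mask], pts = pts, mask = mask, dd_abs = dd_abs,
       radius = radius, n_boundary = sum(!inside_ball),
       dims = dim(reference$values))
}

# lattice of search offsets with |o| <= radius, sorted by distance
offset_lattice <- function(nd, step, radius) {
  k <- floor(radius / step + 1e-9)
  ax <- (-k:k) * step
  off <- as.matrix(expand.grid(rep(list(ax), nd), KEEP.OUT.ATTRS = FALSE))
  d <- sqrt(rowSums(off^2))
  keep <- d <= radius + 1e-9
  off <- off[keep, , drop = FALSE]
  d <- d[keep]
  o <- order(d)
  list(off = unname(off[o, , drop = FALSE]), dist = d[o])
}

# per-point minimum over a (points x offsets) candidate block; offsets is an
# n_pair x nd matrix aligned with rep(point_idx, times = n_off) pairing
pairwise_min_update <- function(evaluated, pts, ref, dd_abs, dta,
                                point_idx, off_pairs, gmin, best) {
  q <- pts[point_idx, , drop = FALSE] + off_pairs
  dval <- grid_interp(evaluated, q)
  d2 <- rowSums(off_pairs^2)
  cand <- sqrt(d2 / dta^2 + ((dval - ref[point_idx]) / dd_abs[point_idx])^2)
  cand[is.na(cand)] <- Inf
  na <- length(unique(point_idx))  # callers pass rep(active, times = n_off)
  ns <- length(cand) / na
  cm <- matrix(cand, na, ns)
  j <- max.col(-cm, ties.method = "first")
  rowmin <- cm[cbind(seq_len(na), j)]
  act <- point_idx[seq_len(na)]
  imp <- which(rowmin < gmin[act])
  if (length(imp)) {
    gmin[act[imp]] <- rowmin[imp]
    best[act[imp], ] <- off_pairs[(j[imp] - 1L) * na + imp, , drop = FALSE]
  }
  list(gmin = gmin, best = best)
}

# one vectorised sweep over a local lattice around each point's current best
# offset (engine refinement); deltas are processed in adaptive batches
refine_stage <- function(evaluated, pts, ref, dd_abs, dta, radius,
                         gmin, best, span, step) {
  k <- round(span / step)
  ax <- (-k:k) * step
  nd <- ncol(pts)
  deltas <- as.matrix(expand.grid(rep(list(ax), nd), KEEP.OUT.ATTRS = FALSE))
  deltas <- deltas[rowSums(abs(deltas)) > 0, , drop = FALSE]
  centre <- best  # fixed per stage: the lattice must not drift with updates
  n <- nrow(pts)
  kbatch <- max(1L, 50000L %/% n)
  idx <- 1L
  while (idx <= nrow(deltas)) {
    hi <- min(idx + kbatch - 1L, nrow(deltas))
    sel <- idx:hi
    ns <- length(sel)
    point_idx <- rep(seq_len(n), times = ns)
    off_pairs <- centre[point_idx, , drop = FALSE] +
      deltas[rep(sel, each = n), , drop = FALSE]
    # discard pairs outside the search ball by inflating their distance term
    out <- rowSums(off_pairs^2) > radius^2 + 1e-9
    if (any(out)) off_pairs[out, ] <- radius * 1e6
    st <- pairwise_min_update(evaluated, pts, ref, dd_abs, dta,
                              point_idx, off_pairs, gmin, best)
    gmin <- st$gmin
    best <- st$best
    idx <- hi + 1L
  }
  list(gmin = gmin, best = best)
}

#' Gamma-index comparison of two dose distributions
#'
#' Computes the gamma index of Low et al. at every reference grid node above
#' the dose cutoff:
#' \deqn{\gamma(r) = \min_{r'} \sqrt{ |r'-r|^2/\Delta d^2 +
#'   (D_e(r') - D_r(r))^2/\Delta D^2 }}
#' where the evaluated distribution \eqn{D_e} is multilinearly interpolated.
#' The minimisation searches a lattice of spatial offsets of step
#' `search_step_fraction * dta_mm` within radius `search_radius_factor *
#' dta_mm` (exact distance-term pruning), then refines the optimum on two
#' successively finer local lattices; in 1D the whole interval is instead
#' scanned densely at a tenth of the coarse step. Reference points
#' whose search ball extends beyond the evaluated extent are minimised over
#' the intersection and counted in `n_boundary`.
#'
#' @param reference reference [dose_grid()] (defines the evaluated points,
#'   the cutoff and the global normalization dose).
#' @param evaluated evaluated [dose_grid()] of equal dimensionality (grids
#'   need not coincide).
#' @param criteria a [gamma_criteria()].
#' @param refine logical; apply the local refinement stages (default `TRUE`).
#' @return a `gamma_result`: gamma map on the reference grid (`NA` below
#'   cutoff), evaluated mask, pass rate (% of evaluated points with γ ≤ 1),
#'   mean gamma, boundary-point count and the criteria used.
#' @references Low D.A. et al., A technique for the quantitative evaluation
#'   of dose distributions, Med. Phys. 25 (1998) 656-661.
#' @export
gamma_index <- function(reference, evaluated, criteria = gamma_criteria(),
                        refine = TRUE) {
  s <- gamma_setup(reference, evaluated, criteria)
  dta <- criteria$dta_mm
  step <- criteria$search_step_fraction * dta
  # in 1D a dense scan of the whole search interval is cheap, so the coarse
  # lattice is simply taken 10x finer and no local refinement is needed
  dense_1d <- ncol(s$pts) == 1L
  if (dense_1d) step <- step / 10
  lat <- offset_lattice(ncol(s$pts), step, s$radius)
  n <- nrow(s$pts)
  gmin <- rep(Inf, n)
  best <- matrix(0, n, ncol(s$pts))
  nlat <- length(lat$dist)
  idx <- 1L
  while (idx <= nlat) {
    # offsets are sorted by distance: a point whose minimum is already below
    # the next distance term cannot improve and drops out of the batch
    active <- which(gmin > lat$dist[idx] / dta)
    if (!length(active)) break
    kbatch <- max(1L, 50000L %/% length(active))
    hi <- min(idx + kbatch - 1L, nlat)
    sel <- idx:hi
    na <- length(active)
    point_idx <- rep(active, times = length(sel))
    off_pairs <- lat$off[rep(sel, each = na), , drop = FALSE]
    st <- pairwise_min_update(evaluated, s$pts, s$ref, s$dd_abs, dta,
                              point_idx, off_pairs, gmin, best)
    gmin <- st$gmin
    best <- st$best
    idx <- hi + 1L
  }
  if (refine && !dense_1d && any(is.finite(gmin))) {
    # local refinement around the coarse optimum; stage sizes balance lattice
    # resolution against the 2^d growth of each stage
    nd <- ncol(s$pts)
    spans <- switch(nd,
                    list(c(2, 1 / 20), c(1 / 10, 1 / 200)),
                    list(c(2, 1 / 5), c(1 / 5, 1 / 25)),
                    list(c(1.5, 1 / 4), c(1 / 4, 1 / 20)))
    st <- list(gmin = gmin, best = best)
    for (sp in spans) {
      st <- refine_stage(evaluated, s$pts, s$ref, s$dd_abs, dta, s$radius,
                         st$gmin, st$best, span = sp[1] * step,
                         step = sp[2] * step)
    }
    gmin <- st$gmin
  }
  new_gamma_result(gmin, s$mask, s$dims, criteria, s$n_boundary)
}

#' Brute-force gamma oracle
#'
#' Same contract as [gamma_index()], computed by exhaustive dense sampling of
#' the search ball at a fixed step of `dta_mm / 100`. Intended as ground
#' truth on small instances (up to roughly 1e4 reference points); the search
#' is pruned only by the exact bound that an offset farther than γ·Δd cannot
#' improve the current minimum, so the result is identical to the unpruned
#' dense search.
#'
#' @inheritParams gamma_index
#' @return a `gamma_result`.
#' @export
gamma_oracle <- function(reference, evaluated, criteria = gamma_criteria()) {
  s <- gamma_setup(reference, evaluated, criteria)
  nd <- ncol(s$pts)
  dta <- criteria$dta_mm
  step <- dta / 100
  n <- nrow(s$pts)
  gmin <- rep(Inf, n)

  if (nd <= 2L) {
    lat <- offset_lattice(nd, step, s$radius)
    chunk <- 4096L
    for (i in seq_len(n)) {
      # start from the zero-offset candidate, then scan outward in chunks
      g <- oracle_cand(evaluated, s$pts[i, , drop = FALSE], 0, s$ref[i],
                       s$dd_abs[i], dta)
      idx <- 1L
      nlat <- length(lat$dist)
      while (idx <= nlat && lat$dist[idx] / dta < g) {
        hi <- min(idx + chunk - 1L, nlat)
        hi <- idx - 1L + findInterval(g * dta + 1e-12, lat$dist[idx:hi])
        if (hi < idx) break
        sel <- idx:hi
        q <- sweep(lat$off[sel, , drop = FALSE], 2L, s$pts[i, ], "+")
        dval <- grid_interp(evaluated, q)
        cand <- sqrt((lat$dist[sel] / dta)^2 +
                       ((dval - s$ref[i]) / s$dd_abs[i])^2)
        g <- min(g, cand, na.rm = TRUE)
        idx <- hi + 1L
      }
      gmin[i] <- g
    }
  } else {
    # 3D: z-slab sweep over a dense in-plane lattice, exact pruning by the
    # running minimum
    lat2 <- offset_lattice(2L, step, s$radius)
    d2sq <- lat2$dist^2
    # a sub-sampled pass (every 10th fine offset) first: tightens the running
    # minimum cheaply, which shrinks the dense-scan radius; still exact
    lat10 <- offset_lattice(3L, 10 * step, s$radius)
    kz <- floor(s$radius / step + 1e-9)
    zs <- (0:kz) * step
    zs <- as.vector(rbind(zs, -zs))[-2L]          # 0, s, -s, 2s, -2s, ...
    for (i in seq_len(n)) {
      p <- s$pts[i, ]
      g <- oracle_cand(evaluated, s$pts[i, , drop = FALSE], 0, s$ref[i],
                       s$dd_abs[i], dta)
      m10 <- findInterval(min(g, Inf) * dta - 1e-12, lat10$dist)
      if (m10 >= 1L) {
        q10 <- sweep(lat10$off[1:m10, , drop = FALSE], 2L, p, "+")
        dv <- grid_interp(evaluated, q10)
        cand <- sqrt((lat10$dist[1:m10] / dta)^2 +
                       ((dv - s$ref[i]) / s$dd_abs[i])^2)
        g <- min(g, cand, na.rm = TRUE)
      }
      # dense scan, z-slabs accumulated into large batches; the running
      # minimum shrinks the admissible in-plane radius between batches
      buf_z <- numeric(0); buf_m <- integer(0); buf_rows <- 0L
      flush <- function() {
        if (buf_rows == 0L) return(invisible())
        qx <- numeric(buf_rows); qy <- numeric(buf_rows); qz <- numeric(buf_rows)
        dd2 <- numeric(buf_rows)
        at <- 0L
        for (j in seq_along(buf_z)) {
          m <- buf_m[j]
          sel <- (at + 1L):(at + m)
          qz[sel] <- p[1L] + buf_z[j]
          qy[sel] <- p[2L] + lat2$off[1:m, 1L]
          qx[sel] <- p[3L] + lat2$off[1:m, 2L]
          dd2[sel] <- buf_z[j]^2 + d2sq[1:m]
          at <- at + m
        }
        dval <- grid_interp(evaluated, cbind(qz, qy, qx))
        cand <- sqrt(dd2 / dta^2 + ((dval - s$ref[i]) / s$dd_abs[i])^2)
        g <<- min(g, cand, na.rm = TRUE)
        buf_z <<- numeric(0); buf_m <<- integer(0); buf_rows <<- 0L
        invisible()
      }
      for (dz in zs) {
        if (abs(dz) / dta >= g) {
          if (dz > 0) next else { flush(); if (abs(dz) / dta >= g) break else next }
        }
        rmax2 <- (min(g, s$radius / dta) * dta)^2 - dz^2
        m <- findInterval(rmax2 + 1e-12, d2sq)
        if (m < 1L) next
        buf_z <- c(buf_z, dz); buf_m <- c(buf_m, m)
        buf_rows <- buf_rows + m
        if (buf_rows >= 400000L) flush()
      }
      flush()
      gmin[i] <- g
    }
  }
  new_gamma_result(gmin, s$mask, s$dims, criteria, s$n_boundary)
}

oracle_cand <- function(evaluated, p, dist, refval, dd_abs, dta) {
  dval <- grid_interp(evaluated, p)
  if (is.na(dval)) return(Inf)
  sqrt((dist / dta)^2 + ((dval - refval) / dd_abs)^2)
}

#' Per-plan gamma comparison with the clinical QA presets
#'
#' Fixed criteria Γ(2%, 1 mm), global-maximum normalization, 10% dose cutoff
#' — the settings used both for 2D measurement-vs-TPS comparisons and for 3D
#' independent-dose-calculation-vs-TPS comparisons.
#'
#' @param reference reference [dose_grid()] (TPS dose).
#' @param evaluated evaluated [dose_grid()] (measurement plane or IDC volume).
#' @param mode `"2d-measurement"` (expects 2-axis grids) or `"3d-idc"`
#'   (expects 3-axis grids).
#' @return a `gamma_result`.
#' @export
compare_plan <- function(reference, evaluated,
                         mode = c("3d-idc", "2d-measurement")) {
  mode <- match.arg(mode)
  want <- if (mode == "2d-measurement") 2L else 3L
  if (grid_ndim(reference) != want || grid_ndim(evaluated) != want) {
    stop("mode '", mode, "' expects ", want, "-axis grids")
  }
  gamma_index(reference, evaluated,
              gamma_criteria(dose_diff_percent = 2, dta_mm = 1,
                             normalization = "global-max",
                             cutoff_percent = 10))
}
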
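---
title: "Gamma-index dose comparison and SPC action levels: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gamma-index dose comparison and SPC action levels: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

This vignette documents the models, conventions and numerical choices behind
`gammaspc`: how the gamma index is computed and verified, how the
statistical-process-control (SPC) action levels are derived, what the
synthetic-data generators emulate, and which design questions were genuinely
open and how they were settled.

## Dose-grid data model

All comparisons operate on `dose_grid` objects: dose values on a uniform,
node-centred grid with per-axis spacing and origin in millimetres. The
physical coordinate of node `i` (1-based) on axis `a` is
`origin[a] + (i - 1) * spacing[a]`. Only uniform grids are supported;
non-uniform input (e.g. an RT Dose object with unequal frame offsets) is
rejected rather than silently resampled, because every downstream statistic
assumes equally weighted voxels.

Depth-dose curves put depth 0 at the water surface, so the build-up region
is part of every comparison interval. DICOM RT Dose volumes are normalised
internally to `(z, y, x)` axis order at read time; the portable JSON grid
format stores axis names explicitly. Both choices exist to remove silent
transposition bugs, the classic failure mode of dose-plane comparisons.

Interpolation is multilinear everywhere (linear / bilinear / trilinear), and
deliberately not spline-based: the multilinear interpolant is monotone
between nodes, cheap, exact for any multilinear function, and — most
importantly — gives the gamma minimisation a single well-defined objective
that an independent dense search can verify against.

## The gamma index

For a reference distribution \(D_r\) and an evaluated distribution \(D_e\),
the per-point index is

\[
\gamma(\mathbf r) \;=\; \min_{\mathbf r'}
\sqrt{\frac{\lVert\mathbf r'-\mathbf r\rVert^2}{\Delta d^2}
     +\frac{\bigl(D_e(\mathbf r')-D_r(\mathbf r)\bigr)^2}{\Delta D^2}},
\]

with \(\Delta d\) the distance-to-agreement criterion (mm) and \(\Delta D\)
the dose-difference criterion, written \(\Gamma(\Delta D\%, \Delta d\,\mathrm{mm})\).
A point passes when \(\gamma \le 1\). Conventions fixed by the package:

* **Normalization.** Under `global-max`, \(\Delta D\) is a percentage of the
  *true* maximum of the reference distribution, taken before any cutoff
  masking; under `local` it is a percentage of the local reference dose.
* **Cutoff.** The dose cutoff masks *reference* points below the given
  percentage of the global reference maximum. Applying the cutoff to the
  reference (rather than the evaluated) side is the dominant convention and
  keeps the evaluated mask independent of the comparison outcome.
* **Pass rule.** A point passes iff \(\gamma \le 1 + 10^{-9}\). The
  tolerance makes the flat-field boundary case — a spatially flat pair
  differing by exactly the dose criterion, where \(\gamma \equiv 1\) —
  deterministically a pass instead of a floating-point coin flip.
* **Boundary points.** Reference points whose search ball extends beyond the
  evaluated extent are minimised over the intersection, and their count is
  reported (`n_boundary`), so optimistic edge gammas are at least visible.
* **Statistics.** Pass rate and mean gamma are computed over the same
  evaluated mask, which keeps the two charted metrics commensurable.

### Search numerics

The engine minimises over a lattice of spatial offsets of step
`search_step_fraction * dta_mm` (default a tenth of the DTA) within radius
`search_radius_factor * dta_mm` (default 3): beyond three DTA the distance
term alone gives \(\gamma > 3\), far above anything a QA decision depends
on. Offsets are visited in order of increasing distance with exact pruning —
once a point's running minimum is below the next offset's distance term, no
farther offset can improve it — and are processed in adaptive batches
(points × offsets per vectorised call) so the cost of a few stubborn
high-gamma points stays bounded.

The coarse optimum is then refined on two fixed-centre local lattices
(spans of about 1.5–2 coarse steps at 4–5× finer pitch, then one coarse-step
fraction at 20–25× finer pitch). The refinement lattice must *not* re-centre
on every improvement: greedy drifting loses the guarantee that the whole
neighbourhood of the coarse optimum is sampled, and measurably worsens
agreement with the dense search. In 1D the entire search interval is instead
scanned densely at a tenth of the coarse step, which is cheaper than
refinement at these problem sizes.

`gamma_oracle()` is a separate, point-major implementation that samples the
search ball exhaustively at a fixed `dta/100` step, pruned only by the exact
distance bound (plus a sub-sampled first pass that merely tightens the
running minimum earlier). It exists to guard the engine's search design: the
test suite requires engine and oracle to agree within 0.01 in gamma and 0.1
percentage points in pass rate over randomized 1D/2D/3D instances.

That agreement bound is demonstrated on *smooth* dose fields (sums of broad
Gaussians). When the evaluated distribution has structure at the voxel scale
— strong per-voxel noise on a steep gradient — the gamma objective acquires
many near-degenerate local minima whose depths differ below the coarse
lattice resolution, and any hierarchical search can mis-rank them; the
engine then errs on the conservative (higher-gamma) side. The oracle suite
therefore shows correctness of the search on resolvable objectives, not a
universal error bound for arbitrarily rough inputs.

## Beam-model validation conventions

* **Output factors.** The relative error is signed as
  `100 * (calculated - measured) / measured`, so a negative value means the
  calculation under-reads; summaries report the per-collimator mean, min–max
  range and within-1%/within-2% counts.
* **Detector correction.** Small-field diode over-response is corrected by a
  user-supplied factor table, linearly interpolated between tabulated field
  sizes and never extrapolated; the factors themselves come from the
  published literature and are inputs, not outputs, of this package.
* **Depth-dose curves** are compared in absolute dose with \(\Delta D\)
  normalised to the global maximum of the *measured* curve, so a global
  output error propagates into the comparison instead of being normalised
  away. Off-centre ratios are first normalised to their central-axis value
  (interpolated at position 0), which makes the comparison invariant to
  independent rescaling of either curve — the defining property of a
  relative profile.
* **Denominators.** Pass rates count measured-curve samples inside the
  common position interval: the measurement is the ground truth being
  validated against. OCR results pool all depths per collimator/field size
  by default; a per-depth split is available.

## SPC action levels

QA metrics are charted as individuals \(x_i\) in chronological order with
the moving range \(R_i = |x_i - x_{i-1}|\) as the dispersion estimate
(the printed defining equation carries no absolute-value bars, but a range
must be non-negative for the range-chart limits to make sense; the absolute
value is standard practice). With \(\bar R\) the mean moving range and the
tabulated constants \(d_2 = 1.128\), \(d_3 = 0.853\) for subgroup size
\(n = 2\):

\[
A_c = \bar x,\qquad
A_{u,l} = A_c \pm \frac{3}{d_2\sqrt n}\,\bar R = A_c \pm 1.88\,\bar R,
\]
\[
R_c = \bar R,\qquad
R_u = \Bigl(1 + \frac{3 d_3}{d_2}\Bigr)\bar R = 3.267\,\bar R,\qquad
R_l = \Bigl(1 - \frac{3 d_3}{d_2}\Bigr)\bar R = -1.267\,\bar R \rightarrow 0 .
\]

\(R_l\) is floored at zero (the raw negative value is kept as a
diagnostic), and for metrics with a physical ceiling — a pass rate cannot
exceed 100% — \(A_u\) is capped and flagged as clipped.

One property of these formulas deserves emphasis. Because the half-width
uses \(3/(d_2\sqrt 2)\) rather than the individuals-chart constant
\(3/d_2 = 2.66\), the limits sit at \(3\sigma/\sqrt 2 \approx 2.12\sigma\)
for Gaussian individuals. Flagging individuals against them therefore trips
on about \(2\Phi(-2.12) \approx 3.4\%\) of in-control points — they are
3-sigma limits for the *mean of two successive measurements*, not for the
individuals themselves. The package follows the method as printed (limits
with the \(\sqrt n\) factor, flags on individuals, as the out-of-control
definition states) and its Monte-Carlo property test asserts the 3.4%
in-control flag rate that this combination mathematically implies.

Other chart decisions:

* **Range-flag attribution.** A flagged moving range spans two successive
  plans; the flag is attributed to the endpoint whose value lies farther
  from the average-chart centre line. This localises the disturbance on the
  plan that caused it: a single deviant plan collects both of its adjacent
  range flags, and with two metrics charted a single plan can cause at most
  four systematic errors (one per chart).
* **Single-pass limits.** Limits are estimated from the full supplied series
  (the retrospective-commissioning case); a `baseline` argument restricts
  estimation to the first N points for prospective monitoring. Flagged
  points are not excluded and the limits are not re-estimated iteratively.
* **No supplementary run rules.** Out-of-control means outside the action
  levels; Western-Electric-style run rules are deliberately not applied.
* **Per-process charts.** Charts are maintained per machine and per
  comparison route (measurement vs TPS, IDC vs TPS), since different
  processes show different behaviour; only metrics with a declared physical
  bound are capped.
* **Plan verdicts.** A plan's pass/fail is decided only by the SPC action
  levels. A static gamma threshold (e.g. pass rate ≥ 90%) can be enabled in
  the pipeline configuration but is off by default, because process-specific
  action levels — not a fixed number — are the point of the SPC approach.

## Synthetic data: what it does and does not emulate

The generators exist to give every pipeline stage inputs with analytic
ground truth; they are *not* beam models.

* **Lateral profiles** are sums of two tanh sigmoid edges with penumbra
  parameter \(\sigma_p\) (default 2.5 mm), normalised to 1 on the central
  axis. The FWHM has a closed form via root finding and equals the nominal
  field size to well under a tenth of a millimetre for all tabulated field
  sizes.
* **Depth-dose curves** follow
  \(D(z) \propto (1 - e^{-\mu_b z})\,e^{-\mu z}\) with defaults
  \(\mu = 0.005\,\mathrm{mm^{-1}}\), \(\mu_b = 0.26\,\mathrm{mm^{-1}}\),
  normalised so the dose at the 15 mm reference depth equals the output
  factor; the depth of maximum is the closed form
  \(z_{\max} = \ln(1+\mu_b/\mu)/\mu_b \approx 15.3\) mm.
* **Output factors** default to the saturating curve
  \(\mathrm{OF}(s) = s^2/(s^2 + 3.5^2)\) — about 0.67 at the 5 mm cone,
  approaching 1 at the largest fields — monotone in field size as any
  physical output factor must be.
* **Dose pairs** sample an analytic pattern (Gaussian target, dual target,
  or flat) on a centred grid and perturb it in the fixed order
  scale → shift → blob → noise. The order matters (noise must not be
  interpolated by the shift; the blob multiplies the already-scaled dose)
  and is part of the reproducibility contract, together with the seed.
  The default target width, a sixth of the grid extent, gives steep
  stereotactic-like gradients; `target_sigma_mm` can widen it to produce
  shallow-gradient distributions where a global dose error is *not*
  compensable by the spatial search — the configurations used for the
  out-of-control cohort plans.
* **QA series** draw i.i.d. Gaussian baselines per metric (defaults: pass
  rate mean 98%, σ 1.5 percentage points; mean gamma 0.27, σ 0.045 —
  plausible values for a well-behaved IDC process), truncate to physical
  bounds, then apply the injected shifts. Ground-truth labels are returned.
* **The detector-array mask** reproduces only the two-pitch chamber layout
  (2.5 mm in a central 55 × 55 mm², 5 mm out to 110 × 110 mm²); it does not
  model chamber volume averaging or angular response.

Not emulated anywhere: Monte-Carlo transport, energy spectra, heterogeneity
and material assignment, collimator scatter, delivery geometry, detector
response. Tests passing on these generators therefore demonstrate that the
*analysis chain* is correct, not that any beam model is accurate.

## Problem sizes and tolerances

The oracle-equivalence suite uses 81-node 1D curves, 11² 2D planes and 6³
3D volumes (roughly a hundred instances, most of them 1D, since the dense
oracle's cost grows with the cube of the gamma values it must bound); these
sizes keep the dense search exact yet affordable while exercising every
code path. End-to-end cohorts use 84 plans — two QA routes at 23² (3 mm)
and 9³ (4 mm) grids — with three injected out-of-control plans per route.
The SPC recovery experiment uses 500 replicates of 84-plan series with
−8σ injections; the in-control false-alarm measurement uses 10⁴ replicates.
Monte-Carlo assertions use tolerances a few standard errors wide at those
replicate counts.

## Degenerate inputs

Constant series give zero mean moving range; the limits then collapse onto
the centre line with a warning rather than an error. An all-zero reference
distribution, mismatched dimensionalities, disjoint curve intervals,
non-uniform grids and out-of-range correction factors all raise immediate
errors. Re-running a plan id appends a new revision (with a warning) rather
than overwriting history: the results file is an append-only chronological
record, which is what makes SPC on it meaningful.

## Known limitations

* The gamma engine's accuracy guarantee is empirical (oracle-backed), not a
  proof; inputs with sub-voxel noise on steep gradients can exceed the 0.01
  agreement bound, always on the conservative side.
* Pure-R search performance is adequate up to tens of thousands of
  evaluated reference points per plan; much larger volumes would warrant a
  compiled backend.
* The DICOM RT Dose reader supports the explicit-VR little-endian subset
  with uniform frame offsets only — sufficient for round-tripping dose
  volumes, not a general DICOM implementation.
* Only individuals/moving-range charts are provided; CUSUM or EWMA charts,
  which detect small persistent shifts earlier, are out of scope.
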
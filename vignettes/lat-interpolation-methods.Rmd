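---
title: "Graph-based LAT map interpolation: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graph-based LAT map interpolation: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements: the
interpolation model and its assumptions, the perceptual error metric, the
sub-sampling protocol, what the synthetic generators do and do not emulate,
and the numerical and design decisions taken where the problem left them
open.

## The interpolation model

A local activation time (LAT) map assigns to each point of the cardiac
surface the delay, in milliseconds, between a depolarisation feature there
and a fixed reference electrogram. The surface arrives as a triangular mesh
`{V, F}` (coordinates in mm); measurements arrive as a few hundred scattered
points that rarely coincide with mesh vertices.

The package treats the map as a *graph signal*. The mesh induces a graph
whose edges are face edges; its weighted Laplacian `L = D − W` uses the
classic cotangent weights

    w_ij = 1/2 Σ cot(θ_ij^k)

summed over the one or two triangles containing edge *(i, j)* (boundary
edges contribute a single half-cotangent). Cotangent weights discretise the
Laplace–Beltrami operator of the surface, but obtuse triangles can make a
weight non-positive; since a smoothing operator needs positive weights, any
non-positive sum is replaced by a small floor (`weight_floor = 1e-6`).
The result is symmetric, has zero row sums, strictly positive edge weights,
and is positive semidefinite by diagonal dominance — the operator contract
the tests enforce on every mesh.

With diagonal 0/1 masks `M_l` (labelled) and `M_u = I − M_l`, and the
observed signal `f_s` (zero off the labelled set), the interpolant solves

    f* = argmin_f ||M_l(f − f_s)||² + α ||M_u f||² + β fᵀLf

whose stationarity condition is the SPD system
`(M_l + α M_u + β L) f* = f_s`. The model's assumptions are therefore
explicit: the signal is smooth *along the retained graph edges* (Dirichlet
term), observations are trusted nearly at face value (the data term has unit
weight), and unlabelled values are weakly shrunk to zero only to keep the
system invertible.

### Edge sparsification

Smoothness is false exactly where the clinical signal is most interesting:
"early-meets-late" boundaries, where re-entrant circuits, reference shifts
or a mis-windowed cycle put LAT values ~250 ms apart on adjacent vertices.
Before solving, the package quantizes the field by assigning every vertex
the value of its nearest observation and deletes every edge whose endpoint
quantization differs by at least `delta_lat = 50` ms (the inequality is
`>=`). The two sides then decouple in the Dirichlet term and the jump is
preserved. Two readings were possible for the rule's domain — quantized
per-vertex values versus observed pairs only — and the per-vertex reading is
implemented, since quantization is precisely what makes the rule applicable
to edges far from any observation. At `delta_lat = 0` only edges whose
endpoints actually differ are removed, so the degenerate setting retains
the documented "removes every differing edge" semantics.

### Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `alpha` | 1e-5 | – | Tikhonov weight on unlabelled magnitudes; any value > 0 guarantees an SPD system. Small, so it only regularises truly unconstrained components. |
| `beta` | 1e-2 | – | Dirichlet smoothness weight. Raising it towards 1 changes results mildly (oversmoothing); lowering it towards 1e-5 lets unlabelled vertices collapse toward 0 and hurts sharply. A test asserts that asymmetry. |
| `delta_lat` | 50 | ms | edge-removal threshold; `Inf` disables removal. |
| `k`, `radius`, `threshold` | 5, 5 mm, 30 ms | – | anomaly rejection (below). |
| `weight_floor` | 1e-6 | – | replacement for non-positive cotangent weights. |

### Pre-processing

Observations are snapped to their Euclidean-nearest vertex; collisions are
merged by the arithmetic mean (unbiased and order-independent — the
acquisition order is not modelled). Nearest-vertex ties are broken by the
lowest vertex index for determinism; because the fast vectorised distance
expansion can flip exact ties by rounding, near-ties are re-decided with the
direct formula.

The anomaly filter emulates the technician's culling: an observation is
dropped when its value differs from the mean of its up-to-5 nearest
co-observations within 5 mm by *strictly more than* 30 ms. Two decisions
were open. First, "5 nearest neighbours within 5 mm" is read as k-NN
restricted to the radius ball (not the first five of the ball); second, the
filter is a single pass judged against the original set — no cascade —
because iterative removal could unravel legitimate steep regions.
Observations with no neighbour in the ball are kept. Distances are Euclidean
3-D distances between observation locations, matching the metric radius in
which the rule is stated.

## The perceptual metric (MDE)

Clinicians read maps as colors, so error is measured in color space: both
maps are rendered through the viridis colormap over a fixed scale
`[s_min, s_max]`, converted sRGB → linear RGB → XYZ (D65) → CIELAB, and
compared point-wise with CIEDE2000 (weights `k_L = k_C = k_H = 1`, the
recommended defaults); the mean over points is the MDE. Out-of-range values
clamp to the colormap endpoints, which gives the metric its windowing
behaviour: restricting the scale to a LAT range of interest automatically
assigns zero error wherever both maps saturate on the same side.

The viridis table is embedded as the public 256-entry RGB table with linear
interpolation between entries, so color assignment is bit-stable and needs
no plotting dependency. The CIEDE2000 implementation reproduces the full
published 34-pair verification suite to 1e-4; each pair was cross-verified
against two independent implementations before being frozen into the tests.

NMSE is reported as a conventional secondary metric. Its normalisation is
defined here as residual sum of squares over the *centred* total sum of
squares, so predicting the truth's mean scores exactly 1.

The harness scores MDE on the held-out observation set (not all vertices),
and fixes the color range to the min/max of the usable observations of the
map across all repetitions, so repetitions are comparable.

## The sub-sampling protocol

Uniform sub-sampling over-represents late activation relative to a real
acquisition, where the technician hunts the earliest site and densifies
mid-to-early regions. The protocol shifts values non-negative
(`x_i = s_i + |s_min|`, applied only when negative values exist), places the
intended peak at `x' = x_min + λ₁ x_avg` with `λ₁ = 0.5` (between the
unrealistic extremes "earliest most likely" and "mean most likely"), scores
each observation `r_i = λ₂ (d_max − d_i) + 1` with `λ₂ = 0.25` (gentle
slope, so no probability is vanishingly small; the minimum score is exactly
1), floors to integer repetitions `f_i` and normalises. The integer cast is
`floor`, which on values ≥ 1 preserves the `f_i ≥ 1` guarantee.

Subsets are drawn *without replacement* with per-draw probability
proportional to the remaining repetition counts (base R's weighted
`sample()` semantics). The repetition-list construction could also be read
as with-replacement sampling, but duplicate observations are useless as
training points, so the without-replacement reading is used. Draws take an
explicit seed, and the global RNG stream is saved and restored around every
draw.

## Synthetic data: what it does and does not emulate

Study conditions are fixed by the generator defaults: icosphere at
subdivision 4 (n = 2562 vertices — the low thousands of clinical meshes),
radius 25 mm (a ventricular chamber scale), conduction velocity 0.8 mm/ms
(working myocardium), measurement noise 3 ms, ~300 observation sites, and a
250 ms early-meets-late jump (the scale of −200 ms meeting +50 ms).

* **Focal activation** emulates a PVC-like centrifugal wavefront:
  LAT = geodesic distance from a focus ÷ conduction velocity + Gaussian
  noise. Geodesics are Dijkstra shortest paths over edge lengths — adequate
  for plausible fields, slightly overestimating true polyhedral geodesics.
  The field is shifted so the focus sits at 0 ms; under noise a constant
  shift cannot force the focus to stay the argmin, so other vertices may dip
  a few ms below it (with zero noise the focus is exactly the minimum).
* **Early-meets-late** adds a constant jump on one side of a plane through
  the mesh centroid, guaranteeing adjacent-vertex jumps far above the 50 ms
  threshold.
* **Observations** probe random distinct vertices with 0.5 mm positional
  jitter, exercising the snapping path.

Not emulated: anisotropic conduction (fibre orientation), spatially
correlated annotation noise, scar regions with absent signal, the spatial
clustering of real catheter trajectories, and reaction–diffusion wavefront
physics. Passing tests therefore demonstrate the *mechanisms* — error
decreasing with m at diminishing rates, sparsification preserving
discontinuities, protocol enrichment of early-to-mid activation — not
clinical error magnitudes, which depend on private patient data.

## Numerical choices

* The closed form is an inverse in notation only; the implementation
  factorises the sparse SPD system (Cholesky) and verifies the residual
  `||A f* − f_s||∞ ≤ 1e-8 ||f_s||∞`, erroring on violation (which would
  signal a malformed Laplacian).
* The eigendecomposition path (`laplacian_eigen` + `spectral_interpolate`)
  is a dense diagnostic tool intended for n up to ~2000; it exists to make
  the filtering interpretation executable and testable
  (`h(λ) = 1/(1+λ)` reproduces the solve exactly when `α = β = 1`).
* Degenerate faces (area < 1e-12 mm²) are an error naming the face, not a
  silent clamp: they indicate a broken mesh upstream.
* GPR length scales (0.01, 0.1, 1) are dimensionless; raw millimetre
  coordinates would make all three kernels effectively zero between
  observations, so coordinates are rescaled to a unit bounding-box diagonal
  by default (`rescale = FALSE` restores raw behaviour). Duplicate training
  sites are an error directing the user to merge, since they make the
  kernel matrix singular beyond what jitter (1e-8) repairs.
* LAT values are not re-centred or detrended before solving.
* Indices are 1-based inside R; mesh files and written CSVs use the 0-based
  convention native to those formats.

## Problem sizes

The test suite runs small analytic meshes (single triangles, squares,
icospheres at subdivisions 1–3) for unit and property tests, random graphs
up to n = 200 against dense oracles, and the full study conditions
(n = 2562, 20–25 repetitions, m = 50–200) for the behavioural properties;
the acceptance script reuses the study conditions. These sizes keep a
complete run in the minutes range on a single CPU while still exercising
the production sparse path well above the dense-oracle regime.

## Known limitations

* The intrinsic-Delaunay ("robust") Laplacian is approximated by the
  clamped cotangent construction; the interface and operator properties are
  identical, but weights on badly shaped clinical triangles may differ from
  an intrinsic construction. Whether that difference matters on well-formed
  meshes is untested.
* Nearest-neighbour quantization uses Euclidean, not geodesic, distance —
  consistent with the metric (5 mm) convention of the pre-processing rules,
  but a geodesic variant could behave differently on thin-walled anatomy
  where Euclidean neighbours are geodesically far.
* MDE weights all test points equally; errors in the clinically critical
  earliest-activation region count no more than elsewhere.
* Binary PLY, mesh repair and proprietary mapping-system exports are out of
  scope; meshes must arrive as ASCII OFF/PLY/OBJ triangle meshes.
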
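# magiclat

Graph-based interpolation of **local activation time (LAT)** maps on
triangulated cardiac-surface meshes, with a perceptual map-error metric and a
clinically motivated evaluation harness.

During catheter ablation procedures an electroanatomic mapping system
acquires a triangular mesh of the cardiac chamber together with a few hundred
scattered LAT measurements (milliseconds relative to a reference
electrogram). Building a full-surface activation map from those sparse points
is an interpolation problem on a curved anatomical surface — and the quality
that matters clinically is how the *rendered, colored map* is perceived by
the electrophysiologist choosing ablation targets. This package is for
researchers in cardiac electrophysiology signal processing who want a
reproducible, desk-scale implementation of that whole chain.

## The method

The mesh `{V, F}` is turned into a weighted graph with the cotangent-weight
Laplacian `L = D − W`, where

    w_ij = 1/2 * Σ_faces cot(angle opposite edge ij),

non-positive weights clamped to a small positive floor so that `L` is
symmetric, positive semidefinite, has zero row sums and strictly positive
edge weights. A nearest-neighbour quantization of the observed LAT field is
used to delete edges whose endpoints differ by ≥ 50 ms — jumps that cannot
arise from continuous conduction (scar block, re-entry boundaries,
mis-windowed cycles) — so the graph matches the physiological manifold.

With `M_l`/`M_u` the diagonal masks of labelled/unlabelled vertices and
`f_s` the observed signal (zero off the labelled set), the interpolant
minimises

    ||M_l (f − f_s)||² + α ||M_u f||² + β fᵀ L f,

whose closed-form solution is the SPD linear system

    (M_l + α M_u + β L) f* = f_s,      α = 10⁻⁵, β = 10⁻²,

solved by sparse Cholesky factorisation. For `α = β = 1` this is exactly the
graph filter `f* = U (I + Λ)⁻¹ Uᵀ f_s` in the Laplacian eigenbasis — a
low-pass filter on the surface — and the package exposes that spectral path
too, plus a Gaussian-process-regression baseline (sum of three RBF kernels).

Map error is measured perceptually with **Mean Delta-E (MDE)**: both maps are
rendered through the viridis colormap over a fixed `[s_min, s_max]` scale,
converted to CIELAB, compared point-wise with the CIEDE2000 color-difference
formula, and averaged. Narrowing the scale focuses the metric on a LAT window
of interest (saturated pairs contribute zero). Conventional NMSE is reported
alongside.

Evaluation mimics clinical acquisition: training subsets are drawn from a
non-uniform distribution peaking midway between the earliest and the mean
activation value (`λ₁ = 0.5`, slope `λ₂ = 0.25`), and cross-validation
repeats the draw with fresh seeds, scoring each method on the held-out
observations.

## Worked example

```r
library(magiclat)

mesh  <- make_mesh("icosphere", subdivisions = 3)          # n = 642, r = 25 mm
truth <- simulate_focal_lat(mesh, focus = 1, noise_sd = 3, seed = 11)
obs   <- sample_observations(mesh, truth, m = 150, seed = 12)

fit <- magic_lat(mesh, obs)
fit
#> Graph-based LAT interpolation fit
#>   mesh: 642 vertices, 1280 faces
#>   labelled vertices: 150; edges removed: 0
#>   alpha = 1e-05, beta = 0.01, delta_lat = 50 ms
#>   interpolated LAT range: [0.3, 104.1] ms

mde(fitted(fit), truth, range(truth))   #> 2.588
nmse(fitted(fit), truth)                #> 0.0180

crossval(mesh, obs, m = 100, reps = 25, methods = c("magic", "gpr"), seed = 1)
#> Cross-validation: m = 100 of 150 observations, 25 repetitions
#>   gpr   MDE 8.664 +/- 2.504   NMSE 0.2053 +/- 0.1556
#>   magic MDE 6.484 +/- 1.826   NMSE 0.1058 +/- 0.0737
```

The fit recovers the full activation map from 150 of 642 vertices with a
perceptual error of ~2.6 ΔE₀₀ units (differences below ~2 are barely
noticeable side by side); under held-out cross-validation at m = 100 the
graph method clearly beats the GPR baseline on both metrics. On
early-meets-late maps (sharp LAT discontinuities), enable/disable the edge
removal via `delta_lat` to see its effect.

A command-line wrapper with `interpolate`, `subsample`, `evaluate`,
`simulate` and `crossval` subcommands is installed at

```sh
Rscript $(Rscript -e 'cat(system.file("cli/magiclat.R", package = "magiclat"))') simulate --subdivisions 4 --outdir demo
```

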
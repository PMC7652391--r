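---
title: "Locating air-water interfaces and quantifying particle partitioning from cryo-ET coordinates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Locating air-water interfaces and quantifying particle partitioning from cryo-ET coordinates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(awipart)
```

## The problem

A vitrified thin film on a cryo-EM grid is a slab of amorphous ice, roughly
20–180 nm thick, bounded by two free surfaces — the air–water interfaces
(AWIs) — that were liquid until the instant of plunge-freezing. Macromolecules
diffuse to those interfaces within milliseconds and many adsorb there, where
they can unfold, adopt preferred orientations, or pile into rafts of tens of
particles. Tomography gives per-particle 3-D coordinates, which is all this
package uses: the interfaces themselves are *inferred from the particles*,
never from image density. That choice makes the analysis independent of
contrast and defocus, at the cost that the surfaces are only defined where
particles exist.

## Interface location

`build_film()` composes three steps, each available separately:

* **Patch grid** (`make_patch_grid()`): the x/y bounding rectangle is tiled
  by `nx × ny` patches. In `auto` mode the total is the largest count ≤ 16
  whose expected occupancy is at least two particles per patch
  (`min(16, floor(n/2))`), split between nx and ny to match the aspect ratio
  of the bounds. The occupancy floor is what makes the per-patch extrema
  meaningful: a patch with one particle contributes the same point to both
  faces and inflates residuals, so sparse clouds get coarser grids.
* **Extremal selection** (`select_extremal()`): per non-empty patch, the
  single z-maximum supports the top surface and the single z-minimum the
  bottom. Ties in z resolve to the lowest input row index, so runs are
  reproducible under any stable input ordering.
* **Surface fit** (`fit_surface()`): ordinary least squares for
  `z = f(x, y)` with a plane (3 coefficients) or full quadratic
  (6 coefficients). In `auto` mode a face is upgraded to order 2 only when
  it has at least 9 support points *and* the quadratic reduces the rms
  residual by more than 20%. The rule is deliberately conservative toward
  planes: an in-sample quadratic always reduces the residual somewhat
  (by roughly `sqrt((n-6)/(n-3))` on pure noise, about 6% at n = 16), so
  the 20% margin demands real curvature. Each face's order is chosen
  independently. Rank-deficient support (collinear x/y) raises a
  degenerate-geometry error rather than a silent pseudo-inverse fit.

The film's mean thickness is the 50 × 50 midpoint quadrature of
top − bottom over the bounds — exact for polynomial surfaces up to the cell
scale. If the fitted surfaces cross on more than 1% of that grid the film is
rejected as inconsistent; coincident surfaces (single-layer input) raise a
zero-thickness error.

## Distances and the bound/bulk rule

`closest_distance()` returns the true 3-D Euclidean minimum from a point to
the surface sheet: closed form for planes, and for quadrics a BFGS
minimization of the squared distance over (x, y) started from the point's
own x/y (with analytic gradient). A signed convention marks the film side:
positive inside, negative beyond a surface. A vertical-gap mode exists for
comparison, because with coordinates alone the two definitions differ only
by the local surface slope; the Euclidean minimum is the default since it is
the geometrically meaningful quantity on tilted or curved films.

`classify_particles()` marks a particle bound when
`min(|d_top|, |d_bottom|) ≤ threshold`, labels it by the nearer face (ties
to top), and counts particles beyond a fitted surface as bound to that
surface — such points are extrema that defined the fit, and their distance
magnitude is small by construction. The threshold is 10 nm, switching to
20 nm when the mean thickness exceeds 80 nm (`threshold_nm = "auto"`);
`repartition()` re-applies any threshold from stored distances, and reports
always carry both fixed thresholds side by side. On a uniform slab of
thickness T the expected bound fraction is `2d/T`, which is the calibration
law the tests lean on.

`summarize_partitions()` averages bound fraction and asymmetry across
tomograms with equal weight per tomogram (the per-tomogram table is always
returned, so count-weighted summaries can be recomputed), reporting SD = 0
for singleton groups.

## Concentration

`film_volume()` integrates top − bottom over either the particle bounding
rectangle (default — the region where the surfaces are supported by data)
or the full tomogram extent, clamping locally crossing fits to zero.
`estimate_concentration()` converts a count and volume to micromolar via
1 µM = 6.02214076 × 10⁻⁷ particles/nm³ (10⁻⁶ mol/L × Avogadro × 10⁻²⁴
L/nm³), counting whole complexes, and reports the fold-change against the
applied concentration. The estimate deliberately ignores particles that may
sit in unimageable over-thick regions: it describes the analysed volume
only.

## The random-placement null model

`simulate_null()` draws the "ideal behaviour" reference: x/y uniform over
the analysis area, z uniform between the two fitted surfaces at that (x, y)
(exact for the slab measure, with rejection only where fits cross), at a
particle number set by the applied concentration — Poisson by default, or
the rounded expectation in `fixed` mode for exact reproducibility. Distances
reuse the same `closest_distance()` code path as real particles.
`compare_to_observed()` reports the maximum absolute difference between the
two empirical CDFs of distance-to-nearer-interface, both overall and
restricted to distances beyond the threshold. The restricted statistic is
the informative one: adsorption crowds the first nanometres, so an
interface-bound cohort departs strongly overall while its bulk remainder
still matches the null. No named two-sample test is attached; the reference
comparison in the test-suite is a permutation bootstrap of the pooled
restricted distances.

## Orientation maps

`euler_to_direction()` takes ZYZ (rot, tilt) to the view axis
`(sin t cos r, sin t sin r, cos t)`; psi is in-plane and drops out. Angles
are canonicalized (tilt into [0°, 180°] by `(rot, tilt) → (rot + 180°,
360° − tilt)`, rot/psi wrapped to [−180°, 180°)), and a `transpose` flag
covers datasets whose refinement stored the inverse convention.

`spherical_kde()` estimates the density as
`Σ_i exp(−θ(g, d_i)² / (2σ²))` with θ the geodesic angle and σ the
bandwidth (default 10°, wider than typical angular assignment accuracy, so
maps are smoothed past over-interpretation), then renormalizes numerically
so the PDF integrates to 1 over the sphere. The kernel is a true Gaussian
in the geodesic angle rather than a von Mises–Fisher density; at this
bandwidth the two differ by less than the renormalization absorbs. The grid
is latitude–longitude with exact per-cell solid angles
(Δλ · (sin(φ+Δφ/2) − sin(φ−Δφ/2))), 1° by default. `kde_kernel_sum()`
exposes the unnormalized sum at arbitrary query directions, which is what
the symmetry-equivariance tests evaluate, free of grid interpolation.

Symmetry expansion (`expand_symmetry()`) replicates directions under Cn
(n rotations about z) or the 24-element octahedral rotation group; it is
**off** by default, so a C7 dataset occupies one-seventh of the sphere as
refinement packages emit it, and expansion is available when a
symmetry-flattened comparison is wanted.

`mollweide_xy()` implements the equal-area Mollweide projection (Newton
iteration on `2θ + sin 2θ = π sin φ`, poles handled exactly), and
`render_mollweide()` writes the gridded (lon, lat, pdf, x, y) table as TSV —
the machine-checkable artifact — with an optional PNG rendering.

### What "flat" means at finite n

The pointwise relative sampling error of this estimator is approximately
`1/(σ√n)` (σ in radians): 0.057 at n = 10,000 with the 10° bandwidth. The
sphere contains roughly `4π/(2πσ²) ≈ 66` kernel-independent patches, so the
*maximum* relative deviation of a uniform sample sits near 2.6 standard
errors, ≈ 0.15 — and that is what the acceptance script measures
(`kde_uniform_max_rel_dev` ≈ 0.15–0.20). Mean absolute deviation, by
contrast, concentrates near 0.8·`1/(σ√n)`. The test suite asserts both at
their statistically correct levels. Similarly, smoothing relocates density:
a 90% preferred component whose raw views put ~89% of their mass within 20°
of the axis retains only ~72% of *smoothed* mass inside 20° (tangent-plane
spread `sqrt(7.65² + 10²) ≈ 12.6°`), while over 80% sits within 30° and the
20° cap is enriched ~24-fold over uniform — those are the bounds the
mixture-recovery test checks.

## The synthetic generator

`film_spec()` defaults describe the regime the pipeline targets: a
1000 × 1000 nm analysis area, 100 nm nominal thickness (mid-range of the
20–180 nm films the method applies to), flat faces unless tilt/curvature
coefficients are given, 2 nm inward half-Gaussian jitter for adsorbed
particles (particle centers of finite-size complexes sit roughly one radius
inside the interface, and 2 nm keeps them unambiguously detectable at the
10 nm rule), and a Poisson particle number at
`applied_µM × volume × 6.02214076e-7`. Adsorbed particles split between the
faces by `top_share`; rafts add clusters with sizes uniform on a 10–50
range within a disc radius on one face and count toward that face's
adsorbed pool. `generate_orientations()` mixes a rotationally symmetric
preferred component — geodesic offset half-Gaussian, dispersion specified
as the convention-free 95% angular radius — with a uniform remainder, and
returns both Euler angles (psi uniform) and the direction vectors.

What the generator does **not** emulate: picking errors and misses near the
interfaces, missing-wedge anisotropy in z, particle exclusion volumes,
adsorption kinetics, or any time dependence of raft growth. Passing recovery
tests therefore demonstrates the estimators are correct and calibrated on
clean geometry, not that picking artifacts cancel on real data.

Recovery obeys an exact law worth stating: with adsorbed fraction `p` and a
uniform bulk remainder, the expected measured bound fraction is
`p + (1−p)·2d/T`, so the unbiased recovery of `p` inverts that:
`p̂ = (f_obs − 2d/T)/(1 − 2d/T)`. The cohort tests and the acceptance script
use this inversion rather than pretending the bulk term away.

## Problem sizes and numerical choices

The shipped tests and acceptance script run at 2,000-particle slabs,
five-tomogram cohorts of ~360 particles, 50-replicate concentration round
trips, ~5,000-particle null runs and 10,000-direction orientation checks on
a 2° grid — sizes at which every binomial/Poisson 3-SE band is a few
percent, chosen once as realistic per-tomogram scales. Other fixed choices:
50 × 50 quadrature and consistency grids; BFGS `reltol` 1e-12 for quadric
distances; 1% crossing tolerance for film consistency; Newton tolerance
1e-13 for the Mollweide auxiliary angle.

## Limitations

* Surfaces exist only where particles do; concentration and null-model
  volumes inherit the particle-bounds convention unless tomogram extents
  are supplied.
* The bound rule is purely geometric; it cannot distinguish a particle
  adsorbed to the interface from a bulk particle that diffused within the
  threshold at freezing time (the `2d/T` term above is exactly that
  population).
* Orientation maps use (rot, tilt) only; in-plane angle statistics and
  per-particle angular accuracy are out of scope.
* No statistical test is attached to device or timepoint comparisons;
  means ± SD per condition are reported and the per-tomogram values are
  exposed for any further inference.
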
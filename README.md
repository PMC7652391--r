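# awipart

Particles suspended in the thin liquid film of a cryo-EM grid rarely stay in
the bulk: most adsorb to one of the film's two air–water interfaces (AWIs),
often asymmetrically between the faces, often in a preferred pose, and the
blotting step can concentrate them well above the applied solution
concentration. `awipart` quantifies all of this from cryo-electron-tomography
particle coordinates alone — no interface is ever detected from image
density. It is written for structural biologists analysing per-particle
(x, y, z) picks and Euler-angle assignments from tomograms of vitrified thin
films.

## What it computes

Given per-particle coordinates (nm) from one tomogram:

1. **Interface location.** The x/y bounding box is divided into patches
   (4–16, chosen so each patch expects ≥ 2 particles). The z-maximum of each
   patch supports the top surface, the z-minimum the bottom, and each face is
   fitted by least squares as a polynomial
   `z = c0 + cx·x + cy·y (+ cxx·x² + cxy·xy + cyy·y²)`, order 1 or 2.
2. **Partitioning.** Each particle's signed 3-D closest distance to both
   fitted surfaces is computed; a particle is *bound* when the smaller
   distance magnitude is ≤ 10 nm (20 nm when the mean film thickness exceeds
   80 nm). Bound particles are labelled top/bottom by the nearer face, and an
   asymmetry index `|n_top − n_bottom| / (n_top + n_bottom)` summarizes
   face preference.
3. **In-film concentration.** The film volume is the quadrature of
   top − bottom over the analysis area; with `N` particles,
   `c = (N / V) / 6.02214076e-7 µM` (1 µM = 6.02214076 × 10⁻⁷ particles/nm³),
   and the fold-change is `c / c_applied`.
4. **Ideal-behaviour null model.** Particles are placed uniformly at random
   between the fitted surfaces at the applied concentration and their
   distance distribution is compared with the observed one (max |CDF
   difference|, overall and restricted to distances beyond the threshold).
5. **Orientation maps.** (rot, tilt) Euler angles become view directions on
   the sphere; a Gaussian kernel in the geodesic angle (bandwidth 10°)
   yields a probability density normalized to integrate to 1 over the
   sphere, optionally expanded under Cn or octahedral symmetry, rendered in
   an equal-area Mollweide projection.

A synthetic generator (`film_spec()` / `generate_film_particles()` /
`generate_orientations()` / `make_cohort()`) produces thin-film particle
sets with known ground truth — adsorbed fraction, face asymmetry, surface
rafts of 10–50 clustered particles, preferred-orientation mixtures — so
every stage can be validated by parameter recovery.

## Worked example

```r
library(awipart)

# synthetic tomogram: 100 nm film, 86% of particles adsorbed, 90% of those
# on the top face
spec      <- film_spec(thickness_nm = 100, applied_uM = 6, p_bound = 0.86,
                       top_share = 0.9)
particles <- generate_film_particles(spec, seed = 11)

film      <- build_film(particles)
partition <- classify_particles(particles, film, threshold_nm = "auto")
conc      <- estimate_concentration(nrow(particles), film_volume(film),
                                    applied_uM = 6)
null_run  <- simulate_null(film, applied_uM = 6, seed = 12)

film
#> <thin_film> mean thickness 97.21 nm over x [5.969, 997.3], y [11.34, 997.8] nm
#>   top:    order 2, rms 0.0738 nm
#>   bottom: order 1, rms 7.34 nm
partition
#> <awi_partition> 350 particles, threshold 20 nm (film 97.2 nm thick)
#>   bound 92.6% (top 280 / middle 26 / bottom 44), asymmetry 0.73
conc
#> # A tibble: 1 x 5
#>   volume_nm3 count conc_uM applied_uM fold_change
#>        <dbl> <int>   <dbl>      <dbl>       <dbl>
#> 1  95069685.   350    6.11          6        1.02
compare_to_observed(null_run, partition)
#> <null_comparison> max |CDF diff| 0.791 overall, 0.162 beyond 10 nm (n_obs 350, n_model 316)
```

Reading the output: the two fitted interfaces enclose a ~97 nm film; at the
auto-selected 20 nm threshold 92.6% of particles are interface-bound
(86% were generated adsorbed; the rest of the bound ones are bulk particles
that happen to fall within the threshold), heavily favouring the top face
(asymmetry 0.73). The in-film concentration matches the applied one
(fold-change 1.02) because adsorption relocates particles without adding
any. The distance distribution departs strongly from the random-placement
null overall (0.79) but much less so away from the interfaces (0.16) — the
signature of interface adsorption rather than bulk enrichment.

For orientation analysis:

```r
angles <- generate_orientations(
  orient_spec(2000, preferred_fraction = 0.9, angular_radius_95_deg = 15),
  seed = 3)
pdf <- spherical_kde(angles, bandwidth_deg = 10, symmetry = "C7")
autoplot(pdf)                               # Mollweide map
render_mollweide(pdf, "map.tsv", "map.png") # gridded table + raster
```

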
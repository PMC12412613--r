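# memclust

Quantitative analysis of high-speed atomic force microscopy (HS-AFM)
topography movies of membrane-protein clusters in supported lipid
bilayers — and a ground-truth-annotated synthetic-data generator that
makes every stage of the analysis testable in closed loop.

## Who this is for

HS-AFM records calibrated height maps (nm) of membranes at sub-second
frame rates. When oligomeric membrane proteins (e.g. pentameric and
tetrameric channels) form 2D clusters in a lipid bilayer, the movies
contain quantitative information about protein–protein and
protein–lipid interactions:

* **Contour dynamics.** An isolated cluster is segmented per frame and
  its boundary expressed as a polar radial profile R(θ, t). The radius
  change ΔR(θ, t) = R(θ, t+δt) − R(θ, t) and the mean leading-edge
  velocity

      μv = ⟨ |ΔR| ⟩ / δt        (averaged over angles and frame pairs)

  measure how mobile the cluster edge is.

* **Line tension by capillary-wave spectroscopy.** In equilibrium the
  boundary fluctuates as capillary waves; expanding R(θ, t)/r0 in a
  Fourier series, equipartition gives per-mode variances

      ⟨a_k² + b_k²⟩ = 2 kB T / (π λ r0 (k² − 1)),   k ≥ 2,

  so a regression of the measured mode powers against
  2/(π r0 (k² − 1)) through the origin yields the boundary line tension
  λ (in kB·T/nm). Mode k = 1 is a pure translation and excluded.

* **Particle geometry.** Each particle is refined by rotational
  symmetrization (the internal symmetry value *isv* is the correlation
  between a particle image and its own nf-fold rotational average);
  protomers are localized on their ring, the tilt ω is the angle between
  the protomer plane normal and the z-axis, neighbor pairs come from a
  Delaunay triangulation with a distance cutoff, and each pair carries
  signed interaction angles (α, β) bounded by ±180/nf degrees
  (±36° for pentamers, ±45° for tetramers).

* **Cluster metrics.** 2D packing fraction
  f = (n_GlpF·A_GlpF + n_FocA·A_FocA)/A_cluster (defaults 38 and
  43 nm²; f > 1 flags apparent nonplanarity), composition ratios,
  ellipse eccentricity, and PCA + 2-component Gaussian-mixture typing of
  an 8-feature cluster table.

* **FRAP.** Recovery traces normalized to the pre-bleach level, the
  effective bleach radius re from the post-bleach profile
  f(x) = 1 − K·exp(−2x²/re²), the recovery half-time τ½, and
  D = (re² + rn²)/(8 τ½).

* **Debye length.** λD = sqrt(εr ε0 kB T / (2 NA e² I)) ≈ 0.8 nm at
  150 mM monovalent salt.

Because the underlying experimental recordings are not publicly
deposited, the package ships a first-class synthetic generator
(`movie_spec()`, `sample_boundary()`, `render_movie()`,
`simulate_frap()`) whose defaults state a realistic imaging world;
every analysis stage is validated by recovering the generator's ground
truth.

## Worked example

```r
library(memclust)

# a stated world: 7 pentamers in a 12 nm cluster, boundary line tension
# 10 kB*T/nm, 40 frames at 0.5 s
spec <- movie_spec(line_tension = 10, n_frames = 40, noise_sd = 0.05, seed = 9)
res  <- run_pipeline(pipeline_config(spec = spec, seed = 9, chi = 0.5))
res
#> memclust_results: 1 cluster(s), 12 pair(s)
#>   cluster       r0      mu_v   lambda packing_fraction
#> 1       1 11.73352 0.3775285 27.11275        0.6925809
```

The mean cluster radius r0 recovers the generator's 12 nm; the
leading-edge velocity 0.38 nm/s reflects the prescribed boundary
fluctuations; λ is order-correct on a 40-frame pixelated movie (the
precise closed loop — |bias| < 10 % at 500 analytic contours — runs in
the test suite); and the packing fraction 0.69 compares with the ground
truth 7·43 nm²/(π·12² nm²) = 0.67.

```r
debye_length(electrolyte_conditions(78.5, 298, 0.15))
#> [1] 0.7854455        # nm, prints as the familiar ~0.8 nm

fit <- analyze_frap(simulate_frap(D = 1.5, rn = 5, noise_sd = 0.005, seed = 9))
fit
#> frap_fit: rn = 5.00 um, re = 7.68 um, tau1/2 = 6.48 s, D = 1.62 um^2/s
```

The FRAP closed loop recovers the generator's D = 1.5 µm²/s within 8 %
using the standard acquisition cadence (1 frame/5 s early, 1 frame/30 s
late).

A command-line interface is installed under
`system.file("cli", "memclust", package = "memclust")` with subcommands
`simulate`, `contour`, `run`, `frap`, `debye`.

## Layout

* `R/synthetic.R` — movie/FRAP generators with ground truth
* `R/preprocess.R` — flattening, alignment, isodata masks, walking
  average, surface coverage, isolated-trace selection
* `R/contour.R` — radial profiles, ΔR, μv, line-tension fit
* `R/particles.R`, `R/delaunay.R` — symmetrization, tilt, pairs, angles
* `R/metrics.R` — packing fraction, composition, PCA/GMM
* `R/frap.R`, `R/physchem.R` — FRAP analysis, Debye length
* `R/io.R`, `R/pipeline.R`, `inst/cli/memclust` — I/O, orchestration, CLI
* `vignettes/memclust-methods.Rmd` — the methods vignette (models,
  parameter choices, limitations)
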
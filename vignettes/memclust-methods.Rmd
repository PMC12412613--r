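---
title: "Models and methods behind memclust"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind memclust}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`memclust` quantifies the organization and dynamics of membrane-protein
clusters in HS-AFM topography movies. This vignette explains the models
the package implements, the tunable parameters and their defaults, what
the synthetic-data generator does and does not emulate, and the
numerical choices made where the design was genuinely open. It states no
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## 1. Preprocessing model

AFM raw frames carry per-scan-line offsets and slopes (piezo drift,
line feedback). `flatten_frame()` fits a degree ≤ 1 polynomial per scan
line **using only pixels below the frame's isodata threshold** — the
membrane/support background — so protein features cannot bias the fit,
then re-references the background median to zero. If a line is entirely
foreground it falls back to a whole-line fit with a warning.

`isodata_threshold()` is the classic intermeans iteration
t ← (mean(px ≤ t) + mean(px > t))/2 started at the frame mean. We
iterate to a tolerance of 1e−6 nm with a cap of 100 iterations; neither
constant is physically meaningful, they only pin down an unstated
numerical contract. The result is a fixed point of the intermeans map
and is affine-equivariant, which the tests assert directly.

Three-class surface coverage (protein / lipid membrane / support) uses
two stacked isodata splits: support vs. rest, then membrane vs.
protein within the upper class. The split is accepted only if the two
thresholds are at least `min_separation` (default 0.2 nm) apart;
otherwise classes are merged with a warning. The published analyses do
not state how the three levels were separated; two sequential isodata
splits are the simplest operator consistent with the single-threshold
masking step.

`walking_average()` applies a majority vote over a 3-frame sliding
window to the rough mask stack (a pixel survives if present in ≥ 2 of 3
consecutive frames), then fills enclosed background ("gap pixels") by
flood-fill from the border. At the stack ends the window is clamped to
the nearest full window inside the stack rather than shrunk to two
frames: a two-frame "majority" is either an AND (which deletes real
pixels) or an OR (which keeps noise), and both degrade the ends for no
benefit.

Drift alignment (`align_frames()`) cross-correlates each frame with the
previously *aligned* frame (a running reference is robust to slow shape
change), refines the correlation peak parabolically to sub-pixel
precision, and applies integer-pixel shifts. The per-frame drift
trajectory is returned for inspection.

`select_isolated_clusters()` tracks connected components across frames
by overlap and applies the published selection rule literally: any
trace that merges (under-segmentation), splits (over-segmentation), or
touches the field border in any frame is rejected; accepted traces span
the whole movie.

## 2. Contour dynamics and line tension

The cluster boundary is expressed as a polar radial profile R(θ, t)
about the per-frame center of mass. `radial_profile()` casts a ray per
angular bin (default δθ = 2°, a choice not stated in the published
method; 180 bins resolve modes to k ≈ 12 comfortably) and takes the
exit of the single inside segment (star-convex direction) or, where the
ray re-enters the mask, the exit of the longest inside segment — our
documented reading of "most probable radius" for non-star-convex
directions, for which no published definition exists.

The radius change is ΔR(θ, t) = R(θ, t+δt) − R(θ, t), and the mean
leading-edge velocity is the time- and angle-averaged |ΔR| per frame
interval. The printed form of the velocity equation is dimensionally
garbled in the source text (the fraction layout was lost); the
implementation uses the only reading that satisfies its own unit
checks: uniform growth of 1 nm/frame at δt = 1 s gives exactly
1 nm·s⁻¹.

**Line tension.** At equilibrium the boundary fluctuates as capillary
waves. We expand the instantaneous normalized profile R(θ, t)/r0 in a
Fourier series (r0 = time- and angle-mean radius) and use the
equipartition relation

var(a_k) = var(b_k) = kB·T / (π λ r0 (k² − 1)),  k ≥ 2,

with λ expressed in kB·T/nm. λ follows from a regression of the
per-mode mean squared amplitude ⟨a_k² + b_k²⟩ on 2/(π r0 (k² − 1))
through the origin (slope = 1/λ); a rank-based (median-of-ratios)
estimate is reported alongside. Two genuinely open points, and how we
resolved them:

* The source text prints *two* mutually inconsistent expansions: a
  frame-difference ratio and a series with a leading "1 +" that only
  makes sense for an instantaneous profile. Equipartition applies to
  instantaneous shape deviations, not frame differences, so the
  instantaneous expansion is the default; the frame-difference variant
  is available via `normalization = "difference"` but has a different
  absolute scale.
* The exact prefactor of the published mode-variance relation is not
  recoverable (figure-only equation). We adopt the standard
  capillary-wave prefactor above **in both the generator and the
  estimator**, so closed-loop recovery validates internal consistency;
  absolute published λ values are not reproduction targets.

Mode k = 1 is a rigid translation and never enters (the generator never
excites it; the estimator never fits it); k = 0 is absorbed in r0. The
default K = 12 keeps the highest mode's wavelength (≈ 2πr0/12 ≈ 6 nm at
r0 = 12 nm) well above the pixel size.

The closed loop (500 analytic contours, 20 seeds, λ ∈ {10, 100, 500})
recovers λ with |bias| < 10 % and sd < 20 %, and the mode-power
spectrum has log–log slope −1 ± 0.1 against (k² − 1) — both asserted in
`test-acceptance.R`. On *rendered movies* the mask discretization
(0.5 nm pixels) adds apparent boundary fluctuation, so λ from short
pixelated movies is order-correct only; the integration test asserts a
factor-3 band at λ = 10 kB·T/nm and 40 frames, and users should prefer
longer movies and larger clusters for quantitative tension work.

## 3. Particle geometry

`refine_particle()` scans candidate origins around a rough seed
(coarse 0.25 nm grid, then a 4× finer local pass). At each origin the
particle patch, resampled on a polar grid, is compared with its own
nf-fold rotational average; the internal symmetry value *isv* is the
Pearson correlation between the patch and the **leave-self-out**
average of its nf − 1 rotated copies, computed outside the innermost
2 px where all rotations share pixels. For pure noise this statistic is
centred at 0 (the self-inclusive variant is centred at 1/√nf ≈ 0.45,
which would defeat the low-confidence flag at its default floor of
0.5); for a true nf-fold particle it is ≈ 1 either way.

A tilted particle is *not* nf-fold symmetric, and its rotational-
average center is biased toward the high side. The refinement therefore
iterates (default 2 passes): fit the protomer plane, subtract it from
the frame, re-center on the detilted frame, and re-read protomer
heights from the *original* frame. This brings the tilt mean absolute
error below 2° for tilts up to 35° at 0.05 nm pixel noise (asserted in
the tests); without it the error exceeds 10° at high tilt.

Protomer angles come from the phase of the nf-th angular harmonic of
the unsymmetrized ring profile (one peak angle modulo 360/nf;
equispacing gives the rest), positions from the ring radius, heights by
bilinear interpolation of the original frame. `tilt_angle()` is the
acute angle between the least-squares protomer-plane normal and the
z-axis — invariant under height offsets and in-plane rotations, and
erroring on collinear geometry.

**Neighbor pairs.** Delaunay triangulation (an in-package
Bowyer–Watson; validated against an independent computational-geometry
oracle on frozen fixtures) proposes neighbor pairs; a distance cutoff
`d_max` (default 1.5× the modal nearest-neighbor distance) replaces the
published manual confirmation step — a documented deviation that makes
the pipeline deterministic.

**Interaction angles.** For each particle of a pair, the interacting
protomer is the one with the smallest angular separation from the
center-to-center line; the signed offset of that protomer from the line
is the interaction angle, positive clockwise. Coordinates follow the
image convention (y along rows), in which increasing mathematical angle
is clockwise on screen. nf-fold symmetry bounds the angle by ±180/nf
(±36° pentamer, ±45° tetramer); an exact tie at the boundary resolves
to +, making outputs deterministic. Density maps over (α, β) use a
periodic Gaussian kernel (default bandwidth 3°, 2° grid — no published
bandwidth exists) and are symmetrized over pair order.

Distance statistics fit a single Gaussian to the distance histogram and
report peak ± sd with n, flagging fits whose histogram R² falls below
0.8 (e.g. bimodal input); `compare_distances()` provides the two-sample
Welch test used for population comparisons.

## 4. Cluster metrics

Packing fraction f = (n_tet·A_tet + n_pent·A_pent)/A_cluster with
default cross-sections 38 and 43 nm². f > 1 is permitted and flagged
(`nonplanar`): domed or tilted architectures legitimately exceed planar
packing. The 8-feature table (particle count, edge and total
composition ratios, lipid fraction χ, f, eccentricity, λ, μv) is
standardized to zero mean and unit variance before PCA — the features
have incommensurable units, and "standard PCA" without scaling would be
dominated by whichever feature has the largest numeric range. Grouping
uses a full-covariance 2-component Gaussian mixture fitted by EM with
10 seeded restarts; with a fixed seed the labels are bit-reproducible.
Eccentricity comes from the second-moment ellipse of the contour (the
published "ellipse best fit" method is unspecified).

## 5. FRAP

The analysis chain is: ROI-mean trace → normalization by the pre-bleach
mean (≥ 3 pre-bleach frames; optional reference-ROI correction for
observational photobleaching, off by default since the published
analysis does not state such a correction) → effective radius re by
fitting f(x) = 1 − K·exp(−2x²/re²) to the radially averaged first
post-bleach frame → recovery half-time τ½ by a single-exponential fit
F(t) = F∞ − (F∞ − F0)·e^(−t ln2/τ½) with F0 pinned to the measured
bleach frame (linear interpolation of the half-crossing is available,
but at 1 frame/5 s early sampling the exponential fit is far more
stable) → D = (re² + rn²)/(8 τ½). The diffusion formula is the cited
standard protocol's; the printed equation is figure-only, so the
formula is exposed as a function argument should a different protocol
be preferred.

The generator (`simulate_frap()`) renders a disk bleach of nominal
radius rn blurred by `sigma0`, then evolves it by free 2D diffusion
(convolution with a Gaussian of sd √(2Dt)). `sigma0` defaults to rn/2:
during a bleach pulse lasting tens of seconds, diffusion smears the
nominal disk substantially, and the standard-protocol formula is
*derived for* that near-Gaussian post-bleach regime (typical measured
re/rn is 1.2–2). A nearly sharp disk violates the formula's own
assumption and biases recovery by ~40 % regardless of D — a property of
the formula, not of this implementation. With the stated world, D ∈
{0.5, 1.5, 3.2} µm²/s is recovered within 20 % at the standard
acquisition cadence (asserted in the tests).

## 6. The synthetic generator: what a green test establishes

`render_movie()` emulates: a flat membrane; a cluster plateau bounded
by independent equilibrium capillary-wave contours of known λ; nf-fold
particles as rings of isotropic Gaussian protomer bumps (σ = 0.35 ×
ring radius — blob-like, as oligomers appear in HS-AFM) placed on a
jittered hexagonal lattice at the modal center-to-center spacing (2.6 ×
ring radius; protein clusters pack near-hexagonally, and rejection
sampling cannot reach realistic densities); rigid-body tilt of edge
particles (a local plane under the bumps — scaling bump amplitudes
instead would invert protomers beyond atan(height/radius) ≈ 23°); and
i.i.d. Gaussian pixel noise.

It does **not** emulate: tip–sample convolution, scan-line noise
correlation or feedback artifacts, time-correlated boundary dynamics
(frames are independent equilibrium draws, which is exactly the
estimator's assumption), protein diffusion/exchange, or lipid
chemistry. A green closed-loop test therefore establishes that the
estimators are unbiased *under their own model assumptions* — it cannot
certify robustness to instrument physics the generator does not
contain. The instrument noise model in particular is a stand-in; the
published work does not state one.

Defaults state one world: 7 pentamers (ring radius 2.8 nm, neighbor
spacing ≈ 7.3 nm, matching reported center-to-center distances of
7–8 nm) in an r0 = 12 nm cluster → packing fraction 0.67, inside the
experimentally reported 0.6–1 range; 0.5 nm/px, 0.5 s/frame, 0.05 nm
noise. These were chosen once on physical grounds and are not tuned.

## 7. Known limitations

* λ from masks of small clusters is biased by pixel quantization; the
  quantitative guarantee holds for the analytic closed loop.
* The radial profile's "longest inside segment" rule for
  non-star-convex directions is one defensible reading among several.
* The Delaunay cutoff stands in for expert pair confirmation; in dense
  heterogeneous clusters it can keep geometrically adjacent but
  non-interacting pairs.
* FRAP assumes full mobile recovery (F∞ free, no immobile-fraction
  model) and pure 2D diffusion.
* Absolute line-tension values depend on a mode-variance prefactor that
  the published record does not fix; only ratios and trends are
  comparable across implementations.
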
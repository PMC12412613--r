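#' Specification of a synthetic HS-AFM cluster movie
#'
#' Describes a ground-truth world for the synthetic generator: a single
#' membrane-protein cluster whose boundary fluctuates as equilibrium
#' capillary waves with line tension `line_tension`, filled with `nf`-fold
#' symmetric particles rendered as rings of Gaussian protomer bumps.
#' Energies are expressed in units of kB*T, so `line_tension` is in
#' kB*T / nm and the mode variances are temperature-independent once
#' expressed that way.
#'
#' Defaults emulate the imaging conditions typical for single-cluster
#' HS-AFM recordings: 80 x 80 nm scan at 0.5 nm/px, 0.5 s per frame,
#' seven pentameric particles (protomer ring radius 2.8 nm, neighbor
#' spacing ~7.3 nm) packed in a 12 nm cluster, giving a packing fraction
#' in the experimentally observed 0.6-1 range.
#'
#' @param nf oligomer symmetry order (4 = tetramer, 5 = pentamer); >= 3.
#' @param n_particles number of particles placed in the cluster.
#' @param particle_radius protomer ring radius around a particle center, nm.
#' @param protomer_height protomer bump peak height above the cluster
#'   plateau, nm.
#' @param membrane_height membrane level above the support, nm.
#' @param cluster_height cluster plateau height above the membrane, nm.
#' @param cluster_r0 mean cluster radius r0, nm.
#' @param line_tension boundary line tension lambda, kB*T/nm; > 0.
#' @param temperature absolute temperature, K (metadata; the fluctuation
#'   amplitudes are parameterized in kB*T units).
#' @param n_modes highest boundary Fourier mode K (modes 2..K are excited).
#' @param edge_tilt_deg maximum tilt (degrees) applied to edge particles.
#' @param pixel_size nm per pixel.
#' @param frame_interval frame interval delta-t, s.
#' @param n_frames number of frames; >= 2.
#' @param noise_sd additive Gaussian pixel noise, nm.
#' @param image_size image side length in pixels (square frames).
#' @param seed RNG seed used by [render_movie()] and [sample_boundary()].
#'
#' @return An object of class `movie_spec`.
#' @seealso [sample_boundary()], [render_movie()]
#' @export
movie_spec <- function(nf = 5L,
                       n_particles = 7L,
                       particle_radius = 2.8,
                       protomer_height = 1.2,
                       membrane_height = 4,
                       cluster_height = 1,
                       cluster_r0 = 12,
                       line_tension = 100,
                       temperature = 298,
                       n_modes = 12L,
                       edge_tilt_deg = 15,
                       pixel_size = 0.5,
                       frame_interval = 0.5,
                       n_frames = 50L,
                       noise_sd = 0.05,
                       image_size = 160L,
                       seed = 1L) {
  spec <- list(nf = as.integer(nf), n_particles = as.integer(n_particles),
               particle_radius = particle_radius,
               protomer_height = protomer_height,
               membrane_height = membrane_height,
               cluster_height = cluster_height,
               cluster_r0 = cluster_r0, line_tension = line_tension,
               temperature = temperature, n_modes = as.integer(n_modes),
               edge_tilt_deg = edge_tilt_deg, pixel_size = pixel_size,
               frame_interval = frame_interval, n_frames = as.integer(n_frames),
               noise_sd = noise_sd, image_size = as.integer(image_size),
               seed = as.integer(seed))
  validate_movie_spec(spec)
  structure(spec, class = "movie_spec")
}

#' @keywords internal
#' @noRd
validate_movie_spec <- function(spec) {
  if (spec$nf < 3L) stop("invalid spec: nf must be >= 3")
  if (!is.finite(spec$line_tension) || spec$line_tension <= 0)
    stop("invalid spec: line_tension must be > 0")
  if (spec$cluster_r0 <= 0) stop("invalid spec: cluster_r0 must be > 0")
  if (spec$n_modes < 2L) stop("invalid spec: n_modes must be >= 2")
  if (spec$pixel_size <= 0) stop("invalid spec: pixel_size must be > 0")
  if (spec$n_frames < 2L) stop("invalid spec: n_frames must be >= 2")
  if (spec$n_particles < 0L) stop("invalid spec: n_particles must be >= 0")
  invisible(spec)
}

#' Per-mode capillary-wave amplitude variance
#'
#' Equilibrium equipartition variance of each boundary Fourier coefficient
#' for modes k >= 2:
#' \deqn{\mathrm{var}(a_k) = \mathrm{var}(b_k)
#'       = \frac{k_B T}{\pi \lambda r_0 (k^2 - 1)}}
#' with the line tension `lambda` in kB*T/nm, so kB*T = 1 in these units.
#' The generator and the estimator in [fit_line_tension()] share this
#' prefactor, making closed-loop recovery self-consistent.
#'
#' @param k integer mode numbers (>= 2).
#' @param lambda line tension, kB*T/nm.
#' @param r0 mean radius, nm.
#' @return Variance of a_k (dimensionless, relative to r0).
#' @export
capillary_mode_variance <- function(k, lambda, r0) {
  stopifnot(all(k >= 2), lambda > 0, r0 > 0)
  1 / (pi * lambda * r0 * (k^2 - 1))
}

#' Sample equilibrium capillary-wave boundary contours
#'
#' Draws independent equilibrium snapshots of a fluctuating closed boundary
#' in polar form
#' \deqn{R(\theta) = r_0 \Big(1 + \sum_{k=2}^{K}
#'       [a_k \cos k\theta + b_k \sin k\theta]\Big)}
#' with `a_k`, `b_k` zero-mean normal with variance
#' [capillary_mode_variance()]. Mode k = 1 (pure translation) is never
#' excited; k = 0 is absorbed into r0. Frames are independent draws from
#' the equilibrium ensemble, not a time-correlated process.
#'
#' @param spec a [movie_spec()].
#' @param n_frames number of boundary snapshots (defaults to
#'   `spec$n_frames`).
#' @param theta angular grid in radians (default 512 uniform points on
#'   `[0, 2*pi)`).
#' @param seed optional seed (defaults to `spec$seed`).
#'
#' @return A list with `radius` (matrix, frames x angles, nm), `theta`,
#'   `coef_a` and `coef_b` (matrices, frames x modes 2..K: the true drawn
#'   coefficients), and `r0`.
#' @export
sample_boundary <- function(spec, n_frames = spec$n_frames,
                            theta = seq(0, 2 * pi, length.out = 513)[-513],
                            seed = spec$seed) {
  validate_movie_spec(spec)
  if (!is.null(seed)) set.seed(seed)
  ks <- 2:spec$n_modes
  vk <- capillary_mode_variance(ks, spec$line_tension, spec$cluster_r0)
  a <- matrix(stats::rnorm(n_frames * length(ks), 0, rep(sqrt(vk), each = n_frames)),
              n_frames, length(ks))
  b <- matrix(stats::rnorm(n_frames * length(ks), 0, rep(sqrt(vk), each = n_frames)),
              n_frames, length(ks))
  basis_c <- cos(outer(ks, theta))   # modes x angles
  basis_s <- sin(outer(ks, theta))
  radius <- spec$cluster_r0 * (1 + a %*% basis_c + b %*% basis_s)
  if (any(radius <= 0))
    stop("generated contour not strictly positive; line tension too small for r0")
  colnames(a) <- colnames(b) <- ks
  list(radius = radius, theta = theta, coef_a = a, coef_b = b,
       r0 = spec$cluster_r0)
}

# Place particle centers inside the (mean) cluster disk at a minimum
# pairwise separation. Clusters pack near-hexagonally at the modal
# center-to-center distance, so centers sit on a randomly rotated
# hexagonal lattice (pitch = min_sep + 2 * jitter) with positional
# jitter; placement errors out when the disk cannot geometrically hold
# the requested count.
#' @keywords internal
#' @noRd
place_particles <- function(n, r_max, min_sep) {
  if (n == 0L) return(matrix(numeric(0), 0, 2))
  jit <- 0.05 * min_sep
  pitch <- min_sep + 2 * jit
  m <- ceiling(r_max / pitch) + 1
  ij <- expand.grid(i = -m:m, j = -m:m)
  hx <- pitch * (ij$i + ij$j / 2)
  hy <- pitch * ij$j * sqrt(3) / 2
  rot <- stats::runif(1, 0, 2 * pi)
  pts <- cbind(hx * cos(rot) - hy * sin(rot), hx * sin(rot) + hy * cos(rot))
  pts <- pts[sqrt(rowSums(pts^2)) <= r_max, , drop = FALSE]
  if (nrow(pts) < n)
    stop(sprintf(
      "could not place %d particles at min separation %.2f nm inside radius %.2f nm (max %d)",
      n, min_sep, r_max, nrow(pts)))
  pts <- pts[order(rowSums(pts^2))[seq_len(n)], , drop = FALSE]
  pts + matrix(stats::runif(2 * n, -jit, jit), n, 2)
}

#' Render a synthetic HS-AFM topography movie with ground truth
#'
#' Builds calibrated height-map frames (nm) containing a flat membrane, a
#' cluster plateau bounded by [sample_boundary()] contours, and `nf`-fold
#' particles rendered as rings of isotropic Gaussian protomer bumps
#' (sigma = `sigma_frac` x `particle_radius`). Particles whose center lies
#' within one particle diameter of the mean contour are "edge" particles
#' and are tilted: their protomer peak heights follow a plane tilted by an
#' angle drawn uniformly in `[0, edge_tilt_deg]` about a random in-plane
#' axis. Additive Gaussian pixel noise of sd `noise_sd` completes the
#' frame.
#'
#' @param spec a [movie_spec()].
#' @param sigma_frac protomer bump sigma as a fraction of
#'   `particle_radius`.
#' @param static_particles if `TRUE` (default) particle positions and
#'   orientations are constant across frames (the time-averaged imaging
#'   situation); boundary fluctuations still animate the cluster edge.
#'
#' @return A list of class `topography_movie_sim` with elements
#'   `movie` (a [topography_movie()]) and `truth`, a list carrying
#'   `line_tension`, `r0`, `centers` (nm, cluster-centered), `orientations`
#'   (deg), `tilts` (deg), `tilt_axes` (deg), `location_class`
#'   (edge/center), `protomer_angles`, `packing_fraction`,
#'   `boundary` (the [sample_boundary()] output) and `spec`.
#' @export
render_movie <- function(spec, sigma_frac = 0.35, static_particles = TRUE) {
  validate_movie_spec(spec)
  set.seed(spec$seed)
  n <- spec$image_size
  px <- spec$pixel_size
  half <- n * px / 2
  bnd <- sample_boundary(spec, seed = NULL)   # uses the stream seeded above

  # particle layout (cluster-centered coordinates, nm); neighbors sit at
  # ~2.6x the protomer ring radius, the modal center-to-center distance
  min_sep <- 2.6 * spec$particle_radius
  r_inner <- max(spec$cluster_r0 - spec$particle_radius, spec$particle_radius)
  centers <- place_particles(spec$n_particles, r_inner, min_sep)
  d_center <- if (spec$n_particles) sqrt(rowSums(centers^2)) else numeric(0)
  loc <- ifelse(spec$cluster_r0 - d_center <= 2 * spec$particle_radius,
                "edge", "center")
  orientations <- stats::runif(spec$n_particles, 0, 360 / spec$nf)
  tilts <- ifelse(loc == "edge",
                  stats::runif(spec$n_particles, 0, spec$edge_tilt_deg), 0)
  tilt_axes <- stats::runif(spec$n_particles, 0, 360)

  # protomer geometry per particle
  proto_ang <- lapply(seq_len(spec$n_particles), function(i)
    (orientations[i] + (0:(spec$nf - 1)) * 360 / spec$nf) %% 360)

  # pixel coordinate grids (nm, cluster-centered)
  xs <- ((seq_len(n)) - 0.5) * px - half
  ys <- ((seq_len(n)) - 0.5) * px - half
  X <- matrix(xs, n, n, byrow = TRUE)
  Y <- matrix(ys, n, n)
  TH <- atan2(Y, X) %% (2 * pi)
  RR <- sqrt(X^2 + Y^2)

  base_particles <- particle_field(
    X, Y, centers, nf = spec$nf, orientations = orientations,
    tilts = tilts, tilt_axes = tilt_axes,
    particle_radius = spec$particle_radius,
    protomer_height = spec$protomer_height, sigma_frac = sigma_frac)

  frames <- vector("list", spec$n_frames)
  for (f in seq_len(spec$n_frames)) {
    rb <- stats::approx(c(bnd$theta, 2 * pi), c(bnd$radius[f, ], bnd$radius[f, 1]),
                        xout = as.vector(TH), rule = 2)$y
    inside <- RR <= matrix(rb, n, n)
    fr <- matrix(spec$membrane_height, n, n)
    fr[inside] <- fr[inside] + spec$cluster_height
    fr <- fr + base_particles * inside
    if (spec$noise_sd > 0)
      fr <- fr + matrix(stats::rnorm(n * n, 0, spec$noise_sd), n, n)
    frames[[f]] <- fr
  }

  # ground-truth packing: molecular cross-section by symmetry order
  # (tetramer/pentamer defaults), else the rendered footprint area
  sig <- sigma_frac * spec$particle_radius
  area_per <- if (spec$nf == 4L) cross_section_areas()[["glpf"]]
  else if (spec$nf == 5L) cross_section_areas()[["foca"]]
  else pi * (spec$particle_radius + sig)^2
  truth <- list(
    line_tension = spec$line_tension,
    r0 = spec$cluster_r0,
    centers = centers + half,             # field coordinates, nm
    centers_rel = centers,                # cluster-centered, nm
    orientations = orientations,
    tilts = tilts,
    tilt_axes = tilt_axes,
    location_class = loc,
    protomer_angles = proto_ang,
    n_pentamer = if (spec$nf == 5L) spec$n_particles else 0L,
    n_tetramer = if (spec$nf == 4L) spec$n_particles else 0L,
    area_cluster = pi * spec$cluster_r0^2,
    packing_fraction = if (spec$n_particles)
      spec$n_particles * area_per / (pi * spec$cluster_r0^2) else 0,
    boundary = bnd,
    spec = spec
  )
  movie <- topography_movie(frames, pixel_size = px,
                            frame_interval = spec$frame_interval)
  structure(list(movie = movie, truth = truth), class = "topography_movie_sim")
}

#' Render nf-fold particles as height bumps on coordinate grids
#'
#' The rendering primitive shared by [render_movie()] and the particle
#' tests: each particle contributes nf isotropic Gaussian protomer bumps
#' of constant peak amplitude `protomer_height` placed on a ring of radius
#' `particle_radius`, sitting on a local tilt plane confined to the
#' particle footprint (a smooth super-Gaussian disk), so a tilted particle
#' tips as a rigid body and its protomers remain protrusions.
#'
#' @param X,Y coordinate matrices (nm), e.g. from `outer`/`matrix` over
#'   the pixel grid.
#' @param centers n x 2 matrix of particle centers (same coordinates as
#'   X/Y), nm.
#' @param nf symmetry order.
#' @param orientations per-particle first-protomer angle, degrees.
#' @param tilts per-particle tilt angle, degrees.
#' @param tilt_axes per-particle tilt (downhill-to-uphill) axis, degrees.
#' @param particle_radius protomer ring radius, nm.
#' @param protomer_height bump peak amplitude, nm.
#' @param sigma_frac bump sigma as fraction of `particle_radius`.
#' @return Height matrix (nm) of the particle contribution.
#' @export
particle_field <- function(X, Y, centers, nf, orientations, tilts, tilt_axes,
                           particle_radius, protomer_height,
                           sigma_frac = 0.35) {
  field <- matrix(0, nrow(X), ncol(X))
  np <- nrow(centers)
  if (np == 0) return(field)
  sig <- sigma_frac * particle_radius
  r_foot <- particle_radius + 3 * sig
  for (i in seq_len(np)) {
    ang <- (orientations[i] + (0:(nf - 1)) * 360 / nf) * pi / 180
    pxs <- centers[i, 1] + particle_radius * cos(ang)
    pys <- centers[i, 2] + particle_radius * sin(ang)
    dx <- X - centers[i, 1]; dy <- Y - centers[i, 2]
    if (tilts[i] != 0) {
      ax <- tilt_axes[i] * pi / 180
      grad <- tan(tilts[i] * pi / 180)
      foot <- exp(-((dx^2 + dy^2) / r_foot^2)^4)   # smooth footprint disk
      field <- field + grad * (dx * cos(ax) + dy * sin(ax)) * foot
    }
    for (j in seq_len(nf)) {
      field <- field + protomer_height *
        exp(-((X - pxs[j])^2 + (Y - pys[j])^2) / (2 * sig^2))
    }
  }
  field
}

#' Simulate a FRAP image series with known diffusion coefficient
#'
#' Forward model for a fluorescence-recovery-after-photobleaching
#' experiment on a uniform membrane: the post-bleach concentration field is
#' a sharp disk of radius `rn` (depth `bleach_depth`) convolved with a
#' small optical blur `sigma0`, which then spreads by free 2D diffusion —
#' at time t after the bleach the field is the initial field convolved
#' with a Gaussian of sd `sqrt(2 D t)`. Pre-bleach frames are uniform at
#' intensity 1.
#'
#' @param D diffusion coefficient, um^2/s; > 0.
#' @param rn nominal bleach ROI radius, um.
#' @param bleach_depth fraction bleached inside the ROI, in (0, 1].
#' @param times frame times in s, strictly increasing; times < 0 are
#'   pre-bleach, the bleach happens just before t = 0 and the frame at
#'   t = 0 is the first post-bleach image. Default is the standard
#'   cadence: 10 pre-bleach frames at 1 s, the bleach frame, 9 more post
#'   frames at 5 s, then 13 at 30 s.
#' @param image_size image side, px.
#' @param field_width physical field width, um.
#' @param sigma0 blur of the bleached edge, um. The default `rn / 2`
#'   stands in for diffusive spreading during the tens-of-seconds bleach
#'   pulse, which in practice makes the post-bleach profile near-Gaussian
#'   with an effective radius well above `rn` — the regime the
#'   standard-protocol diffusion formula assumes. A nearly sharp disk
#'   (`sigma0` near 0) violates that assumption and biases recovery.
#' @param noise_sd additive intensity noise sd (fraction of pre-bleach).
#' @param seed RNG seed for the noise.
#'
#' @return A list of class `frap_sim`: `frames` (list of matrices),
#'   `times` (s), `prebleach` (logical per frame), `rn`, `center` (px),
#'   `pixel_size` (um/px), `true_D`.
#' @export
simulate_frap <- function(D, rn = 5, bleach_depth = 0.9,
                          times = frap_default_times(),
                          image_size = 128L, field_width = 32.4,
                          sigma0 = rn / 2, noise_sd = 0, seed = 1L) {
  if (!is.numeric(D) || D <= 0) stop("D must be > 0")
  if (bleach_depth < 0 || bleach_depth > 1) stop("bleach_depth must be in [0, 1]")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  set.seed(seed)
  n <- as.integer(image_size)
  pxu <- field_width / n                       # um per px
  ctr <- (n + 1) / 2
  xs <- (seq_len(n) - ctr) * pxu
  R2 <- outer(xs^2, xs^2, `+`)
  disk <- 1 - bleach_depth * (sqrt(R2) <= rn)
  bleach0 <- gaussian_blur_fft(disk, sigma0 / pxu)
  frames <- vector("list", length(times))
  pre <- times < 0
  for (i in seq_along(times)) {
    if (pre[i]) {
      fr <- matrix(1, n, n)
    } else {
      sig_d <- sqrt(2 * D * times[i]) / pxu
      fr <- gaussian_blur_fft(bleach0, sig_d)
    }
    if (noise_sd > 0) fr <- fr + matrix(stats::rnorm(n * n, 0, noise_sd), n, n)
    frames[[i]] <- fr
  }
  structure(list(frames = frames, times = times, prebleach = pre,
                 rn = rn, center = c(ctr, ctr), pixel_size = pxu,
                 true_D = D),
            class = "frap_sim")
}

#' Standard FRAP acquisition cadence
#'
#' 10 pre-bleach frames at 1 frame/s, the first post-bleach frame at t = 0,
#' 9 more at 1 frame per 5 s, then 13 at 1 frame per 30 s.
#'
#' @return Numeric vector of frame times in seconds (pre-bleach < 0).
#' @export
frap_default_times <- function() {
  c(seq(-10, -1, by = 1), 0, seq(5, 45, by = 5), seq(75, 435, by = 30))
}
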
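# Single-particle geometry: rotational symmetrization, protomer
# localization, symmetry classification, tilt, neighbor pairs and
# interaction angles.
#
# All positions are in nm in the frame coordinate system (x along columns,
# y along rows); angles returned to the user are in degrees.

# Sample a frame on a polar grid around `center` (nm).
# Returns radii x angles matrix; NA outside the frame.
#' @keywords internal
#' @noRd
polar_samples <- function(frame, center, radii, thetas, pixel_size = 1) {
  pts_x <- outer(radii, cos(thetas)) + center[1]
  pts_y <- outer(radii, sin(thetas)) + center[2]
  col <- pts_x / pixel_size + 0.5
  row <- pts_y / pixel_size + 0.5
  matrix(interp_bilinear(frame, as.vector(row), as.vector(col)),
         length(radii), length(thetas))
}

#' Angular intensity profile at a protomer ring radius
#'
#' Mean height sampled on a circle (or a thin annulus) around a particle
#' center, as a function of the polar angle. This is the polar plot
#' profile whose peaks reveal the protomer positions: an nf-fold particle
#' shows nf peaks with 360/nf degree periodicity.
#'
#' @param frame height matrix (nm).
#' @param center particle center (x, y), nm.
#' @param ring_radius ring radius, nm; `NULL` to estimate it as the radius
#'   maximizing the angular-mean height outside the core.
#' @param pixel_size nm/px.
#' @param n_theta angular samples (default 360).
#' @param band annulus half-width in nm averaged over (default half a
#'   pixel).
#' @param max_radius bound for the ring-radius search, nm (keep it inside
#'   the particle so the cluster boundary does not dominate; default
#'   12 px).
#'
#' @return A list: `theta_deg`, `profile` (nm), `ring_radius`.
#' @export
angular_profile <- function(frame, center, ring_radius = NULL, pixel_size = 1,
                            n_theta = 360L, band = pixel_size / 2,
                            max_radius = 12 * pixel_size) {
  thetas <- seq(0, 2 * pi, length.out = n_theta + 1)[-(n_theta + 1)]
  if (is.null(ring_radius)) {
    rmax <- min(center[1], center[2],
                ncol(frame) * pixel_size - center[1],
                nrow(frame) * pixel_size - center[2]) - pixel_size
    rmax <- min(rmax, max_radius)
    radii <- seq(pixel_size, rmax, by = pixel_size / 2)
    pm <- polar_samples(frame, center, radii, thetas, pixel_size)
    radial_mean <- rowMeans(pm, na.rm = TRUE)
    # protomer ring = radius with maximal angular modulation outside the core
    modulation <- apply(pm, 1, stats::sd, na.rm = TRUE)
    ring_radius <- radii[which.max(modulation * radial_mean)]
  }
  rs <- seq(max(ring_radius - band, pixel_size / 4), ring_radius + band,
            length.out = 3)
  pm <- polar_samples(frame, center, rs, thetas, pixel_size)
  prof <- colMeans(pm, na.rm = TRUE)
  list(theta_deg = thetas * 180 / pi, profile = prof, ring_radius = ring_radius)
}

#' Circular peak positions of an angular profile
#'
#' Local maxima of a periodic profile (wrap-around aware), with parabolic
#' sub-sample refinement; used to measure the angular periodicity of
#' protomer protrusions.
#'
#' @param theta_deg angle grid, degrees.
#' @param profile profile values.
#' @param min_prominence minimum height above the profile mean for a peak
#'   to count, as a fraction of the profile's range (default 0.1).
#' @return Sorted peak angles in degrees, plus attribute `spacing_deg`
#'   (mean circular spacing between adjacent peaks).
#' @export
profile_peaks <- function(theta_deg, profile, min_prominence = 0.1) {
  n <- length(profile)
  prev <- c(profile[n], profile[-n])
  nxt <- c(profile[-1], profile[1])
  floorv <- mean(profile) + min_prominence * (max(profile) - min(profile))
  is_pk <- profile > prev & profile >= nxt & profile > floorv
  idx <- which(is_pk)
  if (length(idx) == 0) return(structure(numeric(0), spacing_deg = NA_real_))
  step <- theta_deg[2] - theta_deg[1]
  refine <- function(i) {
    im <- if (i == 1) n else i - 1
    ip <- if (i == n) 1 else i + 1
    den <- profile[im] - 2 * profile[i] + profile[ip]
    d <- if (den == 0) 0 else 0.5 * (profile[im] - profile[ip]) / den
    (theta_deg[i] + max(min(d, 0.5), -0.5) * step) %% 360
  }
  pk <- sort(vapply(idx, refine, numeric(1)))
  gaps <- diff(c(pk, pk[1] + 360))
  structure(pk, spacing_deg = mean(gaps))
}

#' Refine a particle center by rotational symmetrization
#'
#' For every candidate origin near the rough center, the particle image
#' (sampled on a polar grid) is averaged over its nf rotations; the
#' internal symmetry value isv is the Pearson correlation between the
#' pre- and post-symmetrized images. The origin with the highest isv is
#' the refined center — a well-centered nf-fold particle correlates almost
#' perfectly with its own rotational average. Protomer positions are the
#' nf angularly equispaced ring peaks of the symmetrized image, phased on
#' the original (unsymmetrized) angular profile so that heights of
#' individual protomers (needed for tilt) are preserved.
#'
#' @param frame height matrix (nm).
#' @param rough_center approximate particle center (x, y), nm.
#' @param nf symmetry order.
#' @param search_radius search window half-width around `rough_center`,
#'   nm (default 2 px).
#' @param patch_radius polar patch radius, nm (should cover the particle;
#'   default 8 px).
#' @param ring_radius protomer ring radius, nm; `NULL` to estimate.
#' @param pixel_size nm/px.
#' @param step search grid step, nm (default half a pixel).
#' @param isv_floor below this isv the particle is flagged low-confidence
#'   (default 0.5).
#' @param detilt_iter tilt-compensation iterations: after each pass the
#'   fitted protomer plane is subtracted and the center re-refined, since
#'   the rotational average of a tilted particle is biased toward its high
#'   side (default 2; 0 disables).
#'
#' @return An object of class `particle`: `center` (x, y nm), `nf`,
#'   `protomers` (data.frame x, y, h), `isv`, `tilt_deg`, `ring_radius`,
#'   `low_confidence`, `location_class` (NA until classified).
#' @export
refine_particle <- function(frame, rough_center, nf, search_radius = NULL,
                            patch_radius = NULL, ring_radius = NULL,
                            pixel_size = 1, step = pixel_size / 2,
                            isv_floor = 0.5, detilt_iter = 2L) {
  stopifnot(is.matrix(frame), length(rough_center) == 2, nf >= 3)
  if (is.null(search_radius)) search_radius <- 2 * pixel_size
  if (is.null(patch_radius)) patch_radius <- 8 * pixel_size
  nth <- max(90L, 18L * nf)
  nth <- as.integer(ceiling(nth / nf) * nf)          # divisible by nf
  thetas <- seq(0, 2 * pi, length.out = nth + 1)[-(nth + 1)]
  radii <- seq(pixel_size / 2, patch_radius, by = pixel_size / 2)
  offs <- seq(-search_radius, search_radius, by = step)
  shift_n <- nth / nf

  # isv of one candidate origin. The correlation is taken against the
  # leave-self-out rotational average (the mean of the nf - 1 rotated
  # copies), computed outside the innermost radii where all rotated
  # copies share pixels: this keeps isv near 0 for pure noise while an
  # nf-fold particle still correlates ~1 with its own rotations.
  core <- radii >= 2 * pixel_size
  eval_origin <- function(fr, ctr) {
    pm <- polar_samples(fr, ctr, radii, thetas, pixel_size)
    if (anyNA(pm)) return(NULL)
    acc <- pm
    others <- 0
    for (j in seq_len(nf - 1)) {
      acc <- acc[, c((shift_n + 1):nth, 1:shift_n)]
      others <- others + acc
    }
    others <- others / (nf - 1)
    isv <- suppressWarnings(stats::cor(as.vector(pm[core, ]),
                                       as.vector(others[core, ])))
    if (is.na(isv)) isv <- 0
    list(isv = isv, center = ctr, pm = pm, sym = (pm + others * (nf - 1)) / nf)
  }

  # origin search: coarse grid, then a fine pass at step/4 around the best
  search_origin <- function(fr, center0) {
    best <- list(isv = -Inf)
    for (oy in offs) for (ox in offs) {
      cand <- eval_origin(fr, c(center0[1] + ox, center0[2] + oy))
      if (!is.null(cand) && cand$isv > best$isv) best <- cand
    }
    if (!is.finite(best$isv))
      stop("search window leaves the frame: no valid origin")
    fine <- seq(-step, step, by = step / 4)
    c0 <- best$center
    for (oy in fine) for (ox in fine) {
      cand <- eval_origin(fr, c(c0[1] + ox, c0[2] + oy))
      if (!is.null(cand) && cand$isv > best$isv) best <- cand
    }
    best
  }

  extract <- function(best, fr_phase, rr) {
    if (is.null(rr)) {
      modulation <- apply(best$sym, 1, stats::sd)
      radial_mean <- rowMeans(best$sym)
      rr <- radii[which.max(modulation * radial_mean)]
    }
    # phase of the nf-th angular harmonic of the (unsymmetrized) profile
    # locates the protomers: one peak angle modulo 360/nf, equispacing
    # gives the rest
    prof <- polar_samples(fr_phase, best$center, rr, thetas, pixel_size)[1, ]
    z <- sum(prof * exp(1i * nf * thetas))
    theta0 <- Arg(z) / nf
    pang <- (theta0 + 2 * pi * (0:(nf - 1)) / nf) %% (2 * pi)
    list(ring_radius = rr,
         x = best$center[1] + rr * cos(pang),
         y = best$center[2] + rr * sin(pang),
         angle_deg = pang * 180 / pi)
  }

  heights_at <- function(x, y)
    interp_bilinear(frame, y / pixel_size + 0.5, x / pixel_size + 0.5)

  best <- search_origin(frame, rough_center)
  geo <- extract(best, frame, ring_radius)
  hh <- heights_at(geo$x, geo$y)
  # tilt compensation: subtract the fitted protomer plane and re-center
  for (it in seq_len(detilt_iter)) {
    if (anyNA(hh)) break
    fit <- stats::lm.fit(cbind(1, geo$x, geo$y), hh)
    b <- fit$coefficients[2]; cc <- fit$coefficients[3]
    if (!all(is.finite(c(b, cc))) || (abs(b) < 1e-6 && abs(cc) < 1e-6)) break
    nrp <- nrow(frame); ncp <- ncol(frame)
    Xn <- matrix((seq_len(ncp) - 0.5) * pixel_size, nrp, ncp, byrow = TRUE)
    Yn <- matrix((seq_len(nrp) - 0.5) * pixel_size, nrp, ncp)
    detilted <- frame - b * Xn - cc * Yn
    best <- search_origin(detilted, best$center)
    geo <- extract(best, detilted, ring_radius)
    hh <- heights_at(geo$x, geo$y)
  }
  protomers <- data.frame(x = geo$x, y = geo$y, h = hh,
                          angle_deg = geo$angle_deg)
  ring_radius <- geo$ring_radius
  tilt <- tryCatch(tilt_angle(protomers), error = function(e) NA_real_)
  structure(list(center = best$center, nf = as.integer(nf),
                 protomers = protomers, isv = best$isv, tilt_deg = tilt,
                 ring_radius = ring_radius,
                 low_confidence = best$isv < isv_floor,
                 location_class = NA_character_),
            class = "particle")
}

#' @export
print.particle <- function(x, ...) {
  cat(sprintf("particle: nf = %d at (%.2f, %.2f) nm, isv = %.3f, tilt = %.1f deg%s\n",
              x$nf, x$center[1], x$center[2], x$isv, x$tilt_deg,
              if (x$low_confidence) " [low confidence]" else ""))
  invisible(x)
}

#' Classify oligomeric symmetry from the angular profile
#'
#' Fourier analysis of the angular intensity profile at the protomer ring:
#' the candidate symmetry order with the dominant angular harmonic wins.
#' If no harmonic dominates (power ratio below `min_ratio` against the
#' runner-up) the particle is left unclassified (`NA`).
#'
#' @param frame height matrix (nm).
#' @param center particle center (x, y), nm.
#' @param candidates candidate symmetry orders (default 4, 5, 6).
#' @param ring_radius,pixel_size see [angular_profile()].
#' @param min_ratio dominance ratio required (default 1.5).
#'
#' @return A list: `nf` (integer or `NA`), `spacing_deg` (360/nf),
#'   `power` (named harmonic powers), `peak_spacing_deg` (measured mean
#'   peak spacing).
#' @export
classify_symmetry <- function(frame, center, candidates = c(4L, 5L, 6L),
                              ring_radius = NULL, pixel_size = 1,
                              min_ratio = 1.5) {
  ap <- angular_profile(frame, center, ring_radius, pixel_size)
  th <- ap$theta_deg * pi / 180
  p <- ap$profile - mean(ap$profile)
  pw <- vapply(candidates, function(m) Mod(sum(p * exp(1i * m * th)))^2,
               numeric(1))
  names(pw) <- candidates
  o <- order(pw, decreasing = TRUE)
  pk <- profile_peaks(ap$theta_deg, ap$profile)
  if (length(pw) > 1 && pw[o[1]] < min_ratio * pw[o[2]]) {
    return(list(nf = NA_integer_, spacing_deg = NA_real_, power = pw,
                peak_spacing_deg = attr(pk, "spacing_deg")))
  }
  nf <- as.integer(candidates[o[1]])
  list(nf = nf, spacing_deg = 360 / nf, power = pw,
       peak_spacing_deg = attr(pk, "spacing_deg"))
}

#' Particle tilt from protomer positions and heights
#'
#' Fits the least-squares plane through the protomer points (x, y, h) and
#' returns the acute angle between the plane normal and the z-axis, in
#' degrees in `[0, 90]`. Invariant under adding a constant to all heights
#' and under in-plane rotation.
#'
#' @param protomers data frame (or matrix) with columns x, y, h (nm); at
#'   least 3 non-collinear points.
#' @return Tilt angle omega in degrees.
#' @export
tilt_angle <- function(protomers) {
  m <- as.matrix(protomers[, c("x", "y", "h")])
  if (nrow(m) < 3) stop("need >= 3 protomers")
  if (anyNA(m)) stop("protomer coordinates contain NA")
  xy <- scale(m[, 1:2], scale = FALSE)
  if (min(svd(xy)$d) < 1e-9 * max(svd(xy)$d, 1))
    stop("degenerate geometry: collinear protomer positions")
  fit <- stats::lm.fit(cbind(1, m[, 1], m[, 2]), m[, 3])
  b <- unname(fit$coefficients[2]); c <- unname(fit$coefficients[3])
  cosang <- 1 / sqrt(b^2 + c^2 + 1)
  unname(acos(pmin(pmax(cosang, -1), 1)) * 180 / pi)
}

#' Neighbor particle pairs by Delaunay triangulation
#'
#' Identifies candidate interacting pairs as Delaunay edges of the
#' particle centers and keeps those with center-to-center distance
#' `d <= d_max` (the automated stand-in for a manual interaction check).
#' The default cutoff is 1.5x the modal nearest-neighbor distance.
#'
#' @param particles list of [refine_particle()] objects, or an n x 2
#'   matrix of centers (nm).
#' @param d_max distance cutoff in nm, or `NULL` for the default.
#'
#' @return A data frame of class `neighbor_pairs`: columns `i`, `j`
#'   (particle indices), `d` (nm), and, when particle objects were given,
#'   `alpha_deg`, `beta_deg` from [interaction_angles()]. Zero rows for
#'   fewer than 2 particles.
#' @export
delaunay_pairs <- function(particles, d_max = NULL) {
  have_objs <- is.list(particles) && !is.matrix(particles) &&
    length(particles) > 0 && inherits(particles[[1]], "particle")
  centers <- if (have_objs)
    do.call(rbind, lapply(particles, function(p) p$center))
  else as.matrix(particles)
  empty <- data.frame(i = integer(0), j = integer(0), d = numeric(0))
  class(empty) <- c("neighbor_pairs", "data.frame")
  if (is.null(centers) || nrow(centers) < 2) return(empty)
  ed <- delaunay_edges(centers)
  if (nrow(ed) == 0) return(empty)
  d <- sqrt(rowSums((centers[ed[, 1], , drop = FALSE] -
                       centers[ed[, 2], , drop = FALSE])^2))
  if (is.null(d_max)) {
    # modal nearest-neighbor distance, from each particle's closest edge
    nnd <- vapply(seq_len(nrow(centers)), function(i) {
      sel <- ed[, 1] == i | ed[, 2] == i
      if (!any(sel)) return(NA_real_)
      min(d[sel])
    }, numeric(1))
    nnd <- nnd[is.finite(nnd)]
    mode_d <- if (length(nnd) >= 5) {
      dd <- stats::density(nnd)
      dd$x[which.max(dd$y)]
    } else stats::median(nnd)
    d_max <- 1.5 * mode_d
  }
  keep <- d <= d_max
  out <- data.frame(i = ed[keep, 1], j = ed[keep, 2], d = d[keep])
  if (have_objs && nrow(out) > 0) {
    ab <- t(vapply(seq_len(nrow(out)), function(r)
      interaction_angles(particles[[out$i[r]]], particles[[out$j[r]]]),
      numeric(2)))
    out$alpha_deg <- ab[, 1]
    out$beta_deg <- ab[, 2]
  }
  attr(out, "d_max") <- d_max
  class(out) <- c("neighbor_pairs", "data.frame")
  out
}

#' Signed interaction angles of a neighbor pair
#'
#' For each particle of a pair, the interacting protomer is the one with
#' the smallest angular separation from the center-to-center connection
#' line; the returned angle is the signed angular offset of that protomer
#' from the line, positive when the protomer sits clockwise of the line
#' and negative counterclockwise. By nf-fold symmetry the result is
#' bounded by +-180/nf degrees; an exact tie at the boundary is resolved
#' toward +.
#'
#' @param a,b two [refine_particle()] objects (or lists with `center` and
#'   `protomers$angle_deg`).
#' @return Named numeric vector `c(alpha = , beta = )`, degrees: `alpha`
#'   for particle `a`, `beta` for particle `b`.
#' @export
interaction_angles <- function(a, b) {
  c(alpha = signed_protomer_angle(a, b$center),
    beta = signed_protomer_angle(b, a$center))
}

# signed angle (CW positive) of the protomer of `p` closest to the
# direction toward `target`
#' @keywords internal
#' @noRd
signed_protomer_angle <- function(p, target) {
  psi <- atan2(target[2] - p$center[2], target[1] - p$center[1]) * 180 / pi
  delta <- wrap_deg(p$protomers$angle_deg - psi)
  half <- 180 / p$nf
  j <- which.min(abs(delta))
  # y runs along rows (down in display orientation), so increasing
  # mathematical angle is clockwise on screen: CW offsets are positive
  ang <- delta[j]
  if (abs(abs(ang) - half) < 1e-9) ang <- half   # tie toward +
  unname(ang)
}

#' Probability density map of interaction angles
#'
#' Kernel density estimate of neighbor-pair interaction angles (alpha,
#' beta) on the square [-180/nf, +180/nf]^2 with periodic wrapping at the
#' edges, symmetrized over (alpha, beta) <-> (beta, alpha) since pair
#' order is arbitrary, and normalized so the maximum is 1.
#'
#' @param pairs a `neighbor_pairs` data frame with `alpha_deg`,
#'   `beta_deg`, or a two-column matrix of angles (degrees).
#' @param nf symmetry order defining the angular range (default 5).
#' @param bandwidth Gaussian kernel bandwidth, degrees (default 3).
#' @param bin grid step, degrees (default 2).
#'
#' @return A list: `alpha`, `beta` (grid vectors, degrees), `density`
#'   (matrix alpha x beta, max = 1).
#' @export
angle_density_map <- function(pairs, nf = 5L, bandwidth = 3, bin = 2) {
  ab <- if (is.matrix(pairs)) pairs else cbind(pairs$alpha_deg, pairs$beta_deg)
  if (is.null(ab) || nrow(ab) < 1) stop("need at least one pair")
  half <- 180 / nf
  period <- 360 / nf
  # symmetrize over pair order
  ab <- rbind(ab, ab[, 2:1, drop = FALSE])
  g <- seq(-half, half, by = bin)
  dens <- matrix(0, length(g), length(g))
  shifts <- c(-period, 0, period)   # periodic images
  for (r in seq_len(nrow(ab))) {
    for (sa in shifts) for (sb in shifts) {
      da <- g - (ab[r, 1] + sa)
      db <- g - (ab[r, 2] + sb)
      dens <- dens + outer(exp(-da^2 / (2 * bandwidth^2)),
                           exp(-db^2 / (2 * bandwidth^2)))
    }
  }
  dens <- dens / max(dens)
  list(alpha = g, beta = g, density = dens)
}

#' Gaussian statistics of center-to-center distances
#'
#' Fits a single Gaussian to the histogram of pair distances and reports
#' peak +- 1 sd with the sample count, the way nearest-neighbor distance
#' tables are usually summarized. If the histogram fit does not converge,
#' sample mean/sd are reported with `converged = FALSE`; a residual
#' criterion flags distributions that a single Gaussian describes poorly
#' (e.g. bimodal input).
#'
#' @param pairs a `neighbor_pairs` data frame (column `d`) or a numeric
#'   vector of distances (nm); >= 10 values for a fit.
#' @param min_r2 histogram-fit R^2 below which `poor_fit` is raised
#'   (default 0.8).
#'
#' @return A list: `peak` (nm), `sd` (nm), `n`, `converged`, `poor_fit`,
#'   `r_squared`.
#' @export
distance_stats <- function(pairs, min_r2 = 0.8) {
  d <- if (is.numeric(pairs)) pairs else pairs$d
  d <- d[is.finite(d)]
  n <- length(d)
  if (n == 0) stop("no distances")
  if (stats::sd(d) == 0) {
    return(list(peak = d[1], sd = 0, n = n, converged = TRUE,
                poor_fit = FALSE, r_squared = 1))
  }
  if (n < 10) {
    return(list(peak = mean(d), sd = stats::sd(d), n = n, converged = FALSE,
                poor_fit = NA, r_squared = NA_real_))
  }
  h <- graphics::hist(d, breaks = "Sturges", plot = FALSE)
  x <- h$mids; y <- h$counts
  fit <- tryCatch(
    stats::nls(y ~ A * exp(-(x - mu)^2 / (2 * s^2)),
               start = list(A = max(y), mu = mean(d), s = stats::sd(d)),
               control = stats::nls.control(warnOnly = FALSE)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(list(peak = mean(d), sd = stats::sd(d), n = n, converged = FALSE,
                poor_fit = NA, r_squared = NA_real_))
  }
  cf <- stats::coef(fit)
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((y - mean(y))^2)
  list(peak = unname(cf["mu"]), sd = abs(unname(cf["s"])), n = n,
       converged = TRUE, poor_fit = r2 < min_r2, r_squared = r2)
}

#' Compare two distance populations
#'
#' Two-sample Welch t-test between center-to-center distance populations
#' (e.g. low-chi vs. high-chi lipid conditions).
#'
#' @param d1,d2 numeric distance vectors (nm).
#' @return The `htest` object from [stats::t.test()].
#' @export
compare_distances <- function(d1, d2) stats::t.test(d1, d2)

#' Classify particles as cluster-edge or cluster-center
#'
#' A particle is "edge" when its center lies within one particle diameter
#' of the cluster contour (measured radially from the cluster center), or
#' outside the contour; otherwise "center".
#'
#' @param particles list of [refine_particle()] objects.
#' @param contour a list with `theta` (radians) and `radius` (nm) — e.g.
#'   one frame of a [cluster_trace()] or a [radial_profile()] — plus
#'   `center` (x, y nm; defaults to `contour$center`).
#' @param diameter particle diameter in nm (default 2x the first
#'   particle's ring radius).
#' @param center cluster center override (x, y nm).
#'
#' @return The particle list with `location_class` filled in.
#' @export
classify_edge_center <- function(particles, contour, diameter = NULL,
                                 center = NULL) {
  if (is.null(center)) center <- contour$center
  if (is.null(center)) stop("cluster center required")
  if (is.null(diameter)) diameter <- 2 * particles[[1]]$ring_radius
  th <- contour$theta
  R <- contour$radius
  for (i in seq_along(particles)) {
    p <- particles[[i]]
    dx <- p$center[1] - center[1]; dy <- p$center[2] - center[2]
    r <- sqrt(dx^2 + dy^2)
    a <- atan2(dy, dx) %% (2 * pi)
    Ri <- stats::approx(c(th - 2 * pi, th, th + 2 * pi), rep(R, 3), xout = a,
                        ties = "ordered")$y
    particles[[i]]$location_class <-
      if (Ri - r <= diameter) "edge" else "center"
  }
  particles
}

#' Time-average consecutive movie frames
#'
#' Averages blocks of `n` consecutive frames to boost the signal-to-noise
#' ratio before particle picking.
#'
#' @param movie a [topography_movie()].
#' @param n frames per block (default 5).
#' @return A [topography_movie()] of the block averages.
#' @export
time_average_frames <- function(movie, n = 5L) {
  stopifnot(inherits(movie, "topography_movie"), n >= 1)
  nfr <- length(movie$frames)
  nblk <- nfr %/% n
  if (nblk == 0) stop("movie shorter than the averaging window")
  frames <- lapply(seq_len(nblk), function(b) {
    Reduce(`+`, movie$frames[((b - 1) * n + 1):(b * n)]) / n
  })
  topography_movie(frames, movie$pixel_size, movie$frame_interval * n)
}

#' Simple blob detection for rough particle seeds
#'
#' Local maxima above a height floor with a minimum mutual separation —
#' the automated convenience alternative to hand-picked seed coordinates.
#'
#' @param frame height matrix (nm).
#' @param min_height absolute height floor; default: isodata threshold of
#'   the frame plus half the above-threshold interquartile range.
#' @param min_sep minimum separation between detections, nm.
#' @param pixel_size nm/px.
#' @return Matrix of seed centers (x, y), nm, strongest first.
#' @export
detect_particles <- function(frame, min_height = NULL, min_sep = 5,
                             pixel_size = 1) {
  if (is.null(min_height)) {
    t0 <- isodata_threshold(frame)
    up <- frame[frame > t0]
    min_height <- t0 + 0.5 * stats::IQR(up)
  }
  mx <- frame >= min_height &
    frame >= mat_shift(frame,  1L, 0L, fill = -Inf) &
    frame >= mat_shift(frame, -1L, 0L, fill = -Inf) &
    frame >= mat_shift(frame, 0L,  1L, fill = -Inf) &
    frame >= mat_shift(frame, 0L, -1L, fill = -Inf) &
    frame >= mat_shift(frame,  1L,  1L, fill = -Inf) &
    frame >= mat_shift(frame,  1L, -1L, fill = -Inf) &
    frame >= mat_shift(frame, -1L,  1L, fill = -Inf) &
    frame >= mat_shift(frame, -1L, -1L, fill = -Inf)
  idx <- which(mx, arr.ind = TRUE)
  if (nrow(idx) == 0) return(matrix(numeric(0), 0, 2))
  pts <- cbind(x = (idx[, 2] - 0.5) * pixel_size,
               y = (idx[, 1] - 0.5) * pixel_size)
  o <- order(frame[idx], decreasing = TRUE)
  pts <- pts[o, , drop = FALSE]
  keep <- logical(nrow(pts))
  for (i in seq_len(nrow(pts))) {
    if (!any(keep)) { keep[i] <- TRUE; next }
    sel <- pts[keep, , drop = FALSE]
    if (all(sqrt((sel[, 1] - pts[i, 1])^2 + (sel[, 2] - pts[i, 2])^2) >= min_sep))
      keep[i] <- TRUE
  }
  pts[keep, , drop = FALSE]
}
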
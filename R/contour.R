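#' Polar radial profile of a cluster mask
#'
#' Records the most probable cluster radius at every angle by casting a
#' ray from the center through each angular bin and locating the
#' inside-to-outside boundary crossings of the (bilinearly interpolated)
#' mask. A star-convex direction has a single inside segment, whose exit
#' is the outermost boundary crossing; in non-star-convex directions (the
#' ray re-enters the mask) the crossing bounding the longest inside
#' segment — the most probable radius along that direction — is taken.
#' Bins whose ray finds no crossing (center marginally outside thin
#' sections) are interpolated circularly from their neighbours.
#'
#' @param mask logical matrix (cluster mask).
#' @param center center (x, y) in nm; defaults to the mask center of mass.
#' @param dtheta angular bin width in radians (default 2 degrees).
#' @param pixel_size nm per pixel.
#' @param max_empty_frac reject (error) if more than this fraction of
#'   angular bins has no boundary crossing (default 0.25).
#'
#' @return A list: `theta` (bin centers, radians), `radius` (nm),
#'   `center` (nm).
#' @export
radial_profile <- function(mask, center = NULL, dtheta = 2 * pi / 180,
                           pixel_size = 1, max_empty_frac = 0.25) {
  stopifnot(is.matrix(mask))
  if (!any(mask)) stop("empty mask")
  idx <- which(mask, arr.ind = TRUE)
  if (is.null(center)) {
    center <- c(x = mean(idx[, 2] - 0.5) * pixel_size,
                y = mean(idx[, 1] - 0.5) * pixel_size)
  } else {
    center <- c(x = center[1], y = center[2])
  }
  # center must lie inside the mask
  rc <- floor(center[2] / pixel_size) + 1L
  cc <- floor(center[1] / pixel_size) + 1L
  if (rc < 1 || cc < 1 || rc > nrow(mask) || cc > ncol(mask) || !mask[rc, cc])
    stop("center outside mask")

  nb <- round(2 * pi / dtheta)
  theta <- (seq_len(nb) - 0.5) * dtheta
  m <- mask * 1
  rmax <- sqrt((nrow(mask)^2 + ncol(mask)^2)) * pixel_size / 2 + pixel_size
  rstep <- pixel_size / 4
  rs <- seq(rstep, rmax, by = rstep)
  # sample the mask along all rays at once
  row <- (outer(rs, sin(theta)) + center[2]) / pixel_size + 0.5
  col <- (outer(rs, cos(theta)) + center[1]) / pixel_size + 0.5
  inside <- interp_bilinear(m, as.vector(row), as.vector(col))
  inside[is.na(inside)] <- 0
  inside <- matrix(inside >= 0.5, length(rs), nb)

  radius <- rep(NA_real_, nb)
  for (b in seq_len(nb)) {
    v <- inside[, b]
    if (!v[1]) next
    ex <- which(v[-length(v)] & !v[-1])        # inside -> outside crossings
    en <- which(!v[-length(v)] & v[-1])        # outside -> inside
    if (length(ex) == 0) next
    if (length(ex) == 1) {
      radius[b] <- rs[ex[1]] + rstep / 2       # outermost crossing
    } else {
      # longest inside segment: from 0 or the preceding entry to each exit
      starts <- c(0, rs[en])
      lens <- vapply(seq_along(ex), function(i) {
        s <- starts[max(which(starts < rs[ex[i]]))]
        rs[ex[i]] - s
      }, numeric(1))
      radius[b] <- rs[ex[which.max(lens)]] + rstep / 2
    }
  }
  empty <- is.na(radius)
  if (mean(empty) > max_empty_frac)
    stop(sprintf("trace rejected: %.0f%% of angular bins empty", 100 * mean(empty)))
  if (any(empty)) {   # circular linear interpolation
    good <- which(!empty)
    xi <- c(theta[good] - 2 * pi, theta[good], theta[good] + 2 * pi)
    yi <- rep(radius[good], 3)
    radius[empty] <- stats::approx(xi, yi, xout = theta[empty])$y
  }
  list(theta = theta, radius = radius, center = center)
}

#' Per-frame cluster trace in polar coordinates
#'
#' Bundles the per-frame masks, centers of mass and radial profiles
#' R(theta, t) of one isolated cluster, the container consumed by the
#' radius-change, leading-edge-velocity and line-tension analyses.
#'
#' @param masks list of per-frame logical masks (one cluster), or a matrix
#'   `radius` (frames x angles) if the profile is already known.
#' @param pixel_size nm per pixel.
#' @param frame_interval frame interval, s.
#' @param dtheta angular step, radians.
#' @param theta angle grid (required when `masks` is a radius matrix).
#'
#' @return Object of class `cluster_trace`: `radius` (frames x angles,
#'   nm), `theta`, `centers` (frames x 2, nm), `pixel_size`,
#'   `frame_interval`, `masks` (or NULL).
#' @export
cluster_trace <- function(masks, pixel_size = 1, frame_interval = 1,
                          dtheta = 2 * pi / 180, theta = NULL) {
  if (is.matrix(masks) && is.numeric(masks)) {
    if (is.null(theta)) stop("theta required when passing a radius matrix")
    stopifnot(ncol(masks) == length(theta))
    if (any(masks <= 0)) stop("R(theta, t) must be > 0 everywhere")
    return(structure(list(radius = masks, theta = theta, centers = NULL,
                          pixel_size = pixel_size,
                          frame_interval = frame_interval, masks = NULL),
                     class = "cluster_trace"))
  }
  stopifnot(is.list(masks), length(masks) >= 1)
  profs <- lapply(masks, radial_profile, dtheta = dtheta,
                  pixel_size = pixel_size)
  radius <- do.call(rbind, lapply(profs, `[[`, "radius"))
  centers <- do.call(rbind, lapply(profs, `[[`, "center"))
  structure(list(radius = radius, theta = profs[[1]]$theta, centers = centers,
                 pixel_size = pixel_size, frame_interval = frame_interval,
                 masks = masks),
            class = "cluster_trace")
}

#' @export
print.cluster_trace <- function(x, ...) {
  cat(sprintf("cluster_trace: %d frames x %d angular bins, r0 = %.2f nm\n",
              nrow(x$radius), ncol(x$radius), mean(x$radius)))
  invisible(x)
}

#' Radius change between consecutive frames
#'
#' \deqn{\Delta R(\theta, t) = R(\theta, t + \delta t) - R(\theta, t)}
#' Positive values at an angle signify local extension of the cluster
#' boundary, negative values retraction.
#'
#' @param trace a [cluster_trace()] with >= 2 frames.
#' @return Matrix (frames-1) x angles of radius changes, nm.
#' @export
radius_change <- function(trace) {
  stopifnot(inherits(trace, "cluster_trace"))
  if (nrow(trace$radius) < 2) stop("need >= 2 frames")
  diff(trace$radius)
}

#' Mean leading-edge velocity of a cluster boundary
#'
#' The time- and angle-averaged absolute boundary displacement rate,
#' \deqn{\mu_v = \frac{1}{N_t}\sum_t \frac{\delta\theta}{2\pi}
#'       \sum_\theta \frac{|R(\theta,t+\delta t) - R(\theta,t)|}{\delta t}}
#' i.e. the mean |Delta R| per frame interval, averaged over all angular
#' bins and frame pairs. Always >= 0, and 0 exactly when all radial
#' profiles are identical.
#'
#' @param trace a [cluster_trace()] with >= 2 frames.
#' @return Mean leading-edge velocity in nm/s.
#' @export
mean_leading_edge_velocity <- function(trace) {
  stopifnot(inherits(trace, "cluster_trace"))
  if (nrow(trace$radius) < 2) stop("need >= 2 frames")
  dr <- abs(radius_change(trace))
  mean(rowMeans(dr)) / trace$frame_interval
}

#' Line tension from boundary-fluctuation Fourier modes
#'
#' Capillary-wave spectroscopy of the cluster boundary. Each frame's
#' normalized radial profile R(theta, t) / r0 (r0 = time- and angle-mean
#' radius) is expanded in a Fourier series; the per-mode mean squared
#' amplitude over frames follows equipartition
#' \deqn{\langle a_k^2 + b_k^2 \rangle =
#'       \frac{2 k_B T}{\pi \lambda r_0 (k^2 - 1)}, \quad k \ge 2,}
#' so a linear regression of the measured \eqn{\langle a_k^2+b_k^2\rangle}
#' against \eqn{2/(\pi r_0 (k^2-1))} through the origin has slope
#' \eqn{1/\lambda} (lambda in kB*T/nm). Mode k = 1 is a pure translation
#' and is excluded; k = 0 is absorbed in r0.
#'
#' @param trace a [cluster_trace()]; >= 50 frames recommended.
#' @param kmax highest mode analyzed (default 12).
#' @param normalization `"instantaneous"` (default) expands
#'   R(theta, t)/r0; `"difference"` expands the frame-difference ratio
#'   (R(t+dt) - R(t))/R(t) instead (alternative normalization, different
#'   absolute scale).
#' @param robust also report a rank-based (Theil-Sen style) slope
#'   alongside the least-squares fit (default `TRUE`).
#'
#' @return Object of class `tension_fit`: `lambda` (kB*T/nm), `r0` (nm),
#'   `k` (modes), `mode_power` (per-mode mean a_k^2 + b_k^2), `predictor`
#'   (the equipartition abscissa), `slope`, `lambda_robust`, `r_squared`,
#'   `loglog_slope` (power vs. k^2 - 1), `n_frames`, `normalization`.
#' @export
fit_line_tension <- function(trace, kmax = 12L,
                             normalization = c("instantaneous", "difference"),
                             robust = TRUE) {
  stopifnot(inherits(trace, "cluster_trace"))
  normalization <- match.arg(normalization)
  R <- trace$radius
  theta <- trace$theta
  nth <- length(theta)
  nfr <- nrow(R)
  if (nfr < 2) stop("need >= 2 frames")
  kmax <- as.integer(kmax)
  stopifnot(kmax >= 2, 2 * kmax < nth)

  r0 <- mean(R)
  if (normalization == "instantaneous") {
    Rp <- R / r0
  } else {
    Rp <- (R[-1, , drop = FALSE] - R[-nfr, , drop = FALSE]) / R[-nfr, , drop = FALSE]
  }
  ks <- 2:kmax
  # discrete Fourier coefficients on the uniform angle grid
  ca <- cos(outer(theta, ks))   # angles x modes
  sa <- sin(outer(theta, ks))
  A <- (2 / nth) * Rp %*% ca    # frames x modes
  B <- (2 / nth) * Rp %*% sa
  power <- colMeans(A^2 + B^2)

  if (all(power <= 1e-24)) {   # numerically zero fluctuation
    return(structure(list(lambda = Inf, r0 = r0, k = ks, mode_power = power,
                          predictor = 2 / (pi * r0 * (ks^2 - 1)),
                          slope = 0, lambda_robust = Inf, r_squared = NA_real_,
                          loglog_slope = NA_real_, n_frames = nfr,
                          normalization = normalization,
                          infinite_tension = TRUE),
                     class = "tension_fit"))
  }

  x <- 2 / (pi * r0 * (ks^2 - 1))   # kB*T = 1 in these units
  slope <- sum(x * power) / sum(x^2)          # regression through origin
  if (slope <= 0) stop("fit failure: non-positive slope in equipartition regression")
  lambda <- 1 / slope
  ss_res <- sum((power - slope * x)^2)
  ss_tot <- sum(power^2)
  r2 <- 1 - ss_res / ss_tot
  lam_rob <- if (robust) 1 / stats::median(power / x) else NA_real_
  ll <- stats::lm(log(power) ~ log(ks^2 - 1))
  structure(list(lambda = lambda, r0 = r0, k = ks, mode_power = power,
                 predictor = x, slope = slope, lambda_robust = lam_rob,
                 r_squared = r2,
                 loglog_slope = unname(stats::coef(ll)[2]),
                 n_frames = nfr, normalization = normalization,
                 infinite_tension = FALSE),
            class = "tension_fit")
}

#' @export
print.tension_fit <- function(x, ...) {
  if (isTRUE(x$infinite_tension)) {
    cat("tension_fit: zero boundary fluctuation (infinite line tension)\n")
    return(invisible(x))
  }
  cat(sprintf(
    "tension_fit: lambda = %.3g kB*T/nm (robust %.3g), r0 = %.2f nm, k = %d..%d, R^2 = %.3f, %d frames\n",
    x$lambda, x$lambda_robust, x$r0, min(x$k), max(x$k), x$r_squared,
    x$n_frames))
  invisible(x)
}

#' Reconstruct a contour from its Fourier description
#'
#' Synthesizes the contour R(theta) = r0 * (1 + sum over modes of
#' a_k cos(k theta) + b_k sin(k theta)); used for round-trip checks of
#' the mode decomposition.
#'
#' @param theta angle grid, radians.
#' @param r0 mean radius, nm.
#' @param coef_a,coef_b named or ordered coefficient vectors for modes
#'   `k`.
#' @param k integer mode numbers matching the coefficients.
#' @return Radius vector over `theta`, nm.
#' @export
synthesize_contour <- function(theta, r0, coef_a, coef_b, k) {
  stopifnot(length(coef_a) == length(k), length(coef_b) == length(k))
  r0 * (1 + as.vector(cos(outer(theta, k)) %*% coef_a) +
          as.vector(sin(outer(theta, k)) %*% coef_b))
}
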
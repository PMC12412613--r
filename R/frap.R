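# FRAP analysis: trace normalization, effective bleach radius from the
# post-bleach profile, recovery half-time, diffusion coefficient.

# ROI mean over a disk (center in px, radius in px)
#' @keywords internal
#' @noRd
roi_mean <- function(frame, center_px, radius_px) {
  nr <- nrow(frame); nc <- ncol(frame)
  R2 <- outer((seq_len(nr) - center_px[1])^2, (seq_len(nc) - center_px[2])^2, `+`)
  mean(frame[R2 <= radius_px^2])
}

#' Extract the bleach-ROI recovery trace from a FRAP image series
#'
#' Per-frame mean intensity inside the bleach ROI disk.
#'
#' @param series a `frap_sim` (or list with `frames`, `times`, `center`
#'   in px, `pixel_size` um/px, `rn` um).
#' @return Data frame: `time` (s), `intensity` (raw ROI mean).
#' @export
frap_trace <- function(series) {
  rpx <- series$rn / series$pixel_size
  data.frame(
    time = series$times,
    intensity = vapply(series$frames, roi_mean, numeric(1),
                       center_px = series$center, radius_px = rpx))
}

#' Normalize a FRAP trace to the pre-bleach level
#'
#' Divides the trace by the mean pre-bleach intensity, optionally
#' correcting for observational photobleaching with a reference-region
#' trace (off by default). Idempotent on already-normalized traces.
#'
#' @param raw numeric vector of ROI mean intensities.
#' @param prebleach logical vector (same length) marking pre-bleach
#'   frames, or the number of leading pre-bleach frames; >= 3 required.
#' @param reference optional reference-ROI trace for global-bleach
#'   correction: the trace is divided by `reference / mean(prebleach
#'   reference)`.
#' @return Normalized trace (pre-bleach mean = 1).
#' @export
normalize_trace <- function(raw, prebleach, reference = NULL) {
  if (is.numeric(prebleach) && length(prebleach) == 1)
    prebleach <- seq_along(raw) <= prebleach
  stopifnot(length(prebleach) == length(raw))
  if (sum(prebleach) < 3) stop("need >= 3 pre-bleach frames")
  if (!is.null(reference)) {
    refn <- reference / mean(reference[prebleach])
    raw <- raw / refn
  }
  pb <- mean(raw[prebleach])
  if (pb == 0) stop("zero pre-bleach mean")
  raw / pb
}

#' Effective bleach radius from the first post-bleach profile
#'
#' Radially averages the normalized first post-bleach frame about the ROI
#' center and fits
#' \deqn{f(x) = 1 - K e^{-2 x^2 / r_e^2}}
#' the Gaussian bleach-profile model; `re` is the effective radius that
#' accounts for diffusion during the bleach (always >= the nominal ROI
#' radius for a diffusively blurred profile).
#'
#' @param frame normalized post-bleach image.
#' @param center ROI center (row, col) in px.
#' @param pixel_size um per px.
#' @param r_max maximum radius for the profile, um (default: to the
#'   nearest field edge).
#' @return A list: `re` (um), `K` (bleach depth), `profile` (data frame
#'   x, f).
#' @export
effective_radius <- function(frame, center, pixel_size, r_max = NULL) {
  nr <- nrow(frame); nc <- ncol(frame)
  if (is.null(r_max))
    r_max <- (min(center[1], center[2], nr - center[1], nc - center[2]) - 1) *
      pixel_size
  R <- sqrt(outer((seq_len(nr) - center[1])^2,
                  (seq_len(nc) - center[2])^2, `+`)) * pixel_size
  bins <- seq(0, r_max, by = pixel_size)
  bi <- findInterval(R, bins)
  ok <- R <= r_max
  f <- tapply(frame[ok], bi[ok], mean)
  x <- (bins[as.integer(names(f))] + pixel_size / 2)
  prof <- data.frame(x = x, f = as.numeric(f))
  fit <- tryCatch(
    stats::nls(f ~ 1 - K * exp(-2 * x^2 / re^2), data = prof,
               start = list(K = max(0.1, 1 - min(prof$f)),
                            re = max(x[which(prof$f < 1 - (1 - min(prof$f)) / 2)],
                                     pixel_size))),
    error = function(e) NULL)
  if (is.null(fit)) {
    stop(paste0("effective-radius fit diverged; profile head: ",
                paste(sprintf("%.3f", utils::head(prof$f, 8)), collapse = ", ")))
  }
  cf <- stats::coef(fit)
  list(re = abs(unname(cf["re"])), K = unname(cf["K"]), profile = prof)
}

#' Half-time of post-bleach recovery
#'
#' Fits the normalized post-bleach trace with a single-exponential
#' recovery \deqn{F(t) = F_\infty - (F_\infty - F_0) e^{-t \ln 2 / \tau_{1/2}}}
#' and returns the half-time with a confidence interval. A linear
#' interpolation of the half-recovery crossing is available as an
#' alternative method for densely sampled traces.
#'
#' @param trace normalized intensities (post-bleach portion, first element
#'   = bleach frame at t = 0).
#' @param times frame times (s), same length, starting at 0.
#' @param method `"exponential"` (default) or `"interpolation"`.
#' @param f0 fixed bleach floor; default: the first trace value.
#' @return A list: `tau_half` (s), `f0`, `f_inf`, `ci` (95% interval or
#'   NA), `method`, plus `flagged` when the recovery is faster than the
#'   first sampling interval.
#' @export
half_time <- function(trace, times, method = c("exponential", "interpolation"),
                      f0 = NULL) {
  method <- match.arg(method)
  stopifnot(length(trace) == length(times), times[1] == 0)
  if (is.null(f0)) f0 <- trace[1]
  plateau <- mean(utils::tail(trace, 3))
  if (plateau - f0 <= 0.02)
    stop("no recovery within the series")
  half_level <- f0 + (plateau - f0) / 2
  if (trace[2] >= plateau - 0.02 * (plateau - f0)) {
    # recovery complete within the first post-bleach interval
    return(list(tau_half = times[2] / 2, f0 = f0, f_inf = plateau,
                ci = c(NA_real_, NA_real_), method = method, flagged = TRUE))
  }
  if (method == "interpolation") {
    above <- which(trace >= half_level)
    i <- above[above > 1][1]
    t_half <- stats::approx(trace[(i - 1):i], times[(i - 1):i],
                            xout = half_level)$y
    return(list(tau_half = t_half, f0 = f0, f_inf = plateau,
                ci = c(NA_real_, NA_real_), method = method, flagged = FALSE))
  }
  df <- data.frame(t = times, y = trace)
  start <- list(finf = plateau,
                tau = max(times[which(trace >= half_level)[1]],
                          times[2]) / 2)
  fit <- tryCatch(
    stats::nls(y ~ finf - (finf - f0) * exp(-t * log(2) / tau), data = df,
               start = start),
    error = function(e) NULL)
  if (!is.null(fit)) {
    cf <- stats::coef(fit)
    ci <- tryCatch(suppressMessages(stats::confint(fit, "tau", level = 0.95)),
                   error = function(e) c(NA_real_, NA_real_))
  } else {
    # nls fails on (near-)zero residuals; direct least squares fallback
    ss <- function(p) sum((df$y - (p[1] - (p[1] - f0) *
                                     exp(-df$t * log(2) / p[2])))^2)
    op <- stats::optim(c(start$finf, start$tau), ss)
    cf <- c(finf = op$par[1], tau = op$par[2])
    ci <- c(NA_real_, NA_real_)
  }
  if (cf[["tau"]] <= 0) stop("non-positive fitted half-time")
  list(tau_half = unname(cf["tau"]), f0 = f0, f_inf = unname(cf["finf"]),
       ci = as.numeric(ci), method = method, flagged = FALSE)
}

#' Diffusion coefficient from FRAP geometry and half-time
#'
#' The standard-protocol formula
#' \deqn{D = \frac{r_e^2 + r_n^2}{8 \tau_{1/2}}}
#' with nominal bleach radius rn, effective radius re and recovery
#' half-time tau-1/2. The formula is configurable via `formula` should a
#' different protocol be preferred.
#'
#' @param re effective radius, um.
#' @param rn nominal ROI radius, um.
#' @param tau_half recovery half-time, s.
#' @param formula function(re, rn, tau_half) returning D; default the
#'   standard protocol above.
#' @return D in um^2/s.
#' @export
diffusion_coefficient <- function(re, rn, tau_half,
                                  formula = function(re, rn, tau_half)
                                    (re^2 + rn^2) / (8 * tau_half)) {
  if (re <= 0 || rn <= 0) stop("radii must be > 0")
  if (tau_half <= 0) stop("tau_half must be > 0")
  formula(re, rn, tau_half)
}

#' Full FRAP analysis of an image series
#'
#' Chains [frap_trace()], [normalize_trace()], [effective_radius()],
#' [half_time()] and [diffusion_coefficient()] on a FRAP series (simulated
#' or loaded), returning every intermediate quantity.
#'
#' @param series a `frap_sim`-style list: `frames`, `times` (s, pre-bleach
#'   < 0, first post-bleach frame at 0), `center` (px), `pixel_size`
#'   (um/px), `rn` (um).
#' @param method half-time method, see [half_time()].
#' @return A list of class `frap_fit`: `rn`, `re`, `tau_half`, `D`
#'   (um^2/s), `trace` (normalized data frame), `profile`.
#' @export
analyze_frap <- function(series, method = "exponential") {
  tr <- frap_trace(series)
  pre <- series$times < 0
  if (sum(pre) < 3) stop("need >= 3 pre-bleach frames")
  norm <- normalize_trace(tr$intensity, pre)
  post <- !pre
  ipost1 <- which(post)[1]
  er <- effective_radius(series$frames[[ipost1]] / mean(tr$intensity[pre]),
                         series$center, series$pixel_size)
  ht <- half_time(norm[post], series$times[post], method = method)
  D <- diffusion_coefficient(er$re, series$rn, ht$tau_half)
  structure(list(rn = series$rn, re = er$re, tau_half = ht$tau_half, D = D,
                 bleach_depth = er$K, f0 = ht$f0, f_inf = ht$f_inf,
                 flagged = ht$flagged,
                 trace = data.frame(time = tr$time, intensity = norm),
                 profile = er$profile),
            class = "frap_fit")
}

#' @export
print.frap_fit <- function(x, ...) {
  cat(sprintf("frap_fit: rn = %.2f um, re = %.2f um, tau1/2 = %.2f s, D = %.3g um^2/s\n",
              x$rn, x$re, x$tau_half, x$D))
  invisible(x)
}
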
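# Internal image-matrix utilities.
#
# Convention: a frame is a numeric matrix indexed [row, col]; physical
# coordinates are x = (col - 0.5) * pixel_size, y = (row - 0.5) * pixel_size,
# i.e. x runs along columns and y along rows. All internal angles are
# atan2(dy, dx) in this frame.

#' @keywords internal
#' @noRd
mat_shift <- function(m, dy, dx, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  src_r <- seq_len(nr) - dy
  src_c <- seq_len(nc) - dx
  ok_r <- src_r >= 1 & src_r <= nr
  ok_c <- src_c >= 1 & src_c <= nc
  out[ok_r, ok_c] <- m[src_r[ok_r], src_c[ok_c]]
  out
}

# 4-connected component labelling by iterative min-label propagation.
# Returns an integer matrix, 0 = background, components numbered 1..n
# (renumbered in raster order of first pixel).
#' @keywords internal
#' @noRd
label_components <- function(mask) {
  stopifnot(is.matrix(mask))
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  idx <- which(mask)
  if (length(idx) == 0L) return(lab)
  lab <- matrix(0, nr, nc)
  lab[idx] <- seq_along(idx)
  repeat {
    labp <- lab
    labp[!mask] <- Inf   # background never donates a label
    up    <- mat_shift(labp,  1L, 0L, fill = Inf)
    down  <- mat_shift(labp, -1L, 0L, fill = Inf)
    left  <- mat_shift(labp, 0L,  1L, fill = Inf)
    right <- mat_shift(labp, 0L, -1L, fill = Inf)
    nb <- pmin(up, down, left, right)
    new <- lab
    take <- mask & nb < lab
    new[take] <- nb[take]
    if (all(new == lab)) break
    lab <- new
  }
  # renumber compactly
  ids <- sort(unique(lab[lab > 0]))
  out <- matrix(0L, nr, nc)
  for (i in seq_along(ids)) out[lab == ids[i]] <- i
  out
}

# Fill enclosed background ("gap pixels"): background connected to the image
# border stays background, every other background pixel becomes foreground.
#' @keywords internal
#' @noRd
fill_holes <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  bg <- !mask
  reach <- matrix(FALSE, nr, nc)
  reach[1, ] <- bg[1, ]; reach[nr, ] <- bg[nr, ]
  reach[, 1] <- bg[, 1]; reach[, nc] <- bg[, nc]
  repeat {
    grown <- reach |
      mat_shift(reach,  1L, 0L, fill = FALSE) |
      mat_shift(reach, -1L, 0L, fill = FALSE) |
      mat_shift(reach, 0L,  1L, fill = FALSE) |
      mat_shift(reach, 0L, -1L, fill = FALSE)
    grown <- grown & bg
    if (all(grown == reach)) break
    reach <- grown
  }
  mask | (bg & !reach)
}

# Boundary pixels of a binary mask: foreground with at least one 4-neighbour
# outside the mask (image border counts as outside).
#' @keywords internal
#' @noRd
boundary_mask <- function(mask) {
  inner <- mask &
    mat_shift(mask,  1L, 0L, fill = FALSE) &
    mat_shift(mask, -1L, 0L, fill = FALSE) &
    mat_shift(mask, 0L,  1L, fill = FALSE) &
    mat_shift(mask, 0L, -1L, fill = FALSE)
  mask & !inner
}

# Translation between two equally sized frames by FFT cross-correlation,
# with parabolic sub-pixel refinement of the correlation peak.
# Returns c(dy, dx): the shift to apply to `b` so it best matches `a`.
#' @keywords internal
#' @noRd
xcorr_shift <- function(a, b) {
  stopifnot(all(dim(a) == dim(b)))
  nr <- nrow(a); nc <- ncol(a)
  a0 <- a - mean(a); b0 <- b - mean(b)
  if (sd(a0) == 0 || sd(b0) == 0) {
    warning("flat image: correlation peak ambiguous, assuming zero shift")
    return(c(dy = 0, dx = 0))
  }
  cc <- Re(stats::fft(stats::fft(a0) * Conj(stats::fft(b0)), inverse = TRUE))
  pk <- which(cc == max(cc), arr.ind = TRUE)[1, ]
  # parabolic refinement along each axis (periodic indexing)
  wrap <- function(i, n) ((i - 1) %% n) + 1
  py <- pk[1]; px <- pk[2]
  refine <- function(cm, c0, cp) {
    den <- cm - 2 * c0 + cp
    if (den == 0) return(0)
    d <- 0.5 * (cm - cp) / den
    max(min(d, 0.5), -0.5)
  }
  dy <- refine(cc[wrap(py - 1, nr), px], cc[py, px], cc[wrap(py + 1, nr), px])
  dx <- refine(cc[py, wrap(px - 1, nc)], cc[py, px], cc[py, wrap(px + 1, nc)])
  sy <- (py - 1) + dy; sx <- (px - 1) + dx
  if (sy > nr / 2) sy <- sy - nr
  if (sx > nc / 2) sx <- sx - nc
  out <- c(dy = sy, dx = sx)
  out[abs(out) < 1e-9] <- 0
  out
}

# Bilinear interpolation of matrix m at fractional (row, col) positions.
# Out-of-range positions return NA.
#' @keywords internal
#' @noRd
interp_bilinear <- function(m, row, col) {
  nr <- nrow(m); nc <- ncol(m)
  r0 <- floor(row); c0 <- floor(col)
  fr <- row - r0; fc <- col - c0
  ok <- r0 >= 1 & c0 >= 1 & r0 <= nr - 1 & c0 <= nc - 1
  # clamp exact upper edge
  edge <- row >= 1 & col >= 1 & row <= nr & col <= nc & !ok
  out <- rep(NA_real_, length(row))
  if (any(ok)) {
    i00 <- cbind(r0[ok], c0[ok]); i01 <- cbind(r0[ok], c0[ok] + 1)
    i10 <- cbind(r0[ok] + 1, c0[ok]); i11 <- cbind(r0[ok] + 1, c0[ok] + 1)
    out[ok] <- m[i00] * (1 - fr[ok]) * (1 - fc[ok]) +
      m[i01] * (1 - fr[ok]) * fc[ok] +
      m[i10] * fr[ok] * (1 - fc[ok]) +
      m[i11] * fr[ok] * fc[ok]
  }
  if (any(edge)) {
    out[edge] <- m[cbind(pmin(pmax(round(row[edge]), 1), nr),
                         pmin(pmax(round(col[edge]), 1), nc))]
  }
  out
}

# Gaussian blur by FFT multiplication (periodic boundary). sigma in pixels;
# sigma = 0 returns the input unchanged.
#' @keywords internal
#' @noRd
gaussian_blur_fft <- function(m, sigma) {
  if (sigma <= 0) return(m)
  nr <- nrow(m); nc <- ncol(m)
  ky <- c(0:(nr %/% 2), -((nr - nr %/% 2 - 1):1)) / nr
  kx <- c(0:(nc %/% 2), -((nc - nc %/% 2 - 1):1)) / nc
  if (nr %% 2 == 0) ky <- c(0:(nr / 2 - 1), -(nr / 2):-1) / nr
  if (nc %% 2 == 0) kx <- c(0:(nc / 2 - 1), -(nc / 2):-1) / nc
  mtf <- exp(-2 * pi^2 * sigma^2 * outer(ky^2, kx^2, `+`))
  Re(stats::fft(stats::fft(m) * mtf, inverse = TRUE)) / (nr * nc)
}

# Wrap angle (degrees) to (-180, 180].
#' @keywords internal
#' @noRd
wrap_deg <- function(a) {
  w <- (a + 180) %% 360 - 180
  w[w == -180] <- 180
  w
}
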
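# shared fixtures, all generated in code

# coordinate grids in nm for an n x n frame
grids <- function(n, pixel_size) {
  xs <- (seq_len(n) - 0.5) * pixel_size
  list(X = matrix(xs, n, n, byrow = TRUE), Y = matrix(xs, n, n))
}

# render one particle on a flat base and return frame + truth
render_one <- function(orientation, tilt = 0, tilt_axis = 0, nf = 5L,
                       n = 64L, pixel_size = 0.5, center = c(16, 16),
                       particle_radius = 3.5, protomer_height = 1.2,
                       base = 5, noise_sd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  g <- grids(n, pixel_size)
  fr <- base + particle_field(g$X, g$Y, matrix(center, 1, 2), nf = nf,
                              orientations = orientation, tilts = tilt,
                              tilt_axes = tilt_axis,
                              particle_radius = particle_radius,
                              protomer_height = protomer_height)
  if (noise_sd > 0) fr <- fr + matrix(stats::rnorm(n * n, 0, noise_sd), n, n)
  list(frame = fr, center = center, orientation = orientation, tilt = tilt,
       nf = nf, particle_radius = particle_radius, pixel_size = pixel_size)
}

# minimal particle object with prescribed protomer orientation (degrees)
stub_particle <- function(cx, cy, nf, orientation) {
  structure(list(center = c(cx, cy), nf = as.integer(nf),
                 protomers = data.frame(
                   angle_deg = (orientation + (0:(nf - 1)) * 360 / nf) %% 360),
                 ring_radius = 3.5),
            class = "particle")
}

# binary disk mask
disk_mask <- function(n, cx, cy, r) {
  xs <- seq_len(n) - 0.5
  X <- matrix(xs, n, n, byrow = TRUE); Y <- matrix(xs, n, n)
  (X - cx)^2 + (Y - cy)^2 <= r^2
}
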
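test_that("radial_profile matches closed-form shapes", {
  n <- 100
  # perfect disk radius 20 at the centroid
  rp <- radial_profile(disk_mask(n, 50, 50, 20), pixel_size = 1)
  expect_true(all(abs(rp$radius - 20) <= 0.5))

  # ellipse a = 30, b = 15: polar radius within 1 px
  xs <- seq_len(n) - 0.5
  X <- matrix(xs, n, n, byrow = TRUE); Y <- matrix(xs, n, n)
  ell <- ((X - 50) / 30)^2 + ((Y - 50) / 15)^2 <= 1
  rp2 <- radial_profile(ell, pixel_size = 1)
  rtrue <- 30 * 15 / sqrt((15 * cos(rp2$theta))^2 + (30 * sin(rp2$theta))^2)
  expect_lt(max(abs(rp2$radius - rtrue)), 1)

  # square: diagonal maxima ~ sqrt(2) x edge minima
  sq <- abs(X - 50) <= 15 & abs(Y - 50) <= 15
  rp3 <- radial_profile(sq, pixel_size = 1)
  expect_equal(max(rp3$radius) / min(rp3$radius), sqrt(2), tolerance = 0.05)

  # center outside the mask errors
  expect_error(radial_profile(disk_mask(n, 50, 50, 10), center = c(5, 5)),
               "outside")
})

test_that("radius_change and leading-edge velocity against brute-force oracles", {
  set.seed(9)
  theta <- seq(0, 2 * pi, length.out = 181)[-181]
  R <- matrix(15 + rnorm(50 * 180, 0, 0.5), 50, 180)
  tr <- cluster_trace(R, theta = theta, frame_interval = 0.5)

  # elementwise-difference oracle
  dr <- radius_change(tr)
  oracle <- R[2:50, ] - R[1:49, ]
  expect_identical(dr, oracle)

  # brute-force double sum for mu_v
  s <- 0
  for (t in 1:49) for (b in 1:180) s <- s + abs(R[t + 1, b] - R[t, b])
  muv_oracle <- s / (49 * 180 * 0.5)
  expect_equal(mean_leading_edge_velocity(tr), muv_oracle, tolerance = 1e-12)

  # static trace: mu_v = 0; uniform growth 1 nm/frame at dt = 1 s: 1 nm/s
  Rs <- matrix(15, 10, 180)
  expect_identical(
    mean_leading_edge_velocity(cluster_trace(Rs, theta = theta,
                                             frame_interval = 1)), 0)
  Rg <- outer(0:9, rep(1, 180)) + 15
  expect_equal(
    mean_leading_edge_velocity(cluster_trace(Rg, theta = theta,
                                             frame_interval = 1)), 1)

  # mu_v = 0 iff all radial profiles identical
  expect_gt(mean_leading_edge_velocity(tr), 0)
  expect_error(mean_leading_edge_velocity(
    cluster_trace(Rs[1, , drop = FALSE], theta = theta)), "2 frames")
})

test_that("fit_line_tension recovers the generator tension in closed loop", {
  spec <- movie_spec(line_tension = 100, cluster_r0 = 15, n_modes = 12,
                     n_frames = 500)
  b <- sample_boundary(spec, seed = 21)
  tr <- cluster_trace(b$radius, theta = b$theta, frame_interval = 0.5)
  tf <- fit_line_tension(tr, kmax = 12)
  expect_gt(tf$lambda, 80); expect_lt(tf$lambda, 120)

  # variance spectrum ~ 1/(k^2 - 1): log-log slope -1 +- 0.1
  expect_equal(tf$loglog_slope, -1, tolerance = 0.1)

  # doubling lambda halves every mode variance -> fitted lambda doubles
  spec2 <- movie_spec(line_tension = 200, cluster_r0 = 15, n_modes = 12,
                      n_frames = 500)
  b2 <- sample_boundary(spec2, seed = 21)
  tf2 <- fit_line_tension(cluster_trace(b2$radius, theta = b2$theta,
                                        frame_interval = 0.5), kmax = 12)
  expect_equal(tf2$lambda / tf$lambda, 2, tolerance = 0.15)

  # zero fluctuation: infinite-tension flag
  flat <- cluster_trace(matrix(15, 30, length(b$theta)), theta = b$theta)
  tfi <- fit_line_tension(flat)
  expect_true(tfi$infinite_tension)
  expect_identical(tfi$lambda, Inf)
})

test_that("Fourier round-trip reproduces contours to < 1% RMS", {
  spec <- movie_spec(line_tension = 20, cluster_r0 = 15, n_modes = 12,
                     n_frames = 20)
  b <- sample_boundary(spec, seed = 13)
  for (f in c(1, 7, 20)) {
    rec <- synthesize_contour(b$theta, b$r0, b$coef_a[f, ], b$coef_b[f, ],
                              k = 2:12)
    rms <- sqrt(mean((rec - b$radius[f, ])^2)) / b$r0
    expect_lt(rms, 0.01)
  }

  # and the estimator's coefficients reconstruct the normalized profile:
  tr <- cluster_trace(b$radius, theta = b$theta)
  R <- b$radius / mean(b$radius)
  nth <- length(b$theta)
  ks <- 2:12
  A <- (2 / nth) * R %*% cos(outer(b$theta, ks))
  B <- (2 / nth) * R %*% sin(outer(b$theta, ks))
  rec <- 1 + cos(outer(b$theta, ks)) %*% A[1, ] + sin(outer(b$theta, ks)) %*% B[1, ]
  expect_lt(sqrt(mean((rec - R[1, ])^2)), 0.01)
})

test_that("mu_v is invariant under rigid translation of mask frames", {
  set.seed(14)
  n <- 80
  masks <- lapply(1:6, function(i) disk_mask(n, 40, 40, 12 + rnorm(1, 0, 0.8)))
  tr0 <- cluster_trace(masks, pixel_size = 1, frame_interval = 1)
  shifted <- lapply(seq_along(masks), function(i)
    memclust:::mat_shift(masks[[i]], i %% 3, (i * 2) %% 5, fill = FALSE))
  tr1 <- cluster_trace(shifted, pixel_size = 1, frame_interval = 1)
  expect_equal(mean_leading_edge_velocity(tr1),
               mean_leading_edge_velocity(tr0), tolerance = 0.02)
})
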
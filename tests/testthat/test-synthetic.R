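test_that("sample_boundary draws the equipartition spectrum", {
  spec <- movie_spec(line_tension = 100, cluster_r0 = 15, n_modes = 12,
                     n_frames = 500)
  b <- sample_boundary(spec, seed = 7)
  ks <- 2:12
  vk <- capillary_mode_variance(ks, 100, 15)

  # per-mode sample variance within 15% of the generating formula
  va <- apply(b$coef_a, 2, var)
  vb <- apply(b$coef_b, 2, var)
  expect_true(all(abs(va / vk - 1) < 0.15))
  expect_true(all(abs(vb / vk - 1) < 0.15))

  # chi-square test at the 1% level per mode (n = 500 draws)
  n <- nrow(b$coef_a)
  stat <- (n - 1) * va / vk
  lo <- qchisq(0.005, n - 1); hi <- qchisq(0.995, n - 1)
  expect_true(all(stat > lo & stat < hi))

  # contours strictly positive, correct shape
  expect_true(all(b$radius > 0))
  expect_identical(dim(b$radius), c(500L, length(b$theta)))
})

test_that("mode k = 1 is never present in the generated spectrum", {
  spec <- movie_spec(line_tension = 50, cluster_r0 = 15, n_frames = 200)
  b <- sample_boundary(spec, seed = 3)
  expect_false("1" %in% colnames(b$coef_a))
  # project the realized contours on the k = 1 basis: zero up to rounding
  c1 <- (2 / length(b$theta)) * b$radius %*% cos(b$theta) / b$r0
  s1 <- (2 / length(b$theta)) * b$radius %*% sin(b$theta) / b$r0
  expect_lt(max(abs(c1), abs(s1)), 1e-12)
})

test_that("infinite line tension gives a perfect circle; invalid specs error", {
  spec <- movie_spec(line_tension = 1e12, cluster_r0 = 15, n_frames = 10)
  b <- sample_boundary(spec, seed = 1)
  expect_lt(max(abs(b$radius - 15)), 1e-4)

  expect_error(movie_spec(line_tension = -5), "line_tension")
  expect_error(movie_spec(line_tension = 0), "line_tension")
  expect_error(movie_spec(cluster_r0 = 0), "cluster_r0")
  expect_error(movie_spec(n_modes = 1), "n_modes")
  expect_error(movie_spec(n_frames = 1), "n_frames")
  expect_error(movie_spec(pixel_size = 0), "pixel_size")
})

test_that("render_movie: flat particle heights, ground truth, determinism", {
  # noise-free untilted particle: all protomer peaks equal within tolerance
  spec <- movie_spec(n_particles = 1, noise_sd = 0, edge_tilt_deg = 0,
                     n_frames = 2, cluster_r0 = 12, image_size = 80, seed = 5)
  sim <- render_movie(spec)
  fr <- sim$movie$frames[[1]]
  ctr <- sim$truth$centers[1, ]
  ang <- sim$truth$protomer_angles[[1]] * pi / 180
  x <- ctr[1] + spec$particle_radius * cos(ang)
  y <- ctr[2] + spec$particle_radius * sin(ang)
  pk <- memclust:::interp_bilinear(fr, y / 0.5 + 0.5, x / 0.5 + 0.5)
  expect_lt(max(pk) - min(pk), 0.05)

  # n_particles = 0: membrane + empty fluctuating boundary only
  spec0 <- movie_spec(n_particles = 0, noise_sd = 0, n_frames = 3, seed = 2)
  sim0 <- render_movie(spec0)
  expect_setequal(unique(round(as.vector(sim0$movie$frames[[1]]), 6)),
                  round(c(spec0$membrane_height,
                          spec0$membrane_height + spec0$cluster_height), 6))

  # fixed seed => bit-identical movie
  sim_a <- render_movie(movie_spec(n_frames = 3, n_particles = 4, seed = 11))
  sim_b <- render_movie(movie_spec(n_frames = 3, n_particles = 4, seed = 11))
  expect_identical(sim_a$movie$frames, sim_b$movie$frames)
  expect_identical(sim_a$truth$tilts, sim_b$truth$tilts)

  # ground-truth packing fraction equals the packing formula on true counts
  f <- packing_fraction(0, spec$n_particles, sim$truth$area_cluster)
  expect_identical(as.numeric(f), sim$truth$packing_fraction)
})

test_that("rendered edge-particle tilt is recoverable by plane fit", {
  # put one particle at a known spot and force an edge tilt via the field
  one <- render_one(orientation = 13, tilt = 10, tilt_axis = 0)
  p <- refine_particle(one$frame, one$center, nf = 5, pixel_size = 0.5,
                       ring_radius = 3.5)
  expect_equal(p$tilt_deg, 10, tolerance = 1 / 10)
})

test_that("simulate_frap forward model behaves at its limits", {
  # bleach_depth = 0: constant trace at 1 after normalization
  s0 <- simulate_frap(D = 1, rn = 5, bleach_depth = 0,
                      times = c(-3, -2, -1, 0, 5, 10), seed = 1)
  tr <- frap_trace(s0)
  norm <- normalize_trace(tr$intensity, s0$times < 0)
  expect_lt(max(abs(norm - 1)), 1e-9)

  # very fast diffusion: recovery essentially complete at the first
  # post-bleach sampling point
  sfast <- simulate_frap(D = 500, rn = 2, bleach_depth = 0.9,
                         times = c(-3, -2, -1, 0, 5, 10, 15), seed = 1)
  trf <- frap_trace(sfast)
  nf_ <- normalize_trace(trf$intensity, sfast$times < 0)
  expect_gt(nf_[5], 0.95)   # t = 5 s frame

  # monotone recovery toward pre-bleach level
  s <- simulate_frap(D = 1.5, rn = 5, seed = 2)
  trs <- frap_trace(s)
  post <- trs$intensity[s$times >= 0]
  expect_true(all(diff(post) > -1e-6))
  expect_lt(post[1], 0.5)

  expect_error(simulate_frap(D = -1), "D")
  expect_error(simulate_frap(D = 1, times = c(-1, 0, 0, 5)), "increasing")
  expect_identical(s$true_D, 1.5)
})
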
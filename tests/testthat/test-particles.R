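test_that("refine_particle centers, isv and equivariance", {
  one <- render_one(orientation = 51.3, nf = 5)
  p <- refine_particle(one$frame, one$center + c(1, -0.7), nf = 5,
                       pixel_size = 0.5, ring_radius = 3.5)
  expect_lt(sqrt(sum((p$center - one$center)^2)), 0.25)  # within 0.5 px
  expect_gt(p$isv, 0.99)
  expect_false(p$low_confidence)
  expect_equal(sort(p$protomers$angle_deg %% 72)[1], 51.3 %% 72,
               tolerance = 0.05)

  # translation equivariance: shifting the frame shifts the center
  sh <- memclust:::mat_shift(one$frame, 4, 6, fill = 5)  # +2 nm y, +3 nm x
  p2 <- refine_particle(sh, one$center + c(3, 2) + c(0.8, -0.5), nf = 5,
                        pixel_size = 0.5, ring_radius = 3.5)
  expect_equal(p2$center - p$center, c(3, 2), tolerance = 0.15)

  # pure noise: isv near zero, low-confidence flag
  set.seed(31)
  noise <- matrix(rnorm(64 * 64, 5, 0.3), 64, 64)
  pn <- refine_particle(noise, c(16, 16), nf = 5, pixel_size = 0.5,
                        ring_radius = 3.5, detilt_iter = 0)
  expect_lt(pn$isv, 0.5)
  expect_true(pn$low_confidence)
})

test_that("symmetrized image is exactly nf-fold invariant", {
  # symmetrization average over nf rotations: rotating the polar
  # representation by 360/nf changes nothing
  one <- render_one(orientation = 20, nf = 5)
  nth <- 90L
  thetas <- seq(0, 2 * pi, length.out = nth + 1)[-(nth + 1)]
  pm <- memclust:::polar_samples(one$frame, one$center,
                                 seq(0.25, 6, by = 0.25), thetas, 0.5)
  sym <- pm
  acc <- pm
  for (j in 1:4) {
    acc <- acc[, c(19:nth, 1:18)]
    sym <- sym + acc
  }
  sym <- sym / 5
  rot <- sym[, c(19:nth, 1:18)]
  expect_lt(max(abs(rot - sym)), 1e-9)
})

test_that("classify_symmetry identifies tetramers and pentamers rotation-invariantly", {
  pent <- render_one(orientation = 10, nf = 5)
  cp <- classify_symmetry(pent$frame, pent$center, ring_radius = 3.5,
                          pixel_size = 0.5)
  expect_identical(cp$nf, 5L)
  expect_identical(cp$spacing_deg, 72)
  expect_equal(cp$peak_spacing_deg, 72, tolerance = 0.02)

  tet <- render_one(orientation = 33, nf = 4)
  ct <- classify_symmetry(tet$frame, tet$center, ring_radius = 3.5,
                          pixel_size = 0.5)
  expect_identical(ct$nf, 4L)
  expect_identical(ct$spacing_deg, 90)

  # rotation invariance of the classification
  for (o in c(0, 17, 44.3, 66)) {
    r <- render_one(orientation = o, nf = 5)
    expect_identical(
      classify_symmetry(r$frame, r$center, ring_radius = 3.5,
                        pixel_size = 0.5)$nf, 5L)
  }

  # featureless patch: unclassified
  set.seed(6)
  flat <- matrix(rnorm(64^2, 5, 0.02), 64, 64)
  cf <- classify_symmetry(flat, c(16, 16), ring_radius = 3.5, pixel_size = 0.5)
  expect_true(is.na(cf$nf))
})

test_that("tilt_angle: analytic plane, invariances, degenerate input", {
  # regular pentagon with heights from a 10-degree plane about x
  ang <- (0:4) * 72 * pi / 180
  x <- 3.5 * cos(ang); y <- 3.5 * sin(ang)
  h <- tan(10 * pi / 180) * y          # tilt about the x-axis
  expect_equal(tilt_angle(data.frame(x = x, y = y, h = h)), 10,
               tolerance = 1e-9)

  # flat: omega = 0
  expect_equal(tilt_angle(data.frame(x = x, y = y, h = rep(2, 5))), 0)

  # invariant under height offset and in-plane rotation
  expect_equal(tilt_angle(data.frame(x = x, y = y, h = h + 5)), 10,
               tolerance = 1e-9)
  ro <- 0.6
  xr <- x * cos(ro) - y * sin(ro); yr <- x * sin(ro) + y * cos(ro)
  hr <- tan(10 * pi / 180) * (x * 0 + y)   # same heights, rotated positions
  expect_equal(tilt_angle(data.frame(x = xr, y = yr, h = h)), 10,
               tolerance = 1e-9)

  # collinear points: degenerate
  expect_error(tilt_angle(data.frame(x = 1:4, y = 2 * (1:4), h = rnorm(4))),
               "collinear|degenerate")
})

test_that("tilt recovery on rendered particles: MAE < 2 degrees over 0-35", {
  set.seed(12)
  errs <- c()
  for (tilt in seq(0, 35, by = 5)) {
    one <- render_one(orientation = runif(1, 0, 72), tilt = tilt,
                      tilt_axis = runif(1, 0, 360), noise_sd = 0.05)
    p <- refine_particle(one$frame, one$center + c(0.3, -0.2), nf = 5,
                         pixel_size = 0.5, ring_radius = 3.5)
    errs <- c(errs, abs(p$tilt_deg - tilt))
  }
  expect_lt(mean(errs), 2)
})

test_that("delaunay_edges matches the frozen independent oracle", {
  # 12-point fixture; expected edges computed externally with
  # scipy.spatial.Delaunay and frozen
  set.seed(101)
  pts <- matrix(runif(24, 0, 50), 12, 2)
  expected <- matrix(c(
    1L, 4L, 1L, 5L, 1L, 6L, 1L, 7L, 1L, 9L, 1L, 10L, 2L, 5L, 2L, 6L, 2L, 8L,
    2L, 10L, 3L, 4L, 3L, 7L, 3L, 11L, 3L, 12L, 4L, 7L, 4L, 9L, 4L, 12L,
    5L, 6L, 5L, 10L, 6L, 7L, 6L, 8L, 7L, 8L, 7L, 11L, 8L, 11L, 9L, 10L,
    9L, 12L, 10L, 12L, 11L, 12L), ncol = 2, byrow = TRUE)
  ed <- delaunay_edges(pts)
  expect_identical(unname(ed), unname(expected))

  # degenerate inputs
  expect_identical(nrow(delaunay_edges(matrix(c(1, 1), 1, 2))), 0L)
  expect_identical(delaunay_edges(matrix(c(0, 0, 1, 1), 2, 2)),
                   matrix(c(1L, 2L), 1, 2))
})

test_that("delaunay_pairs: cutoff, collinear chains, oracle equivalence", {
  # equilateral triangle, side < d_max: 3 pairs
  tri <- matrix(c(0, 0, 8, 0, 4, 8 * sqrt(3) / 2), 3, 2, byrow = TRUE)
  expect_identical(nrow(delaunay_pairs(tri, d_max = 10)), 3L)

  # 4 collinear particles spacing 7, d_max 10: 3 chain pairs only
  line <- cbind(c(0, 7, 14, 21), rep(1, 4))
  pl <- delaunay_pairs(line, d_max = 10)
  expect_identical(nrow(pl), 3L)
  expect_true(all(pl$d == 7))

  # single particle: empty
  expect_identical(nrow(delaunay_pairs(matrix(c(1, 2), 1, 2))), 0L)

  # oracle equivalence on random sets (<= 20 particles): triangulation +
  # cutoff equals brute-force all-pairs-within-cutoff restricted to
  # Delaunay edges
  for (s in 1:5) {
    set.seed(s)
    pts <- matrix(runif(2 * sample(5:20, 1), 0, 40), ncol = 2)
    dmax <- 12
    ed <- delaunay_edges(pts)
    brute <- which(as.matrix(dist(pts)) <= dmax & upper.tri(diag(nrow(pts))),
                   arr.ind = TRUE)
    brute_set <- paste(pmin(brute[, 1], brute[, 2]),
                       pmax(brute[, 1], brute[, 2]))
    del_set <- paste(ed[, 1], ed[, 2])
    pr <- delaunay_pairs(pts, d_max = dmax)
    expect_setequal(paste(pr$i, pr$j), intersect(del_set, brute_set))
  }
})

test_that("interaction_angles: sign convention, bounds, tie-break", {
  b <- stub_particle(10, 0, 5, 0)

  # protomer exactly on the connection line: 0
  expect_equal(interaction_angles(stub_particle(0, 0, 5, 0), b)[["alpha"]], 0)

  # pentamer rotated +10 deg (clockwise in display orientation): alpha = +10
  expect_equal(interaction_angles(stub_particle(0, 0, 5, 10), b)[["alpha"]], 10)

  # half-period boundary: |alpha| = 36, tie resolved toward +
  expect_equal(interaction_angles(stub_particle(0, 0, 5, 36), b)[["alpha"]], 36)

  # bounds on 1000 random orientations, pentamer and tetramer
  set.seed(77)
  for (nf in c(5L, 4L)) {
    half <- 180 / nf
    a <- vapply(runif(1000, 0, 360), function(o)
      interaction_angles(stub_particle(0, 0, nf, o), b)[["alpha"]],
      numeric(1))
    expect_true(all(abs(a) <= half + 1e-9))
    expect_gt(max(abs(a)), half - 1)   # the bound is attained
  }
})

test_that("interaction-angle recovery on rendered lattices: RMS < 3 degrees", {
  set.seed(23)
  px <- 0.5
  g <- grids(120, px)
  centers <- rbind(c(20, 20), c(28, 20), c(20, 28), c(28, 28))
  orients <- runif(4, 0, 72)
  fr <- 5 + particle_field(g$X, g$Y, centers, nf = 5, orientations = orients,
                           tilts = rep(0, 4), tilt_axes = rep(0, 4),
                           particle_radius = 3.5, protomer_height = 1.2) +
    matrix(rnorm(120^2, 0, 0.05), 120, 120)
  parts <- lapply(seq_len(4), function(i)
    refine_particle(fr, centers[i, ], nf = 5, pixel_size = px,
                    ring_radius = 3.5))
  pr <- delaunay_pairs(parts, d_max = 9)
  expect_gt(nrow(pr), 0)
  err <- c()
  for (r in seq_len(nrow(pr))) {
    i <- pr$i[r]; j <- pr$j[r]
    truth <- interaction_angles(stub_particle(centers[i, 1], centers[i, 2], 5,
                                              orients[i]),
                                stub_particle(centers[j, 1], centers[j, 2], 5,
                                              orients[j]))
    err <- c(err, pr$alpha_deg[r] - truth[["alpha"]],
             pr$beta_deg[r] - truth[["beta"]])
  }
  expect_lt(sqrt(mean(err^2)), 3)
})

test_that("angle_density_map: peak, uniformity, symmetry", {
  # all pairs at (0, 0): single peak at the origin with value 1
  m0 <- angle_density_map(cbind(rep(0, 10), rep(0, 10)), nf = 5)
  i0 <- which(m0$alpha == 0)
  expect_equal(m0$density[i0, i0], 1)
  expect_true(all(m0$density <= 1))

  # uniform angles: near-flat map
  set.seed(3)
  u <- matrix(runif(2000, -36, 36), ncol = 2)
  mu_ <- angle_density_map(u, nf = 5, bandwidth = 6)
  expect_lt(max(mu_$density) / min(mu_$density), 2)

  # symmetry about the alpha = beta diagonal by construction
  set.seed(4)
  ab <- matrix(runif(60, -36, 36), ncol = 2)
  ms <- angle_density_map(ab, nf = 5)
  expect_lt(max(abs(ms$density - t(ms$density))), 1e-12)
})

test_that("distance_stats recovers Gaussian parameters and flags misfits", {
  set.seed(42)
  d <- rnorm(200, 7.8, 0.8)
  st <- distance_stats(d)
  expect_true(st$converged)
  expect_equal(st$peak, 7.8, tolerance = 0.2 / 7.8)
  expect_equal(st$sd, 0.8, tolerance = 0.2 / 0.8)
  expect_identical(st$n, 200L)

  # identical distances: sd -> 0, peak = value
  st0 <- distance_stats(rep(6.6, 30))
  expect_identical(st0$peak, 6.6)
  expect_identical(st0$sd, 0)

  # bimodal input: poor-fit flag via residual criterion
  set.seed(43)
  bim <- c(rnorm(150, 5, 0.3), rnorm(150, 11, 0.3))
  stb <- distance_stats(bim)
  expect_true(!stb$converged || stb$poor_fit)

  # two-population comparison returns a t-test
  tt <- compare_distances(rnorm(60, 7.8, 0.8), rnorm(60, 8.4, 0.8))
  expect_s3_class(tt, "htest")
  expect_lt(tt$p.value, 0.05)
})

test_that("classify_edge_center matches generator labels", {
  spec <- movie_spec(n_frames = 2, n_particles = 7, noise_sd = 0,
                     edge_tilt_deg = 0, seed = 8)
  sim <- render_movie(spec)
  contour <- list(theta = sim$truth$boundary$theta,
                  radius = colMeans(sim$truth$boundary$radius),
                  center = c(40, 40))   # field center (80 nm field)
  parts <- lapply(seq_len(7), function(i)
    stub_particle(sim$truth$centers[i, 1], sim$truth$centers[i, 2], 5, 0))
  parts <- classify_edge_center(parts, contour,
                                diameter = 2 * spec$particle_radius)
  got <- vapply(parts, function(p) p$location_class, character(1))
  expect_identical(got, sim$truth$location_class)

  # particle at the centroid of a large cluster: center; touching contour: edge
  big <- list(theta = seq(0, 2 * pi, length.out = 90), radius = rep(30, 90),
              center = c(0, 0))
  pc <- classify_edge_center(list(stub_particle(0, 0, 5, 0)), big,
                             diameter = 7)
  expect_identical(pc[[1]]$location_class, "center")
  pe <- classify_edge_center(list(stub_particle(29.9, 0, 5, 0)), big,
                             diameter = 7)
  expect_identical(pe[[1]]$location_class, "edge")
})
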
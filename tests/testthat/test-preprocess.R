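test_that("isodata threshold: frozen fixed points and convergence", {
  # two-valued image: intermeans of the two levels
  expect_equal(isodata_threshold(c(0, 0, 10, 10)), 5)

  # 4-pixel fixture [0, 0, 8, 10]: brute-force iteration from the mean:
  # t0 = 4.5 -> mean(lo) = 0, mean(hi) = 9 -> t1 = 4.5 (fixed point)
  expect_equal(isodata_threshold(c(0, 0, 8, 10)), 4.5)

  # bimodal Gaussian mixture (means 0 and 4, sd 0.3): threshold in [1.5, 2.5]
  set.seed(4)
  v <- c(rnorm(4000, 0, 0.3), rnorm(4000, 4, 0.3))
  thr <- isodata_threshold(v)
  expect_gt(thr, 1.5); expect_lt(thr, 2.5)

  # result is a fixed point of the intermeans map
  t1 <- (mean(v[v <= thr]) + mean(v[v > thr])) / 2
  expect_equal(thr, t1, tolerance = 1e-5)

  # affine equivariance: threshold of a*x + b is a*thr + b
  thr2 <- isodata_threshold(3 * v + 7)
  expect_equal(thr2, 3 * thr + 7, tolerance = 1e-4)

  expect_error(isodata_threshold(rep(1, 10)), "degenerate")
})

test_that("flatten_frame removes per-line backgrounds exactly", {
  set.seed(5)
  base <- matrix(0, 60, 60)
  base[20:40, 20:40] <- 3
  off <- rnorm(60, 0, 0.5)
  slope <- rnorm(60, 0, 0.01)
  tilted <- base + matrix(off, 60, 60) + outer(slope, 1:60)
  fl <- flatten_frame(tilted)
  expect_lt(sqrt(mean((fl - base)^2)), 0.01 * sd(off))   # < 1% RMS

  # constant frame: zero after offset removal
  expect_true(all(flatten_frame(matrix(4, 10, 10)) == 0))

  # exact global plane: flattening inverts it
  pl <- outer(seq_len(50) * 0.02, rep(1, 50)) + 2
  expect_lt(max(abs(flatten_frame(base[1:50, 1:50] + pl) - base[1:50, 1:50])),
            1e-8)
})

test_that("align_frames recovers injected drift", {
  spec <- movie_spec(n_frames = 2, n_particles = 5, noise_sd = 0.05, seed = 2)
  f1 <- render_movie(spec)$movie$frames[[1]]
  frames <- lapply(0:19, function(i)
    memclust:::mat_shift(f1, round(0.5 * i), round(0.5 * i),
                         fill = median(f1)))
  al <- align_frames(topography_movie(frames, 0.5, 0.5))
  slope <- coef(lm(dy ~ frame, data = al$drift))[2]
  expect_equal(unname(slope), 0.5, tolerance = 0.1 / 0.5)

  # identical frames: all shifts exactly 0
  al0 <- align_frames(topography_movie(rep(list(f1), 4), 0.5, 0.5))
  expect_true(all(al0$drift$dy == 0, al0$drift$dx == 0))

  # single frame: identity
  al1 <- align_frames(topography_movie(list(f1), 0.5, 0.5))
  expect_identical(al1$movie$frames[[1]], f1)
})

test_that("walking_average removes flicker, is idempotent, fills holes", {
  disk <- disk_mask(40, 20, 20, 10)

  # single-frame salt pixel removed
  ms <- rep(list(disk), 5)
  noisy <- disk; noisy[5, 5] <- TRUE
  ms[[3]] <- noisy
  out <- walking_average(ms)
  expect_false(out[[3]][5, 5])

  # idempotence on temporally constant stacks
  same <- walking_average(rep(list(disk), 4))
  expect_true(all(vapply(same, function(m) identical(m, disk), logical(1))))
  expect_identical(walking_average(same), same)

  # 5% flicker on the disk: Jaccard > 0.99 after conditioning
  set.seed(5)
  flick <- lapply(1:9, function(i) disk & matrix(runif(1600) >= 0.05, 40, 40))
  wa <- walking_average(flick)
  jac <- vapply(wa, function(m) sum(m & disk) / sum(m | disk), numeric(1))
  expect_gt(min(jac), 0.99)

  # enclosed gap pixels are filled
  holey <- disk; holey[20, 20] <- FALSE
  filled <- walking_average(rep(list(holey), 3))
  expect_true(filled[[1]][20, 20])
})

test_that("surface_coverage recovers painted fractions and sums to 1", {
  set.seed(8)
  fr <- matrix(0, 100, 100)
  fr[1:15, ] <- 4     # lipid 15%
  fr[16:26, ] <- 6    # protein 11%
  sc <- surface_coverage(fr + rnorm(10000, 0, 0.1))
  expect_equal(unname(sc["protein"]), 0.11, tolerance = 0.01 / 0.11)
  expect_equal(unname(sc["lipid"]), 0.15, tolerance = 0.01 / 0.15)
  expect_equal(unname(sc["mica"]), 0.74, tolerance = 0.01 / 0.74)
  expect_equal(sum(sc), 1)

  # uniform membrane: {0, 1, 0} with a warning
  expect_warning(sc1 <- surface_coverage(matrix(4, 20, 20)), "single level")
  expect_equal(as.vector(sc1), c(0, 1, 0))

  # conservation on random frames
  for (s in 1:5) {
    set.seed(s)
    sc_r <- suppressWarnings(surface_coverage(matrix(rnorm(400), 20, 20)))
    expect_equal(sum(sc_r), 1)
  }
})

test_that("select_isolated_clusters rejects merges, splits and border contact", {
  n <- 60
  two <- function(gap) disk_mask(n, 20, 30, 7) | disk_mask(n, 20 + gap, 30, 7)
  mk_stack <- function(masks) {
    structure(list(masks = masks, thresholds = rep(0, length(masks)),
                   pixel_size = 1, frame_interval = 1), class = "mask_stack")
  }

  # stable isolated disk: one accepted trace spanning all frames
  stable <- mk_stack(rep(list(disk_mask(n, 30, 30, 8)), 6))
  tr <- select_isolated_clusters(stable)
  expect_length(tr, 1)
  expect_length(tr[[1]], 6)

  # two disks merging at frame 4: both rejected
  merging <- mk_stack(c(rep(list(two(20)), 3), rep(list(two(10)), 3)))
  expect_warning(tm <- select_isolated_clusters(merging), "no isolated")
  expect_length(tm, 0)

  # disk splitting into two: rejected
  splitting <- mk_stack(c(rep(list(two(10)), 3), rep(list(two(20)), 3)))
  expect_warning(ts <- select_isolated_clusters(splitting), "no isolated")
  expect_length(ts, 0)

  # border-touching cluster rejected
  border <- mk_stack(rep(list(disk_mask(n, 3, 30, 7)), 4))
  expect_warning(tb <- select_isolated_clusters(border), "no isolated")
  expect_length(tb, 0)
})
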
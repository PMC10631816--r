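test_that("hand-computed single-voxel variances come out exactly", {
  # one voxel, two frames: sigma2 = 1 - (A1 A2) / ((A1^2 + A2^2)/2)
  a <- array(c(2, 1), dim = c(1, 1, 2))
  expect_equal(compute_ibdv(a, lateral_window = 1)[1, 1], 1 - 2 / 2.5)
  a0 <- array(c(3, 0), dim = c(1, 1, 2))
  expect_equal(compute_ibdv(a0, lateral_window = 1)[1, 1], 1)
  # identical frames cancel exactly
  f <- matrix(runif(64, 0.1, 2), 8, 8)
  same <- array(rep(f, 4), dim = c(8, 8, 4))
  expect_true(all(compute_ibdv(same, 1) == 0))
  expect_true(all(compute_ibdv(same, 3) == 0))
})

test_that("degenerate inputs are rejected or defined", {
  expect_error(compute_ibdv(array(1, c(4, 4, 1))), ">=2 frames")
  expect_error(compute_ibdv(array(1, c(4, 4, 2)), lateral_window = 2),
               "odd")
  # all-zero voxels (zero denominator) are defined as 0, not NaN
  z <- array(0, c(4, 4, 3))
  expect_true(all(compute_ibdv(z, 1) == 0))
})

test_that("vectorized variance matches the naive per-voxel loop", {
  set.seed(101)
  for (rep in 1:25) {
    a <- rayleigh_frames(8, 8, 3)
    expect_lt(max(abs(compute_ibdv(a, 1) - ibdv_naive(a, 1L))), 1e-12)
    expect_lt(max(abs(compute_ibdv(a, 3) - ibdv_naive(a, 3L))), 1e-12)
  }
})

test_that("variance stays in [0,1] for arbitrary non-negative inputs", {
  set.seed(7)
  for (rep in 1:20) {
    a <- array(runif(8 * 8 * 4, 0, 10), c(8, 8, 4))
    a[sample(length(a), 20)] <- 0
    s <- compute_ibdv(a, sample(c(1, 3, 5), 1))
    expect_true(all(s >= 0 & s <= 1))
  }
})

test_that("independent Rayleigh frames approach the 1 - pi/4 asymptote", {
  set.seed(11)
  a <- rayleigh_frames(100, 100, 65)       # J = 64 pairs, 1e4 voxels
  s <- compute_ibdv(a, lateral_window = 1)
  se <- sd(s) / sqrt(length(s))
  expect_lt(abs(mean(s) - (1 - pi / 4)), 3 * se)
})

test_that("intra-frame pairing preserves shape and the static-zero law", {
  f <- matrix(runif(64, 0.5, 1.5), 8, 8)
  same <- array(rep(f, 3), dim = c(8, 8, 3))
  s <- compute_ibdv(same, 1, pairing = "intraframe")
  expect_equal(dim(s), c(8L, 8L))
  expect_true(all(s >= 0 & s <= 1))
  # constant image has identical neighbouring A-lines: exactly zero
  const <- array(1, c(8, 8, 3))
  expect_true(all(compute_ibdv(const, 1, pairing = "intraframe") == 0))
})

test_that("volume variance is consistent with per-position calls", {
  g <- small_geometry()
  sc <- make_tissue_scene(g, 150, 0.2, seed = 31)
  vol <- render_phantom_volume(sc, decorrelation = 1, noise_floor = 0.05,
                               seed = 2)
  vv <- compute_ibdv_volume(vol, 3)
  expect_equal(dim(vv), c(g$n_depth, g$n_fast, g$n_slow))
  one <- compute_ibdv(vol$frames[[3]], 3)
  expect_equal(vv[, , 3], unclass(one), ignore_attr = TRUE)
  # static phantom gives an all-zero volume up to the (zero) noise floor
  vol0 <- render_phantom_volume(sc, decorrelation = 0, noise_floor = 0,
                                seed = 2)
  expect_true(all(compute_ibdv_volume(vol0, 1) == 0))
  expect_error(compute_ibdv_volume(list()), "non-empty")
})

test_that("vessel voxels carry more variance, increasing with decorrelation", {
  g <- medium_geometry(n_slow = 8L)
  sc <- make_tissue_scene(g, 150, 0.2, seed = 41)
  vm <- sc$vessel_mask[, , 4]
  means <- vapply(c(0, 0.25, 0.5, 1), function(d) {
    fs <- render_frame_sequence(sc, 4, decorrelation = d, noise_floor = 0.05,
                                seed = 13)
    mean(compute_ibdv(fs, 3)[vm])
  }, numeric(1))
  expect_true(all(diff(means) > 0))
  fs1 <- render_frame_sequence(sc, 4, 1, 0.05, seed = 13)
  s1 <- compute_ibdv(fs1, 3)
  expect_gt(mean(s1[vm]), mean(s1[!vm]))
})

test_that("en-face projection averages the requested slab", {
  vol <- array(2, c(6, 5, 4))
  const <- enface_project(vol)
  expect_true(all(const == 2))
  expect_equal(dim(const), c(5L, 4L))
  # depth ramp 0,1,2,...: first four planes average to 1.5
  ramp <- array(rep(0:5, 20), c(6, 5, 4))
  expect_true(all(enface_project(ramp, c(1, 4)) == 1.5))
  # single-plane slab returns that plane
  expect_equal(unclass(enface_project(ramp, c(3, 3))),
               ramp[3, , ], ignore_attr = TRUE)
  expect_error(enface_project(ramp, c(5, 2)), "slab")
  expect_error(enface_project(ramp, c(0, 4)), "slab")
})
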
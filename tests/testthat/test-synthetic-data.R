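test_that("geometry constructor enforces grid invariants", {
  expect_error(phantom_geometry(n_depth = 4), ">= 8")
  expect_error(phantom_geometry(n_repeats = 1), ">= 2")
  expect_error(phantom_geometry(axial_pixel_um = 0), "positive")
  g <- phantom_geometry(n_depth = 64, n_fast = 32, n_slow = 16)
  expect_s3_class(g, "phantom_geometry")
})

test_that("scene rasterizes the epithelium band at the requested thickness", {
  g <- small_geometry()
  sc <- make_tissue_scene(g, thickness_um = 150, vessel_fraction = 0, seed = 1)
  # 150 um at 14 um/px rounds to an 11-pixel band in every column
  expect_true(all(sc$epi_thickness_px == round(150 / 14)))
  expect_true(all(sc$epi_thickness_px == 11L))
  mask <- truth_epithelium_mask(sc, 3L)
  expect_equal(unname(colSums(mask)), rep(11, g$n_fast))
})

test_that("zero vessel fraction gives an empty mask; targeting hits 0.02", {
  g <- medium_geometry(n_slow = 24L)
  sc0 <- make_tissue_scene(g, 150, vessel_fraction = 0, seed = 2)
  expect_false(any(sc0$vessel_mask))
  expect_identical(scene_enface_fraction(sc0), 0)
  sc <- make_tissue_scene(g, 150, vessel_fraction = 0.25, seed = 2)
  f <- scene_enface_fraction(sc)
  expect_gte(f, 0.23); expect_lte(f, 0.27)
  # vessels lie strictly below the epithelium everywhere
  below <- apply(sc$vessel_mask, c(2, 3), function(col) {
    w <- which(col); if (length(w)) min(w) else NA_integer_
  })
  lim <- sc$surface_depth + sc$epi_thickness_px
  expect_true(all(below[!is.na(below)] > lim[!is.na(below)]))
})

test_that("over-deep epithelium errors and names the maximum thickness", {
  g <- small_geometry()
  expect_error(make_tissue_scene(g, thickness_um = 2000, seed = 1),
               "maximum representable thickness")
  expect_error(make_tissue_scene(g, thickness_um = 150,
                                 vessel_fraction = 0.95, seed = 1),
               "vessel_fraction")
})

test_that("identical seeds give bit-identical scenes, frames and cohorts", {
  g <- small_geometry()
  s1 <- make_tissue_scene(g, 140, 0.2, seed = 11)
  s2 <- make_tissue_scene(g, 140, 0.2, seed = 11)
  expect_identical(s1, s2)
  f1 <- render_frame_sequence(s1, 2, 0.5, 0.05, seed = 4)
  f2 <- render_frame_sequence(s2, 2, 0.5, 0.05, seed = 4)
  expect_identical(f1, f2)
  c1 <- generate_cohort(cohort_effect_model(n_patients = 10, seed = 9))
  c2 <- generate_cohort(cohort_effect_model(n_patients = 10, seed = 9))
  expect_identical(c1, c2)
})

test_that("static scene with no noise renders identical repeated frames", {
  g <- small_geometry()
  sc <- make_tissue_scene(g, 150, 0.2, seed = 5)
  fs <- render_frame_sequence(sc, 1, decorrelation = 0, noise_floor = 0,
                              seed = 3)
  expect_true(all(fs >= 0))
  for (j in 2:dim(fs)[3]) expect_identical(fs[, , 1], fs[, , j])
  expect_error(render_frame_sequence(sc, 1, decorrelation = 1.2),
               "decorrelation")
})

test_that("static tissue follows fully developed Rayleigh speckle", {
  g <- medium_geometry(n_slow = 8L)
  sc <- make_tissue_scene(g, 150, 0, seed = 6)
  fs <- render_frame_sequence(sc, 1, 0, 0, seed = 12)
  # uniform lamina block well below the epithelium
  zlo <- max(sc$surface_depth[, 1] + sc$epi_thickness_px[, 1]) + 5L
  blk <- fs[zlo:(zlo + 30L), , 1]
  ratio <- mean(blk) / sd(blk)
  expect_lt(abs(ratio - sqrt(pi / (4 - pi))), 0.05)
})

test_that("full decorrelation makes vessel amplitudes independent across frames", {
  g <- medium_geometry(n_slow = 24L)
  sc <- make_tissue_scene(g, 150, 0.5, seed = 21)
  set.seed(77)
  v1 <- c(); v2 <- c()
  for (y in seq_len(g$n_slow)) {
    fs <- render_frame_sequence(sc, y, decorrelation = 1, noise_floor = 0,
                                seed = NULL)
    vm <- sc$vessel_mask[, , y]
    v1 <- c(v1, fs[, , 1][vm]); v2 <- c(v2, fs[, , 2][vm])
  }
  expect_gt(length(v1), 1e4)
  expect_lt(abs(cor(v1, v2)), 0.03)
})

test_that("air above the surface carries only noise-floor amplitude", {
  g <- small_geometry()
  sc <- make_tissue_scene(g, 150, 0, seed = 8)
  nf <- 0.05
  fs <- render_frame_sequence(sc, 1, 1, noise_floor = nf, seed = 2)
  air <- fs[1:(min(sc$surface_depth[, 1]) - 2L), , 1]
  # Rayleigh noise with mean-square nf^2: mean amplitude nf * sqrt(pi)/2
  expect_lt(abs(mean(air) - nf * sqrt(pi) / 2), 0.2 * nf)
  expect_lt(max(air), 5 * nf)
})

test_that("cohort model validates inputs and zero-noise collapses to the means", {
  expect_error(cohort_effect_model(n_patients = 1), ">= 2")
  expect_error(cohort_effect_model(baseline_bvd_mean = 1.2), "fraction")
  m0 <- cohort_effect_model(
    n_patients = 5,
    sd_between = c(bvd = 0, vet = 0, vhi = 0, vsq = 0),
    sd_within = c(bvd = 0, vet = 0, vhi = 0, vsq = 0),
    bvd_location_offsets = zero_offsets(),
    vet_location_offsets = zero_offsets(), seed = 1)
  tab <- generate_cohort(m0)
  expect_equal(nrow(tab), 5 * 4 * 4)
  expect_true(all(tab$bvd[tab$visit == 1] == 0.217))
  expect_true(all(tab$bvd[tab$visit == 4] == 0.296))
  expect_true(all(tab$vet_um[tab$visit == 1] == 123.3))
})

test_that("cohort recovers generating means and correlation magnitudes", {
  tab <- generate_cohort(cohort_effect_model(n_patients = 400, seed = 3))
  truth <- attr(tab, "truth")
  expect_equal(sort(unique(as.character(tab$location))),
               c("da", "dp", "pa", "pp"))
  # one record per (patient, visit, location)
  expect_equal(nrow(unique(tab[c("patient_id", "visit", "location")])),
               nrow(tab))
  for (v in c(1, 4)) {
    sel <- tab$visit == v
    se <- clustered_se(tab$bvd[sel], tab$patient_id[sel])
    expect_lt(abs(mean(tab$bvd[sel]) - mean(truth$bvd[truth$visit == v])),
              3 * se)
  }
  r <- correlate_metrics(tab, "vhi", "vet_um")
  expect_lt(abs(r$abs_r - 0.853), 0.05)
  expect_identical(r$strength, "strong")
  # VHI scores live on the 5-25 integer scale
  expect_true(all(tab$vhi == round(tab$vhi)))
  expect_true(all(tab$vhi >= 5 & tab$vhi <= 25))
})
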
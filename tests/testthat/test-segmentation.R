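test_that("overlap metrics satisfy their exact identities", {
  a <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2)
  s <- evaluate_segmentation(a, a)
  expect_equal(unlist(s[c("pixel_accuracy", "iou", "dice")]),
               c(pixel_accuracy = 1, iou = 1, dice = 1))
  # disjoint non-empty masks
  b <- !a
  sd <- evaluate_segmentation(a, b)
  expect_equal(sd$iou, 0); expect_equal(sd$dice, 0)
  # empty vs empty scores 1 by convention
  e <- matrix(FALSE, 3, 3)
  expect_equal(evaluate_segmentation(e, e)$dice, 1)
  expect_error(evaluate_segmentation(a, matrix(TRUE, 3, 3)), "same shape")
})

test_that("a 150%-area dilation of a square scores dice 0.8, iou 2/3", {
  truth <- matrix(FALSE, 20, 20)
  truth[6:15, 6:15] <- TRUE                    # 100 pixels
  pred <- truth
  pred[5, 6:15] <- TRUE                        # +10
  pred[16, 6:15] <- TRUE                       # +10
  pred[6:15, 5] <- TRUE                        # +10
  pred[6:15, 16] <- TRUE                       # +10
  pred[5, 5] <- pred[5, 16] <- pred[16, 5] <- pred[16, 16] <- TRUE
  pred[4, 6:11] <- TRUE                        # +6 -> 150 total
  expect_equal(sum(pred), 150L)
  s <- evaluate_segmentation(pred, truth)
  expect_equal(s$dice, 0.8)
  expect_equal(s$iou, 2 / 3)
})

test_that("dice equals 2 iou / (1 + iou) on random mask pairs", {
  set.seed(33)
  for (rep in 1:200) {
    p <- matrix(runif(100) < runif(1), 10, 10)
    t <- matrix(runif(100) < runif(1), 10, 10)
    s <- evaluate_segmentation(p, t)
    expect_equal(s$dice, 2 * s$iou / (1 + s$iou), tolerance = 1e-12)
  }
})

test_that("classical segmenter recovers thickness on speckle phantoms", {
  g <- medium_geometry(n_slow = 8L)
  for (th in c(100, 150, 200)) {
    sc <- make_tissue_scene(g, th, 0, seed = 50 + th)
    vol <- render_phantom_volume(sc, 1, 0.05, seed = 9)
    seg <- segment_epithelium_classical(vol$structural[, , 4])
    vet <- compute_vet(seg, g$axial_pixel_um)
    expect_lt(abs(vet$mean_vet_um - th), 14)
    # per-column boundary deviation against the generating scene
    tru_u <- sc$surface_depth[, 4]
    tru_l <- tru_u + sc$epi_thickness_px[, 4]
    expect_lt(mean(abs(seg$upper - tru_u), na.rm = TRUE), 2)
    expect_lt(mean(abs(seg$lower - tru_l), na.rm = TRUE), 2)
    # mask true exactly between the boundaries
    for (x in c(1, 64, 128)) {
      if (!seg$valid[x]) next
      expect_equal(which(seg$mask[, x]),
                   seq(seg$upper[x], length.out = seg$lower[x] - seg$upper[x]))
    }
  }
})

test_that("zero-thickness tissue yields thickness 0 without error", {
  g <- small_geometry()
  sc <- make_tissue_scene(g, 0, 0, seed = 77)
  vol <- render_phantom_volume(sc, 1, 0.05, seed = 3)
  seg <- segment_epithelium_classical(vol$structural[, , 2])
  vet <- compute_vet(seg, 14)
  expect_lt(vet$mean_vet_um, 28)               # within 2 px of zero
  expect_false(any(seg$mask[, which(seg$lower == seg$upper)]))
})

test_that("featureless noise images are rejected as surface-free", {
  set.seed(12)
  noise <- matrix(sqrt(rnorm(64 * 64)^2 + rnorm(64 * 64)^2), 64, 64)
  expect_error(segment_epithelium_classical(noise), "surface not found")
  expect_error(segment_epithelium_classical(matrix(1, 8, 20)), "16 pixels")
})

test_that("thickness conversion and validity accounting are exact", {
  seg <- structure(list(mask = matrix(FALSE, 30, 4),
                        upper = c(10L, 10L, NA, 12L),
                        lower = c(20L, 15L, NA, 12L),
                        valid = c(TRUE, TRUE, FALSE, TRUE),
                        method = "manual"),
                   class = "epithelium_segmentation")
  vet <- compute_vet(seg, 14)
  expect_equal(vet$thickness_um[1], 140)
  expect_equal(vet$mean_vet_um, mean(c(140, 70, 0)))
  expect_equal(vet$validity, 0.75)
  seg$valid[] <- FALSE
  expect_error(compute_vet(seg, 14), "no valid columns")
})
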
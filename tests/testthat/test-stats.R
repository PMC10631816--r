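toy_table <- function() {
  g <- expand.grid(patient_id = c("P1", "P2", "P3", "P4"), visit = 1:4,
                   location = c("da", "dp", "pa", "pp"),
                   stringsAsFactors = FALSE)
  g$bvd <- 0.2; g$vet_um <- 120; g$vhi <- 15; g$vsq <- 9
  g
}

test_that("cell means, SEs and grand means are plain arithmetic", {
  two <- data.frame(patient_id = c("P1", "P2"), visit = 1, location = "da",
                    bvd = c(0.20, 0.30))
  cell <- aggregate_study(two, "bvd")
  cell <- cell[cell$location == "da", ]
  expect_equal(cell$mean, 0.25)
  expect_equal(cell$se, 0.05)
  expect_equal(cell$n, 2L)
  t <- toy_table()                               # identical values everywhere
  agg <- aggregate_study(t, "bvd")
  const <- agg[agg$visit == 2 & agg$location == "pp", ]
  expect_equal(const$mean, 0.2); expect_equal(const$se, 0)
  grand <- agg[agg$visit == 1 & agg$location == "all", ]
  expect_equal(grand$n, 16L)
  expect_equal(grand$mean, mean(t$bvd[t$visit == 1]))
})

test_that("star annotation is a pure threshold map on p", {
  expect_identical(p_stars(c(0.0005, 0.005, 0.03, 0.07, 1)),
                   c("***", "**", "*", "ns", "ns"))
  # boundaries belong to the weaker class (p < threshold is strict)
  expect_identical(p_stars(c(0.001, 0.01, 0.05)), c("**", "*", "ns"))
  set.seed(2)
  p <- runif(200)
  expect_identical(p_stars(p),
                   ifelse(p < 0.001, "***",
                          ifelse(p < 0.01, "**",
                                 ifelse(p < 0.05, "*", "ns"))))
  expect_error(p_stars(1.3))
})

test_that("baseline comparison handles identical values and real effects", {
  t <- toy_table()
  cmp <- compare_to_baseline(t, "bvd")
  expect_true(all(cmp$p_value == 1))
  expect_true(all(cmp$stars == "ns"))
  expect_equal(nrow(cmp), 12L)                  # 3 later visits x 4 locations
  # a strong uniform increase is detected at the final visit
  tab <- generate_cohort(cohort_effect_model(n_patients = 40, seed = 14))
  cmp4 <- compare_to_baseline(tab, "bvd")
  expect_true(all(cmp4$stars[cmp4$visit == 4] != "ns"))
  w <- compare_to_baseline(tab, "bvd", test = "wilcoxon")
  expect_true(all(w$p_value >= 0 & w$p_value <= 1))
  # consecutive mode compares v with v-1
  cons <- compare_to_baseline(tab, "bvd", comparison = "consecutive")
  expect_equal(nrow(cons), 12L)
  tiny <- t[t$patient_id == "P1", ]
  expect_error(compare_to_baseline(tiny, "bvd"), "insufficient pairs")
})

test_that("null cohorts reject at the nominal 5% rate", {
  set.seed(99)
  hits <- logical(400)
  for (i in seq_along(hits)) {
    tab <- generate_cohort(null_cohort_model(12, seed = 10000 + i))
    sub <- tab[tab$location == "da" & tab$visit %in% c(1, 4), ]
    d <- sub$bvd[sub$visit == 4][order(sub$patient_id[sub$visit == 4])] -
      sub$bvd[sub$visit == 1][order(sub$patient_id[sub$visit == 1])]
    hits[i] <- t.test(d)$p.value < 0.05
  }
  rate <- mean(hits)
  band <- 1.96 * sqrt(0.05 * 0.95 / length(hits))
  expect_lt(abs(rate - 0.05), band + 1e-9)
})

test_that("correlation strength bands are left-closed at 0.1/0.3/0.5", {
  expect_identical(classify_correlation(c(0.05, 0.1, 0.299, 0.3, 0.499,
                                          0.5, 0.99)),
                   c("negligible", "weak", "weak", "moderate", "moderate",
                     "strong", "strong"))
  # the published coefficients classify as reported
  expect_identical(classify_correlation(c(0.310, 0.384)),
                   c("moderate", "moderate"))
  expect_identical(classify_correlation(c(0.754, 0.853, 0.721)),
                   c("strong", "strong", "strong"))
  expect_identical(classify_correlation(-0.754), "strong")
})

test_that("Pearson r is exact on affine data and invariant to rescaling", {
  t <- toy_table()[1:10, ]
  t$vhi <- 1:10
  t$vet_um <- 2 * t$vhi + 1
  r <- correlate_metrics(t, "vhi", "vet_um")
  expect_equal(r$r, 1)
  expect_identical(r$strength, "strong")
  set.seed(3)
  t$vsq <- rnorm(10)
  r0 <- correlate_metrics(t, "vhi", "vsq")$r
  t2 <- t; t2$vhi <- -3 * t2$vhi + 7
  expect_equal(correlate_metrics(t2, "vhi", "vsq")$r, -r0, tolerance = 1e-12)
  t$bvd <- 0.2
  expect_error(correlate_metrics(t, "bvd", "vhi"), "zero variance")
  expect_error(correlate_metrics(t[1:2, ], "vhi", "vsq"), "3 complete")
})

test_that("grouped correlations return one row per level", {
  tab <- generate_cohort(cohort_effect_model(n_patients = 30, seed = 8))
  by_visit <- correlate_metrics(tab, "vhi", "vet_um", group = "visit")
  expect_equal(nrow(by_visit), 4L)
  expect_true(all(abs(by_visit$r) <= 1))
})
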
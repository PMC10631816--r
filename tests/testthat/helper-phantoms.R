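# shared fixtures, all generated in code

small_geometry <- function(n_slow = 8L, n_repeats = 4L)
  phantom_geometry(n_depth = 64L, n_fast = 64L, n_slow = n_slow,
                   n_repeats = n_repeats)

medium_geometry <- function(n_slow = 24L)
  phantom_geometry(n_depth = 128L, n_fast = 128L, n_slow = n_slow,
                   n_repeats = 4L)

# independent-Rayleigh frame sequence (fully developed speckle, no structure)
rayleigh_frames <- function(nz, nx, n_frames, sigma = 1) {
  a <- sqrt(rnorm(nz * nx * n_frames)^2 + rnorm(nz * nx * n_frames)^2) * sigma
  array(a, dim = c(nz, nx, n_frames))
}

# literal transcription of the variance formula, one voxel at a time,
# including the lateral window; the reference the vectorized path is
# checked against
ibdv_naive <- function(a, window = 1L) {
  nz <- dim(a)[1]; nx <- dim(a)[2]; nf <- dim(a)[3]
  h <- (window - 1L) %/% 2L
  out <- matrix(0, nz, nx)
  for (z in seq_len(nz)) for (x in seq_len(nx)) {
    num <- 0; den <- 0
    for (xx in max(1L, x - h):min(nx, x + h)) {
      for (j in seq_len(nf - 1L)) {
        num <- num + a[z, xx, j] * a[z, xx, j + 1L]
        den <- den + (a[z, xx, j]^2 + a[z, xx, j + 1L]^2) / 2
      }
    }
    out[z, x] <- if (den == 0) 0 else 1 - num / den
  }
  out
}

# exhaustive-search Otsu: threshold maximizing between-class variance
otsu_sweep <- function(v, n_grid = 256L) {
  cand <- seq(min(v), max(v), length.out = n_grid)
  best <- cand[1]; best_var <- -Inf
  for (t in cand) {
    lo <- v[v < t]; hi <- v[v >= t]
    if (!length(lo) || !length(hi)) next
    w0 <- length(lo) / length(v); w1 <- 1 - w0
    bv <- w0 * w1 * (mean(lo) - mean(hi))^2
    if (bv > best_var) { best_var <- bv; best <- t }
  }
  best
}

# null cohort: no treatment effect, no location structure
null_cohort_model <- function(n_patients, seed)
  cohort_effect_model(n_patients = n_patients,
                      baseline_bvd_mean = 0.25, final_bvd_mean = 0.25,
                      baseline_vet_mean = 140, final_vet_mean = 140,
                      vhi_means = c(15, 15), vsq_means = c(9, 9),
                      bvd_location_offsets = zero_offsets(),
                      vet_location_offsets = zero_offsets(),
                      seed = seed)

zero_offsets <- function()
  matrix(0, 4, 2, dimnames = list(c("da", "dp", "pa", "pp"),
                                  c("baseline", "final")))

# standard error of a grand mean that respects patient-level clustering
# (records of one patient share a random effect)
clustered_se <- function(values, patient_ids) {
  pm <- tapply(values, patient_ids, mean)
  stats::sd(pm) / sqrt(length(pm))
}
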
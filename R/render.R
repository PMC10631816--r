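#' Render repeated OCT frames for one slow-axis position
#'
#' Simulates the repeated-B-scan acquisition that inter-frame angiography
#' consumes. Each voxel carries a complex circular-Gaussian speckle field
#' whose variance equals the local mean reflectivity, so amplitudes follow
#' fully developed (Rayleigh) speckle statistics. Static tissue keeps the
#' same speckle realization across repeats; vessel voxels evolve between
#' consecutive frames as
#' \code{field_new = sqrt(1 - d) * field_old + sqrt(d) * fresh_draw},
#' giving an inter-frame field correlation of \code{1 - d}. Additive complex
#' detection noise of mean-square amplitude \code{noise_floor^2} is drawn
#' independently per frame, so regions above the tissue surface show pure
#' noise-floor statistics.
#'
#' @param scene a \code{\link{make_tissue_scene}} result.
#' @param position slow-axis index (1-based).
#' @param decorrelation inter-frame speckle decorrelation inside vessels,
#'   in [0, 1]: 0 = static, 1 = fully independent draws per frame.
#' @param noise_floor amplitude scale of additive detection noise.
#' @param seed integer seed, or \code{NULL} to draw from the current RNG
#'   state (used when rendering whole volumes under one outer seed).
#' @return A \code{frame_sequence}: numeric array \code{[z, x, frame]} of
#'   non-negative amplitudes with the geometry attached as an attribute.
#' @export
render_frame_sequence <- function(scene, position = 1L, decorrelation = 1,
                                  noise_floor = 0.05, seed = NULL) {
  stopifnot(inherits(scene, "tissue_scene"))
  if (decorrelation < 0 || decorrelation > 1)
    stop("decorrelation must lie in [0, 1]")
  g <- scene$geometry
  if (position < 1L || position > g$n_slow) stop("position out of range")
  if (!is.null(seed)) set.seed(as.integer(seed))

  nz <- g$n_depth; nx <- g$n_fast; nf <- g$n_repeats
  refl <- reflectivity_bscan(scene, position)
  vmask <- scene$vessel_mask[, , position]

  cplx <- function(var) {
    s <- sqrt(var / 2)
    matrix(complex(real = rnorm(nz * nx, sd = 1),
                   imaginary = rnorm(nz * nx, sd = 1)), nz, nx) * s
  }
  field <- cplx(refl)
  d <- decorrelation
  out <- array(0, dim = c(nz, nx, nf))
  for (j in seq_len(nf)) {
    if (j > 1L && d > 0 && any(vmask)) {
      fresh <- cplx(refl)
      field[vmask] <- sqrt(1 - d) * field[vmask] + sqrt(d) * fresh[vmask]
    }
    noise <- if (noise_floor > 0) cplx(matrix(noise_floor^2, nz, nx)) else 0
    out[, , j] <- Mod(field + noise)
  }
  structure(out, geometry = g, position = as.integer(position),
            class = c("frame_sequence", "array"))
}

# mean-backscatter B-scan (z, x) implied by the scene at one slow position
reflectivity_bscan <- function(scene, position) {
  g <- scene$geometry
  nz <- g$n_depth; nx <- g$n_fast
  surf <- scene$surface_depth[, position]
  tpx <- scene$epi_thickness_px[, position]
  rf <- scene$reflectivity
  z <- matrix(seq_len(nz), nz, nx)
  su <- matrix(surf, nz, nx, byrow = TRUE)
  tp <- matrix(tpx, nz, nx, byrow = TRUE)
  refl <- matrix(0, nz, nx)
  refl[z >= su] <- rf$epithelium              # epithelium from the surface down
  refl[z >= su + tp] <- rf$lamina             # lamina propria below it
  sboost <- rep(rf$surface, nx)
  if (!is.null(scene$ablation_grid))
    sboost <- ifelse(scene$ablation_grid[, position], rf$surface * 1.5, sboost)
  surf_band <- z >= su & z <= su + 1          # 2-pixel specular surface line
  refl[surf_band] <- matrix(sboost, nz, nx, byrow = TRUE)[surf_band]
  refl
}

#' Render a whole phantom volume of repeated frames
#'
#' Renders \code{\link{render_frame_sequence}} at every slow-axis position
#' under a single outer seed, and averages the repeated frames into a
#' structural volume for segmentation.
#'
#' @inheritParams render_frame_sequence
#' @param seed integer seed controlling the whole volume.
#' @return A \code{phantom_volume}: list with \code{frames} (list of
#'   \code{frame_sequence} per slow position), \code{structural}
#'   (\code{[z, x, y]} mean amplitude across repeats), and the \code{scene}.
#' @export
render_phantom_volume <- function(scene, decorrelation = 1,
                                  noise_floor = 0.05, seed = 1L) {
  stopifnot(inherits(scene, "tissue_scene"))
  g <- scene$geometry
  set.seed(as.integer(seed))
  frames <- vector("list", g$n_slow)
  structural <- array(0, dim = c(g$n_depth, g$n_fast, g$n_slow))
  for (y in seq_len(g$n_slow)) {
    fs <- render_frame_sequence(scene, y, decorrelation, noise_floor,
                                seed = NULL)
    frames[[y]] <- fs
    structural[, , y] <- apply(fs, c(1, 2), mean)
  }
  structure(list(frames = frames, structural = structural, scene = scene,
                 params = list(decorrelation = decorrelation,
                               noise_floor = noise_floor,
                               seed = as.integer(seed))),
            class = "phantom_volume")
}
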
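#' Build a layered vaginal-wall phantom scene
#'
#' Constructs the ground-truth anatomy a simulated acquisition images: a
#' gently undulating air--tissue interface topped by a bright surface
#' reflection, a dark epithelium band of known thickness, a bright lamina
#' propria beneath it, and a 3-D network of vessel tubes embedded in the
#' lamina propria. Tube centerlines are random 3-D polylines with en-face
#' radius 1--4 pixels; tubes are added (and the last one trimmed) until the
#' en-face vessel area fraction is within 0.02 of \code{vessel_fraction}.
#'
#' The scene carries its generating parameters so downstream recovery tests
#' need no re-inference: true per-column boundaries, the true thickness
#' field, and the rasterized vessel mask are all stored.
#'
#' @param geometry a \code{\link{phantom_geometry}}.
#' @param thickness_um epithelial thickness in micrometres; a scalar or an
#'   \code{n_fast x n_slow} matrix.
#' @param vessel_fraction target en-face vessel area fraction in [0, 0.9].
#' @param seed integer RNG seed; identical seeds give bit-identical scenes.
#' @param surface_depth_px mean depth (pixels) of the tissue surface.
#' @param surface_undulation_px amplitude of smooth surface height variation.
#' @param vessel_radius_px range of tube radii in en-face pixels.
#' @param ablation_grid if \code{TRUE}, superimpose a grid-like pattern of
#'   enhanced surface reflectivity emulating a fractional-laser treatment
#'   footprint.
#' @param reflectivity named list of mean backscatter intensities for
#'   \code{surface}, \code{epithelium}, \code{lamina} (epithelium must be
#'   darker than lamina propria).
#' @return An object of class \code{tissue_scene}: a list with
#'   \code{geometry}, \code{surface_depth} (x by y matrix of 1-based depth
#'   indices), \code{epi_thickness_um} and \code{epi_thickness_px} (x by y),
#'   \code{vessel_mask} (z,x,y logical array), \code{vessel_fraction_true},
#'   \code{reflectivity}, and \code{params}.
#' @export
make_tissue_scene <- function(geometry,
                              thickness_um = 150,
                              vessel_fraction = 0.2,
                              seed = 1L,
                              surface_depth_px = NULL,
                              surface_undulation_px = 2,
                              vessel_radius_px = c(1L, 4L),
                              ablation_grid = FALSE,
                              reflectivity = list(surface = 1.0,
                                                  epithelium = 0.08,
                                                  lamina = 0.55)) {
  stopifnot(inherits(geometry, "phantom_geometry"))
  if (vessel_fraction < 0 || vessel_fraction > 0.9)
    stop("vessel_fraction must lie in [0, 0.9]")
  if (reflectivity$epithelium >= reflectivity$lamina)
    stop("epithelium must be darker than lamina propria")
  nz <- geometry$n_depth; nx <- geometry$n_fast; ny <- geometry$n_slow

  thick_um <- if (length(thickness_um) == 1L)
    matrix(thickness_um, nx, ny) else thickness_um
  if (!all(dim(thick_um) == c(nx, ny)))
    stop("thickness_um must be scalar or an n_fast x n_slow matrix")
  if (any(thick_um < 0)) stop("epithelial thickness must be >= 0")
  thick_px <- round(thick_um / geometry$axial_pixel_um)

  set.seed(as.integer(seed))

  if (is.null(surface_depth_px)) surface_depth_px <- max(8L, round(0.12 * nz))
  surf <- surface_depth_px +
    smooth_field(nx, ny, sigma = max(nx, ny) / 8) * surface_undulation_px
  surf <- matrix(as.integer(round(pmax(2, surf))), nx, ny)

  # vessels live in a lamina propria band below the deepest epithelium
  vessel_margin <- 3L
  band_lo <- max(surf + thick_px) + vessel_margin
  band_hi <- min(nz - 2L, band_lo + 12L)
  max_thick_um <- (nz - surface_depth_px - vessel_margin - 4L) *
    geometry$axial_pixel_um
  if (band_lo >= band_hi || any(surf + thick_px >= nz - 2L))
    stop(sprintf("epithelial thickness exceeds imaging depth; maximum representable thickness is about %.0f um",
                 max_thick_um))

  vm <- rasterize_vessel_tubes(nz, nx, ny, band_lo, band_hi,
                               target = vessel_fraction,
                               radius_range = vessel_radius_px)

  grid <- NULL
  if (isTRUE(ablation_grid)) {
    pitch <- max(8L, round(nx / 16))
    gx <- (seq_len(nx) %% pitch) < 2L
    gy <- (seq_len(ny) %% pitch) < 2L
    grid <- outer(gx, gy, `|`)
  }

  structure(list(geometry = geometry,
                 surface_depth = surf,
                 epi_thickness_um = thick_um,
                 epi_thickness_px = thick_px,
                 vessel_mask = vm$mask,
                 vessel_fraction_true = vm$fraction,
                 vessel_depth_band = c(band_lo, band_hi),
                 ablation_grid = grid,
                 reflectivity = reflectivity,
                 params = list(thickness_um = thickness_um,
                               vessel_fraction = vessel_fraction,
                               seed = as.integer(seed))),
            class = "tissue_scene")
}

#' @export
print.tissue_scene <- function(x, ...) {
  g <- x$geometry
  cat(sprintf("tissue_scene: %d x %d x %d, epithelium %.0f-%.0f um, vessel fraction %.3f\n",
              g$n_depth, g$n_fast, g$n_slow, min(x$epi_thickness_um),
              max(x$epi_thickness_um), x$vessel_fraction_true))
  invisible(x)
}

# smooth zero-mean random field (a few low-frequency sinusoids), unit SD
smooth_field <- function(nx, ny, sigma) {
  xs <- seq_len(nx) / nx; ys <- seq_len(ny) / ny
  f <- matrix(0, nx, ny)
  for (k in 1:3) {
    p <- sample(1:2, 1); q <- sample(1:2, 1); phi <- runif(2, 0, 2 * pi)
    f <- f + rnorm(1) * outer(sin(2 * pi * p * xs + phi[1]),
                              sin(2 * pi * q * ys + phi[2]))
  }
  s <- stats::sd(f)
  if (s > 0) f / s else f
}

# Random-walk tube centerlines, dilated to radius r in (x,y) and z.
# Tubes are appended until the en-face area fraction reaches `target`;
# the final tube stops mid-stroke, so the achieved fraction lands within
# a pixel-quantization step (< 0.02) of the target.
rasterize_vessel_tubes <- function(nz, nx, ny, band_lo, band_hi, target,
                                   radius_range) {
  mask <- array(FALSE, dim = c(nz, nx, ny))
  enface <- matrix(FALSE, nx, ny)
  if (target <= 0)
    return(list(mask = mask, fraction = 0))
  frac <- 0
  guard <- 0L
  while (frac < target && guard < 10000L) {
    guard <- guard + 1L
    x <- runif(1, 1, nx); y <- runif(1, 1, ny)
    z0 <- runif(1, band_lo + 1, band_hi - 1)
    ang <- runif(1, 0, 2 * pi)
    r <- sample(seq(radius_range[1], radius_range[2]), 1L)
    rz <- r                                     # round tube cross-section
    for (step in seq_len(6L * max(nx, ny))) {
      ang <- ang + rnorm(1, 0, 0.15)
      z0 <- min(max(z0 + rnorm(1, 0, 0.2), band_lo + 1), band_hi - 1)
      x <- x + cos(ang); y <- y + sin(ang)
      if (x < 1 || x > nx || y < 1 || y > ny) break
      xi <- round(x); yi <- round(y); zi <- round(z0)
      xs <- max(1L, xi - r):min(nx, xi + r)
      ys <- max(1L, yi - r):min(ny, yi + r)
      zs <- max(band_lo, zi - rz):min(band_hi, zi + rz)
      disc <- outer((xs - xi)^2, (ys - yi)^2, `+`) <= r^2
      enface[xs, ys] <- enface[xs, ys] | disc
      for (z in zs) mask[z, xs, ys][disc] <- TRUE
      frac <- mean(enface)
      if (frac >= target) break
    }
  }
  list(mask = mask, fraction = mean(enface))
}

#' En-face vessel area fraction of a scene's ground-truth mask
#'
#' @param scene a \code{\link{make_tissue_scene}} result.
#' @return fraction of en-face pixels whose A-line intersects a vessel tube.
#' @export
scene_enface_fraction <- function(scene) {
  mean(apply(scene$vessel_mask, c(2, 3), any))
}
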
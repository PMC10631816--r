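#' Phantom scan geometry
#'
#' Describes the voxel grid of a simulated OCT acquisition: depth samples per
#' A-line, A-lines per B-scan, B-scan (slow-axis) positions, physical pixel
#' pitch, and the number of repeated frames acquired at each slow-axis
#' position for angiography.
#'
#' Defaults emulate a large-field endoscopic scan: a 9 x 9 mm lateral field
#' sampled at 256 A-lines (about 35 um lateral pitch) and a 14 um axial
#' pixel, with 4 repeated frames per position.
#'
#' @param n_depth depth samples per A-line (z).
#' @param n_fast A-lines per B-scan (x).
#' @param n_slow slow-axis B-scan positions (y).
#' @param axial_pixel_um depth pixel size in micrometres.
#' @param lateral_pixel_um lateral pixel size in micrometres.
#' @param n_repeats repeated frames per slow-axis position (>= 2).
#' @return An object of class \code{phantom_geometry}.
#' @export
#' @examples
#' g <- phantom_geometry(n_depth = 128, n_fast = 128, n_slow = 16)
#' g
phantom_geometry <- function(n_depth = 256L, n_fast = 256L, n_slow = 64L,
                             axial_pixel_um = 14, lateral_pixel_um = 9000 / 256,
                             n_repeats = 4L) {
  n_depth <- as.integer(n_depth); n_fast <- as.integer(n_fast)
  n_slow <- as.integer(n_slow); n_repeats <- as.integer(n_repeats)
  if (any(c(n_depth, n_fast, n_slow) < 8L))
    stop("grid counts (n_depth, n_fast, n_slow) must all be >= 8")
  if (n_repeats < 2L)
    stop("n_repeats must be >= 2 (angiography needs repeated frames)")
  if (axial_pixel_um <= 0 || lateral_pixel_um <= 0)
    stop("pixel sizes must be positive")
  structure(list(n_depth = n_depth, n_fast = n_fast, n_slow = n_slow,
                 axial_pixel_um = axial_pixel_um,
                 lateral_pixel_um = lateral_pixel_um,
                 n_repeats = n_repeats),
            class = "phantom_geometry")
}

#' @export
print.phantom_geometry <- function(x, ...) {
  cat(sprintf("phantom_geometry: %d (z) x %d (x) x %d (y), %g um axial, %g um lateral, %d repeats\n",
              x$n_depth, x$n_fast, x$n_slow, x$axial_pixel_um,
              x$lateral_pixel_um, x$n_repeats))
  invisible(x)
}
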
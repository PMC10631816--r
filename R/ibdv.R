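#' Intensity-based Doppler variance of a repeated-frame sequence
#'
#' Computes the amplitude-only Doppler-variance flow contrast
#' \deqn{\sigma^2 = 1 - \frac{\sum_j A_j A_{j+1}}{\sum_j (A_j^2 + A_{j+1}^2)/2}}
#' where the sum runs over the J consecutive pairs formed by the J+1
#' acquired frames (inter-frame pairing: same A-line, same depth, repeated
#' B-scans) and, optionally, over a lateral averaging window centred on each
#' A-line. Static tissue, whose speckle is identical across repeats, gives
#' exactly 0; fully decorrelated speckle approaches the Rayleigh asymptote
#' \eqn{1 - \pi/4}. By the AM--GM inequality the statistic always lies in
#' [0, 1] for non-negative amplitudes. Voxels whose denominator is zero
#' (no signal at all, e.g. air) are defined as \eqn{\sigma^2 = 0} so the
#' background stays dark.
#'
#' Intra-frame pairing (neighbouring A-lines within each frame, the shorter
#' time-scale variant) is available via \code{pairing = "intraframe"}; the
#' inter-frame form is the default because its longer inter-sample interval
#' gives higher flow sensitivity.
#'
#' @param seq a \code{frame_sequence}: numeric array \code{[z, x, frame]}
#'   of non-negative amplitudes with at least 2 frames.
#' @param lateral_window odd number of A-lines pooled into each output
#'   A-line's sums (1 = none, default 3; windows are truncated at image
#'   edges).
#' @param pairing \code{"interframe"} (default) or \code{"intraframe"}.
#' @return numeric matrix \code{[z, x]} of \eqn{\sigma^2} values in [0, 1].
#' @export
compute_ibdv <- function(seq, lateral_window = 3L,
                         pairing = c("interframe", "intraframe")) {
  pairing <- match.arg(pairing)
  a <- unclass(seq)
  if (length(dim(a)) == 2L) dim(a) <- c(dim(a), 1L)
  if (length(dim(a)) != 3L) stop("seq must be a [z, x, frame] array")
  nf <- dim(a)[3]
  if (nf < 2L) stop("inter-frame variance needs >=2 frames")
  if (any(a < 0)) stop("amplitudes must be non-negative")
  w <- as.integer(lateral_window)
  if (w < 1L || w %% 2L == 0L) stop("lateral_window must be an odd count >= 1")

  nz <- dim(a)[1]; nx <- dim(a)[2]
  num <- matrix(0, nz, nx); den <- matrix(0, nz, nx)
  if (pairing == "interframe") {
    for (j in seq_len(nf - 1L)) {
      a1 <- a[, , j]; a2 <- a[, , j + 1L]
      num <- num + a1 * a2
      den <- den + (a1 * a1 + a2 * a2) / 2
    }
  } else {
    if (nx < 2L) stop("intra-frame pairing needs >=2 A-lines")
    for (j in seq_len(nf)) {
      f <- a[, , j]
      p <- f[, -nx, drop = FALSE] * f[, -1L, drop = FALSE]
      q <- (f[, -nx, drop = FALSE]^2 + f[, -1L, drop = FALSE]^2) / 2
      # pair (x, x+1) contributes to output column x; last column reuses
      # its left pair so the output keeps the input width
      num <- num + cbind(p, p[, nx - 1L])
      den <- den + cbind(q, q[, nx - 1L])
    }
  }
  if (w > 1L) {
    num <- box_sum_cols(num, w)
    den <- box_sum_cols(den, w)
  }
  s2 <- 1 - num / den
  s2[den == 0] <- 0
  s2 <- pmin(pmax(s2, 0), 1)
  attr(s2, "provenance") <- list(J = nf - 1L, pairing = pairing,
                                 lateral_window = w)
  s2
}

# running sum over a centred window of w columns, truncated at the edges
box_sum_cols <- function(m, w) {
  h <- (w - 1L) %/% 2L
  nx <- ncol(m)
  cs <- cbind(0, t(apply(m, 1L, cumsum)))
  lo <- pmax(seq_len(nx) - h, 1L)
  hi <- pmin(seq_len(nx) + h, nx)
  cs[, hi + 1L, drop = FALSE] - cs[, lo, drop = FALSE]
}

#' Doppler-variance volume from repeated frames at every slow position
#'
#' Applies \code{\link{compute_ibdv}} at each slow-axis position of a
#' rendered (or loaded) volume.
#'
#' @param volume a \code{phantom_volume}, or a list of \code{frame_sequence}
#'   arrays (one per slow position, identical shapes).
#' @inheritParams compute_ibdv
#' @return a \code{variance_volume}: numeric array \code{[z, x, y]} of
#'   \eqn{\sigma^2} values with provenance attached.
#' @export
compute_ibdv_volume <- function(volume, lateral_window = 3L,
                                pairing = c("interframe", "intraframe")) {
  pairing <- match.arg(pairing)
  frames <- if (inherits(volume, "phantom_volume")) volume$frames else volume
  if (!is.list(frames) || length(frames) == 0L)
    stop("volume must be a phantom_volume or non-empty list of frame sequences")
  dims <- lapply(frames, function(f) dim(unclass(f)))
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1L)
    stop("all slow positions must share the same frame-sequence shape")
  planes <- lapply(frames, compute_ibdv, lateral_window = lateral_window,
                   pairing = pairing)
  out <- array(unlist(planes, use.names = FALSE),
               dim = c(dims[[1]][1], dims[[1]][2], length(planes)))
  attr(out, "provenance") <- attr(planes[[1]], "provenance")
  class(out) <- c("variance_volume", "array")
  out
}

#' En-face projection of a Doppler-variance volume
#'
#' Averages \eqn{\sigma^2} over a depth slab, producing the 2-D angiogram
#' viewed from the tissue surface.
#'
#' @param vol a \code{variance_volume} (\code{[z, x, y]} array).
#' @param z_range inclusive 1-based depth index range \code{c(lo, hi)};
#'   default spans the full depth.
#' @return an \code{enface_map}: numeric matrix \code{[x, y]} with the slab
#'   bounds attached.
#' @export
enface_project <- function(vol, z_range = NULL) {
  a <- unclass(vol)
  if (length(dim(a)) != 3L) stop("vol must be a [z, x, y] array")
  nz <- dim(a)[1]
  if (is.null(z_range)) z_range <- c(1L, nz)
  z_lo <- as.integer(z_range[1]); z_hi <- as.integer(z_range[2])
  if (z_lo < 1L || z_hi > nz || z_lo > z_hi)
    stop("empty or out-of-range depth slab")
  m <- apply(a[z_lo:z_hi, , , drop = FALSE], c(2, 3), mean)
  structure(m, z_range = c(z_lo, z_hi), class = c("enface_map", "matrix"))
}
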
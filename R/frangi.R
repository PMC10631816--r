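#' Multi-scale Frangi vesselness of an en-face angiogram
#'
#' Scores how tube-like each pixel's neighbourhood is from the eigenvalues
#' of the scale-normalized Gaussian Hessian. At each scale \eqn{s} the image
#' is convolved with second-derivative-of-Gaussian kernels, the Hessian
#' eigenvalues are ordered \eqn{|\lambda_1| \le |\lambda_2|}, and the
#' response is
#' \deqn{v = \exp(-R_b^2 / 2\beta^2)\,(1 - \exp(-S^2 / 2c^2))}
#' with blobness \eqn{R_b = \lambda_1/\lambda_2} and structure strength
#' \eqn{S = \sqrt{\lambda_1^2 + \lambda_2^2}}, set to 0 wherever
#' \eqn{\lambda_2 \ge 0} (bright-vessel polarity: flow is bright in
#' Doppler-variance angiograms, so a vessel cross-section is a ridge with a
#' strongly negative principal curvature). The final map is the maximum
#' over scales, normalized to [0, 1].
#'
#' @param map numeric matrix (an \code{enface_map} or any 2-D image), at
#'   least 5 pixels in each dimension.
#' @param scales Gaussian standard deviations in pixels, matched to the
#'   expected vessel radii; default 1--4.
#' @param beta blobness sensitivity (default 0.5, the conventional value).
#' @param c structure-strength sensitivity; \code{NULL} (default) sets it
#'   per scale to half the maximum Hessian norm, the usual auto-scaling.
#' @param alpha accepted for interface compatibility with the 3-D filter;
#'   unused in 2-D.
#' @return a \code{vesselness_map}: numeric matrix in [0, 1] (identically 0
#'   for constant images) with the scales and parameters attached.
#' @export
frangi_vesselness <- function(map, scales = c(1, 2, 3, 4), beta = 0.5,
                              c = NULL, alpha = NULL) {
  img <- unclass(map)
  if (!is.matrix(img)) stop("map must be a 2-D matrix")
  if (any(dim(img) < 5L))
    stop("image must be at least 5 pixels in each dimension")
  if (length(scales) == 0L || any(scales <= 0))
    stop("scales must be a non-empty set of positive values")

  out <- matrix(0, nrow(img), ncol(img))
  if (diff(range(img)) == 0)                    # constant image: zero Hessian
    return(structure(out, scales = scales, beta = beta, c = c,
                     class = c("vesselness_map", "matrix")))
  for (s in scales) {
    H <- gaussian_hessian(img, s)
    # eigenvalues of the symmetric 2x2 Hessian, ordered by magnitude
    root <- sqrt((H$xx - H$yy)^2 + 4 * H$xy^2)
    e1 <- (H$xx + H$yy + root) / 2
    e2 <- (H$xx + H$yy - root) / 2
    swap <- abs(e1) > abs(e2)
    lam1 <- ifelse(swap, e2, e1)
    lam2 <- ifelse(swap, e1, e2)
    S2 <- lam1^2 + lam2^2
    Rb2 <- ifelse(lam2 == 0, 0, (lam1 / lam2)^2)
    c_eff <- if (is.null(c)) max(sqrt(S2)) / 2 else c
    if (c_eff == 0) next                        # constant image at this scale
    v <- exp(-Rb2 / (2 * beta^2)) * (1 - exp(-S2 / (2 * c_eff^2)))
    v[lam2 >= 0] <- 0
    out <- pmax(out, v)
  }
  if (max(out) > 0) out <- out / max(out)
  structure(out, scales = scales, beta = beta, c = c,
            class = c("vesselness_map", "matrix"))
}

# scale-normalized (gamma = 2) Gaussian Hessian via separable convolution
gaussian_hessian <- function(img, s) {
  r <- ceiling(3 * s)
  u <- seq(-r, r)
  g <- dnorm(u, sd = s); g <- g / sum(g)
  d2 <- g * (u^2 / s^4 - 1 / s^2)               # second derivative of Gaussian
  d1 <- g * (-u / s^2)                          # first derivative
  conv <- function(k) filter2_replicate(img, k)
  list(xx = s^2 * conv(outer(d2, g)),
       yy = s^2 * conv(outer(g, d2)),
       xy = s^2 * conv(outer(d1, d1)))
}

# 2-D convolution with replicate (edge-extend) boundary handling that also
# works when the kernel is larger than the image: pad, filter, crop
filter2_replicate <- function(img, k) {
  r <- (dim(k) - 1L) %/% 2L
  padded <- img[pmin(pmax(seq_len(nrow(img) + 2L * r[1]) - r[1], 1L),
                     nrow(img)),
                pmin(pmax(seq_len(ncol(img) + 2L * r[2]) - r[2], 1L),
                     ncol(img)), drop = FALSE]
  out <- EBImage::filter2(padded, k, boundary = "circular")
  as.matrix(out)[r[1] + seq_len(nrow(img)), r[2] + seq_len(ncol(img)),
                 drop = FALSE]
}
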
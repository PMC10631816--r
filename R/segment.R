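#' Classical epithelium segmentation of a structural B-scan
#'
#' Tracks the two dark-to-bright boundaries that delimit the epithelium in
#' a vaginal-wall B-scan: the air-to-surface-reflection transition on top,
#' and the epithelium-to-lamina-propria transition below (the epithelium is
#' the dark band between the bright surface reflection and the bright
#' lamina propria). Each boundary is found per column as a prominent
#' positive axial intensity gradient and refined by a dynamic-programming
#' shortest path across columns with a smoothness penalty on vertical jumps,
#' so single-column speckle outliers cannot pull the boundary away.
#'
#' Columns where no sufficiently strong lower transition exists are either
#' declared zero-thickness (when the tissue immediately below the surface
#' is already bright, i.e. lamina propria with no dark band) or marked
#' invalid (dark but featureless, e.g. shadowed).
#'
#' @param bscan numeric matrix \code{[z, x]}, depth in rows, at least 16
#'   pixels deep.
#' @param smoothing_sigma Gaussian pre-smoothing SDs in pixels,
#'   \code{c(axial, lateral)}.
#' @param min_thickness_px,max_thickness_px admissible epithelial thickness
#'   gate in pixels (defaults 3--60, i.e. roughly 40--840 um at 14 um/px,
#'   generous around the 100--200 um range typical of the atrophic and
#'   healthy epithelium).
#' @param jump_cost smoothness penalty weight: each pixel of vertical jump
#'   between neighbouring columns costs \code{0.1 * jump_cost} in units of
#'   the normalized gradient (default 2).
#' @return an \code{epithelium_segmentation}: list with logical \code{mask}
#'   (\code{[z, x]}, true exactly on rows \code{upper <= z < lower}),
#'   integer vectors \code{upper} and \code{lower} (1-based depth indices;
#'   \code{NA} where invalid), logical \code{valid}, and \code{method}.
#' @export
segment_epithelium_classical <- function(bscan,
                                         smoothing_sigma = c(1, 2),
                                         min_thickness_px = 3L,
                                         max_thickness_px = 60L,
                                         jump_cost = 2) {
  img <- unclass(bscan)
  if (!is.matrix(img)) stop("bscan must be a 2-D matrix")
  nz <- nrow(img); nx <- ncol(img)
  if (nz < 16L) stop("image must be at least 16 pixels deep")

  sm <- separable_blur(img, smoothing_sigma[1], smoothing_sigma[2])
  M <- stats::quantile(sm, 0.99)
  if (M <= 0) stop("surface not found: image has no signal")
  sm <- sm / M

  # raw surface estimate: first strong crossing per column
  cross <- apply(sm >= 0.5, 2, function(col) {
    w <- which(col); if (length(w)) w[1] else NA_integer_
  })
  found <- !is.na(cross)
  if (mean(found) < 0.2)
    stop("surface not found: no coherent air-tissue interface")
  cross[!found] <- stats::median(cross[found])
  # a real interface separates dark air from bright tissue; featureless
  # speckle has no such contrast
  air_px <- unlist(lapply(which(found), function(x)
    if (cross[x] > 4L) sm[1:(cross[x] - 3L), x]))
  tissue_px <- unlist(lapply(which(found), function(x)
    sm[cross[x]:min(nz, cross[x] + 8L), x]))
  if (length(air_px) < 10L || mean(air_px) > 0.3 * mean(tissue_px))
    stop("surface not found: no dark air region above a bright interface")

  # shared boundary cost: negative axial dark-to-bright gradient, so both
  # the air->surface and epithelium->lamina transitions are minima
  grad <- rbind(0, diff(sm))
  gmax <- max(abs(grad)); if (gmax > 0) grad <- grad / gmax
  lambda <- 0.1 * jump_cost
  BIG <- 1e6

  cost_up <- -grad
  band <- abs(row(cost_up) - matrix(cross, nz, nx, byrow = TRUE)) > 4
  cost_up[band] <- cost_up[band] + BIG
  upper <- dp_track(cost_up, lambda)

  zs <- row(grad)
  ub <- matrix(upper, nz, nx, byrow = TRUE)
  in_gate <- zs >= ub + min_thickness_px & zs <= ub + max_thickness_px
  cost_lo <- -grad
  cost_lo[!in_gate] <- BIG
  lower <- dp_track(cost_lo, lambda)

  # per-column validity / zero-thickness resolution: a genuine epithelium
  # is a dark band between the (bright) boundaries; if the stretch between
  # the tracked boundaries is about as bright as the tissue below, there is
  # no band -- the layer is absent (thickness 0) when that tissue is bright,
  # and the column is unusable when everything below is dark
  # darkness statistics use a laterally-smoothed image only, so the bright
  # surface line and lamina do not bleed axially into a thin band
  sml <- separable_blur(img, 0, max(smoothing_sigma[2], 2)) / M
  valid <- rep(TRUE, nx)
  for (x in seq_len(nx)) {
    surf_skip <- 2L                              # clear the surface line
    band <- if (lower[x] - upper[x] > surf_skip + 1L)
      sml[(upper[x] + surf_skip):(lower[x] - 1L), x] else numeric()
    below <- sml[lower[x]:min(nz, lower[x] + 4L), x]
    dark_band <- length(band) > 0L && mean(band) < 0.6 * mean(below)
    if (!dark_band) {
      probe <- sml[(upper[x] + surf_skip):min(nz, upper[x] + surf_skip + 6L),
                   x]
      if (mean(probe) >= 0.3) lower[x] <- upper[x]  # bright below: t = 0
      else valid[x] <- FALSE
    }
  }
  lower[valid] <- pmax(lower[valid], upper[valid])
  upper[!valid] <- NA_integer_; lower[!valid] <- NA_integer_

  mask <- matrix(FALSE, nz, nx)
  for (x in which(valid))
    if (lower[x] > upper[x]) mask[upper[x]:(lower[x] - 1L), x] <- TRUE

  structure(list(mask = mask, upper = upper, lower = lower, valid = valid,
                 method = "classical"),
            class = "epithelium_segmentation")
}

separable_blur <- function(img, sig_z, sig_x) {
  kern <- function(s) {
    if (s <= 0) return(1)
    u <- seq(-ceiling(3 * s), ceiling(3 * s))
    k <- dnorm(u, sd = s); k / sum(k)
  }
  filter2_replicate(img, outer(kern(sig_z), kern(sig_x)))
}

# shortest path through a cost image, one node per column, |jump| penalty;
# the min-convolution with lambda*|dz| is done with two linear passes
dp_track <- function(cost, lambda) {
  nz <- nrow(cost); nx <- ncol(cost)
  C <- cost
  if (nx > 1L) for (x in 2:nx) {
    m <- C[, x - 1L]
    for (z in 2:nz) m[z] <- min(m[z], m[z - 1L] + lambda)
    for (z in (nz - 1L):1L) m[z] <- min(m[z], m[z + 1L] + lambda)
    C[, x] <- cost[, x] + m
  }
  path <- integer(nx)
  path[nx] <- which.min(C[, nx])
  if (nx > 1L) for (x in (nx - 1L):1L)
    path[x] <- which.min(C[, x] + lambda * abs(seq_len(nz) - path[x + 1L]))
  path
}

#' Epithelial thickness profile from a segmentation
#'
#' Converts per-column boundary indices into a thickness profile in
#' micrometres and a scan-level mean vaginal epithelial thickness (VET).
#'
#' @param seg an \code{epithelium_segmentation}.
#' @param axial_pixel_um depth pixel size in micrometres (default 14).
#' @return a \code{vet_profile}: list with \code{thickness_um} per column
#'   (\code{NA} where the segmentation is invalid), \code{mean_vet_um}
#'   averaged over valid columns, \code{validity} (fraction of valid
#'   columns) and \code{axial_pixel_um}.
#' @export
compute_vet <- function(seg, axial_pixel_um = 14) {
  stopifnot(inherits(seg, "epithelium_segmentation"))
  if (!any(seg$valid)) stop("no valid columns: cannot measure thickness")
  t_px <- seg$lower - seg$upper
  t_um <- t_px * axial_pixel_um
  structure(list(thickness_um = t_um,
                 mean_vet_um = mean(t_um[seg$valid]),
                 validity = mean(seg$valid),
                 axial_pixel_um = axial_pixel_um),
            class = "vet_profile")
}

#' @export
print.vet_profile <- function(x, ...) {
  cat(sprintf("VET = %.1f um (validity %.0f%%)\n", x$mean_vet_um,
              100 * x$validity))
  invisible(x)
}

#' Overlap metrics between a predicted and a reference mask
#'
#' @param pred,truth logical matrices of identical shape.
#' @return a \code{segmentation_score}: list with \code{pixel_accuracy},
#'   \code{iou} and \code{dice}, each in [0, 1]. Two empty masks score
#'   (1, 1, 1) by convention.
#' @export
evaluate_segmentation <- function(pred, truth) {
  p <- as.logical(unclass(pred)); t <- as.logical(unclass(truth))
  if (!all(dim(unclass(pred)) == dim(unclass(truth))))
    stop("pred and truth must have the same shape")
  inter <- sum(p & t); uni <- sum(p | t)
  acc <- mean(p == t)
  iou <- if (uni == 0L) 1 else inter / uni
  dice <- if (sum(p) + sum(t) == 0L) 1 else 2 * inter / (sum(p) + sum(t))
  structure(list(pixel_accuracy = acc, iou = iou, dice = dice),
            class = "segmentation_score")
}
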
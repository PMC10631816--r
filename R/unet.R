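#' @name unet
#' @title Lightweight encoder-decoder segmentation network
#'
#' @description
#' A small 3-level encoder-decoder convolutional network with skip
#' connections (the U-Net family) for per-pixel epithelium probability
#' maps. Channels 8/16/32 at the three levels, 3x3 convolutions with ReLU,
#' 2x2 max-pooling, nearest-neighbour upsampling, and a sigmoid 1x1 output
#' head. It is trained with the sum of binary cross-entropy and soft-Dice
#' loss under Adam. The implementation is plain R built on im2col matrix
#' multiplication; at this scale (64 x 64 inputs, ~120k weights) no
#' deep-learning framework is needed and training is fully deterministic
#' under a seed.
NULL

unet_channels <- list(c1 = 8L, c2 = 16L, c3 = 32L)

#' Initialize an untrained network
#'
#' @param input_size image size \code{c(depth, width)}; both must be
#'   divisible by 4.
#' @param seed integer seed for He-normal weight initialization.
#' @return an untrained \code{unet_model}.
#' @export
unet_init <- function(input_size = c(64L, 64L), seed = 1L) {
  if (any(input_size %% 4L != 0L))
    stop("input_size must be divisible by 4 (two pooling levels)")
  set.seed(as.integer(seed))
  ch <- unet_channels
  he <- function(n_in, n_out)
    matrix(rnorm(n_in * n_out, sd = sqrt(2 / n_in)), n_in, n_out)
  w <- list(
    W1 = he(9 * 1, ch$c1),          b1 = numeric(ch$c1),
    W2 = he(9 * ch$c1, ch$c1),      b2 = numeric(ch$c1),
    W3 = he(9 * ch$c1, ch$c2),      b3 = numeric(ch$c2),
    W4 = he(9 * ch$c2, ch$c3),      b4 = numeric(ch$c3),
    W5 = he(9 * (ch$c3 + ch$c2), ch$c2), b5 = numeric(ch$c2),
    W6 = he(9 * (ch$c2 + ch$c1), ch$c1), b6 = numeric(ch$c1),
    W7 = he(1 * ch$c1, 1L),         b7 = numeric(1L))
  structure(list(weights = w, input_size = as.integer(input_size),
                 trained = FALSE, history = NULL),
            class = "unet_model")
}

# ---- array plumbing -------------------------------------------------------

im2col3 <- function(x) {
  H <- dim(x)[1]; W <- dim(x)[2]; C <- dim(x)[3]
  xp <- array(0, c(H + 2L, W + 2L, C))
  xp[2:(H + 1L), 2:(W + 1L), ] <- x
  cols <- matrix(0, H * W, 9L * C)
  k <- 0L
  for (c in seq_len(C)) for (dx in 0:2) for (dz in 0:2) {
    k <- k + 1L
    cols[, k] <- xp[(1:H) + dz, (1:W) + dx, c]
  }
  cols
}

col2im3 <- function(dcols, H, W, C) {
  dxp <- array(0, c(H + 2L, W + 2L, C))
  k <- 0L
  for (c in seq_len(C)) for (dx in 0:2) for (dz in 0:2) {
    k <- k + 1L
    dxp[(1:H) + dz, (1:W) + dx, c] <-
      dxp[(1:H) + dz, (1:W) + dx, c] + matrix(dcols[, k], H, W)
  }
  dxp[2:(H + 1L), 2:(W + 1L), , drop = FALSE]
}

conv_fwd <- function(x, Wm, b) {
  H <- dim(x)[1]; W2 <- dim(x)[2]
  cols <- im2col3(x)
  out <- sweep(cols %*% Wm, 2L, b, `+`)
  list(y = array(out, c(H, W2, ncol(Wm))), cols = cols)
}

conv_bwd <- function(dy, cache_cols, Wm, H, W2, Cin) {
  dmat <- matrix(dy, H * W2, dim(dy)[3])
  list(dW = crossprod(cache_cols, dmat),
       db = colSums(dmat),
       dx = col2im3(dmat %*% t(Wm), H, W2, Cin))
}

pool2_fwd <- function(x) {
  H <- dim(x)[1]; W <- dim(x)[2]
  i1 <- seq(1L, H, 2L); i2 <- seq(2L, H, 2L)
  j1 <- seq(1L, W, 2L); j2 <- seq(2L, W, 2L)
  a <- x[i1, j1, , drop = FALSE]; b <- x[i2, j1, , drop = FALSE]
  cc <- x[i1, j2, , drop = FALSE]; d <- x[i2, j2, , drop = FALSE]
  y <- pmax(a, b, cc, d)
  list(y = y, m = list(a = a == y, b = b == y, cc = cc == y, d = d == y))
}

pool2_bwd <- function(dy, m, H, W) {
  dx <- array(0, c(H, W, dim(dy)[3]))
  i1 <- seq(1L, H, 2L); i2 <- seq(2L, H, 2L)
  j1 <- seq(1L, W, 2L); j2 <- seq(2L, W, 2L)
  ma <- m$a; mb <- m$b & !ma; mc <- m$cc & !ma & !mb
  md <- m$d & !ma & !mb & !mc
  dx[i1, j1, ] <- dy * ma; dx[i2, j1, ] <- dy * mb
  dx[i1, j2, ] <- dy * mc; dx[i2, j2, ] <- dy * md
  dx
}

up2 <- function(x) {
  H <- dim(x)[1]; W <- dim(x)[2]
  x[rep(seq_len(H), each = 2L), rep(seq_len(W), each = 2L), , drop = FALSE]
}

up2_bwd <- function(dy) {
  H <- dim(dy)[1]; W <- dim(dy)[2]
  i1 <- seq(1L, H, 2L); i2 <- seq(2L, H, 2L)
  j1 <- seq(1L, W, 2L); j2 <- seq(2L, W, 2L)
  dy[i1, j1, , drop = FALSE] + dy[i2, j1, , drop = FALSE] +
    dy[i1, j2, , drop = FALSE] + dy[i2, j2, , drop = FALSE]
}

cat3 <- function(a, b) {
  array(c(a, b), c(dim(a)[1], dim(a)[2], dim(a)[3] + dim(b)[3]))
}

unet_forward <- function(w, x, keep_cache = FALSE) {
  ch <- unet_channels
  H <- dim(x)[1]; W2 <- dim(x)[2]
  f1 <- conv_fwd(x, w$W1, w$b1);  a1 <- pmax(f1$y, 0)
  f2 <- conv_fwd(a1, w$W2, w$b2); e1 <- pmax(f2$y, 0)
  p1 <- pool2_fwd(e1)
  f3 <- conv_fwd(p1$y, w$W3, w$b3); e2 <- pmax(f3$y, 0)
  p2 <- pool2_fwd(e2)
  f4 <- conv_fwd(p2$y, w$W4, w$b4); bneck <- pmax(f4$y, 0)
  u2 <- cat3(up2(bneck), e2)
  f5 <- conv_fwd(u2, w$W5, w$b5); d2 <- pmax(f5$y, 0)
  u1 <- cat3(up2(d2), e1)
  f6 <- conv_fwd(u1, w$W6, w$b6); d1 <- pmax(f6$y, 0)
  z <- sweep(matrix(d1, H * W2, ch$c1) %*% w$W7, 2L, w$b7, `+`)
  p <- 1 / (1 + exp(-z))
  res <- list(p = matrix(p, H, W2))
  if (keep_cache)
    res$cache <- list(x = x, f1 = f1, a1 = a1, f2 = f2, e1 = e1, p1 = p1,
                      f3 = f3, e2 = e2, p2 = p2, f4 = f4, bneck = bneck,
                      u2 = u2, f5 = f5, d2 = d2, u1 = u1, f6 = f6, d1 = d1,
                      z = z)
  res
}

unet_backward <- function(w, fwd, y) {
  ch <- unet_channels
  cc <- fwd$cache
  H <- dim(cc$x)[1]; W2 <- dim(cc$x)[2]
  p <- as.vector(fwd$p); yv <- as.vector(y)
  N <- length(yv)
  eps <- 1
  sp <- sum(p); sy <- sum(yv); spy <- sum(p * yv)
  dice_den <- sp + sy + eps
  # d(BCE)/dz = (p - y)/N ; d(1 - dice)/dp chained through the sigmoid
  d_dice_dp <- -(2 * yv * dice_den - (2 * spy + eps)) / dice_den^2
  dz <- (p - yv) / N + d_dice_dp * p * (1 - p)

  d1m <- matrix(cc$d1, H * W2, ch$c1)
  dW7 <- crossprod(d1m, matrix(dz, ncol = 1)); db7 <- sum(dz)
  dd1 <- array(matrix(dz, ncol = 1) %*% t(w$W7), c(H, W2, ch$c1))
  dd1[cc$f6$y <= 0] <- 0
  g6 <- conv_bwd(dd1, cc$f6$cols, w$W6, H, W2, ch$c2 + ch$c1)
  dup1 <- g6$dx[, , seq_len(ch$c2), drop = FALSE]
  de1 <- g6$dx[, , ch$c2 + seq_len(ch$c1), drop = FALSE]
  dd2 <- up2_bwd(dup1)
  dd2[cc$f5$y <= 0] <- 0
  g5 <- conv_bwd(dd2, cc$f5$cols, w$W5, H / 2L, W2 / 2L, ch$c3 + ch$c2)
  dupb <- g5$dx[, , seq_len(ch$c3), drop = FALSE]
  de2 <- g5$dx[, , ch$c3 + seq_len(ch$c2), drop = FALSE]
  dbneck <- up2_bwd(dupb)
  dbneck[cc$f4$y <= 0] <- 0
  g4 <- conv_bwd(dbneck, cc$f4$cols, w$W4, H / 4L, W2 / 4L, ch$c2)
  dp2 <- g4$dx
  de2 <- de2 + pool2_bwd(dp2, cc$p2$m, H / 2L, W2 / 2L)
  de2[cc$f3$y <= 0] <- 0
  g3 <- conv_bwd(de2, cc$f3$cols, w$W3, H / 2L, W2 / 2L, ch$c1)
  dp1 <- g3$dx
  de1 <- de1 + pool2_bwd(dp1, cc$p1$m, H, W2)
  de1[cc$f2$y <= 0] <- 0
  g2 <- conv_bwd(de1, cc$f2$cols, w$W2, H, W2, ch$c1)
  da1 <- g2$dx
  da1[cc$f1$y <= 0] <- 0
  g1 <- conv_bwd(da1, cc$f1$cols, w$W1, H, W2, 1L)
  list(W1 = g1$dW, b1 = g1$db, W2 = g2$dW, b2 = g2$db,
       W3 = g3$dW, b3 = g3$db, W4 = g4$dW, b4 = g4$db,
       W5 = g5$dW, b5 = g5$db, W6 = g6$dW, b6 = g6$db,
       W7 = dW7, b7 = db7)
}

unet_loss <- function(p, y) {
  eps_p <- 1e-7
  pc <- pmin(pmax(p, eps_p), 1 - eps_p)
  bce <- -mean(y * log(pc) + (1 - y) * log(1 - pc))
  dice <- (2 * sum(p * y) + 1) / (sum(p) + sum(y) + 1)
  bce + (1 - dice)
}

# ---- training -------------------------------------------------------------

#' Train the encoder-decoder on image/mask pairs
#'
#' Runs per-sample Adam updates of the binary-cross-entropy + soft-Dice
#' loss and keeps the weights of the epoch with the best validation Dice
#' (computed at the 0.6 probability threshold used at inference).
#' Deterministic under a fixed seed.
#'
#' @param train,val lists of pairs \code{list(image =, mask =)}; images are
#'   numeric matrices matching \code{model$input_size}, masks logical.
#'   At least 50 training pairs are required.
#' @param model an untrained model from \code{\link{unet_init}} (one is
#'   created when omitted).
#' @param epochs training epochs (default 12).
#' @param lr Adam learning rate.
#' @param seed seed for initialization and shuffling.
#' @param verbose print per-epoch progress.
#' @return a trained \code{unet_model} with a \code{history} data.frame
#'   (epoch, train_loss, val_dice).
#' @export
train_network <- function(train, val, model = NULL, epochs = 12L,
                          lr = 1e-3, seed = 1L, verbose = FALSE) {
  if (length(train) == 0L) stop("empty training set")
  if (length(train) < 50L) stop("need at least 50 training pairs")
  if (length(val) == 0L) stop("empty validation set")
  if (is.null(model)) model <- unet_init(dim(train[[1]]$image), seed = seed)
  sz <- model$input_size
  check_pair <- function(p) {
    if (!all(dim(p$image) == sz) || !all(dim(p$mask) == sz))
      stop("image/mask shape mismatch with the model input size")
  }
  lapply(train, check_pair); lapply(val, check_pair)

  set.seed(as.integer(seed))
  w <- model$weights
  adam <- lapply(w, function(p) list(m = p * 0, v = p * 0))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; t <- 0L
  hist <- data.frame(epoch = integer(), train_loss = numeric(),
                     val_dice = numeric())
  best <- list(dice = -Inf, w = w)
  for (ep in seq_len(epochs)) {
    ord <- sample(length(train))
    tot <- 0
    for (i in ord) {
      pair <- train[[i]]
      fwd <- unet_forward(w, array(pair$image, c(sz, 1L)), keep_cache = TRUE)
      y <- matrix(as.numeric(pair$mask), sz[1], sz[2])
      tot <- tot + unet_loss(fwd$p, y)
      gr <- unet_backward(w, fwd, y)
      t <- t + 1L
      for (nm in names(w)) {
        adam[[nm]]$m <- b1 * adam[[nm]]$m + (1 - b1) * gr[[nm]]
        adam[[nm]]$v <- b2 * adam[[nm]]$v + (1 - b2) * gr[[nm]]^2
        mhat <- adam[[nm]]$m / (1 - b1^t)
        vhat <- adam[[nm]]$v / (1 - b2^t)
        w[[nm]] <- w[[nm]] - lr * mhat / (sqrt(vhat) + eps)
      }
    }
    vd <- mean(vapply(val, function(p) {
      pr <- unet_forward(w, array(p$image, c(sz, 1L)))$p
      evaluate_segmentation(pr >= 0.6, p$mask)$dice
    }, numeric(1)))
    hist <- rbind(hist, data.frame(epoch = ep,
                                   train_loss = tot / length(train),
                                   val_dice = vd))
    if (vd > best$dice) best <- list(dice = vd, w = w)
    if (verbose)
      message(sprintf("epoch %d: loss %.4f, val Dice %.3f", ep,
                      tot / length(train), vd))
  }
  model$weights <- best$w
  model$trained <- TRUE
  model$history <- hist
  model$best_val_dice <- best$dice
  model
}

#' Per-pixel epithelium probability map
#'
#' @param model a trained \code{unet_model}.
#' @param image numeric matrix matching the model input size (already
#'   normalized as by \code{\link{normalize_bscan}}).
#' @return numeric matrix of probabilities in (0, 1).
#' @export
predict_unet <- function(model, image) {
  if (!isTRUE(model$trained))
    stop("untrained model: fit it with train_network() first")
  sz <- model$input_size
  if (!all(dim(image) == sz)) stop("image does not match model input size")
  unet_forward(model$weights, array(image, c(sz, 1L)))$p
}

#' Normalize a B-scan for network input
#'
#' Scales by the 99th intensity percentile and clips to [0, 2], the
#' preprocessing applied to every training image.
#'
#' @param bscan numeric matrix.
#' @return normalized matrix.
#' @export
normalize_bscan <- function(bscan) {
  q <- stats::quantile(bscan, 0.99)
  if (q <= 0) return(bscan * 0)
  pmin(bscan / q, 2)
}

#' Threshold a probability map
#'
#' @param p numeric probability matrix.
#' @param threshold probability cut in (0, 1); pixels with
#'   \code{p >= threshold} are retained. Default 0.6.
#' @return logical matrix.
#' @export
apply_probability_threshold <- function(p, threshold = 0.6) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must lie in (0, 1)")
  unclass(p) >= threshold
}

#' Network-based epithelium segmentation
#'
#' Resizes the B-scan to the network input size, predicts a probability
#' map, thresholds it (default 0.6), keeps the largest connected band, and
#' extracts per-column boundaries in the original pixel grid.
#'
#' @param bscan numeric matrix \code{[z, x]}.
#' @param model a trained \code{unet_model}.
#' @param threshold probability threshold in (0, 1), default 0.6.
#' @return an \code{epithelium_segmentation} (method \code{"network"}) with
#'   the probability map attached as attribute \code{probability}.
#' @export
segment_epithelium_network <- function(bscan, model, threshold = 0.6) {
  if (!isTRUE(model$trained))
    stop("untrained model: fit it with train_network() first")
  if (threshold <= 0 || threshold >= 1) stop("threshold must lie in (0, 1)")
  img <- unclass(bscan)
  sz <- model$input_size
  small <- as.matrix(EBImage::resize(EBImage::Image(normalize_bscan(img)),
                                     w = sz[1], h = sz[2]))
  p_small <- predict_unet(model, small)
  p <- as.matrix(EBImage::resize(EBImage::Image(p_small),
                                 w = nrow(img), h = ncol(img)))
  mask <- apply_probability_threshold(p, threshold)
  if (any(mask)) {
    lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
    tab <- tabulate(as.integer(lab)[as.integer(lab) > 0])
    mask <- as.matrix(lab) == which.max(tab)
  }
  nx <- ncol(mask)
  upper <- rep(NA_integer_, nx); lower <- rep(NA_integer_, nx)
  valid <- rep(FALSE, nx)
  for (x in seq_len(nx)) {
    w <- which(mask[, x])
    if (length(w)) {
      upper[x] <- w[1]; lower[x] <- w[length(w)] + 1L; valid[x] <- TRUE
    }
  }
  structure(list(mask = mask, upper = upper, lower = lower, valid = valid,
                 method = "network", probability_threshold = threshold),
            class = "epithelium_segmentation", probability = p)
}

#' Synthetic B-scan / epithelium-mask pairs for network training
#'
#' Renders single-position speckle phantoms with randomly drawn epithelial
#' thickness and returns normalized structural images with their
#' ground-truth epithelium masks.
#'
#' @param n number of pairs.
#' @param seed integer seed.
#' @param size image size \code{c(depth, width)}.
#' @param thickness_range_um range the true thickness is drawn from.
#' @param axial_pixel_um depth pixel size.
#' @param noise_floor additive noise amplitude.
#' @return list of \code{list(image =, mask =, thickness_um =)}.
#' @export
make_segmentation_dataset <- function(n, seed = 1L, size = c(64L, 64L),
                                      thickness_range_um = c(60, 260),
                                      axial_pixel_um = 14,
                                      noise_floor = 0.05) {
  set.seed(as.integer(seed))
  g <- phantom_geometry(n_depth = size[1], n_fast = size[2], n_slow = 8L,
                        axial_pixel_um = axial_pixel_um, n_repeats = 4L)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    th <- runif(1, thickness_range_um[1], thickness_range_um[2])
    scene <- make_tissue_scene(g, thickness_um = th, vessel_fraction = 0,
                               seed = sample.int(2^30, 1))
    fs <- render_frame_sequence(scene, position = 1L, decorrelation = 0,
                                noise_floor = noise_floor, seed = NULL)
    img <- apply(fs, c(1, 2), mean)
    out[[i]] <- list(image = normalize_bscan(img),
                     mask = truth_epithelium_mask(scene, 1L),
                     thickness_um = th)
  }
  out
}

#' Ground-truth epithelium mask of a scene at one slow position
#'
#' True on rows \code{surface <= z < surface + thickness}, matching the
#' boundary convention of the segmenters.
#'
#' @param scene a \code{tissue_scene}.
#' @param position slow-axis index.
#' @return logical matrix \code{[z, x]}.
#' @export
truth_epithelium_mask <- function(scene, position = 1L) {
  g <- scene$geometry
  u <- scene$surface_depth[, position]
  t_px <- scene$epi_thickness_px[, position]
  z <- matrix(seq_len(g$n_depth), g$n_depth, g$n_fast)
  su <- matrix(u, g$n_depth, g$n_fast, byrow = TRUE)
  tp <- matrix(t_px, g$n_depth, g$n_fast, byrow = TRUE)
  z >= su & z < su + tp
}
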
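# Residual U-Net emitting four per-pixel heads (seed logit, raw bandwidth,
# row/col embedding offsets), with hand-derived backprop. Feature maps are
# (H*W) x C matrices in column-major pixel order; convolutions are 3x3 same,
# every convolution is followed by batch normalisation (computed over the
# image's pixels, so inference is deterministic per image), and each scale of
# both branches carries a residual block.

#' Network architecture specification
#'
#' @param depth number of scales (resolution halves between scales).
#' @param baseChannels channels at the finest scale; doubled per scale.
#' @param inChannels input image channels (1 for brightfield).
#' @return list of class `NetworkSpec`.
#' @export
networkSpec <- function(depth = 3L, baseChannels = 16L, inChannels = 1L) {
  stopifnot(depth >= 1, baseChannels >= 1)
  structure(list(depth = as.integer(depth),
                 baseChannels = as.integer(baseChannels),
                 inChannels = as.integer(inChannels),
                 headChannels = 4L),
            class = "NetworkSpec")
}

#' Training configuration
#'
#' Defaults are desk-scale: 128-px crops and a small batch; the published
#' full-scale setting (1,024-px crops) is reached by changing `cropSize`.
#' The Adam learning rate default is 1e-4.
#'
#' @param cropSize square crop edge in pixels (must divide the scenes).
#' @param steps optimisation steps.
#' @param learningRate Adam learning rate.
#' @param batchSize crops per step.
#' @param augment random flips/rotations (the 8 dihedral transforms).
#' @param seed RNG seed controlling crop sampling, augmentation and
#'   initialisation.
#' @param seedLossWeight weight of the seed-map regression term.
#' @param bandwidthScale scale applied to softplus of the raw bandwidth
#'   head; keeps sigma on the order of a cell radius in normalised
#'   coordinates.
#' @param valEvery validation cadence in steps.
#' @param validationFraction fraction of scenes held out for validation
#'   when no explicit validation set is given.
#' @return list of class `TrainConfig`.
#' @export
trainConfig <- function(cropSize = 128L, steps = 500L, learningRate = 1e-4,
                        batchSize = 2L, augment = TRUE, seed = 1L,
                        seedLossWeight = 1, bandwidthScale = 0.1,
                        valEvery = 50L, validationFraction = 0.2) {
  stopifnot(learningRate > 0, cropSize >= 8, steps >= 1, batchSize >= 1)
  structure(list(cropSize = as.integer(cropSize), steps = as.integer(steps),
                 learningRate = learningRate,
                 batchSize = as.integer(batchSize), augment = augment,
                 seed = as.integer(seed), seedLossWeight = seedLossWeight,
                 bandwidthScale = bandwidthScale,
                 valEvery = as.integer(valEvery),
                 validationFraction = validationFraction),
            class = "TrainConfig")
}

softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))
sigmoid <- function(x) 1 / (1 + exp(-x))

convUnitNames <- function(spec) {
  D <- spec$depth
  c(paste0("enc_in_", seq_len(D)), paste0("enc_res_", seq_len(D)),
    if (D > 1) paste0("dec_in_", seq_len(D - 1)),
    if (D > 1) paste0("dec_res_", seq_len(D - 1)))
}

unitChannels <- function(spec, name) {
  ch <- function(l) spec$baseChannels * 2^(l - 1)
  l <- as.integer(sub(".*_", "", name))
  if (startsWith(name, "enc_in_")) {
    c(if (l == 1) spec$inChannels else ch(l - 1), ch(l))
  } else if (startsWith(name, "enc_res_")) c(ch(l), ch(l))
  else if (startsWith(name, "dec_in_")) c(ch(l + 1), ch(l))
  else c(ch(l), ch(l))
}

#' Initialise network parameters
#'
#' He-initialised convolutions; the head starts near zero so the initial
#' embeddings equal the pixel coordinates and the initial seed scores sit
#' below threshold. Encoder and residual convolutions are 3x3; the
#' decoder's channel-change convolutions are 1x1 (the residual blocks do
#' the spatial mixing at each scale).
#'
#' @param spec a [networkSpec()].
#' @param seed RNG seed.
#' @return list of class `ldNetParams`.
#' @export
initNetwork <- function(spec, seed = 1L) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  units <- list()
  for (nm in convUnitNames(spec)) {
    io <- unitChannels(spec, nm)
    k <- if (startsWith(nm, "dec_in_")) 1L else 3L
    fanIn <- k * k * io[1]
    units[[nm]] <- list(
      W = matrix(stats::rnorm(fanIn * io[2], 0, sqrt(2 / fanIn)),
                 fanIn, io[2]),
      b = numeric(io[2]), gamma = rep(1, io[2]), beta = numeric(io[2]),
      k = k)
  }
  c1 <- spec$baseChannels
  units$head <- list(
    W = matrix(stats::rnorm(c1 * 4, 0, 0.01), c1, 4),
    b = c(-1, 0, 0, 0))   # seed starts low, sigma at softplus(0)*scale
  structure(list(units = units, spec = spec), class = "ldNetParams")
}

bnForward <- function(z, gamma, beta, eps = 1e-5) {
  .bnForwardC(z, gamma, beta, eps)
}

bnBackward <- function(dy, cache, gamma) {
  .bnBackwardC(dy, cache$xhat, cache$sd, gamma)
}

unitConvForward <- function(unit, x, H, W) {
  if (identical(unit$k, 1L)) {
    sweep(x %*% unit$W, 2, unit$b, "+")
  } else {
    .convForward(x, unit$W, unit$b, H, W)
  }
}

unitConvBackward <- function(unit, x, dz, H, W) {
  if (identical(unit$k, 1L)) {
    list(dX = dz %*% t(unit$W), dW = t(x) %*% dz, db = colSums(dz))
  } else {
    .convBackward(x, unit$W, dz, H, W)
  }
}

# conv -> BN -> ReLU
cbrForward <- function(unit, x, H, W) {
  z <- unitConvForward(unit, x, H, W)
  bn <- bnForward(z, unit$gamma, unit$beta)
  y <- pmax(bn$y, 0)
  list(y = y, cache = list(x = x, bn = bn, mask = bn$y > 0, H = H, W = W))
}

cbrBackward <- function(unit, dy, cache) {
  dy <- dy * cache$mask
  bb <- bnBackward(dy, cache$bn, unit$gamma)
  cv <- unitConvBackward(unit, cache$x, bb$dz, cache$H, cache$W)
  list(dx = cv$dX,
       grads = list(W = cv$dW, b = as.numeric(cv$db),
                    gamma = as.numeric(bb$dgamma),
                    beta = as.numeric(bb$dbeta)))
}

# residual block: relu(x + BN(conv(x)))
resForward <- function(unit, x, H, W) {
  z <- unitConvForward(unit, x, H, W)
  bn <- bnForward(z, unit$gamma, unit$beta)
  pre <- x + bn$y
  list(y = pmax(pre, 0),
       cache = list(x = x, bn = bn, mask = pre > 0, H = H, W = W))
}

resBackward <- function(unit, dy, cache) {
  dy <- dy * cache$mask
  bb <- bnBackward(dy, cache$bn, unit$gamma)
  cv <- unitConvBackward(unit, cache$x, bb$dz, cache$H, cache$W)
  list(dx = dy + cv$dX,
       grads = list(W = cv$dW, b = as.numeric(cv$db),
                    gamma = as.numeric(bb$dgamma),
                    beta = as.numeric(bb$dbeta)))
}

# full forward pass; returns head output (HW x 4) and all caches
netForward <- function(params, x, H, W) {
  spec <- params$spec
  D <- spec$depth
  u <- params$units
  caches <- list()
  skips <- list()
  dims <- list()
  h <- H; w <- W
  for (l in seq_len(D)) {
    f <- cbrForward(u[[paste0("enc_in_", l)]], x, h, w)
    caches[[paste0("enc_in_", l)]] <- f$cache
    f2 <- resForward(u[[paste0("enc_res_", l)]], f$y, h, w)
    caches[[paste0("enc_res_", l)]] <- f2$cache
    x <- f2$y
    skips[[l]] <- x
    dims[[l]] <- c(h, w)
    if (l < D) {
      mp <- .maxpoolForward(x, h, w)
      caches[[paste0("pool_", l)]] <- mp$idx
      x <- mp$y
      h <- h %/% 2L; w <- w %/% 2L
    }
  }
  for (l in rev(seq_len(D - 1))) {
    hw <- dims[[l]]
    x <- .upsampleForward(x, hw[1] %/% 2L, hw[2] %/% 2L)
    h <- hw[1]; w <- hw[2]
    f <- cbrForward(u[[paste0("dec_in_", l)]], x, h, w)
    caches[[paste0("dec_in_", l)]] <- f$cache
    y <- f$y + skips[[l]]
    f2 <- resForward(u[[paste0("dec_res_", l)]], y, h, w)
    caches[[paste0("dec_res_", l)]] <- f2$cache
    x <- f2$y
  }
  Y <- x %*% u$head$W
  Y <- sweep(Y, 2, u$head$b, "+")
  list(Y = Y, headIn = x, caches = caches, dims = dims)
}

# full backward pass from dY; returns gradients mirroring the params
netBackward <- function(params, fwd, dY) {
  spec <- params$spec
  D <- spec$depth
  u <- params$units
  grads <- list()
  grads$head <- list(W = t(fwd$headIn) %*% dY, b = colSums(dY))
  dx <- dY %*% t(u$head$W)
  dskip <- vector("list", D)   # gradient flowing into each skip connection
  for (l in seq_len(D - 1)) {  # decoder, finest scale first
    b2 <- resBackward(u[[paste0("dec_res_", l)]], dx,
                      fwd$caches[[paste0("dec_res_", l)]])
    grads[[paste0("dec_res_", l)]] <- b2$grads
    dskip[[l]] <- b2$dx        # the skip add passes gradient through
    b1 <- cbrBackward(u[[paste0("dec_in_", l)]], b2$dx,
                      fwd$caches[[paste0("dec_in_", l)]])
    grads[[paste0("dec_in_", l)]] <- b1$grads
    hw <- fwd$dims[[l]]
    dx <- .upsampleBackward(b1$dx, hw[1] %/% 2L, hw[2] %/% 2L)
  }
  # encoder, deepest scale first
  for (l in rev(seq_len(D))) {
    d <- if (l == D) dx else {
      hw <- fwd$dims[[l]]
      .maxpoolBackward(dx, fwd$caches[[paste0("pool_", l)]], hw[1], hw[2]) +
        dskip[[l]]
    }
    b2 <- resBackward(u[[paste0("enc_res_", l)]], d,
                      fwd$caches[[paste0("enc_res_", l)]])
    grads[[paste0("enc_res_", l)]] <- b2$grads
    b1 <- cbrBackward(u[[paste0("enc_in_", l)]], b2$dx,
                      fwd$caches[[paste0("enc_in_", l)]])
    grads[[paste0("enc_in_", l)]] <- b1$grads
    dx <- b1$dx
  }
  grads
}
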
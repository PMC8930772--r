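#' @useDynLib ldscope, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
NULL

# Deterministic seed fan-out: a Lehmer-style integer walk so that per-scene /
# per-stage seeds derived from one master seed are reproducible, pairwise
# distinct in practice, and stay below 2^31.
MOD31 <- 2147483647

#' Derive a reproducible child seed from a master seed
#'
#' Stages and scenes draw their own seeds from the run's master seed through a
#' fixed multiplicative congruential walk, so any stage can be re-run in
#' isolation with the same randomness.
#'
#' @param master integer master seed.
#' @param ... integers (or strings, hashed by character codes) identifying the
#'   child stream, e.g. a stage index and a scene index.
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
deriveSeed <- function(master, ...) {
  keys <- list(...)
  s <- (as.numeric(master) %% MOD31)
  s <- (s * 48271 + 11) %% MOD31
  for (k in keys) {
    if (is.character(k)) k <- sum(utf8ToInt(paste(k, collapse = ""))) * 131
    for (ki in as.numeric(k)) {
      s <- (s * 48271 + (ki %% MOD31) + 7919) %% MOD31
    }
  }
  as.integer(if (s < 1) s + 1 else s)
}

# truncated separable Gaussian weights, renormalised over the finite support
gaussWeights <- function(sigma, radius) {
  w <- exp(-(seq(-radius, radius))^2 / (2 * sigma^2))
  w / sum(w)
}

# Separable shift-and-add blur with zero padding. Finite kernel support is
# deliberate: blurred signal spreads exactly `radius` pixels, never further.
blurImage <- function(img, sigma = 0.6, radius = 1L) {
  if (sigma <= 0 || radius < 1) return(img)
  w <- gaussWeights(sigma, radius)
  H <- nrow(img); W <- ncol(img)
  out <- matrix(0, H, W)
  for (k in seq_along(w)) {        # rows
    d <- k - radius - 1L
    src <- max(1L, 1L - d):min(H, H - d)
    out[src + d, ] <- out[src + d, ] + w[k] * img[src, ]
  }
  out2 <- matrix(0, H, W)
  for (k in seq_along(w)) {        # cols
    d <- k - radius - 1L
    src <- max(1L, 1L - d):min(W, W - d)
    out2[, src + d] <- out2[, src + d] + w[k] * out[, src]
  }
  out2
}

# linear index helpers (column-major, 1-based)
pixRow <- function(idx, H) ((idx - 1L) %% H) + 1L
pixCol <- function(idx, H) ((idx - 1L) %/% H) + 1L

clampInt <- function(x, lo = 0L, hi = 65535L) {
  y <- pmin(pmax(round(x), lo), hi)
  storage.mode(y) <- "integer"
  y
}

# dilate a set of linear pixel indices by a Chebyshev radius, clipped to image
dilateIndices <- function(idx, H, W, radius = 1L) {
  if (radius < 1L || length(idx) == 0L) return(idx)
  r <- pixRow(idx, H); c <- pixCol(idx, H)
  off <- expand.grid(dr = -radius:radius, dc = -radius:radius)
  rr <- outer(r, off$dr, "+"); cc <- outer(c, off$dc, "+")
  keep <- rr >= 1L & rr <= H & cc >= 1L & cc <= W
  unique((cc[keep] - 1L) * H + rr[keep])
}

stopIfNot16bit <- function(img, what = "image") {
  if (!is.matrix(img)) stop(what, " must be a matrix")
  if (any(img < 0 | img > 65535)) {
    stop(what, " has values outside the 16-bit range [0, 65535]")
  }
  invisible(img)
}
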
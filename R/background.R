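## Rolling-ball background estimation of the Cy3 channel: grayscale opening
## with a non-flat sphere-cap structuring element. For large radii the
## estimate is computed on a block-minimum shrunken image and interpolated
## back, which keeps the cost independent of the ball area at full scale;
## the background is clamped below the input so subtraction never goes
## negative.

## Offsets and heights of the sphere cap of radius rb (in px of the working
## scale). h is the cap height above the ball's equatorial plane.
.ballElement <- function(rb) {
  R <- floor(rb)
  g <- expand.grid(dx = -R:R, dy = -R:R)
  keep <- g$dx^2 + g$dy^2 <= rb^2
  g <- g[keep, , drop = FALSE]
  g$h <- sqrt(rb^2 - g$dx^2 - g$dy^2)
  g
}

.erodeBall <- function(I, se) {
  n <- nrow(I); m <- ncol(I)
  K <- max(abs(c(se$dx, se$dy)), 0L)
  P <- matrix(Inf, n + 2 * K, m + 2 * K)
  P[K + seq_len(n), K + seq_len(m)] <- I
  E <- matrix(Inf, n, m)
  for (i in seq_len(nrow(se)))
    E <- pmin(E, P[K + se$dx[i] + seq_len(n), K + se$dy[i] + seq_len(m)] -
                   se$h[i])
  E
}

.dilateBall <- function(I, se) {
  n <- nrow(I); m <- ncol(I)
  K <- max(abs(c(se$dx, se$dy)), 0L)
  P <- matrix(-Inf, n + 2 * K, m + 2 * K)
  P[K + seq_len(n), K + seq_len(m)] <- I
  D <- matrix(-Inf, n, m)
  for (i in seq_len(nrow(se)))
    D <- pmax(D, P[K + se$dx[i] + seq_len(n), K + se$dy[i] + seq_len(m)] +
                   se$h[i])
  D
}

.openBall <- function(I, rb) {
  se <- .ballElement(rb)
  .dilateBall(.erodeBall(I, se), se)
}

## Block-minimum downscale by integer factor s (trailing rows/cols padded
## by edge replication so every block is full).
.shrinkMin <- function(I, s) {
  n <- nrow(I); m <- ncol(I)
  n2 <- ceiling(n / s); m2 <- ceiling(m / s)
  if (n2 * s > n) I <- I[c(seq_len(n), rep(n, n2 * s - n)), , drop = FALSE]
  if (m2 * s > m) I <- I[, c(seq_len(m), rep(m, m2 * s - m)), drop = FALSE]
  A <- I[seq(1, n2 * s, by = s), , drop = FALSE]
  for (k in 2:s) A <- pmin(A, I[seq(k, n2 * s, by = s), , drop = FALSE])
  B <- A[, seq(1, m2 * s, by = s), drop = FALSE]
  for (k in 2:s) B <- pmin(B, A[, seq(k, m2 * s, by = s), drop = FALSE])
  B
}

## Bilinear upscale of the shrunken background to the original size; sample
## points sit at block centres, extrapolation holds edge values.
.enlargeBilinear <- function(B, n, m, s) {
  xs <- (seq_len(nrow(B)) - 0.5) * s + 0.5
  ys <- (seq_len(ncol(B)) - 0.5) * s + 0.5
  tmp <- matrix(0, n, ncol(B))
  for (j in seq_len(ncol(B)))
    tmp[, j] <- stats::approx(xs, B[, j], xout = seq_len(n), rule = 2)$y
  out <- matrix(0, n, m)
  for (i in seq_len(n))
    out[i, ] <- stats::approx(ys, tmp[i, ], xout = seq_len(m), rule = 2)$y
  out
}

## ImageJ-style shrink factor: keeps the working ball area bounded.
.autoShrink <- function(radius) {
  if (radius <= 10) 1L else if (radius <= 30) 2L else if (radius <= 100) 4L
  else 8L
}

#' Rolling-ball background estimate
#'
#' Estimates the smooth local background of a grayscale field as the
#' grayscale opening of the image with a sphere-cap (ball) structuring
#' element of the given radius: no structure smaller than the ball survives
#' into the estimate and the estimate never exceeds the image. For radii
#' above 10 px the opening is computed on a block-minimum shrunken copy
#' (factor 2, 4 or 8, growing with the radius) and interpolated back,
#' trading per-pixel exactness for speed on large balls; \code{shrink = 1}
#' forces the exact opening.
#'
#' @param image a \linkS4class{FieldImage} or numeric matrix.
#' @param radius ball radius in px (default 50).
#' @param shrink integer shrink factor, or \code{NULL} for automatic
#'   selection.
#' @param smoothing apply a 3 x 3 mean pre-filter to the copy used for
#'   background estimation (off by default).
#' @return Numeric matrix: the estimated background, clamped to be
#'   pointwise \code{<=} the input.
#' @export
rollingBallBackground <- function(image, radius = 50, shrink = NULL,
                                  smoothing = FALSE) {
  px <- .asPixels(image)
  if (radius < 1) stop("radius must be >= 1")
  if (radius > nrow(px) && radius > ncol(px))
    stop("ball radius larger than both image dimensions")
  work <- px
  if (smoothing) {
    k <- matrix(1 / 9, 3, 3)
    work <- EBImage::filter2(work, k)
  }
  s <- if (is.null(shrink)) .autoShrink(radius) else as.integer(shrink)
  stopifnot(s >= 1L)
  if (s == 1L) {
    bg <- .openBall(work, radius)
  } else {
    small <- .shrinkMin(work, s)
    bg <- .openBall(small, radius / s)
    bg <- .enlargeBilinear(bg, nrow(px), ncol(px), s)
  }
  pmin(bg, px)
}

#' Subtract rolling-ball background from a field
#'
#' Computes [rollingBallBackground()] and subtracts it, clipping at zero.
#' In this workflow the subtraction is applied to the Cy3 (signal) channel
#' only, never to the DAPI channel used for segmentation. Adding a constant
#' to the input leaves the output unchanged, and re-running the subtraction
#' on its own output is (up to shrink-interpolation effects) a no-op.
#'
#' @inheritParams rollingBallBackground
#' @return Same type as the input: a \linkS4class{FieldImage} with
#'   background-subtracted pixels, or a numeric matrix.
#' @examples
#' m <- matrix(300, 64, 64)          # flat background ...
#' range(rollingBallSubtract(m, 10)) # ... is removed completely
#' @export
rollingBallSubtract <- function(image, radius = 50, shrink = NULL,
                                smoothing = FALSE) {
  px <- .asPixels(image)
  bg <- rollingBallBackground(px, radius = radius, shrink = shrink,
                              smoothing = smoothing)
  out <- pmax(px - bg, 0)
  if (is(image, "FieldImage")) {
    image@pixels <- out
    validObject(image)
    image
  } else out
}
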
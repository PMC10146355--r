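# Independent oracles, kept deliberately naive so they share no code path
# with the package implementation.

# Exhaustive Otsu oracle: same histogram contract (256 bins over
# [min, max]), but the split is chosen by directly computing and minimizing
# the weighted within-class variance of the bin indices for every
# candidate cut, with the lowest qualifying cut on ties.
oracleOtsu <- function(v, bins = 256L) {
  lo <- min(v); hi <- max(v)
  stopifnot(lo < hi)
  width <- hi - lo + 1
  b <- floor((as.numeric(v) - lo) * bins / width)
  counts <- tabulate(b + 1L, nbins = bins)
  idx <- 0:(bins - 1)
  best <- Inf; bestCut <- NA_integer_
  for (cut in 0:(bins - 2)) {
    n0 <- sum(counts[idx <= cut]); n1 <- sum(counts[idx > cut])
    if (n0 == 0 || n1 == 0) next
    i0 <- idx[idx <= cut]; c0 <- counts[idx <= cut]
    i1 <- idx[idx > cut]; c1 <- counts[idx > cut]
    m0 <- sum(i0 * c0) / n0; m1 <- sum(i1 * c1) / n1
    wcv <- sum(c0 * (i0 - m0)^2) + sum(c1 * (i1 - m1)^2)
    if (wcv < best - 1e-9) {
      best <- wcv
      bestCut <- cut
    }
  }
  lo + ceiling((bestCut + 1) * width / bins) - 1
}

# Naive grayscale opening with a sphere-cap element: per-pixel loops,
# usable only on small images.
oracleBallOpening <- function(I, radius) {
  R <- floor(radius)
  off <- expand.grid(dx = -R:R, dy = -R:R)
  off <- off[off$dx^2 + off$dy^2 <= radius^2, ]
  off$h <- sqrt(radius^2 - off$dx^2 - off$dy^2)
  n <- nrow(I); m <- ncol(I)
  ero <- matrix(NA_real_, n, m)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    best <- Inf
    for (k in seq_len(nrow(off))) {
      ii <- i + off$dx[k]; jj <- j + off$dy[k]
      if (ii >= 1 && ii <= n && jj >= 1 && jj <= m)
        best <- min(best, I[ii, jj] - off$h[k])
    }
    ero[i, j] <- best
  }
  out <- matrix(NA_real_, n, m)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    best <- -Inf
    for (k in seq_len(nrow(off))) {
      ii <- i + off$dx[k]; jj <- j + off$dy[k]
      if (ii >= 1 && ii <= n && jj >= 1 && jj <= m)
        best <- max(best, ero[ii, jj] + off$h[k])
    }
    out[i, j] <- best
  }
  out
}

# Per-pixel accumulation oracle for object measurement.
oracleMeasure <- function(lab, img) {
  ids <- sort(unique(lab[lab > 0]))
  sums <- numeric(length(ids)); cnts <- integer(length(ids))
  for (i in seq_len(nrow(lab))) for (j in seq_len(ncol(lab))) {
    l <- lab[i, j]
    if (l > 0) {
      k <- match(l, ids)
      sums[k] <- sums[k] + img[i, j]
      cnts[k] <- cnts[k] + 1L
    }
  }
  data.frame(label = ids, areaPx = cnts, mfv = sums / cnts)
}

# Sort-based linear-interpolation quantile (type 7 convention, written from
# the definition).
oracleQuantile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# Rasterized disk fixture built by direct looping (independent of the
# package's renderer).
fixtureDisks <- function(size, centers, radius, amp = 100) {
  img <- matrix(0, size[1], size[2])
  for (k in seq_len(nrow(centers))) {
    for (i in seq_len(size[1])) for (j in seq_len(size[2])) {
      if ((i - centers[k, 1])^2 + (j - centers[k, 2])^2 <= radius^2)
        img[i, j] <- amp
    }
  }
  img
}

# Printed well-level means from the 4 h and 24 h screening tables,
# with the published MoA / fold / RA columns for round-trip checks.
publishedWellTables <- function() {
  rbind(
    data.frame(time = "4h", line = "CHO-K1",
               sample = c("ctrl", "val30", "val15"),
               mfv = c(1.641, 2.179, 2.151),
               area = c(2.130, 1.423, 1.614),
               moa = c(0.770, 1.531, 1.333),
               fold = c(1, 1.987, 1.730),
               ra = c(100, 66.81, 75.78)),
    data.frame(time = "4h", line = "HeLa",
               sample = c("ctrl", "val30", "val15"),
               mfv = c(0.132, 0.127, 0.119),
               area = c(3.249, 2.955, 3.040),
               moa = c(0.041, 0.043, 0.039),
               fold = c(1, 1.063, 0.966),
               ra = c(100, 90.94, 93.56)),
    data.frame(time = "24h", line = "CHO-K1",
               sample = c("ctrl", "val30", "val15"),
               mfv = c(1.518, 2.785, 2.605),
               area = c(2.186, 0.893, 1.173),
               moa = c(0.694, 3.119, 2.221),
               fold = c(1, 4.495, 3.199),
               ra = c(100, 40.83, 53.66)),
    data.frame(time = "24h", line = "HeLa",
               sample = c("ctrl", "val30", "val15"),
               mfv = c(0.064, 0.595, 0.358),
               area = c(2.919, 2.070, 2.227),
               moa = c(0.022, 0.287, 0.161),
               fold = c(1, 13.200, 7.376),
               ra = c(100, 70.91, 76.30))
  )
}

# Small synthetic plate used by several integration tests: quick to
# generate but with enough objects for stable well means.
smallPlateConfig <- function(seed = 42L, ...) {
  syntheticPlateConfig(
    wells = c(B2 = "ctrl", B4 = "treated"),
    effects = data.frame(condition = c("ctrl", "treated"),
                         cy3Gain = c(1, 2), areaScale = c(1, 0.8),
                         countScale = c(1, 1)),
    fieldsPerWell = 3L, imageSize = c(256L, 256L), nucleiPerField = 50,
    poissonGain = 0.5, gaussianSd = 2, seed = seed, ...)
}
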
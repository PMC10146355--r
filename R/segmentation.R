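## Nuclei segmentation of the DAPI channel: Otsu auto-threshold (computed
## per well and propagated to all fields of the well), 8-connected
## component labeling, border-object exclusion, per-object area.

.asPixels <- function(x) {
  if (is(x, "FieldImage")) pixels(x) else {
    stopifnot(is.matrix(x), is.numeric(x))
    x
  }
}

.constantImageError <- function() {
  errorCondition(
    "image has a single intensity value; no Otsu threshold exists",
    class = c("constant_image_error", "error", "condition"))
}

## Histogram convention shared by all threshold modes: `bins` equal-width
## bins spanning [min, max] of the (pooled) integer data, bin index
## b(v) = floor((v - lo) * bins / (hi - lo + 1)), matching the ImageJ
## auto-threshold treatment of >8-bit images.
.otsuFromValues <- function(v, bins = 256L) {
  lo <- min(v); hi <- max(v)
  if (lo == hi) stop(.constantImageError())
  width <- (hi - lo + 1)
  b <- floor((as.numeric(v) - lo) * bins / width)  # 0-based bin index
  counts <- tabulate(b + 1L, nbins = bins)
  p <- counts / sum(counts)
  idx <- seq_len(bins) - 1L                        # bin "values"
  w0 <- cumsum(p)
  mu <- cumsum(p * idx)
  muT <- mu[bins]
  ## between-class variance for a split after bin c (c = 0 .. bins-2);
  ## splits with an empty class get -Inf so they can never win
  c_ <- seq_len(bins - 1L)                         # index into w0/mu
  denom <- w0[c_] * (1 - w0[c_])
  bcv <- ifelse(denom > 0, (muT * w0[c_] - mu[c_])^2 / denom, -Inf)
  cut <- which.max(bcv) - 1L                       # lowest bin wins ties
  ## threshold value: largest integer intensity whose bin index is <= cut,
  ## so that foreground == {v : v > threshold} exactly on integer data
  thr <- lo + ceiling((cut + 1) * width / bins) - 1
  structure(as.numeric(thr), bin = cut, lo = lo, hi = hi, bins = bins)
}

#' Otsu auto-threshold of a field image
#'
#' Builds a 256-bin histogram spanning the image's own \code{[min, max]}
#' intensity range and returns the threshold that maximizes between-class
#' variance (equivalently, minimizes within-class variance). Foreground is
#' defined as pixels strictly above the returned value. Ties in the
#' criterion are broken toward the lowest qualifying bin, making the result
#' deterministic.
#'
#' @param image a \linkS4class{FieldImage} or integer-valued matrix with at
#'   least two distinct values.
#' @param bins number of histogram bins (default 256).
#' @return Numeric threshold (attributes record the chosen bin and the
#'   histogram range). Raises a \code{constant_image_error} on constant
#'   images.
#' @examples
#' m <- matrix(10, 10, 10); m[1:2, ] <- 200
#' otsuThreshold(m)
#' @export
otsuThreshold <- function(image, bins = 256L) {
  .otsuFromValues(as.vector(.asPixels(image)), bins = as.integer(bins))
}

## 8-connected labeling: EBImage::bwlabel is 4-connected, so components
## that touch only diagonally are merged afterwards with a union-find pass.
.labelConnected8 <- function(bin) {
  storage.mode(bin) <- "double"
  lab <- EBImage::bwlabel(bin)
  lab <- matrix(as.integer(round(lab)), nrow(bin), ncol(bin))
  nlab <- max(lab)
  if (nlab <= 1L) return(lab)
  n <- nrow(lab); m <- ncol(lab)
  a1 <- lab[-n, -m]; b1 <- lab[-1, -1]   # diagonal (+1, +1)
  a2 <- lab[-n, -1]; b2 <- lab[-1, -m]   # anti-diagonal (+1, -1)
  sel1 <- a1 > 0L & b1 > 0L & a1 != b1
  sel2 <- a2 > 0L & b2 > 0L & a2 != b2
  pairs <- unique(rbind(cbind(a1[sel1], b1[sel1]), cbind(a2[sel2], b2[sel2])))
  if (nrow(pairs)) {
    parent <- seq_len(nlab)
    find <- function(i) {
      while (parent[i] != i) {
        parent[i] <<- parent[parent[i]]
        i <- parent[i]
      }
      i
    }
    for (k in seq_len(nrow(pairs))) {
      ra <- find(pairs[k, 1]); rb <- find(pairs[k, 2])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
    root <- vapply(seq_len(nlab), find, integer(1))
    remap <- match(root, sort(unique(root)))
    lab[lab > 0L] <- remap[lab[lab > 0L]]
  }
  lab
}

## Binarize at a threshold and label; optional hole filling and minimum
## object size, both off by default (the screening macro applies neither).
.maskFromThreshold <- function(px, threshold, minAreaPx = 0L,
                               fillHoles = FALSE) {
  bin <- (px > threshold) * 1
  if (fillHoles) {
    bin <- EBImage::fillHull(bin)
    bin <- matrix(as.numeric(bin > 0), nrow(px), ncol(px))
  }
  lab <- .labelConnected8(bin)
  if (minAreaPx > 0L && max(lab) > 0L) {
    sizes <- tabulate(lab[lab > 0L], nbins = max(lab))
    keep <- which(sizes >= minAreaPx)
    remap <- integer(max(lab))
    remap[keep] <- seq_along(keep)
    lab[lab > 0L] <- remap[lab[lab > 0L]]
  }
  .LabeledMask(lab, threshold, max(lab))
}

#' Segment all DAPI fields of one well
#'
#' Thresholds every DAPI field of a well and labels nuclei as 8-connected
#' components. Under the default policy, the Otsu threshold is computed on
#' the lexicographically first field of the well and propagated to all its
#' fields; \code{"per_well_pooled"} instead computes one threshold from the
#' pooled histogram of all fields, and \code{"per_image"} thresholds each
#' field independently.
#'
#' @param dapiFields list of \linkS4class{FieldImage} (or matrices). When
#'   field positions are available the list is ordered lexicographically by
#'   position token before the "first field" is chosen; otherwise the given
#'   order is used.
#' @param policy threshold propagation policy.
#' @param bins histogram bins for [otsuThreshold()].
#' @param minAreaPx optional minimum object size in px (0 = keep all).
#' @param fillHoles fill holes in the binary mask before labeling.
#' @return List of \linkS4class{LabeledMask}, one per field, each carrying
#'   the threshold it was produced with.
#' @export
segmentWell <- function(dapiFields,
                        policy = c("per_well_first_field", "per_well_pooled",
                                   "per_image"),
                        bins = 256L, minAreaPx = 0L, fillHoles = FALSE) {
  policy <- match.arg(policy)
  if (!length(dapiFields)) stop("need at least one DAPI field")
  if (!is.list(dapiFields)) dapiFields <- list(dapiFields)
  pos <- vapply(dapiFields, function(f)
    if (is(f, "FieldImage")) fieldInfo(f)$position else NA_character_,
    character(1))
  if (!anyNA(pos) && !anyDuplicated(pos))
    dapiFields <- dapiFields[order(pos)]
  pxs <- lapply(dapiFields, .asPixels)

  masks <- switch(policy,
    per_well_first_field = {
      thr <- otsuThreshold(pxs[[1]], bins)
      lapply(pxs, .maskFromThreshold, threshold = as.numeric(thr),
             minAreaPx = minAreaPx, fillHoles = fillHoles)
    },
    per_well_pooled = {
      thr <- .otsuFromValues(unlist(lapply(pxs, as.vector)), bins)
      lapply(pxs, .maskFromThreshold, threshold = as.numeric(thr),
             minAreaPx = minAreaPx, fillHoles = fillHoles)
    },
    per_image = lapply(pxs, function(p)
      .maskFromThreshold(p, as.numeric(otsuThreshold(p, bins)),
                         minAreaPx = minAreaPx, fillHoles = fillHoles))
  )
  names(masks) <- if (!anyNA(pos)) sort(pos) else names(dapiFields)
  masks
}

#' Remove objects touching the image border
#'
#' Any object with at least one pixel on the first/last row or column is
#' discarded (truncated nuclei would bias the area statistics); survivors
#' are relabeled contiguously 1..n in ascending original-label order. The
#' operation is idempotent.
#'
#' @param mask a \linkS4class{LabeledMask}.
#' @return A \linkS4class{LabeledMask} without border objects.
#' @export
excludeEdgeObjects <- function(mask) {
  stopifnot(is(mask, "LabeledMask"))
  lab <- maskLabels(mask)
  if (mask@nObjects == 0L) return(mask)
  n <- nrow(lab); m <- ncol(lab)
  border <- unique(c(lab[1, ], lab[n, ], lab[, 1], lab[, m]))
  border <- border[border > 0L]
  if (length(border)) {
    keep <- setdiff(seq_len(mask@nObjects), border)
    remap <- integer(mask@nObjects)
    remap[keep] <- seq_along(keep)
    pos <- lab > 0L
    lab[pos] <- remap[lab[pos]]
    mask <- .LabeledMask(lab, thresholdUsed(mask), length(keep))
  }
  mask
}

#' Per-object areas in pixels and square micrometres
#'
#' @param mask a \linkS4class{LabeledMask}.
#' @param calibration um per pixel edge; areas in um^2 are
#'   \code{areaPx * calibration^2}.
#' @return data.frame with columns \code{label}, \code{areaPx},
#'   \code{areaUm2}; one row per object.
#' @export
objectAreas <- function(mask, calibration = 2.6) {
  stopifnot(is(mask, "LabeledMask"), calibration > 0)
  n <- mask@nObjects
  if (n == 0L)
    return(data.frame(label = integer(), areaPx = integer(),
                      areaUm2 = numeric()))
  lab <- maskLabels(mask)
  areaPx <- tabulate(lab[lab > 0L], nbins = n)
  data.frame(label = seq_len(n), areaPx = areaPx,
             areaUm2 = areaPx * calibration^2)
}
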
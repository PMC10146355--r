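## Synthetic two-channel plate generator. Elliptical, non-overlapping
## nuclei with Gaussian-blurred edges are rendered into a DAPI channel;
## the Cy3 channel carries a per-nucleus amplitude scaled by the
## condition's gain, an additive background gradient, and Poisson-Gaussian
## noise. Ground truth (geometry, areas, per-nucleus mean Cy3) is returned
## alongside, so segmentation, measurement and the genotoxicity statistics
## are testable end to end without a microscope. Nuclei never overlap by
## construction because the segmentation deliberately has no declumping
## step; simulator realism must not be confounded with segmentation limits.

#' Build a synthetic plate configuration
#'
#' See \linkS4class{SyntheticPlateConfig} for the meaning and rationale of
#' every parameter. The defaults describe a two-well plate (negative
#' control "ctrl" in B2, a genotoxic-plus-cytotoxic "treated" condition in
#' B4 with 3x Cy3 gain, 0.7x nucleus area and 0.85x cell count), 16 fields
#' per well of 512 x 512 px, about 120 nuclei per field (pooled well totals
#' near 1900), and mild shot + read noise.
#'
#' @param wells named character vector, well -> condition.
#' @param effects data.frame with columns \code{condition}, \code{cy3Gain},
#'   \code{areaScale}, \code{countScale}.
#' @param controlCondition which condition is the negative control.
#' @param fieldsPerWell,imageSize,nucleiPerField,countDistribution,
#'   radiusMeanPx,radiusSdPx,radiusMinPx,axisRatioRange,dapiAmplitude,
#'   dapiAmplitudeSdLog,cy3Amplitude,cy3AmplitudeSdLog,backgroundDapi,
#'   backgroundCy3,edgeBlurSigma,poissonGain,gaussianSd,bitDepth,
#'   calibration,placementMargin,maxPlacementTries,dateToken,acqRun,seed
#'   see \linkS4class{SyntheticPlateConfig}.
#' @return A validated \linkS4class{SyntheticPlateConfig}.
#' @examples
#' cfg <- syntheticPlateConfig(seed = 7L, fieldsPerWell = 2L,
#'                             imageSize = c(128L, 128L),
#'                             nucleiPerField = 12)
#' cfg
#' @export
syntheticPlateConfig <- function(
    wells = c(B2 = "ctrl", B4 = "treated"),
    effects = data.frame(condition = c("ctrl", "treated"),
                         cy3Gain = c(1, 3), areaScale = c(1, 0.7),
                         countScale = c(1, 0.85),
                         stringsAsFactors = FALSE),
    controlCondition = "ctrl",
    fieldsPerWell = 16L, imageSize = c(512L, 512L),
    nucleiPerField = 120, countDistribution = c("poisson", "fixed"),
    radiusMeanPx = 6, radiusSdPx = 1.2, radiusMinPx = 3,
    axisRatioRange = c(0.75, 1),
    dapiAmplitude = 12000, dapiAmplitudeSdLog = 0.15,
    cy3Amplitude = 3000, cy3AmplitudeSdLog = 0.25,
    backgroundDapi = c(offset = 80, gradX = 40, gradY = 30),
    backgroundCy3 = c(offset = 150, gradX = 120, gradY = 80),
    edgeBlurSigma = 1, poissonGain = 1, gaussianSd = 5,
    bitDepth = 16L, calibration = 2.6,
    placementMargin = NA_real_, maxPlacementTries = 200L,
    dateToken = "20230101", acqRun = "01", seed = 1L) {
  countDistribution <- match.arg(countDistribution)
  new("SyntheticPlateConfig",
    wells = wells, effects = effects,
    controlCondition = as.character(controlCondition),
    fieldsPerWell = as.integer(fieldsPerWell),
    imageSize = as.integer(imageSize),
    nucleiPerField = as.numeric(nucleiPerField),
    countDistribution = countDistribution,
    radiusMeanPx = as.numeric(radiusMeanPx),
    radiusSdPx = as.numeric(radiusSdPx),
    radiusMinPx = as.numeric(radiusMinPx),
    axisRatioRange = as.numeric(axisRatioRange),
    dapiAmplitude = as.numeric(dapiAmplitude),
    dapiAmplitudeSdLog = as.numeric(dapiAmplitudeSdLog),
    cy3Amplitude = as.numeric(cy3Amplitude),
    cy3AmplitudeSdLog = as.numeric(cy3AmplitudeSdLog),
    backgroundDapi = as.numeric(backgroundDapi),
    backgroundCy3 = as.numeric(backgroundCy3),
    edgeBlurSigma = as.numeric(edgeBlurSigma),
    poissonGain = as.numeric(poissonGain),
    gaussianSd = as.numeric(gaussianSd),
    bitDepth = as.integer(bitDepth), calibration = as.numeric(calibration),
    placementMargin = as.numeric(placementMargin),
    maxPlacementTries = as.integer(maxPlacementTries),
    dateToken = as.character(dateToken), acqRun = as.character(acqRun),
    seed = as.integer(seed))
}

#' Plate layout implied by a synthetic configuration
#'
#' @param config a \linkS4class{SyntheticPlateConfig}.
#' @return Layout data.frame (see [plateLayout()]) in which every
#'   non-control condition points at the configured control condition.
#' @export
layoutFromConfig <- function(config) {
  stopifnot(is(config, "SyntheticPlateConfig"))
  cond <- unname(config@wells)
  ctrl <- ifelse(cond == config@controlCondition, NA_character_,
                 config@controlCondition)
  plateLayout(names(config@wells), cond, ctrl)
}

## Deterministic per-field seed: independent of generation order, well
## below 2^31.
.fieldSeed <- function(seed, well, fieldIndex) {
  h <- sum(utf8ToInt(well) * seq_along(utf8ToInt(well)) * 131)
  as.integer((as.numeric(seed %% 65011L) * 33013 + h * 2063 +
                fieldIndex * 509) %% 2147483562)
}

#' Rasterize elliptical nuclei into an intensity image
#'
#' Renders filled, sharp-edged ellipses (one amplitude each) into a zero
#' image. Ellipses are clipped at the image border; the returned ground
#' truth notes which ones touch it. This low-level renderer backs
#' [generateField()] and is exported so tests and users can construct
#' fields with exactly known geometry.
#'
#' @param size integer length-2, image size (rows, cols).
#' @param centerRow,centerCol nucleus centre coordinates (px, 1-based).
#' @param major,minor semi-axes in px.
#' @param theta rotation of the major axis in radians.
#' @param amplitude per-nucleus intensity.
#' @return list with \code{image} (numeric matrix), \code{areaPx}
#'   (rasterized pixel count per nucleus, after clipping),
#'   \code{edgeTouching} (logical per nucleus).
#' @examples
#' f <- renderNuclei(c(64, 64), 32, 32, 10, 10, 0, 100)
#' f$areaPx  # close to pi * 10^2
#' @export
renderNuclei <- function(size, centerRow, centerCol, major, minor, theta,
                         amplitude) {
  n <- as.integer(size[1]); m <- as.integer(size[2])
  k <- length(centerRow)
  stopifnot(length(centerCol) == k, length(major) == k, length(minor) == k)
  theta <- rep_len(theta, k)
  amplitude <- rep_len(amplitude, k)
  img <- matrix(0, n, m)
  areaPx <- integer(k)
  edge <- logical(k)
  for (i in seq_len(k)) {
    a <- major[i]; b <- minor[i]
    r0 <- max(1L, floor(centerRow[i] - a)); r1 <- min(n, ceiling(centerRow[i] + a))
    c0 <- max(1L, floor(centerCol[i] - a)); c1 <- min(m, ceiling(centerCol[i] + a))
    if (r0 > r1 || c0 > c1) next
    rows <- r0:r1; cols <- c0:c1
    dr <- outer(rows - centerRow[i], rep(1, length(cols)))
    dc <- outer(rep(1, length(rows)), cols - centerCol[i])
    u <- (dr * cos(theta[i]) + dc * sin(theta[i])) / a
    v <- (-dr * sin(theta[i]) + dc * cos(theta[i])) / b
    inside <- u^2 + v^2 <= 1
    areaPx[i] <- sum(inside)
    if (any(inside)) {
      block <- img[rows, cols, drop = FALSE]
      block[inside] <- block[inside] + amplitude[i]
      img[rows, cols] <- block
      edge[i] <- any(inside[rows == 1 | rows == n, , drop = FALSE]) ||
        any(inside[, cols == 1 | cols == m, drop = FALSE])
    }
  }
  list(image = img, areaPx = areaPx, edgeTouching = edge)
}

.addNoise <- function(img, poissonGain, gaussianSd, bitDepth) {
  if (poissonGain > 0)
    img <- matrix(stats::rpois(length(img), img / poissonGain) * poissonGain,
                  nrow(img), ncol(img))
  if (gaussianSd > 0)
    img <- img + matrix(stats::rnorm(length(img), 0, gaussianSd),
                        nrow(img), ncol(img))
  img <- round(img)
  pmin(pmax(img, 0), 2^bitDepth - 1)
}

.backgroundPlane <- function(n, m, par) {
  par <- as.numeric(par)
  offset <- par[1]; gx <- par[2]; gy <- par[3]
  outer(seq_len(n) / n * gy, rep(1, m)) +
    outer(rep(1, n), seq_len(m) / m * gx) + offset
}

#' Generate one synthetic two-channel field
#'
#' Draws nucleus count, geometry and amplitudes from the configured
#' distributions (scaled by the well condition's treatment effects), places
#' nuclei by rejection sampling so they never overlap, renders and blurs
#' both channels, adds the background gradient and Poisson-Gaussian noise.
#' Fully deterministic given (config seed, well, field index) -- the
#' per-field RNG stream does not depend on generation order.
#'
#' @param config a \linkS4class{SyntheticPlateConfig}.
#' @param well well name; must appear in \code{config@wells}.
#' @param fieldIndex 1-based field index within the well.
#' @return list with \code{dapi} and \code{cy3}
#'   (\linkS4class{FieldImage}s) and \code{truth}, a data.frame with one
#'   row per placed nucleus: centre, semi-axes, orientation, rasterized
#'   \code{areaPx} / \code{areaUm2}, per-pixel amplitudes and
#'   \code{edgeTouching}. Nuclei that could not be placed without overlap
#'   within the retry budget are dropped and counted in attribute
#'   \code{"nDropped"} of \code{truth}.
#' @export
generateField <- function(config, well, fieldIndex) {
  stopifnot(is(config, "SyntheticPlateConfig"))
  if (!well %in% names(config@wells))
    stop("well ", well, " is not in the configuration")
  cond <- config@wells[[well]]
  eff <- config@effects[config@effects$condition == cond, , drop = FALSE]
  n <- config@imageSize[1]; m <- config@imageSize[2]

  set.seed(.fieldSeed(config@seed, well, fieldIndex))

  lambda <- config@nucleiPerField * eff$countScale
  k <- if (config@countDistribution == "poisson") stats::rpois(1, lambda)
       else as.integer(round(lambda))

  truthCols <- c("nucleus", "centerRow", "centerCol", "major", "minor",
                 "theta", "areaPx", "areaUm2", "dapiAmp", "cy3Mean",
                 "edgeTouching")
  emptyTruth <- function(nDropped = 0L) {
    t <- data.frame(nucleus = integer(), centerRow = numeric(),
                    centerCol = numeric(), major = numeric(),
                    minor = numeric(), theta = numeric(), areaPx = integer(),
                    areaUm2 = numeric(), dapiAmp = numeric(),
                    cy3Mean = numeric(), edgeTouching = logical())
    attr(t, "nDropped") <- nDropped
    t
  }

  mkImage <- function(px, channel) {
    FieldImage(px, bitDepth = config@bitDepth,
               calibration = config@calibration, channel = channel,
               dateToken = config@dateToken, well = well,
               position = sprintf("%04d", fieldIndex), acqRun = config@acqRun)
  }

  if (k == 0L) {
    bgD <- .backgroundPlane(n, m, config@backgroundDapi)
    bgC <- .backgroundPlane(n, m, config@backgroundCy3)
    dapi <- .addNoise(bgD, config@poissonGain, config@gaussianSd,
                      config@bitDepth)
    cy3 <- .addNoise(bgC, config@poissonGain, config@gaussianSd,
                     config@bitDepth)
    return(list(dapi = mkImage(dapi, "DAPI"), cy3 = mkImage(cy3, "Cy3"),
                truth = emptyTruth()))
  }

  radii <- stats::rnorm(k, config@radiusMeanPx, config@radiusSdPx)
  radii <- pmax(radii, config@radiusMinPx) * sqrt(eff$areaScale)
  q <- stats::runif(k, config@axisRatioRange[1], config@axisRatioRange[2])
  major <- radii / sqrt(q)
  minor <- radii * sqrt(q)
  theta <- stats::runif(k, 0, pi)
  dapiAmp <- stats::rlnorm(k, log(config@dapiAmplitude),
                           config@dapiAmplitudeSdLog)
  cy3Amp <- stats::rlnorm(k, log(config@cy3Amplitude),
                          config@cy3AmplitudeSdLog) * eff$cy3Gain

  ## rejection-sampled, non-overlapping placement (bounding-circle test
  ## with a 2 px guard band)
  cr <- numeric(0); cc <- numeric(0); placed <- integer(0)
  for (i in seq_len(k)) {
    mar <- if (is.na(config@placementMargin))
      major[i] + 3 * config@edgeBlurSigma else config@placementMargin
    lo_r <- 1 + mar; hi_r <- n - mar
    lo_c <- 1 + mar; hi_c <- m - mar
    if (lo_r >= hi_r || lo_c >= hi_c) next
    done <- FALSE
    for (try in seq_len(config@maxPlacementTries)) {
      y <- stats::runif(1, lo_r, hi_r)
      x <- stats::runif(1, lo_c, hi_c)
      if (!length(cr) ||
          all((cr - y)^2 + (cc - x)^2 >
                (major[placed] + major[i] + 2)^2)) {
        cr <- c(cr, y); cc <- c(cc, x); placed <- c(placed, i)
        done <- TRUE
        break
      }
    }
  }
  nDropped <- k - length(placed)
  if (!length(placed)) {
    bgD <- .backgroundPlane(n, m, config@backgroundDapi)
    bgC <- .backgroundPlane(n, m, config@backgroundCy3)
    dapi <- .addNoise(bgD, config@poissonGain, config@gaussianSd,
                      config@bitDepth)
    cy3 <- .addNoise(bgC, config@poissonGain, config@gaussianSd,
                     config@bitDepth)
    return(list(dapi = mkImage(dapi, "DAPI"), cy3 = mkImage(cy3, "Cy3"),
                truth = emptyTruth(nDropped)))
  }

  major <- major[placed]; minor <- minor[placed]; theta <- theta[placed]
  dapiAmp <- dapiAmp[placed]; cy3Amp <- cy3Amp[placed]

  rd <- renderNuclei(c(n, m), cr, cc, major, minor, theta, dapiAmp)
  rc <- renderNuclei(c(n, m), cr, cc, major, minor, theta, cy3Amp)

  blur <- function(img) {
    if (config@edgeBlurSigma > 0)
      img <- pmax(EBImage::gblur(img, sigma = config@edgeBlurSigma), 0)
    img
  }
  maxv <- 2^config@bitDepth - 1
  dapiPx <- pmin(blur(rd$image) + .backgroundPlane(n, m, config@backgroundDapi),
                 maxv)
  cy3Px <- pmin(blur(rc$image) + .backgroundPlane(n, m, config@backgroundCy3),
                maxv)
  dapiPx <- .addNoise(dapiPx, config@poissonGain, config@gaussianSd,
                      config@bitDepth)
  cy3Px <- .addNoise(cy3Px, config@poissonGain, config@gaussianSd,
                     config@bitDepth)

  truth <- data.frame(
    nucleus = seq_along(placed), centerRow = cr, centerCol = cc,
    major = major, minor = minor, theta = theta,
    areaPx = rd$areaPx, areaUm2 = rd$areaPx * config@calibration^2,
    dapiAmp = dapiAmp, cy3Mean = cy3Amp, edgeTouching = rd$edgeTouching,
    stringsAsFactors = FALSE)
  attr(truth, "nDropped") <- nDropped
  stopifnot(identical(names(truth), truthCols))
  list(dapi = mkImage(dapiPx, "DAPI"), cy3 = mkImage(cy3Px, "Cy3"),
       truth = truth)
}

#' Generate a complete synthetic plate on disk
#'
#' Writes every field of every configured well as two TIFFs named by the
#' acquisition filename convention (so [sortPlate()] consumes the folder
#' directly), plus a ground-truth CSV, the implied plate-layout CSV and the
#' generating configuration as YAML.
#'
#' @param config a \linkS4class{SyntheticPlateConfig}.
#' @param outDir output directory (created if needed).
#' @return Invisibly, a list with \code{dir}, \code{truth} (path of the
#'   ground-truth CSV), \code{layout} (path of the layout CSV) and
#'   \code{nFiles} (number of TIFFs written).
#' @export
generatePlate <- function(config, outDir) {
  stopifnot(is(config, "SyntheticPlateConfig"))
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  truthAll <- NULL
  nFiles <- 0L
  for (w in names(config@wells)) {
    for (f in seq_len(config@fieldsPerWell)) {
      fld <- generateField(config, w, f)
      for (chan in c("dapi", "cy3")) {
        img <- fld[[chan]]
        ref <- fieldInfo(img)
        fn <- composeFieldFilename(ref)
        .writeFieldTiff(pixels(img), file.path(outDir, fn),
                        bitDepth = bitDepth(img))
        nFiles <- nFiles + 1L
      }
      tr <- fld$truth
      if (nrow(tr)) {
        tr$well <- w
        tr$field <- sprintf("%04d", f)
        truthAll <- rbind(truthAll, tr)
      }
    }
  }
  truthPath <- file.path(outDir, "ground_truth.csv")
  if (is.null(truthAll))
    truthAll <- data.frame(nucleus = integer(), well = character(),
                           field = character())
  utils::write.csv(truthAll, truthPath, row.names = FALSE)
  layout <- layoutFromConfig(config)
  layoutPath <- file.path(outDir, "plate_layout.csv")
  utils::write.csv(layout, layoutPath, row.names = FALSE)
  cfgPath <- file.path(outDir, "plate_config.yaml")
  yaml::write_yaml(.configAsList(config), cfgPath)
  invisible(list(dir = outDir, truth = truthPath, layout = layoutPath,
                 config = cfgPath, nFiles = nFiles))
}

.configAsList <- function(config) {
  sl <- slotNames(config)
  out <- lapply(sl, function(s) {
    v <- slot(config, s)
    if (is.data.frame(v)) as.list(v) else v
  })
  names(out) <- sl
  out
}
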
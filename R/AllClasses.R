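#' FieldImage: one single-channel microscopy field
#'
#' A single grayscale field acquired from one well position in one channel,
#' together with its acquisition identity and spatial calibration. Pixel
#' values are non-negative and bounded by the bit depth; they may be
#' non-integer after processing steps such as background subtraction.
#'
#' @slot pixels numeric matrix of intensities (rows = image rows).
#' @slot bitDepth integer, 8 or 16.
#' @slot calibration numeric scalar, micrometres per pixel edge (isotropic).
#' @slot channel character, canonical channel name ("DAPI" or "Cy3";
#'   \code{NA} when unknown).
#' @slot dateToken character, opaque date token from the filename.
#' @slot well character, plate well such as "B8" (\code{NA} when unknown).
#' @slot position character, field-position token within the well.
#' @slot acqRun character, acquisition-run token.
#' @slot path character, source file path (\code{NA} for in-memory images).
#'
#' @seealso [FieldImage()], [readFieldImage()]
#' @export
setClass("FieldImage",
  representation(
    pixels = "matrix",
    bitDepth = "integer",
    calibration = "numeric",
    channel = "character",
    dateToken = "character",
    well = "character",
    position = "character",
    acqRun = "character",
    path = "character"
  )
)

setValidity("FieldImage", function(object) {
  msg <- character()
  px <- object@pixels
  if (!is.numeric(px)) msg <- c(msg, "pixels must be a numeric matrix")
  if (length(object@bitDepth) != 1L || !object@bitDepth %in% c(8L, 16L))
    msg <- c(msg, "bitDepth must be 8 or 16")
  else if (is.numeric(px) && length(px)) {
    if (any(px < 0)) msg <- c(msg, "pixel values must be non-negative")
    if (any(px > 2^object@bitDepth - 1))
      msg <- c(msg, sprintf("pixel values must be <= 2^%d - 1", object@bitDepth))
  }
  if (length(object@calibration) != 1L || !is.finite(object@calibration) ||
      object@calibration <= 0)
    msg <- c(msg, "calibration must be a positive scalar (um/px)")
  if (length(msg)) msg else TRUE
})

#' Construct a FieldImage
#'
#' @param pixels numeric matrix of intensities.
#' @param bitDepth 8 or 16.
#' @param calibration micrometres per pixel edge; the default 2.6 um/px
#'   corresponds to a 0.65 um camera pixel with 4x4 binning.
#' @param channel,dateToken,well,position,acqRun,path acquisition identity
#'   tokens; all optional.
#' @return A \linkS4class{FieldImage}.
#' @examples
#' img <- FieldImage(matrix(0:3, 2, 2), bitDepth = 8L, calibration = 1)
#' pixels(img)
#' @export
FieldImage <- function(pixels, bitDepth = 16L, calibration = 2.6,
                       channel = NA_character_, dateToken = NA_character_,
                       well = NA_character_, position = NA_character_,
                       acqRun = NA_character_, path = NA_character_) {
  storage.mode(pixels) <- "double"
  new("FieldImage",
    pixels = pixels, bitDepth = as.integer(bitDepth),
    calibration = as.numeric(calibration),
    channel = as.character(channel), dateToken = as.character(dateToken),
    well = as.character(well), position = as.character(position),
    acqRun = as.character(acqRun), path = as.character(path))
}

#' @rdname pixels
#' @export
setMethod("pixels", "FieldImage", function(x) x@pixels)

#' @rdname bitDepth
#' @export
setMethod("bitDepth", "FieldImage", function(x) x@bitDepth)

#' @rdname calibration
#' @export
setMethod("calibration", "FieldImage", function(x) x@calibration)

#' @rdname fieldInfo
#' @export
setMethod("fieldInfo", "FieldImage", function(x) {
  list(channel = x@channel, dateToken = x@dateToken, well = x@well,
       position = x@position, acqRun = x@acqRun, path = x@path)
})

setMethod("show", "FieldImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("FieldImage: %d x %d px, %d-bit, %.3g um/px\n",
              d[1], d[2], object@bitDepth, object@calibration))
  cat(sprintf("  channel: %s  well: %s  position: %s\n",
              object@channel, object@well, object@position))
  if (length(object@pixels))
    cat(sprintf("  intensity range: [%g, %g]\n",
                min(object@pixels), max(object@pixels)))
  invisible(NULL)
})

#' LabeledMask: connected-component segmentation of one field
#'
#' Labels derived from a thresholded DAPI field: 0 marks background and
#' 1..nObjects mark 8-connected nuclei objects. The threshold that produced
#' the mask travels with it so that per-well threshold propagation is
#' auditable in the run log.
#'
#' @slot labels integer matrix, same shape as the source field.
#' @slot threshold numeric, the intensity threshold used (foreground is
#'   strictly above it).
#' @slot nObjects integer, number of objects.
#' @seealso [segmentWell()], [excludeEdgeObjects()]
#' @export
setClass("LabeledMask",
  representation(labels = "matrix", threshold = "numeric",
                 nObjects = "integer"))

setValidity("LabeledMask", function(object) {
  msg <- character()
  lab <- object@labels
  if (!is.numeric(lab)) msg <- c(msg, "labels must be an integer matrix")
  else {
    if (any(lab < 0)) msg <- c(msg, "labels must be non-negative")
    n <- object@nObjects
    if (length(n) != 1L || n < 0L) msg <- c(msg, "nObjects must be >= 0")
    else if (length(lab)) {
      present <- unique(as.integer(lab))
      present <- present[present > 0L]
      if (length(present) && max(present) > n)
        msg <- c(msg, "labels exceed nObjects")
      if (n > 0L && !all(seq_len(n) %in% present))
        msg <- c(msg, "labels 1..nObjects must all occur")
    }
  }
  if (length(object@threshold) != 1L)
    msg <- c(msg, "threshold must be a scalar")
  if (length(msg)) msg else TRUE
})

.LabeledMask <- function(labels, threshold, nObjects) {
  storage.mode(labels) <- "integer"
  new("LabeledMask", labels = labels, threshold = as.numeric(threshold),
      nObjects = as.integer(nObjects))
}

#' @rdname maskLabels
#' @export
setMethod("maskLabels", "LabeledMask", function(x) x@labels)

#' @rdname thresholdUsed
#' @export
setMethod("thresholdUsed", "LabeledMask", function(x) x@threshold)

#' @rdname nObjects
#' @export
setMethod("nObjects", "LabeledMask", function(x) x@nObjects)

setMethod("show", "LabeledMask", function(object) {
  d <- dim(object@labels)
  cat(sprintf("LabeledMask: %d x %d px, %d objects, threshold %g\n",
              d[1], d[2], object@nObjects, object@threshold))
  invisible(NULL)
})

#' SyntheticPlateConfig: generative ground truth for a simulated plate
#'
#' Captures every parameter of the synthetic two-channel plate generator:
#' plate layout, per-condition treatment effects, nuclei geometry and
#' brightness distributions, background gradients, noise model and seed.
#' With a fixed seed the generator output is fully deterministic.
#'
#' The defaults emulate the acquisition geometry of a 10x widefield screen
#' (512 x 512 px fields after 4x4 binning, 16 fields per well, 2.6 um/px)
#' with pooled well totals of roughly 1000--3000 nuclei, and a treatment
#' that raises per-nucleus Cy3 brightness while shrinking nuclei area --
#' the direction of effect expected for a genotoxic and cytotoxic compound.
#'
#' @slot wells named character; names are wells ("B2"), values condition
#'   labels.
#' @slot effects data.frame with columns \code{condition}, \code{cy3Gain}
#'   (multiplier on per-nucleus Cy3 pixel amplitude), \code{areaScale}
#'   (multiplier on nucleus area), \code{countScale} (multiplier on the
#'   expected nuclei count per field).
#' @slot controlCondition character, which condition is the negative
#'   control.
#' @slot fieldsPerWell integer, default 16 (a 4 x 4 tile).
#' @slot imageSize integer length-2, field size in px (rows, cols).
#' @slot nucleiPerField numeric, expected nuclei per field before
#'   \code{countScale}.
#' @slot countDistribution "poisson" or "fixed".
#' @slot radiusMeanPx,radiusSdPx,radiusMinPx nucleus equivalent-radius
#'   distribution (normal, truncated below) in px.
#' @slot axisRatioRange numeric length-2 in (0, 1]; minor/major axis ratio
#'   is drawn uniformly from it (area is preserved).
#' @slot dapiAmplitude,dapiAmplitudeSdLog per-nucleus DAPI amplitude
#'   (log-normal: given mean scale, log-sd).
#' @slot cy3Amplitude,cy3AmplitudeSdLog per-nucleus Cy3 amplitude before
#'   the condition gain.
#' @slot backgroundDapi,backgroundCy3 numeric length-3
#'   (offset, gradX, gradY): additive plane offset + gradX * col/ncol +
#'   gradY * row/nrow.
#' @slot edgeBlurSigma Gaussian blur sigma (px) applied to both channels.
#' @slot poissonGain scale of Poisson (shot) noise; 0 disables it.
#' @slot gaussianSd additive Gaussian read-noise sd; 0 disables it.
#' @slot bitDepth output bit depth (8 or 16).
#' @slot calibration um per pixel edge.
#' @slot placementMargin px margin kept between nucleus centres and the
#'   field border; \code{NA} means automatic (major axis + 3 blur sigmas,
#'   keeping every nucleus fully interior).
#' @slot maxPlacementTries rejection-sampling retries per nucleus before
#'   giving up on placing it.
#' @slot dateToken,acqRun filename tokens used when writing TIFFs.
#' @slot seed integer master seed.
#' @seealso [syntheticPlateConfig()], [generateField()], [generatePlate()]
#' @export
setClass("SyntheticPlateConfig",
  representation(
    wells = "character", effects = "data.frame",
    controlCondition = "character",
    fieldsPerWell = "integer", imageSize = "integer",
    nucleiPerField = "numeric", countDistribution = "character",
    radiusMeanPx = "numeric", radiusSdPx = "numeric", radiusMinPx = "numeric",
    axisRatioRange = "numeric",
    dapiAmplitude = "numeric", dapiAmplitudeSdLog = "numeric",
    cy3Amplitude = "numeric", cy3AmplitudeSdLog = "numeric",
    backgroundDapi = "numeric", backgroundCy3 = "numeric",
    edgeBlurSigma = "numeric", poissonGain = "numeric", gaussianSd = "numeric",
    bitDepth = "integer", calibration = "numeric",
    placementMargin = "numeric", maxPlacementTries = "integer",
    dateToken = "character", acqRun = "character", seed = "integer"
  )
)

setValidity("SyntheticPlateConfig", function(object) {
  msg <- character()
  if (!length(object@wells) || is.null(names(object@wells)))
    msg <- c(msg, "wells must be a named character vector (well -> condition)")
  else {
    bad <- !grepl("^[A-H](1[0-2]|[1-9])$", names(object@wells))
    if (any(bad))
      msg <- c(msg, paste("invalid well name(s):",
                          paste(names(object@wells)[bad], collapse = ", ")))
    if (anyDuplicated(names(object@wells)))
      msg <- c(msg, "duplicated well names")
  }
  eff <- object@effects
  need <- c("condition", "cy3Gain", "areaScale", "countScale")
  if (!all(need %in% names(eff)))
    msg <- c(msg, paste("effects must have columns:", paste(need, collapse = ", ")))
  else {
    if (!all(object@wells %in% eff$condition))
      msg <- c(msg, "every well condition must have an effects row")
    if (any(eff$cy3Gain <= 0) || any(eff$areaScale <= 0) || any(eff$countScale < 0))
      msg <- c(msg, "cy3Gain and areaScale must be > 0, countScale >= 0")
  }
  if (length(object@controlCondition) != 1L ||
      !object@controlCondition %in% eff$condition)
    msg <- c(msg, "controlCondition must name one effects condition")
  if (object@fieldsPerWell < 1L) msg <- c(msg, "fieldsPerWell must be >= 1")
  if (length(object@imageSize) != 2L || any(object@imageSize < 32L))
    msg <- c(msg, "imageSize must be two values >= 32")
  if (object@radiusMinPx < 1) msg <- c(msg, "radiusMinPx must be >= 1")
  if (length(object@axisRatioRange) != 2L ||
      any(object@axisRatioRange <= 0) || any(object@axisRatioRange > 1))
    msg <- c(msg, "axisRatioRange must lie in (0, 1]")
  if (object@poissonGain < 0 || object@gaussianSd < 0)
    msg <- c(msg, "noise parameters must be >= 0")
  if (!object@bitDepth %in% c(8L, 16L)) msg <- c(msg, "bitDepth must be 8 or 16")
  if (object@calibration <= 0) msg <- c(msg, "calibration must be > 0")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SyntheticPlateConfig", function(object) {
  cat(sprintf("SyntheticPlateConfig: %d well(s), %d field(s)/well, %d x %d px, seed %d\n",
              length(object@wells), object@fieldsPerWell,
              object@imageSize[1], object@imageSize[2], object@seed))
  lay <- paste(sprintf("%s=%s", names(object@wells), object@wells),
               collapse = ", ")
  cat("  layout:", lay, "\n")
  cat("  control condition:", object@controlCondition, "\n")
  print(object@effects, row.names = FALSE)
  invisible(NULL)
})
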
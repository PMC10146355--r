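#' @import methods
NULL

#' Pixel matrix of an image object
#'
#' @param x a \linkS4class{FieldImage}.
#' @return Numeric matrix of pixel intensities (rows = image rows).
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))

#' Bit depth of an image object
#'
#' @param x a \linkS4class{FieldImage}.
#' @return Integer, 8 or 16.
#' @export
setGeneric("bitDepth", function(x) standardGeneric("bitDepth"))

#' Spatial calibration (micrometres per pixel edge)
#'
#' @param x a \linkS4class{FieldImage}.
#' @return Numeric scalar, um per pixel (isotropic).
#' @export
setGeneric("calibration", function(x) standardGeneric("calibration"))

#' Acquisition identity of a field image
#'
#' @param x a \linkS4class{FieldImage}.
#' @return Named list with elements \code{channel}, \code{dateToken},
#'   \code{well}, \code{position}, \code{acqRun} and \code{path}.
#' @export
setGeneric("fieldInfo", function(x) standardGeneric("fieldInfo"))

#' Label matrix of a segmentation mask
#'
#' @param x a \linkS4class{LabeledMask}.
#' @return Integer matrix; 0 is background, 1..n are object labels.
#' @export
setGeneric("maskLabels", function(x) standardGeneric("maskLabels"))

#' Intensity threshold recorded in a segmentation mask
#'
#' @param x a \linkS4class{LabeledMask}.
#' @return Numeric scalar: pixels strictly above this value were foreground.
#' @export
setGeneric("thresholdUsed", function(x) standardGeneric("thresholdUsed"))

#' Number of labeled objects in a mask
#'
#' @param x a \linkS4class{LabeledMask}.
#' @return Integer count of objects.
#' @export
setGeneric("nObjects", function(x) standardGeneric("nObjects"))
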
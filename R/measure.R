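## Canonical zero-row per-object record table.
.emptyRecords <- function() {
  data.frame(well = character(), field = character(), label = integer(),
             areaPx = integer(), areaUm2 = numeric(), mfv = numeric(),
             stringsAsFactors = FALSE)
}

#' Measure per-nucleus mean Cy3 fluorescence under DAPI-derived labels
#'
#' For every labeled object, computes the arithmetic mean of the
#' (background-subtracted) Cy3 pixel values over the object's pixels, plus
#' its area in px and um^2. The ROI is applied to the Cy3 channel exactly
#' as derived from DAPI, with no dilation or erosion. The totals are
#' conserved: summing \code{mfv * areaPx} over objects reproduces the sum
#' of Cy3 intensity over all labeled pixels.
#'
#' @param mask a \linkS4class{LabeledMask} (already edge-excluded in the
#'   standard pipeline).
#' @param cy3 background-subtracted Cy3 \linkS4class{FieldImage} or matrix
#'   of identical shape.
#' @param calibration um per pixel edge (taken from \code{cy3} when it is a
#'   \linkS4class{FieldImage} and left at default).
#' @param well,field identity columns stamped onto the records; default to
#'   the Cy3 image's metadata when available.
#' @return data.frame with one row per object: \code{well}, \code{field},
#'   \code{label}, \code{areaPx}, \code{areaUm2}, \code{mfv}.
#' @export
measureObjects <- function(mask, cy3, calibration = NULL, well = NULL,
                           field = NULL) {
  stopifnot(is(mask, "LabeledMask"))
  px <- .asPixels(cy3)
  lab <- maskLabels(mask)
  if (!identical(dim(lab), dim(px)))
    stop("mask and Cy3 image shapes differ: ",
         paste(dim(lab), collapse = "x"), " vs ",
         paste(dim(px), collapse = "x"))
  info <- if (is(cy3, "FieldImage")) fieldInfo(cy3) else
    list(well = NA_character_, position = NA_character_)
  if (is.null(well)) well <- info$well
  if (is.null(field)) field <- info$position
  if (is.null(calibration))
    calibration <- if (is(cy3, "FieldImage")) calibration(cy3) else 2.6

  n <- mask@nObjects
  if (n == 0L) return(.emptyRecords())
  sel <- lab > 0L
  l <- lab[sel]
  v <- px[sel]
  cnt <- tabulate(l, nbins = n)
  tot <- as.vector(rowsum(v, l))   # groups 1..n, all present, sorted
  data.frame(well = well, field = field, label = seq_len(n),
             areaPx = cnt, areaUm2 = cnt * calibration^2, mfv = tot / cnt,
             stringsAsFactors = FALSE)
}
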
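## Genotoxicity statistics. MoA (mean fluorescence value over area) scales
## the well's mean gammaH2AX signal by the mean nucleus area; the fold
## change of MoA over the negative control flags genotoxicity above 1.5x,
## while the relative nuclei area (RA, % of control) is the cytotoxicity
## proxy standing in for relative cell counts: a strong signal in a well
## whose cell mass collapsed below 25% of control is scored as a
## cytotoxicity-driven false positive, not as genotoxicity.

#' Mean fluorescence value over area (MoA)
#'
#' @param mfvMean well-level mean of per-object mean fluorescence.
#' @param areaMean well-level mean nucleus area (must be > 0).
#' @return \code{mfvMean / areaMean}; vectorized.
#' @examples
#' moa(1.641, 2.130)  # 0.770...
#' @export
moa <- function(mfvMean, areaMean) {
  if (any(!is.finite(areaMean)) || any(areaMean <= 0))
    stop("areaMean must be positive and finite")
  mfvMean / areaMean
}

#' Fold change of MoA over the negative control
#'
#' @param moaSample MoA of the treated condition.
#' @param moaCtrl MoA of its negative control (must be > 0).
#' @return \code{moaSample / moaCtrl}; vectorized. Invariant under any
#'   common rescaling of intensities or of the spatial calibration.
#' @examples
#' foldChange(moa(2.179, 1.423), moa(1.641, 2.130))  # about 1.99
#' @export
foldChange <- function(moaSample, moaCtrl) {
  if (any(!is.finite(moaCtrl)) || any(moaCtrl <= 0))
    stop("control MoA must be positive and finite")
  moaSample / moaCtrl
}

#' Relative area (RA, percent of control)
#'
#' @param areaSample mean nucleus area of the treated condition.
#' @param areaCtrl mean nucleus area of its control (must be > 0).
#' @return \code{100 * areaSample / areaCtrl}; vectorized. Values above
#'   100 (proliferation above control) are allowed.
#' @examples
#' relativeArea(1.423, 2.130)  # 66.8 %
#' @export
relativeArea <- function(areaSample, areaCtrl) {
  if (any(!is.finite(areaCtrl)) || any(areaCtrl <= 0))
    stop("control area must be positive and finite")
  100 * areaSample / areaCtrl
}

.CALLS <- c("GENOTOXIC", "NON_GENOTOXIC",
            "CYTOTOXICITY_DRIVEN_FALSE_POSITIVE", "EQUIVOCAL",
            "NOT_EVALUABLE")

#' Classify a (fold, RA) pair
#'
#' Applies the screening decision rules: fold above the threshold with RA
#' above the limit is GENOTOXIC; fold below the threshold is NON_GENOTOXIC
#' at any RA; fold above the threshold but RA below the limit is a
#' cytotoxicity-driven false positive; fold exactly at the threshold
#' (within \code{tol}) with RA at or above the limit is EQUIVOCAL. The two
#' cells the rules leave open -- fold exactly at threshold with RA below
#' the limit, and fold above threshold with RA exactly at the limit -- are
#' returned as NOT_EVALUABLE with a warning rather than silently coerced.
#'
#' @param fold MoA fold change(s) over control.
#' @param raPercent relative area(s), percent of control.
#' @param foldThreshold genotoxicity threshold on fold (default 1.5).
#' @param raLimit evaluability limit on RA in percent (default 25).
#' @param tol tolerance for "exactly at threshold" (default 1e-9).
#' @return character vector of calls; non-finite inputs give
#'   NOT_EVALUABLE.
#' @examples
#' classifyGenotox(4.495, 40.83)   # GENOTOXIC
#' classifyGenotox(1.063, 90.94)   # NON_GENOTOXIC
#' classifyGenotox(2.0, 20.0)      # false positive
#' @export
classifyGenotox <- function(fold, raPercent, foldThreshold = 1.5,
                            raLimit = 25, tol = 1e-9) {
  stopifnot(length(fold) == length(raPercent))
  out <- character(length(fold))
  for (i in seq_along(fold)) {
    f <- fold[i]; ra <- raPercent[i]
    if (!is.finite(f) || !is.finite(ra)) {
      out[i] <- "NOT_EVALUABLE"
      next
    }
    if (abs(f - foldThreshold) <= tol) {
      if (ra >= raLimit) out[i] <- "EQUIVOCAL"
      else {
        warning("fold exactly at threshold with RA below limit: ",
                "not evaluable", call. = FALSE)
        out[i] <- "NOT_EVALUABLE"
      }
    } else if (f > foldThreshold) {
      if (ra > raLimit) out[i] <- "GENOTOXIC"
      else if (ra < raLimit) out[i] <- "CYTOTOXICITY_DRIVEN_FALSE_POSITIVE"
      else {
        warning("fold above threshold with RA exactly at limit: ",
                "not evaluable", call. = FALSE)
        out[i] <- "NOT_EVALUABLE"
      }
    } else out[i] <- "NON_GENOTOXIC"
  }
  out
}

#' Score every treated condition against its negative control
#'
#' Aggregates well summaries to condition level (wells sharing a condition
#' are pooled by object-count-weighted means, which equals pooling the raw
#' objects), computes MoA for sample and control, the fold change, the
#' relative area, and the classification call. Conditions whose summary or
#' control is missing or degenerate are reported as NOT_EVALUABLE.
#'
#' @param summaries data.frame of well summaries (see [summarizeWell()]).
#' @param layout plate layout (see [plateLayout()]); its \code{control}
#'   column links each treated condition to its negative control.
#' @param foldThreshold,raLimit classification thresholds (see
#'   [classifyGenotox()]).
#' @return data.frame with one row per treated condition: \code{condition},
#'   \code{control}, \code{moaSample}, \code{moaCtrl}, \code{fold},
#'   \code{raPercent}, \code{call}. Zero rows when the layout has no
#'   treated condition.
#' @export
scoreConditions <- function(summaries, layout, foldThreshold = 1.5,
                            raLimit = 25) {
  stopifnot(all(c("well", "condition", "control") %in% names(layout)))
  treated <- unique(layout[!is.na(layout$control),
                           c("condition", "control")])
  res <- data.frame(condition = character(), control = character(),
                    moaSample = numeric(), moaCtrl = numeric(),
                    fold = numeric(), raPercent = numeric(),
                    call = character(), stringsAsFactors = FALSE)
  if (!nrow(treated)) return(res)

  condStats <- function(cond) {
    s <- summaries[!is.na(summaries$condition) & summaries$condition == cond &
                     summaries$nObjects > 0, , drop = FALSE]
    if (!nrow(s)) return(list(mfv = NA_real_, area = NA_real_))
    w <- s$nObjects
    list(mfv = sum(w * s$mfvMean) / sum(w),
         area = sum(w * s$areaMeanUm2) / sum(w))
  }

  for (i in seq_len(nrow(treated))) {
    cond <- treated$condition[i]
    ctrl <- treated$control[i]
    cs <- condStats(cond)
    xs <- condStats(ctrl)
    ok <- is.finite(cs$mfv) && is.finite(cs$area) && cs$area > 0 &&
      is.finite(xs$mfv) && is.finite(xs$area) && xs$area > 0
    if (ok) {
      moaS <- moa(cs$mfv, cs$area)
      moaC <- moa(xs$mfv, xs$area)
      fold <- if (moaC > 0) foldChange(moaS, moaC) else NA_real_
      ra <- relativeArea(cs$area, xs$area)
      call <- classifyGenotox(fold, ra, foldThreshold, raLimit)
    } else {
      moaS <- moaC <- fold <- ra <- NA_real_
      call <- "NOT_EVALUABLE"
    }
    res <- rbind(res, data.frame(
      condition = cond, control = ctrl, moaSample = moaS, moaCtrl = moaC,
      fold = fold, raPercent = ra, call = call, stringsAsFactors = FALSE))
  }
  res
}
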
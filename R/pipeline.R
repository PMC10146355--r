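## Orchestration of the three workflow steps: sorting the image dump,
## image analysis (segmentation, background subtraction, measurement), and
## feature analysis (well statistics, genotoxicity scoring).

## QC export: object outlines as a PNG (white outline on black).
.writeOutlinePng <- function(mask, path) {
  lab <- maskLabels(mask)
  fg <- lab > 0L
  n <- nrow(fg); m <- ncol(fg)
  pad <- function(M, dr, dc) {
    out <- matrix(FALSE, n, m)
    rs <- seq_len(n) + dr; cs <- seq_len(m) + dc
    ok_r <- rs >= 1 & rs <= n; ok_c <- cs >= 1 & cs <= m
    out[ok_r, ok_c] <- M[rs[ok_r], cs[ok_c]]
    out
  }
  interior <- fg & pad(fg, 1, 0) & pad(fg, -1, 0) & pad(fg, 0, 1) &
    pad(fg, 0, -1)
  outline <- fg & !interior
  png::writePNG(outline * 1, path)
  invisible(path)
}

#' Run the full screening pipeline on an image folder
#'
#' Sorts the folder into per-well field groups, segments nuclei in the
#' DAPI channel (per-well threshold propagation by default), removes
#' edge-touching objects, subtracts the rolling-ball background from the
#' Cy3 channel, measures each nucleus, pools objects into well summaries,
#' scores each treated condition against its negative control and writes
#' all result tables, the run log and the effective configuration.
#'
#' Soft per-well failures (a constant threshold image) are logged; the well
#' keeps an empty summary and any condition depending on it is reported as
#' NOT_EVALUABLE. Two runs on identical inputs produce identical CSVs.
#'
#' @param inputDir folder of acquisition TIFFs named by the filename
#'   convention.
#' @param outputDir where results are written.
#' @param layout plate layout data.frame (see [plateLayout()]) or path to a
#'   layout CSV/YAML.
#' @param calibration um per pixel edge.
#' @param thresholdPolicy threshold propagation mode (see [segmentWell()]).
#' @param bins histogram bins for Otsu.
#' @param backgroundRadius rolling-ball radius in px for the Cy3 channel.
#' @param minAreaPx,fillHoles optional particle filters (see
#'   [segmentWell()]).
#' @param foldThreshold,raLimit classification thresholds (see
#'   [classifyGenotox()]).
#' @param channels canonical-to-token channel map (see
#'   [parseFieldFilename()]).
#' @param overlay also write per-field object-outline PNGs for QC.
#' @return Invisibly, a list with \code{records} (per-object data.frame),
#'   \code{summaries} (per-well), \code{conditions} (per treated
#'   condition) and \code{paths} (files written).
#' @export
runPipeline <- function(inputDir, outputDir, layout,
                        calibration = 2.6,
                        thresholdPolicy = "per_well_first_field",
                        bins = 256L, backgroundRadius = 50,
                        minAreaPx = 0L, fillHoles = FALSE,
                        foldThreshold = 1.5, raLimit = 25,
                        channels = .DEFAULT_CHANNELS, overlay = FALSE) {
  if (is.character(layout)) layout <- readPlateLayout(layout)
  layout <- plateLayout(layout$well, layout$condition, layout$control)

  plan <- sortPlate(inputDir, channels)
  dir.create(outputDir, recursive = TRUE, showWarnings = FALSE)

  records <- NULL
  summaries <- NULL
  logLines <- character()

  for (w in names(plan)) {
    pw <- plan[[w]]
    cond <- layout$condition[match(w, layout$well)]
    dapiRows <- pw[!is.na(pw$dapi), , drop = FALSE]
    if (!nrow(dapiRows)) {
      logLines <- c(logLines, sprintf("well %s: no DAPI fields, skipped", w))
      next
    }
    dapiImgs <- lapply(dapiRows$dapi, readFieldImage,
                       calibration = calibration, channels = channels)
    d <- dim(pixels(dapiImgs[[1]]))
    masks <- tryCatch(
      segmentWell(dapiImgs, policy = thresholdPolicy, bins = bins,
                  minAreaPx = minAreaPx, fillHoles = fillHoles),
      constant_image_error = function(e) NULL)
    if (is.null(masks)) {
      logLines <- c(logLines, sprintf(
        "well %s: constant threshold image, well flagged (not analyzable)", w))
      sm <- suppressWarnings(summarizeWell(.emptyRecords(), condition = cond))
      sm$well <- w
      summaries <- rbind(summaries, sm)
      next
    }
    masks <- lapply(masks, excludeEdgeObjects)
    thr <- thresholdUsed(masks[[1]])

    wellRecords <- NULL
    for (i in seq_len(nrow(dapiRows))) {
      pos <- dapiRows$position[i]
      mk <- masks[[pos]]
      cy3Path <- pw$cy3[pw$position == pos]
      if (is.na(cy3Path)) next   # unpaired field: segmented but unmeasured
      cy3 <- readFieldImage(cy3Path, calibration = calibration,
                            channels = channels)
      cy3s <- rollingBallSubtract(cy3, radius = backgroundRadius)
      rec <- measureObjects(mk, cy3s, calibration = calibration,
                            well = w, field = pos)
      wellRecords <- rbind(wellRecords, rec)
      if (overlay)
        .writeOutlinePng(mk, file.path(outputDir,
                                       sprintf("overlay_%s_%s.png", w, pos)))
    }
    if (is.null(wellRecords)) wellRecords <- .emptyRecords()
    sm <- withCallingHandlers(
      summarizeWell(wellRecords, condition = cond, threshold = thr),
      warning = function(wn) {
        logLines <<- c(logLines, sprintf("well %s: %s", w,
                                         conditionMessage(wn)))
        invokeRestart("muffleWarning")
      })
    if (sm$nObjects == 0L && is.na(sm$well)) sm$well <- w
    summaries <- rbind(summaries, sm)
    records <- rbind(records, wellRecords)
    logLines <- c(logLines, sprintf(
      "well %s: fields=%d imageSize=%dx%d objects=%d threshold=%s policy=%s",
      w, nrow(dapiRows), d[1], d[2], sm$nObjects, format(thr),
      thresholdPolicy))
  }

  conditions <- scoreConditions(summaries, layout,
                                foldThreshold = foldThreshold,
                                raLimit = raLimit)

  paths <- writeResults(records, summaries, outputDir,
                        conditions = conditions, logLines = logLines)
  cfg <- list(inputDir = inputDir, outputDir = outputDir,
              calibration = calibration, thresholdPolicy = thresholdPolicy,
              bins = as.integer(bins), backgroundRadius = backgroundRadius,
              minAreaPx = as.integer(minAreaPx), fillHoles = fillHoles,
              foldThreshold = foldThreshold, raLimit = raLimit,
              channels = as.list(channels))
  cfgPath <- file.path(outputDir, "effective_config.yaml")
  yaml::write_yaml(cfg, cfgPath)
  paths <- c(paths, effective_config = cfgPath)

  invisible(list(records = records, summaries = summaries,
                 conditions = conditions, paths = paths))
}
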
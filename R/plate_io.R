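## Acquisition filename convention:
##   ChannelName_DateToken_Well_PositionInWell_AcqRun.FileFormat
## The date token is opaque (its day-field width is ambiguous); it is never
## parsed as a date. Wells are A-H x 1-12.

.WELL_RE <- "^[A-H](1[0-2]|[1-9])$"
.DEFAULT_CHANNELS <- c(DAPI = "DAPI", Cy3 = "Cy3")

## Tokenize a vector of bare filenames; returns a data.frame with an `ok`
## column instead of raising, so callers can choose strict or skip semantics.
.parseFieldTokens <- function(names, channels = .DEFAULT_CHANNELS) {
  stopifnot(is.character(names))
  base <- tools::file_path_sans_ext(basename(names))
  parts <- strsplit(base, "_", fixed = TRUE)
  n <- length(names)
  out <- data.frame(
    filename = basename(names),
    channel = NA_character_, dateToken = NA_character_,
    well = NA_character_, position = NA_character_, acqRun = NA_character_,
    ok = FALSE, reason = NA_character_,
    stringsAsFactors = FALSE
  )
  for (i in seq_len(n)) {
    p <- parts[[i]]
    if (length(p) != 5L) {
      out$reason[i] <- sprintf("expected 5 underscore-separated tokens, got %d",
                               length(p))
      next
    }
    if (!grepl(.WELL_RE, p[3])) {
      out$reason[i] <- sprintf("invalid well token '%s'", p[3])
      next
    }
    canon <- names(channels)[match(p[1], channels)]
    if (is.na(canon)) {
      out$reason[i] <- sprintf("unknown channel token '%s'", p[1])
      next
    }
    out$channel[i] <- canon
    out$dateToken[i] <- p[2]
    out$well[i] <- p[3]
    out$position[i] <- p[4]
    out$acqRun[i] <- p[5]
    out$ok[i] <- TRUE
  }
  out
}

#' Parse acquisition filenames into field references
#'
#' Splits bare filenames of the form
#' \code{ChannelName_DateToken_Well_PositionInWell_AcqRun.ext} into their
#' five tokens. The date token is kept as an opaque string. Malformed names
#' raise an error rather than being guessed at.
#'
#' @param names character vector of bare filenames (extension included).
#' @param channels named character vector mapping canonical channel names
#'   (names) to the channel tokens used in the filenames (values); defaults
#'   to \code{c(DAPI = "DAPI", Cy3 = "Cy3")}.
#' @return data.frame with columns \code{filename}, \code{channel}
#'   (canonical), \code{dateToken}, \code{well}, \code{position},
#'   \code{acqRun}; one row per input name.
#' @examples
#' parseFieldFilename("DAPI_20230101_B8_0003_01.tif")
#' @export
parseFieldFilename <- function(names, channels = .DEFAULT_CHANNELS) {
  tok <- .parseFieldTokens(names, channels)
  if (any(!tok$ok)) {
    bad <- which(!tok$ok)[1]
    stop(errorCondition(
      sprintf("malformed field filename '%s': %s",
              tok$filename[bad], tok$reason[bad]),
      class = c("malformed_name_error", "error", "condition")))
  }
  tok$ok <- NULL
  tok$reason <- NULL
  tok
}

#' Compose an acquisition filename from its tokens
#'
#' Inverse of [parseFieldFilename()]: for any valid reference,
#' \code{parseFieldFilename(composeFieldFilename(ref))} returns the tokens
#' unchanged.
#'
#' @param ref data.frame or named list with \code{channel} (canonical),
#'   \code{dateToken}, \code{well}, \code{position}, \code{acqRun}.
#' @param ext file extension without dot, default "tif".
#' @param channels canonical-to-token channel map (see
#'   [parseFieldFilename()]).
#' @return character vector of filenames.
#' @export
composeFieldFilename <- function(ref, ext = "tif",
                                 channels = .DEFAULT_CHANNELS) {
  tokens <- channels[as.character(ref$channel)]
  if (any(is.na(tokens)))
    stop("unknown canonical channel in ref")
  paste0(tokens, "_", ref$dateToken, "_", ref$well, "_", ref$position, "_",
         ref$acqRun, ".", ext)
}

#' Sort a flat image dump into per-well, channel-paired field groups
#'
#' Scans a folder of acquisition TIFFs, parses each filename, groups files
#' by well and pairs the DAPI and Cy3 image of each field position by exact
#' position-token match. Non-parseable files are skipped with a warning.
#' The result is independent of file-system ordering: wells are sorted by
#' row letter then column number and positions lexicographically.
#'
#' @param folder directory containing the images.
#' @param channels canonical-to-token channel map.
#' @param pattern regular expression selecting image files.
#' @return Named list (one element per well) of data.frames with columns
#'   \code{position}, \code{dapi}, \code{cy3} (absolute file paths,
#'   \code{NA} when a channel is missing) and \code{complete}. Skipped
#'   filenames are attached as attribute \code{"skipped"}.
#' @export
sortPlate <- function(folder, channels = .DEFAULT_CHANNELS,
                      pattern = "\\.(tif|tiff)$") {
  if (!dir.exists(folder)) stop("folder does not exist: ", folder)
  files <- sort(list.files(folder, pattern = pattern, ignore.case = TRUE))
  if (!length(files))
    stop(errorCondition(paste("no image files found in", folder),
                        class = c("empty_folder_error", "error", "condition")))
  tok <- .parseFieldTokens(files, channels)
  if (any(!tok$ok)) {
    skipped <- tok$filename[!tok$ok]
    warning(sprintf("skipping %d non-parseable file(s): %s",
                    length(skipped),
                    paste(utils::head(skipped, 5), collapse = ", ")),
            call. = FALSE)
  } else skipped <- character()
  tok <- tok[tok$ok, , drop = FALSE]
  if (!nrow(tok))
    stop(errorCondition("no parseable image files in folder",
                        class = c("empty_folder_error", "error", "condition")))
  tok$path <- file.path(normalizePath(folder), tok$filename)

  wells <- unique(tok$well)
  wells <- wells[order(substr(wells, 1, 1),
                       as.integer(substring(wells, 2)))]
  out <- vector("list", length(wells))
  names(out) <- wells
  for (w in wells) {
    tw <- tok[tok$well == w, , drop = FALSE]
    positions <- sort(unique(tw$position))
    pick <- function(chan, pos) {
      p <- tw$path[tw$channel == chan & tw$position == pos]
      if (length(p) > 1) {
        warning(sprintf("well %s position %s: %d duplicate %s files, using first",
                        w, pos, length(p), chan), call. = FALSE)
        p <- p[1]
      }
      if (length(p)) p else NA_character_
    }
    dapi <- vapply(positions, pick, character(1), chan = "DAPI")
    cy3 <- vapply(positions, pick, character(1), chan = "Cy3")
    complete <- !is.na(dapi) & !is.na(cy3)
    if (any(!complete))
      warning(sprintf("well %s: %d field position(s) with an unpaired channel",
                      w, sum(!complete)), call. = FALSE)
    out[[w]] <- data.frame(position = positions, dapi = unname(dapi),
                           cy3 = unname(cy3), complete = unname(complete),
                           stringsAsFactors = FALSE)
  }
  attr(out, "skipped") <- skipped
  out
}

#' Read one single-channel TIFF field
#'
#' Reads an 8- or 16-bit single-page grayscale TIFF into a
#' \linkS4class{FieldImage}, taking acquisition identity from the filename
#' when it follows the naming convention. Multi-channel or multi-page files
#' are rejected.
#'
#' @param path TIFF file path.
#' @param calibration um per pixel edge (default 2.6: 0.65 um camera pixel
#'   with 4x4 binning).
#' @param channels canonical-to-token channel map for filename parsing.
#' @return A \linkS4class{FieldImage} with integer-valued pixels.
#' @export
readFieldImage <- function(path, calibration = 2.6,
                           channels = .DEFAULT_CHANNELS) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  info <- tiff::readTIFF(path, payload = FALSE)
  bits <- unique(unlist(info$bits.per.sample))
  if (length(bits) != 1L || !bits %in% c(8L, 16L))
    stop("unsupported bit depth in ", path)
  px <- tiff::readTIFF(path, as.is = TRUE)
  if (!is.matrix(px))
    stop("only single-channel single-page grayscale TIFFs are supported: ",
         path)
  tok <- .parseFieldTokens(basename(path), channels)
  FieldImage(px, bitDepth = as.integer(bits), calibration = calibration,
             channel = tok$channel, dateToken = tok$dateToken,
             well = tok$well, position = tok$position, acqRun = tok$acqRun,
             path = path)
}

## Write a FieldImage (or integer matrix) as a grayscale TIFF.
.writeFieldTiff <- function(pixels, path, bitDepth = 16L) {
  scale <- 2^bitDepth - 1
  stopifnot(all(pixels >= 0), all(pixels <= scale))
  tiff::writeTIFF(pixels / scale, path, bits.per.sample = as.integer(bitDepth))
  invisible(path)
}

#' Write per-object, per-well and per-condition result tables plus run log
#'
#' Writes one per-object CSV per well (into a \code{Results} subfolder), a
#' plate-level well-summary CSV, an optional condition-result CSV and a
#' plain-text run log recording the package version, image sizes, object
#' counts and the threshold used in every well. All CSVs use "." as decimal
#' separator and "," as delimiter. Apart from the timestamp line of the log,
#' reruns on identical input produce byte-identical files.
#'
#' @param records per-object data.frame (see [measureObjects()]); may have
#'   zero rows.
#' @param summaries per-well summary data.frame (see [summarizeWell()]).
#' @param outDir output directory (created if needed).
#' @param conditions optional condition-result data.frame
#'   (see [scoreConditions()]).
#' @param logLines optional extra character lines for the run log.
#' @return Named character vector of the files written (invisibly).
#' @export
writeResults <- function(records, summaries, outDir, conditions = NULL,
                         logLines = character()) {
  resDir <- file.path(outDir, "Results")
  dir.create(resDir, recursive = TRUE, showWarnings = FALSE)
  paths <- c()

  if (is.null(records) || !nrow(records)) {
    warning("no object records to write; emitting header-only CSV",
            call. = FALSE)
    empty <- data.frame(well = character(), field = character(),
                        label = integer(), areaPx = integer(),
                        areaUm2 = numeric(), mfv = numeric())
    p <- file.path(resDir, "objects_EMPTY.csv")
    utils::write.csv(empty, p, row.names = FALSE)
    paths <- c(paths, objects = p)
  } else {
    for (w in sort(unique(records$well))) {
      p <- file.path(resDir, sprintf("objects_%s.csv", w))
      sub <- records[records$well == w, , drop = FALSE]
      sub <- sub[order(sub$field, sub$label), , drop = FALSE]
      utils::write.csv(sub, p, row.names = FALSE)
      paths <- c(paths, stats::setNames(p, paste0("objects_", w)))
    }
  }

  sp <- file.path(resDir, "well_summary.csv")
  utils::write.csv(summaries, sp, row.names = FALSE)
  paths <- c(paths, well_summary = sp)

  if (!is.null(conditions)) {
    cp <- file.path(resDir, "condition_results.csv")
    utils::write.csv(conditions, cp, row.names = FALSE)
    paths <- c(paths, condition_results = cp)
  }

  lp <- file.path(resDir, "run_log.txt")
  hdr <- c(
    paste("timestamp:", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    paste("genotoxHCS version:", as.character(utils::packageVersion("genotoxHCS")))
  )
  wellLines <- character()
  if (!is.null(summaries) && nrow(summaries)) {
    wellLines <- sprintf(
      "well %s: objects=%s threshold=%s",
      summaries$well, summaries$nObjects,
      vapply(summaries$thresholdUsed, function(t)
        if (is.na(t)) "NA" else format(t), character(1)))
  }
  writeLines(c(hdr, logLines, wellLines), lp)
  paths <- c(paths, run_log = lp)
  invisible(paths)
}

#' Construct and validate a plate layout
#'
#' A plate layout maps each analyzed well to a condition label and each
#' treated condition to exactly one negative-control condition.
#'
#' @param well character vector of wells ("A1".."H12").
#' @param condition condition label per well.
#' @param control for treated wells, the condition label of their negative
#'   control; \code{NA} for control wells themselves.
#' @return Validated data.frame with columns \code{well}, \code{condition},
#'   \code{control}.
#' @examples
#' plateLayout(c("B2", "B4"), c("ctrl", "val30"), c(NA, "ctrl"))
#' @export
plateLayout <- function(well, condition, control = NA_character_) {
  lay <- data.frame(well = as.character(well),
                    condition = as.character(condition),
                    control = as.character(control),
                    stringsAsFactors = FALSE)
  bad <- !grepl(.WELL_RE, lay$well)
  if (any(bad))
    stop("invalid well name(s): ", paste(lay$well[bad], collapse = ", "))
  if (anyDuplicated(lay$well))
    stop("duplicated wells in layout")
  if (any(is.na(lay$condition) | lay$condition == ""))
    stop("every well needs a condition label")
  treated <- lay[!is.na(lay$control), , drop = FALSE]
  if (nrow(treated)) {
    ctrlMap <- tapply(treated$control, treated$condition,
                      function(x) length(unique(x)))
    if (any(ctrlMap > 1))
      stop("a treated condition resolves to more than one control condition")
    missing <- setdiff(unique(treated$control), lay$condition)
    if (length(missing))
      stop("control condition(s) not present in layout: ",
           paste(missing, collapse = ", "))
  }
  lay
}

#' Read a plate layout from CSV or YAML
#'
#' @param path file with columns/keys \code{well}, \code{condition},
#'   \code{control}.
#' @return Validated layout data.frame (see [plateLayout()]).
#' @export
readPlateLayout <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yml", "yaml")) {
    y <- yaml::read_yaml(path)
    lay <- do.call(rbind, lapply(y, function(r)
      data.frame(well = r$well, condition = r$condition,
                 control = if (is.null(r$control)) NA_character_ else r$control,
                 stringsAsFactors = FALSE)))
  } else {
    lay <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  if (!"control" %in% names(lay)) lay$control <- NA_character_
  plateLayout(lay$well, lay$condition, lay$control)
}
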
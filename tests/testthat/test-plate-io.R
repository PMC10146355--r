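test_that("filename parsing extracts the five convention tokens", {
  ref <- parseFieldFilename("DAPI_20230101_B8_0003_01.tif")
  expect_equal(ref$channel, "DAPI")
  expect_equal(ref$well, "B8")
  expect_equal(ref$position, "0003")
  expect_equal(ref$dateToken, "20230101")
  expect_equal(ref$acqRun, "01")

  ref2 <- parseFieldFilename("Cy3_20230101_C4_0016_01.tif")
  expect_equal(ref2$channel, "Cy3")
  expect_equal(ref2$well, "C4")
  expect_equal(ref2$position, "0016")
})

test_that("malformed names raise instead of guessing", {
  expect_error(parseFieldFilename("nuclei.tif"),
               class = "malformed_name_error")
  expect_error(parseFieldFilename("DAPI_20230101_Z4_0001_01.tif"),
               class = "malformed_name_error")   # invalid well row
  expect_error(parseFieldFilename("DAPI_20230101_B13_0001_01.tif"),
               class = "malformed_name_error")   # invalid well column
  expect_error(parseFieldFilename("FITC_20230101_B8_0001_01.tif"),
               class = "malformed_name_error")   # unsupported channel
})

test_that("compose/parse round-trips on randomized valid tokens", {
  set.seed(17)
  wells <- paste0(sample(LETTERS[1:8], 50, TRUE), sample(1:12, 50, TRUE))
  refs <- data.frame(
    channel = sample(c("DAPI", "Cy3"), 50, TRUE),
    dateToken = sprintf("2023%03d", sample(1:999, 50, TRUE)),
    well = wells,
    position = sprintf("%04d", sample(1:16, 50, TRUE)),
    acqRun = sprintf("%02d", sample(1:9, 50, TRUE)),
    stringsAsFactors = FALSE)
  back <- parseFieldFilename(composeFieldFilename(refs))
  expect_equal(back[names(refs)], refs)
})

test_that("channel aliases are configurable", {
  ch <- c(DAPI = "Hoechst", Cy3 = "AF555")
  ref <- parseFieldFilename("Hoechst_20230101_B8_0001_01.tif", channels = ch)
  expect_equal(ref$channel, "DAPI")
  expect_equal(composeFieldFilename(ref, channels = ch),
               "Hoechst_20230101_B8_0001_01.tif")
})

makeDump <- function(dir, wells, positions, channels = c("DAPI", "Cy3"),
                     drop = character()) {
  dir.create(dir, showWarnings = FALSE)
  files <- c(outer(channels, as.vector(outer(wells, positions, paste,
                                             sep = "_")),
                   function(c, wp) paste0(c, "_20230101_", wp, "_01.tif")))
  files <- setdiff(files, drop)
  file.create(file.path(dir, sample(files)))  # creation order randomized
  files
}

test_that("sortPlate groups paired fields per well deterministically", {
  dir <- withr::local_tempdir()
  pos <- sprintf("%04d", 1:16)
  makeDump(dir, c("B8", "C4"), pos)
  plan <- sortPlate(dir)
  expect_named(plan, c("B8", "C4"))
  expect_equal(nrow(plan$B8), 16)
  expect_true(all(plan$B8$complete))
  expect_equal(plan$B8$position, pos)   # lexicographic within well
})

test_that("sortPlate is invariant to file creation order", {
  pos <- sprintf("%04d", 1:8)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  set.seed(1); makeDump(d1, c("A1", "H12"), pos)
  set.seed(99); makeDump(d2, c("A1", "H12"), pos)
  p1 <- sortPlate(d1); p2 <- sortPlate(d2)
  strip <- function(p) lapply(p, function(df) df[c("position", "complete")])
  expect_equal(strip(p1), strip(p2))
  expect_equal(names(p1), names(p2))
})

test_that("an unpaired channel is flagged but the DAPI field is retained", {
  dir <- withr::local_tempdir()
  makeDump(dir, "B8", sprintf("%04d", 1:4),
           drop = "Cy3_20230101_B8_0002_01.tif")
  expect_warning(plan <- sortPlate(dir), "unpaired")
  b8 <- plan$B8
  expect_equal(nrow(b8), 4)
  expect_false(b8$complete[b8$position == "0002"])
  expect_false(is.na(b8$dapi[b8$position == "0002"]))
  expect_true(is.na(b8$cy3[b8$position == "0002"]))
})

test_that("non-parseable files are skipped with a warning; empty folder errors", {
  dir <- withr::local_tempdir()
  makeDump(dir, "B8", sprintf("%04d", 1:2))
  file.create(file.path(dir, "nuclei.tif"))
  expect_warning(plan <- sortPlate(dir), "skipping")
  expect_equal(attr(plan, "skipped"), "nuclei.tif")

  empty <- withr::local_tempdir()
  expect_error(sortPlate(empty), class = "empty_folder_error")
})

test_that("result writing emits per-well CSVs, summary, and a provenance log", {
  rec <- data.frame(well = "B2", field = "0001", label = 1:3,
                    areaPx = c(10L, 20L, 30L), areaUm2 = c(10, 20, 30) * 6.76,
                    mfv = c(1.5, 2.5, 3.5))
  sm <- summarizeWell(rec, condition = "ctrl", threshold = 123)
  dir <- withr::local_tempdir()
  paths <- writeResults(rec, sm, dir)
  obj <- read.csv(paths[["objects_B2"]])
  expect_equal(nrow(obj), 3)
  expect_equal(obj$mfv, rec$mfv)
  log <- readLines(paths[["run_log"]])
  expect_true(any(grepl("threshold=123", log)))
  expect_true(any(grepl("version", log)))
})

test_that("empty record set yields a header-only CSV with a warning", {
  rec <- data.frame(well = character(), field = character(),
                    label = integer(), areaPx = integer(),
                    areaUm2 = numeric(), mfv = numeric())
  sm <- suppressWarnings(summarizeWell(rec))
  dir <- withr::local_tempdir()
  expect_warning(paths <- writeResults(rec, sm, dir), "header-only")
  expect_equal(nrow(read.csv(paths[["objects"]])), 0)
})

test_that("reruns produce byte-identical CSVs (log differs only by timestamp)", {
  rec <- data.frame(well = "B2", field = "0001", label = 1:5,
                    areaPx = 11:15, areaUm2 = (11:15) * 6.76,
                    mfv = sqrt(2:6) * pi)
  sm <- summarizeWell(rec, condition = "ctrl", threshold = 77)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- writeResults(rec, sm, d1)
  p2 <- writeResults(rec, sm, d2)
  for (key in c("objects_B2", "well_summary"))
    expect_identical(readBin(p1[[key]], "raw", 1e6),
                     readBin(p2[[key]], "raw", 1e6))
  l1 <- readLines(p1[["run_log"]]); l2 <- readLines(p2[["run_log"]])
  expect_identical(l1[-1], l2[-1])
})

test_that("plate layout validation enforces the control mapping", {
  lay <- plateLayout(c("B2", "B4"), c("ctrl", "val30"), c(NA, "ctrl"))
  expect_equal(nrow(lay), 2)
  expect_error(plateLayout("Z9", "ctrl"), "invalid well")
  expect_error(plateLayout(c("B2", "B4"), c("ctrl", "val30"),
                           c(NA, "missing")), "not present")
  expect_error(plateLayout(c("B2", "B3", "B4", "B5"),
                           c("c1", "c2", "val", "val"),
                           c(NA, NA, "c1", "c2")),
               "more than one control")
})

test_that("TIFF write/read round-trips pixels, bit depth and identity", {
  dir <- withr::local_tempdir()
  px <- matrix(sample(0:65535, 32 * 32, TRUE), 32, 32)
  path <- file.path(dir, "DAPI_20230101_B8_0001_01.tif")
  genotoxHCS:::.writeFieldTiff(px, path, 16L)
  img <- readFieldImage(path, calibration = 1.3)
  expect_equal(pixels(img), px, ignore_attr = TRUE)
  expect_equal(bitDepth(img), 16L)
  expect_equal(calibration(img), 1.3)
  expect_equal(fieldInfo(img)$well, "B8")
  expect_equal(fieldInfo(img)$channel, "DAPI")
})
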
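test_that("field generation is deterministic and order-independent", {
  cfg <- smallPlateConfig(seed = 101L)
  a <- generateField(cfg, "B4", 2)
  b <- generateField(cfg, "B2", 1)     # interleave another field
  c <- generateField(cfg, "B4", 2)
  expect_identical(pixels(a$dapi), pixels(c$dapi))
  expect_identical(pixels(a$cy3), pixels(c$cy3))
  expect_identical(a$truth, c$truth)
  expect_false(identical(pixels(a$dapi), pixels(b$dapi)))
})

test_that("a zero count scale yields an empty field and empty truth", {
  cfg <- syntheticPlateConfig(
    wells = c(B2 = "ctrl", B4 = "dead"),
    effects = data.frame(condition = c("ctrl", "dead"), cy3Gain = c(1, 1),
                         areaScale = c(1, 1), countScale = c(1, 0)),
    fieldsPerWell = 1L, imageSize = c(96L, 96L), seed = 3L)
  f <- generateField(cfg, "B4", 1)
  expect_equal(nrow(f$truth), 0)
  # nothing but background + noise: far below any nucleus amplitude
  expect_lt(max(pixels(f$dapi)), 1000)
})

test_that("a clean single disk is recovered at its true intensity and area", {
  cfg <- syntheticPlateConfig(
    wells = c(B2 = "ctrl"),
    effects = data.frame(condition = "ctrl", cy3Gain = 1, areaScale = 1,
                         countScale = 1),
    fieldsPerWell = 1L, imageSize = c(128L, 128L),
    nucleiPerField = 1, countDistribution = "fixed",
    radiusMeanPx = 20, radiusSdPx = 0, radiusMinPx = 20,
    axisRatioRange = c(1, 1),
    cy3Amplitude = 100, cy3AmplitudeSdLog = 0,
    dapiAmplitudeSdLog = 0,
    backgroundDapi = c(0, 0, 0), backgroundCy3 = c(0, 0, 0),
    edgeBlurSigma = 0, poissonGain = 0, gaussianSd = 0, seed = 9L)
  f <- generateField(cfg, "B2", 1)
  expect_equal(nrow(f$truth), 1)
  mask <- excludeEdgeObjects(segmentWell(list(f$dapi))[[1]])
  expect_equal(nObjects(mask), 1L)
  rec <- measureObjects(mask, f$cy3)
  expect_lt(abs(rec$mfv - 100) / 100, 0.02)
  expect_lt(abs(rec$areaPx - pi * 20^2) / (pi * 20^2), 0.05)
})

test_that("generated plates are written per the filename convention", {
  cfg <- syntheticPlateConfig(
    wells = c(B2 = "ctrl", B4 = "treated"),
    fieldsPerWell = 2L, imageSize = c(96L, 96L), nucleiPerField = 15,
    seed = 33L)
  dir <- withr::local_tempdir()
  out <- generatePlate(cfg, dir)
  expect_equal(out$nFiles, 2 * 2 * 2)   # wells x fields x channels
  expect_true(file.exists(out$truth))
  plan <- sortPlate(dir)
  expect_named(plan, c("B2", "B4"))
  expect_true(all(vapply(plan, nrow, 1L) == 2))
  expect_true(all(unlist(lapply(plan, `[[`, "complete"))))

  truth <- read.csv(out$truth)
  expect_true(all(c("well", "field", "areaPx", "cy3Mean") %in% names(truth)))
  expect_true(all(truth$well %in% c("B2", "B4")))
})

test_that("the rendered ground truth drives parameter recovery end to end", {
  g <- 2; a <- 0.8
  cfg <- smallPlateConfig(seed = 55L)
  dir <- withr::local_tempdir()
  generatePlate(cfg, dir)
  res <- suppressWarnings(
    runPipeline(dir, file.path(dir, "out"), layoutFromConfig(cfg)))
  s <- res$summaries
  ctrl <- s[s$condition == "ctrl", ]
  trt <- s[s$condition == "treated", ]
  # the generator applies a pixel-level Cy3 gain and an area scale, so the
  # recoverable effects are: MFV ratio ~ gain, RA ~ 100 * areaScale, and
  # MoA fold ~ gain / areaScale
  expect_lt(abs(trt$mfvMean / ctrl$mfvMean - g) / g, 0.1)
  expect_lt(abs(res$conditions$raPercent - 100 * a) / (100 * a), 0.1)
  expect_lt(abs(res$conditions$fold - g / a) / (g / a), 0.1)
  expect_equal(res$conditions$call, "GENOTOXIC")
})

test_that("nuclei never overlap and respect the placement margin", {
  cfg <- smallPlateConfig(seed = 77L)
  f <- generateField(cfg, "B2", 1)
  tr <- f$truth
  if (nrow(tr) > 1) {
    d <- as.matrix(dist(cbind(tr$centerRow, tr$centerCol)))
    diag(d) <- Inf
    lim <- outer(tr$major, tr$major, "+")
    expect_true(all(d > lim))
  }
  expect_false(any(tr$edgeTouching))
})
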
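test_that("a forced two-class image thresholds between the classes", {
  set.seed(4)
  v <- c(rep(10L, 900), rep(200L, 100))
  m <- matrix(sample(v), 25, 40)
  thr <- otsuThreshold(m)
  expect_gte(as.numeric(thr), 10)
  expect_lt(as.numeric(thr), 200)
  expect_equal(mean(m > as.numeric(thr)), 0.10)
})

test_that("otsu equals the exhaustive within-class-variance oracle", {
  set.seed(21)
  for (i in 1:40) {
    n <- sample(16:48, 1)
    v <- if (i %% 2 == 0) sample(0:255, n * n, replace = TRUE)
         else sample(0:65535, n * n, replace = TRUE)
    m <- matrix(v, n, n)
    expect_equal(as.numeric(otsuThreshold(m)), oracleOtsu(v))
  }
})

test_that("constant images raise a constant-image error", {
  expect_error(otsuThreshold(matrix(500L, 10, 10)),
               class = "constant_image_error")
})

test_that("per-image segmentation is equivariant to intensity shifts", {
  set.seed(8)
  m <- matrix(sample(0:4000, 40 * 40, TRUE), 40, 40)
  shift <- 137L
  t1 <- otsuThreshold(m)
  t2 <- otsuThreshold(m + shift)
  expect_equal(as.numeric(t2), as.numeric(t1) + shift)
  expect_identical(m > as.numeric(t1), (m + shift) > as.numeric(t2))
})

test_that("the well threshold comes from the first field and is reused", {
  set.seed(12)
  mk <- function(amp) {
    img <- fixtureDisks(c(64, 64), cbind(c(20, 44), c(20, 44)), 8, amp)
    matrix(as.integer(img + sample(0:10, length(img), TRUE)), 64, 64)
  }
  fields <- list(mk(1000), mk(4000), mk(8000))   # individual thresholds differ
  indiv <- vapply(fields, function(f) as.numeric(otsuThreshold(f)), 1)
  expect_gt(max(indiv) - min(indiv), 0)
  masks <- segmentWell(fields, policy = "per_well_first_field")
  expect_equal(unique(vapply(masks, thresholdUsed, 1)), indiv[1])

  one <- segmentWell(fields[1], policy = "per_well_first_field")
  oneImg <- segmentWell(fields[1], policy = "per_image")
  expect_identical(maskLabels(one[[1]]), maskLabels(oneImg[[1]]))
  expect_equal(thresholdUsed(one[[1]]), thresholdUsed(oneImg[[1]]))

  pooled <- segmentWell(fields, policy = "per_well_pooled")
  expect_length(unique(vapply(pooled, thresholdUsed, 1)), 1)
})

test_that("disks on zero background are counted exactly in every field", {
  centers <- cbind(c(15, 15, 40, 40, 55), c(15, 40, 15, 40, 55))
  fields <- lapply(c(500, 2000), function(a)
    fixtureDisks(c(70, 70), centers, 6, a))
  masks <- segmentWell(fields)
  expect_equal(vapply(masks, nObjects, 1L), c(5L, 5L))
})

test_that("labeling is 8-connected", {
  m <- matrix(0L, 6, 6)
  m[2, 2] <- 1000L; m[3, 3] <- 1000L   # touch only diagonally
  mask <- segmentWell(list(m))[[1]]
  expect_equal(nObjects(mask), 1L)
})

test_that("edge exclusion removes exactly the border-touching objects", {
  # 5 x 5 grid of disks: the outer ring touches the borders, 9 survive
  cs <- seq(5, 61, by = 14)
  centers <- as.matrix(expand.grid(cs, cs))
  img <- fixtureDisks(c(65, 65), centers, 5, 3000)
  mask <- segmentWell(list(matrix(as.integer(img), 65, 65)))[[1]]
  expect_equal(nObjects(mask), 25L)
  kept <- excludeEdgeObjects(mask)
  expect_equal(nObjects(kept), 9L)
  lab <- maskLabels(kept)
  expect_true(all(lab[1, ] == 0) && all(lab[65, ] == 0) &&
                all(lab[, 1] == 0) && all(lab[, 65] == 0))

  # idempotent, never increases labeled area, interior-only is a no-op
  again <- excludeEdgeObjects(kept)
  expect_identical(maskLabels(again), maskLabels(kept))
  expect_lte(sum(maskLabels(kept) > 0), sum(maskLabels(mask) > 0))
})

test_that("object areas follow pixel counts and the calibration square", {
  img <- matrix(0L, 31, 31)
  img[10:20, 10:20] <- 4000L          # 11 x 11 square
  mask <- segmentWell(list(img))[[1]]
  a <- objectAreas(mask, calibration = 2.6)
  expect_equal(a$areaPx, 121L)
  expect_equal(a$areaUm2, 121 * 6.76)
  expect_equal(objectAreas(mask, calibration = 1)$areaUm2, 121)

  # rasterized disk close to the analytic pi r^2 for r >= 10
  disk <- fixtureDisks(c(64, 64), cbind(32, 32), 12, 5000)
  dm <- segmentWell(list(matrix(as.integer(disk), 64, 64)))[[1]]
  expect_lt(abs(objectAreas(dm)$areaPx - pi * 12^2) / (pi * 12^2), 0.05)
})

test_that("total labeled area equals the surviving foreground pixel count", {
  set.seed(31)
  cfg <- smallPlateConfig(seed = 5L)
  f <- generateField(cfg, "B2", 1)
  mask <- excludeEdgeObjects(segmentWell(list(f$dapi))[[1]])
  a <- objectAreas(mask)
  expect_equal(sum(a$areaPx), sum(maskLabels(mask) > 0))
})

test_that("optional particle filters: minimum size and hole filling", {
  img <- matrix(0L, 40, 40)
  img[5:25, 5:25] <- 3000L
  img[12:16, 12:16] <- 0L              # hole
  img[35, 35] <- 3000L                 # 1-px speck
  plain <- segmentWell(list(img))[[1]]
  expect_equal(nObjects(plain), 2L)
  filtered <- segmentWell(list(img), minAreaPx = 10L, fillHoles = TRUE)[[1]]
  expect_equal(nObjects(filtered), 1L)
  expect_equal(objectAreas(filtered)$areaPx, 21L * 21L)
})
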
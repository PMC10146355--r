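test_that("MoA reproduces the published well-level values", {
  expect_equal(moa(1.641, 2.130), 0.770, tolerance = 1e-3)
  expect_equal(moa(201.5, 72.9), 2.764, tolerance = 1e-3)
  expect_equal(moa(5.5, 1), 5.5)
  expect_error(moa(1, 0), "positive")
})

test_that("fold change reproduces the published ratios", {
  expect_equal(foldChange(moa(2.179, 1.423), moa(1.641, 2.130)), 1.987,
               tolerance = 0.005 / 1.987)
  expect_equal(foldChange(2, 2), 1)
  expect_equal(round(foldChange(moa(201.5, 72.9), moa(90.4, 184)), 1), 5.6)
  expect_error(foldChange(1, 0), "positive")
})

test_that("relative area reproduces the published percentages", {
  expect_equal(relativeArea(1.423, 2.130), 66.81, tolerance = 1e-4)
  expect_equal(relativeArea(1.173, 2.186), 53.66, tolerance = 1e-4)
  expect_equal(relativeArea(3, 3), 100)
  expect_error(relativeArea(1, 0), "positive")
})

test_that("the decision rules cover the whole (fold, RA) table", {
  expect_equal(classifyGenotox(4.495, 40.83), "GENOTOXIC")
  expect_equal(classifyGenotox(1.063, 90.94), "NON_GENOTOXIC")
  expect_equal(classifyGenotox(2.0, 20.0),
               "CYTOTOXICITY_DRIVEN_FALSE_POSITIVE")
  expect_equal(classifyGenotox(1.5, 30), "EQUIVOCAL")
  expect_warning(und <- classifyGenotox(1.5, 10), "not evaluable")
  expect_equal(und, "NOT_EVALUABLE")
  expect_equal(classifyGenotox(NA_real_, 50), "NOT_EVALUABLE")
  # RA above 100% (proliferation) follows the same rules, no clamping
  expect_equal(classifyGenotox(2.2, 140), "GENOTOXIC")
  expect_equal(classifyGenotox(0.9, 140), "NON_GENOTOXIC")
})

test_that("classification is monotone in fold at fixed RA", {
  folds <- c(0.5, 1.2, 1.6, 2.5, 8)
  calls <- classifyGenotox(folds, rep(60, 5))
  rank <- c(NON_GENOTOXIC = 0, EQUIVOCAL = 1, GENOTOXIC = 2)
  expect_true(all(diff(rank[calls]) >= 0))
})

test_that("fold and RA are invariant to gain and calibration rescaling", {
  mfv <- c(ctrl = 120, trt = 300)
  area <- c(ctrl = 800, trt = 560)
  base <- foldChange(moa(mfv["trt"], area["trt"]), moa(mfv["ctrl"], area["ctrl"]))
  for (k in c(0.01, 7, 1e4)) {
    expect_equal(foldChange(moa(k * mfv["trt"], area["trt"]),
                            moa(k * mfv["ctrl"], area["ctrl"])), base)
    expect_equal(foldChange(moa(mfv["trt"], k * area["trt"]),
                            moa(mfv["ctrl"], k * area["ctrl"])), base)
    expect_equal(relativeArea(k * area["trt"], k * area["ctrl"]),
                 relativeArea(area["trt"], area["ctrl"]))
  }
})

test_that("published MFV/area means round-trip to MoA, fold and RA", {
  tab <- publishedWellTables()
  for (grp in split(tab, paste(tab$time, tab$line))) {
    ctrl <- grp[grp$sample == "ctrl", ]
    for (i in seq_len(nrow(grp))) {
      row <- grp[i, ]
      moaHat <- moa(row$mfv, row$area)
      expect_lt(abs(moaHat - row$moa) / row$moa, 0.01)
      foldHat <- foldChange(moaHat, moa(ctrl$mfv, ctrl$area))
      expect_lt(abs(foldHat - row$fold) / row$fold, 0.01)
      raHat <- relativeArea(row$area, ctrl$area)
      expect_lt(abs(raHat - row$ra) / row$ra, 0.01)
    }
  }
})

test_that("condition scoring pools wells and links controls", {
  sums <- rbind(
    summarizeWell(data.frame(well = "B2", field = "0001", label = 1:2,
                             areaPx = 100L, areaUm2 = c(90, 110),
                             mfv = c(10, 14)), condition = "ctrl"),
    summarizeWell(data.frame(well = "B4", field = "0001", label = 1:2,
                             areaPx = 100L, areaUm2 = c(60, 80),
                             mfv = c(30, 34)), condition = "val30"))
  lay <- plateLayout(c("B2", "B4"), c("ctrl", "val30"), c(NA, "ctrl"))
  res <- scoreConditions(sums, lay)
  expect_equal(nrow(res), 1)
  expect_equal(res$fold, (32 / 70) / (12 / 100))
  expect_equal(res$raPercent, 70)
  expect_equal(res$call, "GENOTOXIC")

  # control-only layouts produce no condition results
  layCtrl <- plateLayout("B2", "ctrl")
  expect_equal(nrow(scoreConditions(sums[1, ], layCtrl)), 0)

  # a missing control well cannot be evaluated
  res2 <- scoreConditions(sums[2, ], lay)
  expect_equal(res2$call, "NOT_EVALUABLE")
})
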
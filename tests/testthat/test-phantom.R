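test_that("atlas construction honours its contract", {
  atl <- makeAtlas(c(40, 48, 40), nRegions = 10, voxelSizeMm = 1.5, seed = 7)
  sizes <- regionSizes(atl)
  expect_length(sizes, 10)
  expect_true(all(sizes > 0))
  expect_true("cerebellum" %in% names(sizes))
  expect_identical(referenceRegion(atl), "cerebellum")
  # small structures are capped to expose partial volume effects
  expect_lte(sizes[["amygdala"]], 150)
  # determinism
  atl2 <- makeAtlas(c(40, 48, 40), nRegions = 10, voxelSizeMm = 1.5, seed = 7)
  expect_identical(voxels(atl), voxels(atl2))
  expect_false(identical(voxels(atl),
                         voxels(makeAtlas(c(40, 48, 40), nRegions = 10,
                                          seed = 8))))
})

test_that("atlas works on a minimal grid and rejects impossible requests", {
  atl <- makeAtlas(c(8, 8, 8), nRegions = 2, seed = 1,
                   regionNames = c("cerebellum", "target"))
  expect_length(regionSizes(atl), 2)
  expect_true(all(regionSizes(atl) >= 1))
  expect_true(any(voxels(atl) == 0L)) # partitions only part of the grid
  expect_error(makeAtlas(c(6, 6, 6), nRegions = 50,
                         regionNames = sprintf("r%02d", c(0, seq_len(49))),
                         smallRegions = character(0)),
               "must include 'cerebellum'")
  expect_error(makeAtlas(c(6, 6, 6), nRegions = 50,
                         regionNames = c("cerebellum",
                                         sprintf("r%02d", seq_len(49))),
                         smallRegions = character(0)),
               "too small")
})

test_that("simulated cohorts are deterministic with the stated structure", {
  tr <- simulateCohort(nPerGroup = 4, seed = 42)
  tr2 <- simulateCohort(nPerGroup = 4, seed = 42)
  expect_identical(truthTable(tr), truthTable(tr2))
  expect_identical(subjectTable(tr), subjectTable(tr2))
  st <- subjectTable(tr)
  expect_equal(sum(st$carrier), 4)
  expect_equal(nrow(st), 8)
  expect_true(all(st$event_or_censor_month <= max(tr@scanMonths)))
  expect_true(all(st$event_or_censor_month > 0))
  expect_true(all(st$education_years >= 0))
  tt <- truthTable(tr)
  expect_true(all(tt$uptake > 0))
  # reference truth pinned to 1 at every visit
  expect_true(all(tt$uptake[tt$region == "cerebellum"] == 1))
})

test_that("zero slopes give visit-constant truth; extreme slopes error", {
  months <- defaultScanMonths()
  ep <- defaultEffectParams(months, c("cerebellum", "parietal"))
  ep$pctCarrier <- ep$pctNoncarrier <- 0
  ep$slopeCarrier <- ep$slopeNoncarrier <- 0
  tr <- simulateCohort(nPerGroup = 3, scanMonths = months, effectParams = ep,
                       seed = 5, visitSd = 0, noiseSd = 0)
  tt <- truthTable(tr)
  perSubj <- tapply(tt$uptake[tt$region == "parietal"],
                    tt$subject_id[tt$region == "parietal"],
                    function(x) diff(range(x)))
  expect_true(all(perSubj == 0))
  epBad <- ep
  epBad$slopeCarrier <- -0.2 # drives uptake negative well before 84 months
  expect_error(simulateCohort(nPerGroup = 3, scanMonths = months,
                              effectParams = epBad, seed = 5),
               "non-positive")
  expect_error(simulateCohort(nPerGroup = 3,
                              hazards = c(carrier = 0.001,
                                          noncarrier = 0.01)),
               "hazard")
})

test_that("slope calibration reproduces the requested mean percent change", {
  months <- defaultScanMonths()
  for (pct in c(-1.5, -0.31, 0.291)) {
    s <- slopeForPercentChange(pct, 1.034, months)
    expect_equal(longpet:::meanPctForSlope(s, 1.034, months), pct,
                 tolerance = 1e-9)
  }
})

test_that("noise-free unblurred rendering is exactly piecewise constant", {
  atl <- makeAtlas(c(20, 24, 20), nRegions = 5, seed = 3)
  tr <- simulateCohort(nPerGroup = 2, scanMonths = c(0, 12),
                       effectParams = defaultEffectParams(
                         c(0, 12), defaultRegionNames(5)),
                       seed = 9, visitSd = 0.01)
  img <- renderVisitImage(tr, "C01", 0, atl, psfFwhmMm = 0, noiseSd = 0)
  tt <- truthTable(tr)
  means <- roiMeans(img, atl)
  for (rg in names(means)) {
    truthVal <- tt$uptake[tt$subject_id == "C01" & tt$month == 0 &
                            tt$region == rg]
    expect_equal(unname(means[[rg]]), truthVal, tolerance = 1e-12)
  }
  # determinism of the noisy render
  i1 <- renderVisitImage(tr, "C01", 12, atl, psfFwhmMm = 8, seed = 77)
  i2 <- renderVisitImage(tr, "C01", 12, atl, psfFwhmMm = 8, seed = 77)
  expect_identical(voxels(i1), voxels(i2))
  expect_error(renderVisitImage(tr, "nope", 0, atl), "no truth")
  expect_error(renderVisitImage(tr, "C01", 7, atl), "no truth")
})

test_that("atrophy erosion removes boundary voxels progressively", {
  atl <- makeAtlas(c(20, 24, 20), nRegions = 4, seed = 3,
                   regionNames = defaultRegionNames(4),
                   smallRegions = character(0))
  tr <- simulateCohort(nPerGroup = 2, scanMonths = c(0, 24, 48),
                       effectParams = defaultEffectParams(
                         c(0, 24, 48), defaultRegionNames(4)),
                       seed = 4, visitSd = 0, noiseSd = 0, atrophyRate = 0.004)
  img0 <- renderVisitImage(tr, "C01", 0, atl, psfFwhmMm = 0, noiseSd = 0)
  img48 <- renderVisitImage(tr, "C01", 48, atl, psfFwhmMm = 0, noiseSd = 0)
  zero0 <- sum(voxels(img0) == 0)
  zero48 <- sum(voxels(img48) == 0)
  expect_gt(zero48, zero0) # eroded voxels became background
})

test_that("injected group slope differences are recovered monotonically", {
  months <- defaultScanMonths()
  deltas <- c(0.0005, 0.001, 0.002) # SUVR/month slope differences
  recovered <- vapply(deltas, function(dl) {
    ests <- vapply(1:8, function(rep) {
      ep <- defaultEffectParams(months, c("cerebellum", "parietal"))
      ep$slopeNoncarrier <- -0.0002
      ep$slopeCarrier <- -0.0002 - dl
      tr <- simulateCohort(nPerGroup = 12, scanMonths = months,
                           effectParams = ep, seed = 1000 + rep,
                           visitSd = 0.015)
      fitRoiLmm(simulateSuvrTable(tr), "parietal", subjectTable(tr))$estimate
    }, numeric(1))
    mean(abs(ests))
  }, numeric(1))
  expect_true(all(diff(recovered) > 0))
})
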
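test_that("density binning conserves pulses and normalises the energy factor", {
  ## a single pulse at the grid centre
  dm1 <- densityMap(list(x = 1e-4, y = 1e-4), gridShape = 16, fovDiameter = 2)
  expect_identical(sum(pulseCounts(dm1)), 1L)
  expect_identical(sum(energyFactor(dm1) == 1), 1L)
  expect_identical(sum(energyFactor(dm1) == 0), 255L)
  ## closed form: counts 9 vs max 99 -> log10(10)/log10(100) = 0.5
  pts <- list(x = c(rep(1e-4, 9), rep(0.3001, 99)), y = rep(1e-4, 108))
  dm <- densityMap(pts, gridShape = 10, fovDiameter = 2)
  expect_identical(energyFactor(dm)[pulseCounts(dm) == 9L], 0.5)
  expect_identical(energyFactor(dm)[pulseCounts(dm) == 99L], 1)
  ## every pulse of a real frame lands in exactly one pixel
  tr <- makeTrajectory(SpiralParams("AFS", nPoints = 8192L))
  expect_identical(sum(pulseCounts(densityMap(tr, 128))), 8192L)
  ## pulses outside the grid extent are an error naming the offender
  expect_error(densityMap(list(x = 5, y = 0), gridShape = 8, fovDiameter = 2),
               "outside the grid extent")
})

test_that("central pulse fraction equals independent point-in-disk counting", {
  tr <- makeTrajectory(SpiralParams("AFS", nPoints = 8192L))
  pos <- positions(tr)
  for (f in c(1 / 256, 1 / 64, 0.3)) {
    oracle <- 100 * mean(pos$x^2 + pos$y^2 <= f)   # R = 1 mm, squared radii
    expect_equal(centralPulseFraction(tr, f), oracle, tolerance = 1e-12)
  }
})

test_that("central pulse fraction is monotone in the area fraction", {
  for (pat in c("AS", "FS", "AFS")) {
    tr <- makeTrajectory(SpiralParams(pat, nPoints = 8192L))
    fr <- vapply(c(0.01, 0.05, 0.2, 0.5, 0.9, 0.999999),
                 centralPulseFraction, 0, traj = tr)
    expect_true(all(diff(fr) >= 0))
    expect_gte(fr[6], 99.9)     # whole-disk limit
  }
  tr <- makeTrajectory(SpiralParams("AS", nPoints = 128L))
  expect_error(centralPulseFraction(tr, 0), "areaFraction")
  expect_error(centralPulseFraction(tr, 1), "areaFraction")
  expect_error(centralPulseFraction(tr, -0.2), "areaFraction")
})

test_that("radial fill profiles expose the pattern-specific coverage", {
  ## saturated map: every annulus fully filled
  cts <- matrix(1L, 32, 32)
  sat <- new("SamplingDensityMap", counts = cts,
             energyFactor = log10(cts + 1) / max(log10(cts + 1)),
             pixelSize = 0.01)
  expect_true(all(radialFillProfile(sat, 8)$fillFraction == 1))
  expect_error(radialFillProfile(sat, 0), "nBins")

  trAS <- makeTrajectory(SpiralParams("AS"))
  trAFS <- makeTrajectory(SpiralParams("AFS"))
  pAS <- radialFillProfile(densityMap(trAS, 256), 16)
  pAFS <- radialFillProfile(densityMap(trAFS, 256), 16)
  ## AS coverage decays from centre outward (one-bin noise allowed)
  d <- diff(pAS$fillFraction)
  expect_lte(sum(d > 0), 2L)
  expect_true(all(d < 0.01))
  ## the compound pattern fills the edge better at equal pulse budget
  expect_gt(pAFS$fillFraction[16], pAS$fillFraction[16])
  expect_gt(mean(tail(pAFS$fillFraction, 4)), mean(tail(pAS$fillFraction, 4)))
})

test_that("compound scanning halves the central pulse load", {
  dmAS <- densityMap(makeTrajectory(SpiralParams("AS")), 256)
  dmAFS <- densityMap(makeTrajectory(SpiralParams("AFS")), 256)
  rr <- pixelRadii(dim(pulseCounts(dmAS)), pixelSize(dmAS))
  ctr <- rr <= 1 / 16                       # central 1/256-area disk
  ratio <- sum(pulseCounts(dmAFS)[ctr]) / sum(pulseCounts(dmAS)[ctr])
  expect_gt(ratio, 0.4); expect_lt(ratio, 0.65)
  ## the AS hot spot is central, and the compound pattern cools it
  hot <- which(pulseCounts(dmAS) == max(pulseCounts(dmAS)), arr.ind = TRUE)
  expect_true(all(rr[hot] <= 1 / 16))
  expect_lt(mean(energyFactor(dmAFS)[ctr]), mean(energyFactor(dmAS)[ctr]))
})
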
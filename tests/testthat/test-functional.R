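test_that("the packaged extinction table is positive and near-isosbestic at 532 nm", {
  ext <- hemoglobinExtinction()
  e532 <- extinctionValues(ext, 532)
  e558 <- extinctionValues(ext, 558)
  expect_true(all(c(e532, e558) > 0))
  expect_lte(abs(e532[["epsHbO2"]] - e532[["epsHb"]]) / e532[["epsHbO2"]], 0.1)
  ## 558 nm separates the species (otherwise the system would be singular)
  expect_gt(abs(e558[["epsHbO2"]] - e558[["epsHb"]]) / e558[["epsHbO2"]], 0.2)
  expect_error(extinctionValues(ext, 600), "not in extinction table")
})

test_that("unmixing inverts the forward model exactly", {
  ext <- hemoglobinExtinction()
  mk <- function(s, c, wl) asReconstructedImage(
    matrix(forwardAbsorption(s, c, ext, wl), 3, 3), 0.01, wl)
  for (s in c(0, 0.25, 0.5, 0.75, 1)) {
    fm <- unmix(mk(s, 0.8, 532), mk(s, 0.8, 558), ext, ampThreshold = 0)
    expect_equal(so2Map(fm)[2, 2], s, tolerance = 1e-9)
    expect_equal(chbtMap(fm)[2, 2], 0.8, tolerance = 1e-9)
    ## interior mixtures never clamp; the pure endpoints may clamp a
    ## zero component at numerical precision
    if (s > 0 && s < 1) expect_identical(clampCount(fm), 0L)
  }
  ## pure oxyhemoglobin
  fm1 <- unmix(mk(1, 0.5, 532), mk(1, 0.5, 558), ext, ampThreshold = 0)
  expect_equal(so2Map(fm1)[1, 1], 1, tolerance = 1e-9)

  ## sO2 is invariant to a common amplitude scale; C_HbT scales with it
  i5 <- mk(0.7, 1, 532); i8 <- mk(0.7, 1, 558)
  s5 <- asReconstructedImage(imagePixels(i5) * 3.7, 0.01, 532)
  s8 <- asReconstructedImage(imagePixels(i8) * 3.7, 0.01, 558)
  f0 <- unmix(i5, i8, ext, ampThreshold = 0)
  f1 <- unmix(s5, s8, ext, ampThreshold = 0)
  expect_equal(so2Map(f1), so2Map(f0), tolerance = 1e-9)
  expect_equal(chbtMap(f1), 3.7 * chbtMap(f0), tolerance = 1e-9)

  ## amplitudes inconsistent with the model are clamped and counted
  bad5 <- asReconstructedImage(matrix(1, 2, 2), 0.01, 532)
  bad8 <- asReconstructedImage(matrix(10, 2, 2), 0.01, 558)
  fb <- unmix(bad5, bad8, ext, ampThreshold = 0)
  expect_identical(clampCount(fb), 4L)
  expect_true(all(so2Map(fb)[fb@mask] %in% c(0, 1)))

  ## proportional extinction rows make the system singular
  sing <- new("ExtinctionTable", table = data.frame(
    wavelength = c(532, 558), epsHbO2 = c(100, 200), epsHb = c(95, 190),
    source = "synthetic"))
  expect_error(unmix(bad5, bad8, sing), "singular")
  expect_error(unmix(bad5, asReconstructedImage(matrix(1, 3, 3), 0.01, 558)),
               "share one grid")
})

test_that("sO2 recovery survives acquisition noise", {
  errs <- vapply(1:10, function(s) {
    ph <- makePhantom("parallel", size = 128, seed = 100 + s)
    tr <- makeTrajectory(SpiralParams("AFS", nPoints = 33332L))
    peak <- max(absorptionMap(ph, 532))
    prs <- acquire(ph, tr, noiseSigma = 0.02 * peak, seed = s)
    i5 <- reconstruct(prs, 128, pixelSize = pixelSize(ph), wavelength = 532)
    i8 <- reconstruct(prs, 128, pixelSize = pixelSize(ph), wavelength = 558)
    fm <- unmix(i5, i8)
    sel <- fm@mask & vesselMask(ph)
    mean(abs(so2Map(fm)[sel] - so2Map(ph)[sel]))
  }, 0)
  expect_lt(mean(errs), 0.05)
})

test_that("fractional change series reference the early-frame baseline", {
  expect_true(all(fractionalChange(rep(4.2, 8)) == 0))
  expect_equal(fractionalChange(c(10, 10, 10, 10, 10, 8))[6], -0.2)
  expect_error(fractionalChange(c(0, 0, 0, 0, 0, 1)), "baseline")
  expect_error(fractionalChange(c(1, 2), baselineFrames = 5), "baselineFrames")

  ## simulated hypoxia ramp: monotone decrease after the baseline window
  mkMap <- function(s) new("FunctionalMaps",
    so2 = matrix(s, 4, 4), chbtRel = matrix(1, 4, 4),
    mask = matrix(TRUE, 4, 4), clampCount = 0L, pixelSize = 0.01)
  ramp <- c(rep(0.95, 5), seq(0.95, 0.6, length.out = 10))
  ser <- fractionalChangeSeries(lapply(ramp, mkMap), baselineFrames = 5)
  expect_true(all(ser$so2[1:5] == 0))
  expect_true(all(diff(ser$so2[-(1:5)]) < 0))
  expect_true(all(ser$chbt == 0))
})
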
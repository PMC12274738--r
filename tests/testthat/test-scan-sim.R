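test_that("acquisition samples the absorption raster bilinearly", {
  ph <- constantPhantom(32, v532 = 5, v558 = 3)
  tr <- makeTrajectory(SpiralParams("AFS", nPoints = 1024L))
  prs <- acquire(ph, tr, noiseSigma = 0)
  rec <- pulseRecords(prs)
  expect_identical(nrow(rec), 2048L)           # both wavelengths
  expect_equal(rec$amplitude[rec$wavelength == 532], rep(5, 1024),
               tolerance = 1e-12)
  expect_equal(rec$amplitude[rec$wavelength == 558], rep(3, 1024),
               tolerance = 1e-12)

  ## pulse exactly on a pixel centre returns that pixel's value
  ph2 <- makePhantom("grid", size = 64, seed = 3)
  px <- pixelSize(ph2)
  centre <- c((10 - 0.5) * px - 1, 1 - (20 - 0.5) * px)  # col 10, row 20
  t2 <- twoPointTraj(c(centre[1], centre[1] + px), c(centre[2], centre[2]))
  amp <- pulseRecords(acquire(ph2, t2, dualWavelength = FALSE))$amplitude
  expect_equal(amp[1], absorptionMap(ph2, 532)[20, 10], tolerance = 1e-12)

  ## fixed seed reproduces the noisy record set exactly
  a <- acquire(ph2, makeTrajectory(SpiralParams("AS", nPoints = 512L)),
               noiseSigma = 10, seed = 42)
  b <- acquire(ph2, makeTrajectory(SpiralParams("AS", nPoints = 512L)),
               noiseSigma = 10, seed = 42)
  expect_identical(pulseRecords(a), pulseRecords(b))
  expect_true(all(pulseRecords(a)$amplitude >= 0))

  ## trajectory wider than the phantom is refused
  wide <- makeTrajectory(SpiralParams("AS", nPoints = 512L, fovDiameter = 4))
  expect_error(acquire(ph2, wide), "exceeds the phantom extent")
})

test_that("bin_mean reconstruction averages in-pixel samples", {
  rec <- data.frame(t = c(0, 1e-5), x = c(0.01, 0.02), y = c(0.01, 0.02),
                    wavelength = 532, amplitude = c(1, 3))
  prs <- new("PulseRecordSet", records = rec, noiseSigma = 0, rngSeed = 1L)
  img <- reconstruct(prs, gridShape = 4, pixelSize = 0.5)
  expect_identical(imagePixels(img)[fillMask(img)], 2)  # mean of 1 and 3
  expect_identical(sum(fillMask(img)), 1L)

  empty <- new("PulseRecordSet", records = rec[0, ], noiseSigma = 0,
               rngSeed = 1L)
  expect_error(reconstruct(empty, 4, 0.5), "empty")

  dual <- rbind(rec, transform(rec, wavelength = 558))
  prs2 <- new("PulseRecordSet", records = dual, noiseSigma = 0, rngSeed = 1L)
  expect_error(reconstruct(prs2, 4, 0.5), "select one")
})

test_that("dense noiseless acquisition round-trips the phantom exactly", {
  ph <- makePhantom("grid", size = 64, seed = 2)
  truth <- absorptionMap(ph, 532)
  prs <- densePulseRecords(truth, pixelSize(ph))
  img <- reconstruct(prs, 64, pixelSize = pixelSize(ph))
  expect_true(all(fillMask(img)))
  expect_identical(imagePixels(img), unname(truth))
})

test_that("the compound pattern reduces edge undersampling error", {
  ph <- makePhantom("grid", size = 256, seed = 7)
  truth <- absorptionMap(ph, 532)
  rmse <- vapply(c("AS", "AFS"), function(pat) {
    tr <- makeTrajectory(SpiralParams(pat, nPoints = 33332L))
    img <- reconstruct(acquire(ph, tr, dualWavelength = FALSE),
                       256, pixelSize = pixelSize(ph), wavelength = 532)
    edgeAnnulusRMSE(img, truth, pixelSize(ph))
  }, 0)
  expect_lt(rmse[["AFS"]], rmse[["AS"]])
})

test_that("reconstruction error decreases with the pulse budget", {
  ph <- makePhantom("grid", size = 256, seed = 7)
  truth <- absorptionMap(ph, 532)
  rmse <- vapply(c(8334L, 33332L, 131072L), function(n) {
    tr <- makeTrajectory(SpiralParams("AFS", nPoints = n))
    img <- reconstruct(acquire(ph, tr, dualWavelength = FALSE),
                       256, pixelSize = pixelSize(ph), wavelength = 532)
    sqrt(mean((imagePixels(img) - truth)^2))
  }, 0)
  expect_true(all(diff(rmse) < 0))
})

test_that("scattered interpolation fills unsampled pixels and flags them", {
  rec <- data.frame(t = (0:3) * 1e-5, x = c(-0.3, 0.3, -0.3, 0.3),
                    y = c(-0.3, -0.3, 0.3, 0.3), wavelength = 532,
                    amplitude = 5)
  prs <- new("PulseRecordSet", records = rec, noiseSigma = 0, rngSeed = 1L)
  for (m in c("nearest", "linear")) {
    img <- reconstruct(prs, 16, pixelSize = 1 / 16, method = m)
    expect_true(all(imagePixels(img) == 5))
    expect_identical(img@inpainted, !fillMask(img))
  }
  raw <- reconstruct(prs, 16, pixelSize = 1 / 16, method = "bin_mean")
  expect_true(all(imagePixels(raw)[!fillMask(raw)] == 0))
  expect_false(any(raw@inpainted))
})

test_that("rigid landmark alignment recovers exact and jittered transforms", {
  set.seed(7)
  M <- cbind(runif(6), runif(6))
  id <- fitRigid(M, M)
  expect_equal(id@rotation, 0, tolerance = 1e-12)
  expect_equal(id@translation, c(0, 0), tolerance = 1e-12)
  expect_equal(id@residualRMS, 0, tolerance = 1e-12)

  a <- 0.3; R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
  F_ <- M %*% t(R) + rep(c(0.5, -0.2), each = 6)
  tr <- fitRigid(M, F_)
  expect_equal(tr@rotation, 0.3, tolerance = 1e-9)
  expect_equal(tr@translation, c(0.5, -0.2), tolerance = 1e-9)
  expect_equal(applyRigid(tr, M), F_, tolerance = 1e-9)
  expect_equal(applyRigid(tr, applyRigid(tr, M), inverse = TRUE), M,
               tolerance = 1e-9)

  ## residual scales with the injected jitter
  res <- vapply(c(0.005, 0.02), function(s) {
    set.seed(99)
    mean(vapply(1:20, function(i)
      fitRigid(M, F_ + matrix(rnorm(12, 0, s), 6, 2))@residualRMS, 0))
  }, 0)
  expect_gt(res[2], res[1])
  expect_gt(res[1], 0.005 / 5); expect_lt(res[1], 0.005 * 5)
  expect_gt(res[2], 0.02 / 5); expect_lt(res[2], 0.02 * 5)

  expect_error(fitRigid(M[1, , drop = FALSE], M[1, , drop = FALSE]),
               "at least 2")
  same <- matrix(1, 3, 2)
  expect_error(fitRigid(same, same), "coincide")
})

test_that("stitching composites tiles in a common world frame", {
  set.seed(3)
  scene <- matrix(runif(40 * 60), 40, 60)
  left <- asReconstructedImage(scene[, 1:40], 0.01)
  right <- asReconstructedImage(scene[, 21:60], 0.01)

  solo <- stitch(list(left), list(RigidTransform2D()))
  expect_identical(imagePixels(solo), scene[, 1:40])

  mo <- stitch(list(left, right),
               list(RigidTransform2D(0, c(-0.1, 0)),
                    RigidTransform2D(0, c(0.1, 0))),
               blend = "feather_mean")
  expect_identical(dim(imagePixels(mo)), dim(scene))
  expect_equal(imagePixels(mo), scene, tolerance = 1e-12)

  a <- asReconstructedImage(matrix(1, 10, 10), 0.01)
  b <- asReconstructedImage(matrix(2, 10, 10), 0.01)
  far <- stitch(list(a, b),
                list(RigidTransform2D(), RigidTransform2D(0, c(0.5, 0))))
  expect_identical(sum(fillMask(far)), 200L)
  expect_identical(sum(imagePixels(far)), 100 + 200)
})
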
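test_that("Archimedes double spiral concentrates sqrt(f) of its pulses centrally", {
  n <- 4096L
  tr <- makeTrajectory(SpiralParams("AS", nPoints = n, nTurns = 16L,
                                    fovDiameter = 2))
  R <- 1
  expect_lt(abs(mean(radii(tr) <= R / 16) - 1 / 16), 2 / n)
  out <- radii(tr)[segmentLabels(tr) == "AS_out"]
  expect_identical(out[1], 0)                      # starts at the centre
  expect_equal(out[length(out)], R)                # reaches the FOV edge
  ## largest consecutive gap on the outward pass sits at the edge
  pos <- positions(tr)[segmentLabels(tr) == "AS_out", ]
  step <- sqrt(diff(pos$x)^2 + diff(pos$y)^2)
  expect_equal(which.max(step), length(step))
})

test_that("Fermat double spiral samples the area uniformly", {
  n <- 4096L
  tr <- makeTrajectory(SpiralParams("FS", nPoints = n, nTurns = 16L))
  expect_lt(abs(mean(radii(tr) <= 1 / 16) - 1 / 256), 2 / n)
  out <- radii(tr)[segmentLabels(tr) == "FS_out"]
  expect_true(all(diff(out) >= -1e-12))            # monotone outward
  ## counts in equal-area annuli are flat to Poisson-like error
  edges <- sqrt(seq(0, 1, length.out = 17))        # 16 equal-area annuli
  cnt <- table(cut(radii(tr), edges, include.lowest = TRUE))
  expect_true(all(abs(cnt - n / 16) < 4 * sqrt(n / 16) + 2))
})

test_that("cumulative point-fraction laws hold across pulse budgets", {
  for (n in c(1024L, 8192L, 65536L)) {
    trA <- makeTrajectory(SpiralParams("AS", nPoints = n))
    trF <- makeTrajectory(SpiralParams("FS", nPoints = n))
    for (rho in c(0.25, 0.5, 0.75)) {
      expect_lt(abs(mean(radii(trA) <= rho) - rho), 2 / n)
      expect_lt(abs(mean(radii(trF) <= rho) - rho^2), 2 / n)
    }
  }
})

test_that("the compound frame lies strictly between its parent patterns", {
  n <- 8192L
  trs <- lapply(c("AS", "FS", "AFS"),
                function(p) makeTrajectory(SpiralParams(p, nPoints = n)))
  for (f in c(1 / 256, 1 / 64, 1 / 16, 1 / 4, 1 / 2)) {
    fr <- vapply(trs, centralPulseFraction, 0, areaFraction = f)
    expect_lt(fr[2], fr[3])    # FS < AFS
    expect_lt(fr[3], fr[1])    # AFS < AS
  }
  ## the compound fraction is the mean of the two pass closed forms
  expect_lt(abs(centralPulseFraction(trs[[3]], 1 / 256) / 100 -
                (1 / 16 + 1 / 256) / 2), 2 / n)
})

test_that("frame timing is exact by construction", {
  p <- SpiralParams("AFS", nPoints = 33332L, prf = 2e5)
  expect_identical(frameRate(p) * p@nPoints, p@prf)
  expect_identical(framePeriod(p), 33332 / 2e5)
  tr <- makeTrajectory(p)
  expect_equal(diff(positions(tr)$t), rep(1 / 2e5, 33331), tolerance = 1e-9)
})

test_that("all patterns reach the FOV edge and are continuous", {
  for (n in c(1024L, 8192L, 65536L)) for (pat in c("AS", "FS", "AFS")) {
    tr <- makeTrajectory(SpiralParams(pat, nPoints = n))
    expect_equal(max(radii(tr)), 1, tolerance = 1e-12)
    pos <- positions(tr)
    step <- sqrt(diff(pos$x)^2 + diff(pos$y)^2)
    expect_lte(max(step), 4 * median(step))
  }
})

test_that("invalid pulse budgets are rejected", {
  expect_error(SpiralParams("AS", nPoints = 4097L), "even")
  expect_error(SpiralParams("AFS", nPoints = 4098L,
                            composition = "as_roundtrip_fs_roundtrip"),
               "divisible by 4")
})

test_that("compound composition variants assemble the stated passes", {
  tr <- makeTrajectory(SpiralParams("AFS", nPoints = 8192L))
  tab <- table(segmentLabels(tr))
  expect_identical(sort(names(tab)), c("AS_out", "FS_in"))
  expect_true(all(tab == 4096L))
  tr4 <- makeTrajectory(SpiralParams("AFS", nPoints = 8192L,
                                     composition = "as_roundtrip_fs_roundtrip"))
  tab4 <- table(segmentLabels(tr4))
  expect_identical(sort(names(tab4)), c("AS_in", "AS_out", "FS_in", "FS_out"))
  expect_true(all(tab4 == 2048L))
})

test_that("driving waveforms align smoothly at pass junctions", {
  for (pat in c("AS", "FS", "AFS")) {
    tr <- makeTrajectory(SpiralParams(pat, nPoints = 33332L))
    wf <- drivingWaveforms(tr)
    expect_gte(nrow(wf$junctions), 1L)
    ## the junction jump is an ordinary step: at worst the edge-length
    ## step of an Archimedes pass (2x the median step, reached exactly
    ## by the pure AS outer junction)
    expect_true(all(wf$junctions$ratio <= 2 + 0.01))
    if (pat == "AFS") expect_true(all(wf$junctions$ratio <= 2))
    ## polar-to-Cartesian identity of the commands
    expect_equal(wf$x, radii(tr) * cos(positions(tr)$theta), tolerance = 1e-12)
  }
})

test_that("reversing a trajectory twice restores the waveforms", {
  tr <- makeTrajectory(SpiralParams("AFS", nPoints = 2048L))
  wf1 <- drivingWaveforms(tr)
  wf2 <- drivingWaveforms(reverseTrajectory(reverseTrajectory(tr)))
  expect_identical(wf1$x, wf2$x)
  expect_identical(wf1$y, wf2$y)
})
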
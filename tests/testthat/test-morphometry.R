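test_that("segmentation thresholds and cleans the vessel mask", {
  bw <- matrix(0, 30, 30); bw[10:20, 5:25] <- 1
  expect_identical(segmentVessels(bw, "fixed", threshold = 0.5,
                                  minArea = 0, fillHoles = FALSE), bw == 1)
  expect_error(segmentVessels(matrix(0, 20, 20), "fixed", threshold = 0.5),
               "identically zero")
  ## objects below minArea are dropped
  sp <- bw; sp[2, 2] <- 1
  m <- segmentVessels(sp, "fixed", threshold = 0.5, minArea = 5,
                      fillHoles = FALSE)
  expect_false(m[2, 2]); expect_true(m[15, 15])
  expect_error(segmentVessels(matrix(c(1, 0, 0, 0), 20, 20), "fixed",
                              threshold = 0.5, minArea = 50),
               "after cleanup")
})

test_that("Otsu segmentation recovers the noiseless phantom mask to a 1-px band", {
  ph <- makePhantom("parallel", size = 256, seed = 9)
  truth <- vesselMask(ph)
  m <- segmentVessels(absorptionMap(ph, 532), "otsu")
  wrong <- m != truth
  expect_lt(mean(wrong), 0.02)
  if (any(wrong)) {
    dToVessel <- as.matrix(EBImage::distmap(1 - truth))   # px to vessel
    dToBg <- as.matrix(EBImage::distmap(truth + 0))       # px to background
    fp <- wrong & m; fn <- wrong & !m
    if (any(fp)) expect_lte(max(dToVessel[fp]), 1.5)
    if (any(fn)) expect_lte(max(dToBg[fn]), 1.5)
  }
})

test_that("skeleton graphs capture fixture topology", {
  g <- skeletonizeGraph(barMask(), pixelSize = 1)
  nd <- graphNodes(g)
  expect_identical(sum(nd$type == "endpoint"), 2L)
  expect_identical(sum(nd$type == "branchpoint"), 0L)
  expect_identical(length(vesselSegments(g)), 1L)
  s <- vesselSegments(g)[[1]]
  ## interior diameters track the 6-px bar width
  mid <- s$diameters[10:(length(s$diameters) - 10)]
  expect_true(all(abs(mid - 6) <= 1))

  gc <- skeletonizeGraph(crossMask(), pixelSize = 1)
  tab <- table(graphNodes(gc)$type)
  expect_identical(unname(tab[["branchpoint"]]), 1L)
  expect_identical(unname(tab[["endpoint"]]), 4L)

  ip <- matrix(FALSE, 9, 9); ip[5, 5] <- TRUE
  gi <- skeletonizeGraph(ip, pixelSize = 1)
  expect_identical(nrow(graphNodes(gi)), 1L)
  expect_identical(graphNodes(gi)$type, "isolated")
  expect_identical(length(vesselSegments(gi)), 0L)
})

test_that("tortuosity oracles: straight is 1, a semicircle is pi/2", {
  rep1 <- computeMetrics(skeletonizeGraph(barMask(), 1), barMask(),
                         boxSizes = c(2, 4))
  expect_identical(rep1@VT, 1)
  rep2 <- computeMetrics(semicircleGraph(), matrix(TRUE, 8, 8),
                         boxSizes = c(2, 4))
  expect_equal(rep2@VT, pi / 2, tolerance = 0.02)
})

test_that("box-counting fractal dimension matches analytic references", {
  sq <- matrix(TRUE, 512, 512)
  expect_equal(fractalDimension(sq)$FD, 2, tolerance = 0.05)
  ln <- matrix(FALSE, 512, 512); ln[256, ] <- TRUE
  expect_equal(fractalDimension(ln)$FD, 1, tolerance = 0.05)
  cp <- sierpinskiCarpet(3, 8)
  expect_equal(fractalDimension(cp, c(8, 24, 72))$FD, log(8) / log(3),
               tolerance = 0.05)
  expect_error(fractalDimension(sq, boxSizes = 4), "2 distinct")
})

test_that("morphometry recovers phantom ground truth", {
  cases <- list(list(style = "parallel", seed = 3, fill = TRUE),
                list(style = "parallel", seed = 11, fill = TRUE),
                list(style = "grid", seed = 3, fill = FALSE),
                list(style = "grid", seed = 7, fill = FALSE),
                list(style = "loops", seed = 3, fill = TRUE))
  for (cs in cases) {
    ph <- makePhantom(cs$style, size = 512, seed = cs$seed)
    mask <- segmentVessels(absorptionMap(ph, 532), "fixed",
                           threshold = 1e-9, fillHoles = cs$fill)
    g <- skeletonizeGraph(mask, pixelSize(ph))
    est <- metricValues(computeMetrics(g, mask))
    tru <- truthMetrics(ph)
    expect_lt(abs(est[["VL"]] - tru$VL) / tru$VL, 0.05)
    expect_lte(abs(est[["NBP"]] - tru$NBP), max(1, ceiling(tru$NBP / 10)))
    expect_lte(abs(est[["MVD"]] - tru$MVD), pixelSize(ph))
    if (cs$style != "loops")   # VT error scales with VT magnitude
      expect_lte(abs(est[["VT"]] - tru$VT), 0.05)
  }
})

test_that("metrics are scale-equivariant and monotone under additions", {
  m <- barMask()
  r1 <- metricValues(computeMetrics(skeletonizeGraph(m, 1), m,
                                    boxSizes = c(2, 4, 8)))
  r2 <- metricValues(computeMetrics(skeletonizeGraph(m, 2), m,
                                    boxSizes = c(2, 4, 8)))
  expect_equal(r2[["VL"]], 2 * r1[["VL"]], tolerance = 1e-12)
  expect_equal(r2[["MVD"]], 2 * r1[["MVD"]], tolerance = 1e-12)
  expect_identical(r2[["NBP"]], r1[["NBP"]])
  expect_identical(r2[["VT"]], r1[["VT"]])
  expect_identical(r2[["FD"]], r1[["FD"]])

  m2 <- m; m2[30:35, 11:110] <- TRUE          # add a disjoint vessel
  r3 <- metricValues(computeMetrics(skeletonizeGraph(m2, 1), m2,
                                    boxSizes = c(2, 4, 8)))
  expect_gte(r3[["VL"]], r1[["VL"]])
  expect_gte(r3[["NBP"]], r1[["NBP"]])
})

test_that("normal-ray diameters agree with the distance transform on straight tubes", {
  g <- skeletonizeGraph(barMask(), 1, diameterMethod = "normal")
  d <- vesselSegments(g)[[1]]$diameters
  mid <- d[10:(length(d) - 10)]
  expect_true(all(abs(mid - 6) <= 1, na.rm = TRUE))
})
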
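## Shared fixtures, all built in code.

barMask <- function(nr = 40, nc = 120, rows = 18:23, cols = 11:110) {
  m <- matrix(FALSE, nr, nc)
  m[rows, cols] <- TRUE
  m
}

crossMask <- function(n = 60) {
  m <- matrix(FALSE, n, n)
  mid <- (n %/% 2 - 2):(n %/% 2 + 2)
  m[mid, 6:(n - 5)] <- TRUE
  m[6:(n - 5), mid] <- TRUE
  m
}

## analytic semicircular-arc vessel graph (one segment)
semicircleGraph <- function(R = 1, n = 2000) {
  th <- seq(0, pi, length.out = n)
  pts <- cbind(R * cos(th), R * sin(th))
  new("VesselGraph",
      nodes = data.frame(x = pts[c(1, n), 1], y = pts[c(1, n), 2],
                         type = "endpoint"),
      segments = list(list(points = pts,
                           arcLength = sum(sqrt(rowSums(diff(pts)^2))),
                           chordLength = 2 * R,
                           diameters = rep(0.1, n))),
      pixelSize = NA_real_)
}

sierpinskiCarpet <- function(iter = 3, scale = 8) {
  m <- matrix(TRUE, 1, 1)
  for (i in seq_len(iter)) {
    z <- matrix(FALSE, nrow(m), ncol(m))
    m <- rbind(cbind(m, m, m), cbind(m, z, m), cbind(m, m, m))
  }
  m[rep(seq_len(nrow(m)), each = scale), rep(seq_len(ncol(m)), each = scale)]
}

pixelRadii <- function(d, px) {
  xc <- (seq_len(d[2]) - 0.5) * px - d[2] * px / 2
  yc <- d[1] * px / 2 - (seq_len(d[1]) - 0.5) * px
  sqrt(outer(yc^2, xc^2, "+"))
}

## two-point trajectory (always passes the continuity validity check)
twoPointTraj <- function(x, y, fov = 2, prf = 2e5) {
  p <- SpiralParams("AS", fovDiameter = fov, nPoints = 2L, prf = prf)
  new("ScanTrajectory", params = p, t = c(0, 1 / prf), x = x, y = y,
      r = sqrt(x^2 + y^2), theta = atan2(y, x),
      segment = c("AS_out", "AS_in"))
}

## phantom with spatially constant absorption at both wavelengths
constantPhantom <- function(size = 32, v532 = 5, v558 = 3, pixelSize = 2 / size) {
  muA <- array(0, c(size, size, 2), dimnames = list(NULL, NULL, c("532", "558")))
  muA[, , "532"] <- v532
  muA[, , "558"] <- v558
  g <- new("VesselGraph",
           nodes = data.frame(x = numeric(0), y = numeric(0),
                              type = character(0)),
           segments = list(), pixelSize = NA_real_)
  new("VascularPhantom", truthGraph = g,
      so2Map = matrix(0.8, size, size), chbtMap = matrix(1, size, size),
      muA = muA, pixelSize = pixelSize, style = "parallel", rngSeed = 0L)
}

## pulse records covering every pixel centre of a raster exactly once
densePulseRecords <- function(m, pixelSize, wavelength = 532) {
  d <- dim(m)
  xc <- (seq_len(d[2]) - 0.5) * pixelSize - d[2] * pixelSize / 2
  yc <- d[1] * pixelSize / 2 - (seq_len(d[1]) - 0.5) * pixelSize
  grid <- expand.grid(row = seq_len(d[1]), col = seq_len(d[2]))
  new("PulseRecordSet",
      records = data.frame(t = seq_len(nrow(grid)) / 2e5,
                           x = xc[grid$col], y = yc[grid$row],
                           wavelength = wavelength,
                           amplitude = m[cbind(grid$row, grid$col)]),
      noiseSigma = 0, rngSeed = 1L)
}

edgeAnnulusRMSE <- function(img, truth, px, lo = 0.8, hi = 1) {
  rr <- pixelRadii(dim(truth), px)
  sel <- rr > lo & rr <= hi
  sqrt(mean((imagePixels(img)[sel] - truth[sel])^2))
}
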
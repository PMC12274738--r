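## Half-open pixel binning shared by the density map and the image
## reconstruction.  Pixel (i, j) covers [xLeft + (j-1) d, xLeft + j d) in x
## and (yTop - i d, yTop - (i-1) d] in y: row 1 is the top of the image, x
## maps to columns, y to rows.  A point exactly on the far edge of the
## grid is assigned to the last pixel (closed outer boundary).
.binIndices <- function(x, y, gridDim, pixelSize, origin = NULL,
                        what = "pulse") {
  nr <- gridDim[1]; nc <- gridDim[2]
  if (is.null(origin))
    origin <- c(-nc * pixelSize / 2, nr * pixelSize / 2)
  xl <- origin[1]; yt <- origin[2]
  col <- floor((x - xl) / pixelSize) + 1L
  row <- floor((yt - y) / pixelSize) + 1L
  eps <- 1e-9
  col[col == nc + 1L & x <= xl + nc * pixelSize + eps] <- nc
  row[row == nr + 1L & y >= yt - nr * pixelSize - eps] <- nr
  row[row == 0L & y <= yt + eps] <- 1L
  bad <- which(col < 1L | col > nc | row < 1L | row > nr)
  if (length(bad))
    stop(sprintf("%s %d at (%.6g, %.6g) mm lies outside the grid extent",
                 what, bad[1], x[bad[1]], y[bad[1]]))
  list(row = as.integer(row), col = as.integer(col))
}

#' Bin a trajectory onto a pixel grid
#'
#' Counts the laser pulses of a trajectory landing in each pixel of a
#' FOV-centred reconstruction grid (half-open pixel binning) and derives
#' the per-pixel energy factor, `log10(counts + 1)` normalised by its
#' grid maximum — a relative proxy for local laser-energy deposition.
#'
#' @param traj a [ScanTrajectory-class] object, or any data.frame /
#'   list with `x` and `y` components (a scattered point cloud, e.g.
#'   read from CSV), in which case `fovDiameter` must be given unless
#'   `pixelSize` is.
#' @param gridShape integer, grid side in pixels (square grid), or a
#'   length-2 vector (rows, cols).  Default 512.
#' @param pixelSize pixel edge in mm; default `fovDiameter / gridShape`
#'   so the grid spans the field of view.
#' @param fovDiameter field-of-view diameter in mm for point-cloud
#'   input (ignored for trajectories).
#' @return a [SamplingDensityMap-class] object.
#' @examples
#' dm <- densityMap(makeTrajectory(SpiralParams("AFS", nPoints = 8192L)),
#'                  gridShape = 128)
#' sum(pulseCounts(dm))  # every pulse lands in exactly one pixel
#' @export
densityMap <- function(traj, gridShape = 512L, pixelSize = NULL,
                       fovDiameter = NULL) {
  if (is(traj, "ScanTrajectory")) fovDiameter <- traj@params@fovDiameter
  if (length(gridShape) == 1L) gridShape <- c(gridShape, gridShape)
  gridShape <- as.integer(gridShape)
  if (is.null(pixelSize)) {
    if (is.null(fovDiameter))
      stop("point-cloud input needs fovDiameter or pixelSize")
    pixelSize <- fovDiameter / max(gridShape)
  }
  xy <- if (is(traj, "ScanTrajectory")) list(x = traj@x, y = traj@y) else traj
  ij <- .binIndices(xy$x, xy$y, gridShape, pixelSize)
  idx <- (ij$col - 1L) * gridShape[1] + ij$row
  counts <- matrix(tabulate(idx, nbins = prod(gridShape)),
                   nrow = gridShape[1], ncol = gridShape[2])
  storage.mode(counts) <- "integer"
  lg <- log10(counts + 1)
  ef <- lg / max(lg)
  new("SamplingDensityMap", counts = counts, energyFactor = ef,
      pixelSize = pixelSize)
}

#' Fraction of pulses in a central disk
#'
#' Percentage of a trajectory's laser pulses whose radial position falls
#' inside the central disk holding the given fraction of the scan area
#' (a disk of area fraction `f` has radius `R * sqrt(f)`).  This is the
#' quantity that exposes centre oversampling: an Archimedes spiral puts
#' `sqrt(f)` of its pulses there, a Fermat spiral only `f`, and the
#' compound pattern the average of the two.
#'
#' @param traj a [ScanTrajectory-class] object, or a data.frame / list
#'   with `x` and `y` (then `fovDiameter` is required).
#' @param areaFraction number in (0, 1), the central disk's share of the
#'   scan area (e.g. 1/256 or 1/64).
#' @param fovDiameter field-of-view diameter in mm for point-cloud
#'   input.
#' @return percentage in (0, 100\].
#' @examples
#' centralPulseFraction(makeTrajectory(SpiralParams("AS", nPoints = 4096L)),
#'                      1 / 256)
#' @export
centralPulseFraction <- function(traj, areaFraction, fovDiameter = NULL) {
  if (!is.numeric(areaFraction) || length(areaFraction) != 1L ||
      areaFraction <= 0 || areaFraction >= 1)
    stop("areaFraction must lie strictly inside (0, 1)")
  if (is(traj, "ScanTrajectory")) {
    R <- traj@params@fovDiameter / 2
    r <- traj@r
  } else {
    if (is.null(fovDiameter))
      stop("point-cloud input needs fovDiameter")
    R <- fovDiameter / 2
    r <- sqrt(traj$x^2 + traj$y^2)
  }
  100 * mean(r <= R * sqrt(areaFraction))
}

#' Radial fill-density profile of a density map
#'
#' Splits the circular scan domain into `nBins` equal-width annuli and
#' reports, per annulus, the fraction of pixels hit by at least one pulse
#' and the mean pulse count per pixel.  Pixels whose centres lie outside
#' the inscribed disk are ignored.
#'
#' @param dmap a [SamplingDensityMap-class] object.
#' @param nBins integer >= 1, number of annuli.
#' @return a data.frame with columns `annulus`, `rInner`, `rOuter` (mm),
#'   `fillFraction`, `meanCounts`.
#' @export
radialFillProfile <- function(dmap, nBins = 16L) {
  stopifnot(is(dmap, "SamplingDensityMap"))
  nBins <- as.integer(nBins)
  if (nBins < 1L) stop("nBins must be >= 1")
  d <- dim(dmap@counts)
  px <- dmap@pixelSize
  xc <- (seq_len(d[2]) - 0.5) * px - d[2] * px / 2
  yc <- d[1] * px / 2 - (seq_len(d[1]) - 0.5) * px
  rr <- sqrt(outer(yc^2, xc^2, "+"))
  R <- min(d) * px / 2
  bin <- pmin(nBins, floor(rr / (R / nBins)) + 1L)
  keep <- rr <= R
  fill <- tapply(dmap@counts[keep] > 0, bin[keep], mean)
  mc <- tapply(as.numeric(dmap@counts[keep]), bin[keep], mean)
  idx <- as.integer(names(fill))
  data.frame(annulus = idx,
             rInner = (idx - 1) * R / nBins,
             rOuter = idx * R / nBins,
             fillFraction = as.numeric(fill),
             meanCounts = as.numeric(mc))
}

#' @rdname accessors
#' @export
setMethod("pulseCounts", "SamplingDensityMap", function(object) object@counts)

#' @rdname accessors
#' @export
setMethod("energyFactor", "SamplingDensityMap",
          function(object) object@energyFactor)

#' @rdname accessors
#' @export
setMethod("pixelSize", "SamplingDensityMap", function(object) object@pixelSize)

setMethod("show", "SamplingDensityMap", function(object) {
  d <- dim(object@counts)
  cat(sprintf(
    "SamplingDensityMap: %dx%d px (%.4g mm/px), %d pulses, %d filled pixels (%.1f%%)\n",
    d[1], d[2], object@pixelSize, sum(object@counts),
    sum(object@counts > 0), 100 * mean(object@counts > 0)))
})
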
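## Bilinear interpolation of a raster (row 1 = top) at world coordinates
## (mm).  origin = c(xLeft, yTop); values outside the outermost pixel
## centres are clamped to the edge.
.bilinear <- function(m, x, y, pixelSize, origin) {
  nr <- nrow(m); nc <- ncol(m)
  gx <- (x - origin[1]) / pixelSize + 0.5   # == j at the centre of col j
  gy <- (origin[2] - y) / pixelSize + 0.5
  gx <- pmin(pmax(gx, 1), nc)
  gy <- pmin(pmax(gy, 1), nr)
  j0 <- pmin(floor(gx), nc - 1L); i0 <- pmin(floor(gy), nr - 1L)
  fx <- gx - j0; fy <- gy - i0
  (1 - fx) * (1 - fy) * m[cbind(i0, j0)] +
    fx * (1 - fy) * m[cbind(i0, j0 + 1L)] +
    (1 - fx) * fy * m[cbind(i0 + 1L, j0)] +
    fx * fy * m[cbind(i0 + 1L, j0 + 1L)]
}

#' Simulate per-pulse acquisition of a phantom along a trajectory
#'
#' Samples the phantom's absorption raster by bilinear interpolation at
#' every pulse position, adds zero-mean Gaussian amplitude noise and
#' clips at zero.  In dual-wavelength mode each position emits a
#' co-located 532/558-nm pulse pair (zero lag); `lagOnePulse` instead
#' fires the 558-nm pulse at the *next* trajectory position, emulating
#' sequential excitation and the spatial misregistration it causes.
#'
#' @param phantom a [VascularPhantom-class] object.
#' @param traj a [ScanTrajectory-class] object; its field of view must
#'   fit inside the phantom extent.
#' @param noiseSigma standard deviation of the additive amplitude noise
#'   (same relative units as the phantom absorption).
#' @param seed integer seed for the noise draw.
#' @param dualWavelength if TRUE (default) acquire both wavelengths.
#' @param lagOnePulse if TRUE, the 558-nm record of a pair is taken one
#'   pulse later along the trajectory.
#' @return a [PulseRecordSet-class] object.
#' @export
acquire <- function(phantom, traj, noiseSigma = 0, seed = 1L,
                    dualWavelength = TRUE, lagOnePulse = FALSE) {
  stopifnot(is(phantom, "VascularPhantom"), is(traj, "ScanTrajectory"))
  d <- dim(phantom@so2Map)
  W2 <- c(d[2], d[1]) * phantom@pixelSize / 2
  if (max(abs(traj@x)) > W2[1] + 1e-9 || max(abs(traj@y)) > W2[2] + 1e-9)
    stop("trajectory exceeds the phantom extent")
  origin <- c(-W2[1], W2[2])
  n <- length(traj@x)
  sample1 <- function(wl, shift = 0L) {
    idx <- pmin(seq_len(n) + shift, n)
    amp <- .bilinear(phantom@muA[, , as.character(wl)],
                     traj@x[idx], traj@y[idx],
                     phantom@pixelSize, origin)
    data.frame(t = traj@t[idx], x = traj@x[idx], y = traj@y[idx],
               wavelength = wl, amplitude = amp)
  }
  rec <- sample1(532)
  if (dualWavelength)
    rec <- rbind(rec, sample1(558, shift = if (lagOnePulse) 1L else 0L))
  if (noiseSigma > 0)
    rec$amplitude <- .withSeed(seed,
      rec$amplitude + rnorm(nrow(rec), 0, noiseSigma))
  rec$amplitude <- pmax(rec$amplitude, 0)
  new("PulseRecordSet", records = rec, noiseSigma = noiseSigma,
      rngSeed = as.integer(seed))
}

#' @rdname accessors
#' @export
setMethod("pulseRecords", "PulseRecordSet", function(object) object@records)

setMethod("show", "PulseRecordSet", function(object) {
  wl <- table(object@records$wavelength)
  cat(sprintf("PulseRecordSet: %d records (%s), noise sigma %.4g, seed %d\n",
              nrow(object@records),
              paste(sprintf("%s nm: %d", names(wl), wl), collapse = ", "),
              object@noiseSigma, object@rngSeed))
})
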
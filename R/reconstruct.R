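## Shift a matrix by (dr, dc), padding with `fill`.
.shiftMat <- function(m, dr, dc, fill) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

## Fill empty pixels with the value of the (chamfer-) nearest filled
## pixel by iterative 8-neighbour distance propagation.
.nearestFill <- function(pixels, filled) {
  dist <- matrix(Inf, nrow(pixels), ncol(pixels))
  dist[filled] <- 0
  val <- pixels
  offs <- cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1),
                dc = c(-1, 0, 1, -1, 1, -1, 0, 1))
  cost <- ifelse(abs(offs[, 1]) + abs(offs[, 2]) == 2, sqrt(2), 1)
  repeat {
    changed <- FALSE
    for (k in seq_len(nrow(offs))) {
      cand <- .shiftMat(dist, offs[k, 1], offs[k, 2], Inf) + cost[k]
      better <- cand < dist
      if (any(better)) {
        changed <- TRUE
        dist[better] <- cand[better]
        val[better] <- .shiftMat(val, offs[k, 1], offs[k, 2], NA)[better]
      }
    }
    if (!changed) break
  }
  val
}

## Harmonic (discrete-Laplace) fill: empty pixels relax to the mean of
## their 4-neighbours while filled pixels stay fixed.  Initialised by the
## nearest fill so convergence is fast.
.harmonicFill <- function(pixels, filled, iters = 100L) {
  val <- .nearestFill(pixels, filled)
  empty <- !filled
  for (it in seq_len(iters)) {
    s <- .shiftMat(val, 1, 0, NA) ; n1 <- !is.na(s); s[!n1] <- 0
    acc <- s; cnt <- n1 + 0
    for (o in list(c(-1, 0), c(0, 1), c(0, -1))) {
      s <- .shiftMat(val, o[1], o[2], NA); ok <- !is.na(s); s[!ok] <- 0
      acc <- acc + s; cnt <- cnt + ok
    }
    new <- acc / pmax(cnt, 1)
    delta <- max(abs(new[empty] - val[empty]), 0)
    val[empty] <- new[empty]
    if (delta < 1e-10) break
  }
  val
}

#' Reconstruct a gridded image from scattered pulse records
#'
#' Grids the scattered per-pulse samples of one wavelength onto a
#' FOV-centred pixel raster.  `"bin_mean"` is the raw mode: every pixel
#' takes the mean of the pulses that landed in it and unsampled pixels
#' stay at 0 with `fillMask` FALSE (no post-processing, matching raw
#' scan-pattern comparisons).  `"nearest"` and `"linear"` additionally
#' fill the unsampled pixels by scattered interpolation — nearest-sample
#' propagation and harmonic (discrete-Laplace) interpolation from the
#' filled boundary, respectively — and flag them in the `inpainted` mask.
#'
#' @param prs a [PulseRecordSet-class] object.
#' @param gridShape grid side in pixels, or (rows, cols).  Default 512.
#' @param pixelSize mm per pixel; default spans the records' extent.
#' @param method `"bin_mean"`, `"nearest"` or `"linear"`.
#' @param wavelength which wavelength to reconstruct (532 or 558);
#'   mandatory when the record set holds both.
#' @return a [ReconstructedImage-class] object.
#' @export
reconstruct <- function(prs, gridShape = 512L, pixelSize = NULL,
                        method = c("bin_mean", "nearest", "linear"),
                        wavelength = NULL) {
  stopifnot(is(prs, "PulseRecordSet"))
  method <- match.arg(method)
  rec <- prs@records
  if (nrow(rec) == 0L) stop("empty pulse record set")
  wls <- unique(rec$wavelength)
  if (is.null(wavelength)) {
    if (length(wls) > 1L)
      stop("records hold both wavelengths; select one via `wavelength`")
    wavelength <- wls
  }
  rec <- rec[rec$wavelength == wavelength, ]
  if (nrow(rec) == 0L) stop("no records at wavelength ", wavelength)
  if (length(gridShape) == 1L) gridShape <- c(gridShape, gridShape)
  gridShape <- as.integer(gridShape)
  if (is.null(pixelSize))
    pixelSize <- 2 * max(abs(c(rec$x, rec$y))) / max(gridShape)
  ij <- .binIndices(rec$x, rec$y, gridShape, pixelSize, what = "record")
  idx <- (ij$col - 1L) * gridShape[1] + ij$row
  npix <- prod(gridShape)
  counts <- tabulate(idx, nbins = npix)
  sums <- numeric(npix)
  agg <- rowsum(rec$amplitude, idx)
  sums[as.integer(rownames(agg))] <- agg[, 1]
  pix <- matrix(ifelse(counts > 0, sums / pmax(counts, 1), 0),
                gridShape[1], gridShape[2])
  filled <- matrix(counts > 0, gridShape[1], gridShape[2])
  inpainted <- matrix(FALSE, gridShape[1], gridShape[2])
  if (method != "bin_mean" && any(!filled)) {
    pix <- if (method == "nearest") .nearestFill(pix, filled)
           else .harmonicFill(pix, filled)
    inpainted <- !filled
  }
  new("ReconstructedImage", pixels = pix, fillMask = filled,
      inpainted = inpainted, pixelSize = pixelSize,
      origin = c(-gridShape[2] * pixelSize / 2, gridShape[1] * pixelSize / 2),
      wavelength = as.numeric(wavelength))
}

#' Wrap a plain raster as a ReconstructedImage
#'
#' Convenience constructor used when a raster from elsewhere (a phantom
#' channel, a file) needs to enter the functional or morphometry chain.
#'
#' @param pixels numeric matrix (row 1 = top).
#' @param pixelSize mm per pixel.
#' @param wavelength optional wavelength tag (nm).
#' @param fillMask optional logical matrix; default all TRUE.
#' @return a [ReconstructedImage-class] object.
#' @export
asReconstructedImage <- function(pixels, pixelSize, wavelength = NA_real_,
                                 fillMask = NULL) {
  if (is.null(fillMask)) fillMask <- matrix(TRUE, nrow(pixels), ncol(pixels))
  new("ReconstructedImage", pixels = pixels, fillMask = fillMask,
      inpainted = matrix(FALSE, nrow(pixels), ncol(pixels)),
      pixelSize = pixelSize,
      origin = c(-ncol(pixels) * pixelSize / 2, nrow(pixels) * pixelSize / 2),
      wavelength = as.numeric(wavelength))
}

#' @rdname accessors
#' @export
setMethod("imagePixels", "ReconstructedImage", function(object) object@pixels)

#' @rdname accessors
#' @export
setMethod("fillMask", "ReconstructedImage", function(object) object@fillMask)

#' @rdname accessors
#' @export
setMethod("pixelSize", "ReconstructedImage", function(object) object@pixelSize)

setMethod("show", "ReconstructedImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf(
    "ReconstructedImage: %dx%d px (%.4g mm/px), %snm, %.1f%% filled, %.1f%% inpainted\n",
    d[1], d[2], object@pixelSize,
    ifelse(is.na(object@wavelength), "untagged ", paste0(object@wavelength, " ")),
    100 * mean(object@fillMask), 100 * mean(object@inpainted)))
})
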
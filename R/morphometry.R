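#' Segment vessels in a reconstructed image
#'
#' Produces a binary vessel mask.  The default pipeline suppresses slow
#' background with a disc top-hat, thresholds globally by Otsu's method,
#' removes objects smaller than `minArea` pixels and fills holes.
#' `"adaptive"` uses a local-mean threshold instead; `"fixed"` applies
#' the given absolute threshold to the raw image.
#'
#' @param img a [ReconstructedImage-class] object or a numeric matrix.
#' @param method `"otsu"` (default), `"adaptive"` or `"fixed"`.
#' @param threshold absolute threshold, required for `"fixed"`.
#' @param minArea smallest connected component kept, in pixels.
#' @param tophatRadius disc radius (px) of the background-suppression
#'   top-hat applied before Otsu; 0 disables it.
#' @param fillHoles fill enclosed holes in the mask (default TRUE).
#' @return logical matrix (TRUE = vessel).
#' @export
segmentVessels <- function(img, method = c("otsu", "adaptive", "fixed"),
                           threshold = NULL, minArea = 20L,
                           tophatRadius = 20L, fillHoles = TRUE) {
  method <- match.arg(method)
  m <- if (is(img, "ReconstructedImage")) img@pixels else img
  if (!is.matrix(m)) stop("img must be a matrix or ReconstructedImage")
  if (max(m) == 0) stop("empty foreground: the image is identically zero")
  if (method == "fixed") {
    if (is.null(threshold)) stop("method 'fixed' needs a threshold")
    mask <- m > threshold
  } else {
    mn <- m / max(m)
    if (method == "otsu") {
      if (tophatRadius > 0) {
        brush <- EBImage::makeBrush(2L * as.integer(tophatRadius) + 1L,
                                    shape = "disc")
        mn <- EBImage::whiteTopHat(mn, brush)
        if (max(mn) > 0) mn <- mn / max(mn)
      }
      th <- EBImage::otsu(EBImage::Image(mn))
      mask <- mn > th
    } else {
      mask <- EBImage::thresh(EBImage::Image(mn), w = 15, h = 15,
                              offset = 0.02) > 0
    }
  }
  mask <- matrix(as.logical(mask), nrow(m), ncol(m))
  if (minArea > 0 && any(mask)) {
    lab <- EBImage::bwlabel(EBImage::Image(mask + 0))
    sizes <- tabulate(as.integer(lab))
    keep <- which(sizes >= minArea)
    mask <- matrix(as.integer(lab) %in% keep, nrow(m), ncol(m))
  }
  if (fillHoles && any(mask))
    mask <- as.matrix(EBImage::fillHull(EBImage::Image(mask + 0))) > 0
  if (!any(mask))
    stop("empty foreground after cleanup: no vessel-like structures found")
  mask
}

## Box-counting: number of non-empty r x r boxes anchored at the image
## origin.
.boxCount <- function(mask, r) {
  ij <- which(mask, arr.ind = TRUE)
  key <- ((ij[, 1] - 1L) %/% r) * (ncol(mask) %/% r + 2L) +
    ((ij[, 2] - 1L) %/% r)
  length(unique(key))
}

#' Box-counting fractal dimension
#'
#' Overlays the binary raster with grids of boxes of side `r` (anchored
#' at the image origin), counts the non-empty boxes N(r) at every scale,
#' and returns the least-squares slope of log N(r) against log(1/r) —
#' the multi-scale reading of FD = log N(r) / log(1/r).
#'
#' @param mask logical (or 0/1) matrix.
#' @param boxSizes integer vector of box sides in px (>= 2 distinct
#'   values); default powers of 2 from 2 to `min(dim(mask)) / 4`.
#' @return list with `FD` (slope), and the `boxSizes` / `counts` used.
#' @export
fractalDimension <- function(mask, boxSizes = NULL) {
  mask <- mask > 0
  if (is.null(boxSizes)) {
    kmax <- floor(log2(min(dim(mask)) / 4))
    boxSizes <- 2^seq(1, max(1, kmax))
  }
  boxSizes <- sort(unique(as.integer(boxSizes)))
  if (length(boxSizes) < 2L)
    stop("need at least 2 distinct box sizes for the regression")
  counts <- vapply(boxSizes, function(r) .boxCount(mask, r), 0L)
  fit <- lm(log(counts) ~ log(1 / boxSizes))
  list(FD = unname(coef(fit)[2]), boxSizes = boxSizes, counts = counts)
}

#' Compute the five morphometric summary metrics
#'
#' From a traced vessel graph and its source mask: total vessel length
#' VL (sum of segment arc lengths), number of branch points NBP, mean
#' vessel diameter MVD (mean of all per-point diameters), mean vessel
#' tortuosity VT (arc length / chord length, averaged over segments —
#' unweighted by default, optionally length-weighted) and box-counting
#' fractal dimension FD of the mask.
#'
#' @param g a [VesselGraph-class] object (from [skeletonizeGraph()] or a
#'   phantom's ground truth).
#' @param mask the binary vessel raster the FD is computed on.
#' @param boxSizes box sides for [fractalDimension()]; default powers
#'   of 2.
#' @param lengthWeightedVT if TRUE, weight each segment's tortuosity by
#'   its arc length.
#' @return a [MorphometryReport-class] object.
#' @examples
#' bar <- matrix(FALSE, 40, 120); bar[18:23, 11:110] <- TRUE
#' g <- skeletonizeGraph(bar, pixelSize = 1)
#' metricValues(computeMetrics(g, bar))
#' @export
computeMetrics <- function(g, mask, boxSizes = NULL,
                           lengthWeightedVT = FALSE) {
  stopifnot(is(g, "VesselGraph"))
  arcs <- vapply(g@segments, function(s) s$arcLength, 0)
  chords <- vapply(g@segments, function(s) s$chordLength, 0)
  dia <- unlist(lapply(g@segments, function(s) s$diameters))
  ok <- chords > 0
  vt <- if (!any(ok)) NA_real_
        else if (lengthWeightedVT)
          sum(arcs[ok] / chords[ok] * arcs[ok]) / sum(arcs[ok])
        else mean(arcs[ok] / chords[ok])
  fd <- fractalDimension(mask, boxSizes)
  new("MorphometryReport",
      VL = sum(arcs),
      NBP = sum(g@nodes$type == "branchpoint"),
      MVD = if (length(dia)) mean(dia, na.rm = TRUE) else NA_real_,
      VT = vt,
      FD = fd$FD,
      provenance = list(boxSizes = fd$boxSizes, boxCounts = fd$counts,
                        lengthWeightedVT = lengthWeightedVT,
                        nSegments = length(g@segments),
                        pixelSize = g@pixelSize))
}

#' One-call morphometry of an image
#'
#' Convenience wrapper: segment, skeletonise, trace and summarise.
#'
#' @param img a [ReconstructedImage-class] object or numeric matrix.
#' @param pixelSize mm per pixel (taken from the image when available).
#' @param ... passed to [segmentVessels()].
#' @return a [MorphometryReport-class] object.
#' @export
morphometry <- function(img, pixelSize = NULL, ...) {
  if (is(img, "ReconstructedImage") && is.null(pixelSize))
    pixelSize <- img@pixelSize
  if (is.null(pixelSize)) pixelSize <- 1
  mask <- segmentVessels(img, ...)
  g <- skeletonizeGraph(mask, pixelSize)
  computeMetrics(g, mask)
}

#' @rdname accessors
#' @export
setMethod("metricValues", "MorphometryReport", function(object)
  c(VL = object@VL, NBP = as.numeric(object@NBP), MVD = object@MVD,
    VT = object@VT, FD = object@FD))

setMethod("show", "MorphometryReport", function(object) {
  cat(sprintf(
    "MorphometryReport: VL %.4g mm | NBP %d | MVD %.4g mm | VT %.4g | FD %.4g\n",
    object@VL, object@NBP, object@MVD, object@VT, object@FD))
})
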
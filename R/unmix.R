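#' Background noise estimate of a reconstructed image
#'
#' Median-absolute-deviation amplitude of the filled pixels that border
#' unfilled ones (the fill fringe, which carries no coherent vessel
#' signal in sparsely sampled images).  Returns 0 for a fully filled
#' image.
#'
#' @param img a [ReconstructedImage-class] object.
#' @return numeric noise scale (same units as the image).
#' @export
estimateNoise <- function(img) {
  f <- img@fillMask
  if (all(f)) return(0)
  nearEmpty <- matrix(FALSE, nrow(f), ncol(f))
  for (o in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
                 c(-1, -1), c(-1, 1), c(1, -1), c(1, 1)))
    nearEmpty <- nearEmpty | !.shiftMat(f, o[1], o[2], TRUE)
  sel <- f & nearEmpty
  if (!any(sel)) return(0)
  mad(img@pixels[sel], center = 0)
}

#' Two-wavelength linear unmixing into sO2 and relative C_HbT
#'
#' Inverts the forward model `PA(lambda) = k (eps_HbO2(lambda) C_HbO2 +
#' eps_Hb(lambda) C_Hb)` per pixel for the two wavelength images: the
#' 2x2 extinction system is solved for the component amplitudes
#' `k C_HbO2` and `k C_Hb` (the shared proportionality constant k —
#' Grueneisen parameter times fluence — stays absorbed in the relative
#' units), giving `sO2 = C_HbO2 / (C_HbO2 + C_Hb)` and the relative
#' total hemoglobin `C_HbT = PA(532) / (sO2 eps_HbO2(532) +
#' (1 - sO2) eps_Hb(532))`.  Pixels are unmixed only where both
#' wavelengths are filled and the 532-nm amplitude clears
#' `ampThreshold`; negative component estimates are clamped to zero and
#' counted.
#'
#' @param img532,img558 co-registered [ReconstructedImage-class] objects
#'   on the same grid.
#' @param ext an [ExtinctionTable-class]; default the packaged table.
#' @param ampThreshold amplitude threshold for the validity mask;
#'   default 5x the [estimateNoise()] of the 532-nm image.
#' @return a [FunctionalMaps-class] object.
#' @examples
#' ext <- hemoglobinExtinction()
#' a532 <- forwardAbsorption(0.8, 1, ext, 532)
#' a558 <- forwardAbsorption(0.8, 1, ext, 558)
#' fm <- unmix(asReconstructedImage(matrix(a532, 4, 4), 0.01, 532),
#'             asReconstructedImage(matrix(a558, 4, 4), 0.01, 558))
#' so2Map(fm)[1, 1]   # recovers 0.8
#' @export
unmix <- function(img532, img558, ext = hemoglobinExtinction(),
                  ampThreshold = NULL) {
  stopifnot(is(img532, "ReconstructedImage"), is(img558, "ReconstructedImage"))
  if (!identical(dim(img532@pixels), dim(img558@pixels)))
    stop("the two wavelength images must share one grid")
  e532 <- extinctionValues(ext, 532)
  e558 <- extinctionValues(ext, 558)
  E <- rbind(e532, e558)
  if (abs(det(E)) < 1e-9 * prod(abs(E[, 1]) + abs(E[, 2])))
    stop("singular extinction system: the two wavelength rows are proportional")
  if (is.null(ampThreshold)) ampThreshold <- 5 * estimateNoise(img532)
  usable532 <- img532@fillMask | img532@inpainted
  usable558 <- img558@fillMask | img558@inpainted
  mask <- usable532 & usable558 & img532@pixels > ampThreshold
  Ei <- solve(E)
  pa <- rbind(as.vector(img532@pixels[mask]), as.vector(img558@pixels[mask]))
  comp <- Ei %*% pa                     # rows: k C_HbO2, k C_Hb
  clamped <- comp < 0
  clampCount <- sum(colSums(clamped) > 0)
  comp[clamped] <- 0
  tot <- colSums(comp)
  so2v <- ifelse(tot > 0, comp[1, ] / tot, NA_real_)
  chbtv <- ifelse(!is.na(so2v),
                  pa[1, ] / (so2v * e532[["epsHbO2"]] +
                             (1 - so2v) * e532[["epsHb"]]),
                  NA_real_)
  d <- dim(img532@pixels)
  so2 <- matrix(NA_real_, d[1], d[2]); so2[mask] <- so2v
  chbt <- matrix(NA_real_, d[1], d[2]); chbt[mask] <- chbtv
  mask[mask][is.na(so2v)] <- FALSE
  so2[!mask] <- NA_real_; chbt[!mask] <- NA_real_
  new("FunctionalMaps", so2 = so2, chbtRel = chbt, mask = mask,
      clampCount = as.integer(clampCount), pixelSize = img532@pixelSize)
}

#' Fractional change of FOV-mean functional values over time
#'
#' The baseline is the mean of the first `baselineFrames` frames of the
#' FOV-mean series; every frame is then reported as
#' `(value - baseline) / baseline`.
#'
#' `fractionalChange` operates on a plain numeric series;
#' `fractionalChangeSeries` takes a time-ordered list of
#' [FunctionalMaps-class] objects and returns both the sO2 and the
#' C_HbT fractional-change series.
#'
#' @param series numeric vector of per-frame values.
#' @param baselineFrames integer, number of leading frames that define
#'   the baseline (default 5).
#' @return numeric vector of fractional changes (same length as input).
#' @export
fractionalChange <- function(series, baselineFrames = 5L) {
  baselineFrames <- as.integer(baselineFrames)
  if (length(series) < baselineFrames)
    stop("need at least baselineFrames frames")
  base <- mean(series[seq_len(baselineFrames)])
  if (!is.finite(base) || base == 0) stop("zero or undefined baseline")
  (series - base) / base
}

#' @rdname fractionalChange
#' @param maps time-ordered list of [FunctionalMaps-class] objects.
#' @return for `fractionalChangeSeries`: a data.frame with columns
#'   `frame`, `so2`, `chbt` of per-frame fractional changes.
#' @export
fractionalChangeSeries <- function(maps, baselineFrames = 5L) {
  stopifnot(all(vapply(maps, is, TRUE, "FunctionalMaps")))
  mso2 <- vapply(maps, function(m) mean(m@so2[m@mask]), 0)
  mchbt <- vapply(maps, function(m) mean(m@chbtRel[m@mask]), 0)
  data.frame(frame = seq_along(maps),
             so2 = fractionalChange(mso2, baselineFrames),
             chbt = fractionalChange(mchbt, baselineFrames))
}

#' @rdname accessors
#' @export
setMethod("so2Map", "FunctionalMaps", function(object) object@so2)

#' @rdname accessors
#' @export
setMethod("chbtMap", "FunctionalMaps", function(object) object@chbtRel)

#' @rdname accessors
#' @export
setMethod("pixelSize", "FunctionalMaps", function(object) object@pixelSize)

#' Number of clamped pixels of an unmixing result
#' @param object a [FunctionalMaps-class] object.
#' @return integer.
#' @export
clampCount <- function(object) object@clampCount

setMethod("show", "FunctionalMaps", function(object) {
  cat(sprintf(
    "FunctionalMaps: %dx%d px, %d masked pixels, mean sO2 %.3f, mean C_HbT %.3g, %d clamped\n",
    nrow(object@so2), ncol(object@so2), sum(object@mask),
    mean(object@so2[object@mask]), mean(object@chbtRel[object@mask]),
    object@clampCount))
})
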
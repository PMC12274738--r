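#' Construct a rigid 2-D transform
#'
#' @param rotation angle in rad (counter-clockwise).
#' @param translation numeric length 2 (mm).
#' @param residualRMS optional RMS landmark misfit (filled by
#'   [fitRigid()]).
#' @return a [RigidTransform2D-class] object.
#' @export
RigidTransform2D <- function(rotation = 0, translation = c(0, 0),
                             residualRMS = NA_real_) {
  new("RigidTransform2D", rotation = rotation,
      translation = as.numeric(translation), residualRMS = residualRMS)
}

#' Apply a rigid transform to points
#'
#' @param transform a [RigidTransform2D-class] object.
#' @param points n x 2 matrix of (x, y) coordinates.
#' @param inverse if TRUE apply the inverse transform.
#' @return n x 2 matrix of transformed coordinates.
#' @export
applyRigid <- function(transform, points, inverse = FALSE) {
  points <- matrix(as.numeric(points), ncol = 2)
  a <- transform@rotation
  R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
  if (inverse)
    t(t(points) - transform@translation) %*% R      # R^T applied rowwise
  else
    points %*% t(R) + rep(transform@translation, each = nrow(points))
}

#' Least-squares rigid alignment of landmark pairs
#'
#' Orthogonal Procrustes without scaling: finds the rotation and
#' translation mapping the moving landmarks onto the fixed ones with
#' minimal sum of squared pair distances (Kabsch solution via SVD of the
#' cross-covariance, reflection excluded), as used when stitching
#' adjacent fields of view by matched anatomical landmarks.
#'
#' @param landmarksMoving,landmarksFixed n x 2 matrices of matched
#'   (x, y) landmark coordinates, n >= 2, not all coincident.
#' @return a [RigidTransform2D-class] object with `residualRMS` set.
#' @examples
#' fx <- cbind(c(0, 1, 0), c(0, 0, 1))
#' tr <- fitRigid(fx, fx)  # identity, zero residual
#' @export
fitRigid <- function(landmarksMoving, landmarksFixed) {
  M <- matrix(as.numeric(landmarksMoving), ncol = 2)
  F_ <- matrix(as.numeric(landmarksFixed), ncol = 2)
  if (nrow(M) != nrow(F_)) stop("landmark lists must have equal length")
  if (nrow(M) < 2L) stop("need at least 2 landmark pairs")
  cm <- colMeans(M); cf <- colMeans(F_)
  Mc <- sweep(M, 2, cm); Fc <- sweep(F_, 2, cf)
  if (max(abs(Mc)) < 1e-12 || max(abs(Fc)) < 1e-12)
    stop("degenerate landmarks: all points coincide")
  H <- t(Mc) %*% Fc
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, d)) %*% t(s$u)
  ang <- atan2(R[2, 1], R[1, 1])
  trans <- as.numeric(cf - R %*% cm)
  res <- sqrt(mean(rowSums((Mc %*% t(R) - Fc)^2)))
  RigidTransform2D(rotation = ang, translation = trans, residualRMS = res)
}

setMethod("show", "RigidTransform2D", function(object) {
  cat(sprintf(
    "RigidTransform2D: rotation %.6g rad, translation (%.6g, %.6g) mm%s\n",
    object@rotation, object@translation[1], object@translation[2],
    if (is.na(object@residualRMS)) ""
    else sprintf(", residual RMS %.3g mm", object@residualRMS)))
})

#' Stitch reconstructed images into a mosaic
#'
#' Places each image into a common frame through its rigid transform and
#' composites them on a canvas sized to the union bounding box.
#' Overlapping filled pixels are combined per the blend mode:
#' `"overwrite"` lets later images win, `"feather_mean"` weights each
#' contribution by its distance to the tile's fill boundary so seams
#' fade smoothly.  The mosaic fill mask is the union of the transformed
#' tile masks.
#'
#' @param images list of [ReconstructedImage-class] objects.
#' @param transforms list of [RigidTransform2D-class] objects of the same
#'   length, mapping each image's coordinates into the common frame.
#' @param blend `"overwrite"` or `"feather_mean"`.
#' @return a [ReconstructedImage-class] mosaic.
#' @export
stitch <- function(images, transforms, blend = c("overwrite", "feather_mean")) {
  blend <- match.arg(blend)
  stopifnot(length(images) == length(transforms), length(images) >= 1L)
  px <- images[[1]]@pixelSize
  ## union bounding box of transformed image corners
  corners <- lapply(seq_along(images), function(k) {
    im <- images[[k]]
    w <- ncol(im@pixels) * im@pixelSize; h <- nrow(im@pixels) * im@pixelSize
    cs <- rbind(c(0, 0), c(w, 0), c(0, -h), c(w, -h))
    cs <- sweep(cs, 2, -c(im@origin[1], im@origin[2]))  # + origin
    applyRigid(transforms[[k]], cs)
  })
  allc <- do.call(rbind, corners)
  xl <- floor(min(allc[, 1]) / px + 1e-6) * px
  yt <- ceiling(max(allc[, 2]) / px - 1e-6) * px
  nc <- as.integer(ceiling((max(allc[, 1]) - xl) / px - 1e-6))
  nr <- as.integer(ceiling((yt - min(allc[, 2])) / px - 1e-6))
  num <- matrix(0, nr, nc); den <- matrix(0, nr, nc)
  out <- matrix(0, nr, nc); fill <- matrix(FALSE, nr, nc)
  ## mosaic pixel centres in world coordinates
  gx <- xl + (seq_len(nc) - 0.5) * px
  gy <- yt - (seq_len(nr) - 0.5) * px
  P <- cbind(rep(gx, each = nr), rep(gy, times = nc))
  for (k in seq_along(images)) {
    im <- images[[k]]
    Q <- applyRigid(transforms[[k]], P, inverse = TRUE)
    j <- as.integer(round((Q[, 1] - im@origin[1]) / im@pixelSize + 0.5))
    i <- as.integer(round((im@origin[2] - Q[, 2]) / im@pixelSize + 0.5))
    ok <- i >= 1L & i <= nrow(im@pixels) & j >= 1L & j <= ncol(im@pixels)
    src <- cbind(i[ok], j[ok])
    valid <- im@fillMask[src]
    tgt <- which(ok)[valid]
    src <- src[valid, , drop = FALSE]
    v <- im@pixels[src]
    if (blend == "overwrite") {
      out[tgt] <- v
    } else {
      m0 <- matrix(0, nrow(im@pixels) + 2L, ncol(im@pixels) + 2L)
      m0[2:(nrow(im@pixels) + 1L), 2:(ncol(im@pixels) + 1L)] <- im@fillMask
      Dw <- as.matrix(EBImage::distmap(m0))[
        2:(nrow(im@pixels) + 1L), 2:(ncol(im@pixels) + 1L)]
      w <- pmax(Dw[src], .5)
      num[tgt] <- num[tgt] + w * v
      den[tgt] <- den[tgt] + w
    }
    fill[tgt] <- TRUE
  }
  if (blend == "feather_mean") out[fill] <- num[fill] / den[fill]
  new("ReconstructedImage", pixels = out, fillMask = fill,
      inpainted = matrix(FALSE, nr, nc), pixelSize = px,
      origin = c(xl, yt), wavelength = images[[1]]@wavelength)
}
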
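## Densify a polyline (n x 2, mm) to roughly uniform spacing `step` by
## linear interpolation along its arc length.
.resamplePolyline <- function(pts, step) {
  keep <- c(TRUE, rowSums(abs(diff(pts))) > 1e-12)   # drop repeated points
  pts <- pts[keep, , drop = FALSE]
  if (nrow(pts) < 2) return(pts)
  seglen <- sqrt(rowSums(diff(pts)^2))
  L <- sum(seglen)
  if (L == 0) return(pts[1, , drop = FALSE])
  s <- c(0, cumsum(seglen))
  so <- seq(0, L, length.out = max(2L, ceiling(L / step) + 1L))
  cbind(approx(s, pts[, 1], so, ties = "ordered")$y,
        approx(s, pts[, 2], so, ties = "ordered")$y)
}

.polyArcLength <- function(pts) sum(sqrt(rowSums(diff(pts)^2)))
.chord <- function(pts) sqrt(sum((pts[nrow(pts), ] - pts[1, ])^2))

## One vessel: dense centreline polyline (mm), diameter (mm), sO2, C_HbT.
.vesselSpecs <- function(style, W, vesselDensity, so2Range, diameterRange) {
  half <- 0.45 * W
  drawSo2 <- function(k) {
    if (!is.null(so2Range)) return(runif(k, so2Range[1], so2Range[2]))
    ## arteries high, veins low, alternating
    ifelse(seq_len(k) %% 2 == 1, runif(k, 0.95, 0.98), runif(k, 0.60, 0.75))
  }
  vessels <- list()
  branchPoints <- NULL
  if (style == "parallel") {
    nV <- max(2L, round(8 * vesselDensity))
    xs <- seq(-half, half, length.out = nV)
    so2 <- drawSo2(nV); chbt <- runif(nV, 0.6, 1)
    dia <- runif(nV, diameterRange[1], diameterRange[2])
    for (i in seq_len(nV)) {
      cy <- seq(-half, half, length.out = 6)
      cx <- xs[i] + rnorm(6, 0, 0.02 * W)
      sp <- spline(cy, cx, n = 200)
      vessels[[i]] <- list(points = cbind(pmin(pmax(sp$y, -W / 2), W / 2),
                                          sp$x),
                           diameter = dia[i], so2 = so2[i], chbt = chbt[i])
    }
  } else if (style == "grid") {
    nH <- max(1L, round(3 * vesselDensity))
    nV <- max(1L, round(3 * vesselDensity))
    ## evenly spaced with bounded jitter so lines never merge
    spaced <- function(k) seq(-half, half, length.out = k + 2)[2:(k + 1)] +
      runif(k, -0.2, 0.2) * 2 * half / (k + 1)
    ys <- spaced(nH)
    xs <- spaced(nV)
    k <- 0L
    so2 <- drawSo2(nH + nV); chbt <- runif(nH + nV, 0.6, 1)
    dia <- runif(nH + nV, diameterRange[1], diameterRange[2])
    for (y in ys) {
      k <- k + 1L
      vessels[[k]] <- list(points = cbind(c(-half, half), c(y, y)),
                           diameter = dia[k], so2 = so2[k], chbt = chbt[k])
    }
    for (x in xs) {
      k <- k + 1L
      vessels[[k]] <- list(points = cbind(c(x, x), c(-half, half)),
                           diameter = dia[k], so2 = so2[k], chbt = chbt[k])
    }
    branchPoints <- as.matrix(expand.grid(x = xs, y = ys))
  } else if (style == "loops") {
    nL <- max(1L, round(4 * vesselDensity))
    so2 <- drawSo2(nL); chbt <- runif(nL, 0.6, 1)
    dia <- runif(nL, diameterRange[1], diameterRange[2])
    x0 <- seq(-half, half, length.out = nL + 2)[-c(1, nL + 2)]
    for (i in seq_len(nL)) {
      w <- runif(1, 0.05, 0.10) * W          # limb separation
      y0 <- -half; y1 <- runif(1, 0.1, 0.8) * half
      th <- seq(pi, 0, length.out = 60)      # semicircular cap
      cap <- cbind(x0[i] + (w / 2) * cos(th), y1 + (w / 2) * sin(th))
      pts <- rbind(cbind(x0[i] - w / 2, seq(y0, y1, length.out = 40)),
                   cap,
                   cbind(x0[i] + w / 2, seq(y1, y0, length.out = 40)))
      vessels[[i]] <- list(points = pts, diameter = dia[i],
                           so2 = so2[i], chbt = chbt[i])
    }
  } else if (style == "random_tree") {
    nTrees <- max(1L, round(2 * vesselDensity))
    so2all <- drawSo2(nTrees)
    k <- 0L
    bp <- list()
    for (tr in seq_len(nTrees)) {
      chbt <- runif(1, 0.6, 1)
      root <- c(runif(1, -half / 2, half / 2), -half)
      grow <- function(p, ang, len, depth, dia) {
        q <- p + len * c(sin(ang), cos(ang))
        q <- pmin(pmax(q, -W / 2 + 0.02 * W), W / 2 - 0.02 * W)
        k <<- k + 1L
        vessels[[k]] <<- list(points = rbind(p, q), diameter = dia,
                              so2 = so2all[tr], chbt = chbt)
        if (depth > 0) {
          bp[[length(bp) + 1L]] <<- q
          da <- runif(2, pi / 9, pi / 4.5)
          grow(q, ang - da[1], len * 0.72, depth - 1L, dia * 0.85)
          grow(q, ang + da[2], len * 0.72, depth - 1L, dia * 0.85)
        }
      }
      grow(root, runif(1, -pi / 12, pi / 12), 0.35 * half, 3L,
           runif(1, diameterRange[1], diameterRange[2]))
    }
    if (length(bp)) branchPoints <- do.call(rbind, bp)
  }
  list(vessels = vessels, branchPoints = branchPoints)
}

#' Generate a synthetic vascular phantom
#'
#' Draws a seeded synthetic vascular scene with exactly known ground
#' truth, standing in for the in vivo targets of endoscopic imaging:
#' smooth centreline curves rasterised as tubes of known diameter, each
#' carrying a per-vessel oxygen saturation (arteries high, veins low) and
#' a relative hemoglobin concentration on a dark background.  Styles
#' emulate the vascular patterns seen in vivo: `"parallel"` (dense
#' longitudinally parallel vessels), `"grid"` (sparse crossing pattern),
#' `"loops"` (capillary hairpin loops) and `"random_tree"` (branching
#' arborisation).  The generating centreline graph, with exact arc
#' lengths, chord lengths, diameters and branch points, is retained as
#' the recovery oracle for the morphometry suite.
#'
#' @param style one of `"parallel"`, `"grid"`, `"loops"`, `"random_tree"`.
#' @param size raster side in pixels (>= 64).
#' @param seed integer; the same seed reproduces the phantom bit-for-bit.
#' @param vesselDensity relative density multiplier (default 1).
#' @param so2Range optional length-2 range overriding the default
#'   arterial (0.95-0.98) / venous (0.60-0.75) assignment.
#' @param diameterRange vessel diameter range in mm.
#' @param pixelSize mm per pixel; default `2 / size` (a 2-mm scene).
#' @param gaussianProfile if TRUE, hemoglobin falls off as a Gaussian
#'   across the tube section instead of the default uniform disk.
#' @return a [VascularPhantom-class] object.
#' @examples
#' ph <- makePhantom("grid", size = 128, seed = 7)
#' truthMetrics(ph)$NBP
#' @export
makePhantom <- function(style = c("parallel", "grid", "loops", "random_tree"),
                        size = 512L, seed = 1L, vesselDensity = 1,
                        so2Range = NULL,
                        diameterRange = c(0.02, 0.06),
                        pixelSize = NULL, gaussianProfile = FALSE) {
  style <- match.arg(style)
  size <- as.integer(size)
  if (size < 64L) stop("size must be >= 64 pixels")
  if (diameterRange[1] <= 0 || diameterRange[2] < diameterRange[1])
    stop("invalid diameterRange")
  if (!is.null(so2Range) &&
      (so2Range[1] < 0 || so2Range[2] > 1 || so2Range[1] > so2Range[2]))
    stop("so2Range must lie within [0, 1]")
  if (is.null(pixelSize)) pixelSize <- 2 / size
  W <- size * pixelSize

  spec <- .withSeed(seed, .vesselSpecs(style, W, vesselDensity,
                                       so2Range, diameterRange))
  vessels <- spec$vessels

  ## rasterise: per-vessel distance-to-centreline via a distance map
  so2Map <- matrix(0, size, size)
  chbtMap <- matrix(0, size, size)
  bestNorm <- matrix(Inf, size, size)
  for (v in vessels) {
    pts <- .resamplePolyline(v$points, 0.4 * pixelSize)
    ij <- .binIndices(pmin(pmax(pts[, 1], -W / 2), W / 2 - 1e-9),
                      pmin(pmax(pts[, 2], -W / 2 + 1e-9), W / 2),
                      c(size, size), pixelSize, what = "centreline point")
    m <- matrix(1, size, size)
    m[cbind(ij$row, ij$col)] <- 0
    D <- as.matrix(EBImage::distmap(m)) * pixelSize   # mm to centreline
    rad <- v$diameter / 2
    hit <- D <= rad & D / rad < bestNorm
    if (any(hit)) {
      bestNorm[hit] <- (D / rad)[hit]
      so2Map[hit] <- v$so2
      chbtMap[hit] <- if (gaussianProfile)
        v$chbt * exp(-2 * (D[hit] / rad)^2) else v$chbt
    }
  }
  if (mean(chbtMap > 0) > 0.9)
    stop("vessel density too high: vessels cover more than 90% of pixels, ",
         "the phantom cannot be meaningfully skeletonised")

  ext <- hemoglobinExtinction()
  muA <- array(0, dim = c(size, size, 2),
               dimnames = list(NULL, NULL, c("532", "558")))
  muA[, , "532"] <- forwardAbsorption(so2Map, chbtMap, ext, 532)
  muA[, , "558"] <- forwardAbsorption(so2Map, chbtMap, ext, 558)

  ## ground-truth graph
  nodes <- data.frame(x = numeric(0), y = numeric(0),
                      type = character(0), stringsAsFactors = FALSE)
  segments <- list()
  for (v in vessels) {
    pts <- .resamplePolyline(v$points, 0.25 * pixelSize)
    segments[[length(segments) + 1L]] <- list(
      points = pts,
      arcLength = .polyArcLength(pts),
      chordLength = .chord(pts),
      diameters = rep(v$diameter, nrow(pts)))
    nodes <- rbind(nodes,
                   data.frame(x = pts[c(1, nrow(pts)), 1],
                              y = pts[c(1, nrow(pts)), 2],
                              type = "endpoint", stringsAsFactors = FALSE))
  }
  if (!is.null(spec$branchPoints))
    nodes <- rbind(nodes,
                   data.frame(x = spec$branchPoints[, 1],
                              y = spec$branchPoints[, 2],
                              type = "branchpoint", stringsAsFactors = FALSE))
  tg <- new("VesselGraph", nodes = nodes, segments = segments,
            pixelSize = NA_real_)

  new("VascularPhantom", truthGraph = tg, so2Map = so2Map,
      chbtMap = chbtMap, muA = muA, pixelSize = pixelSize,
      style = style, rngSeed = as.integer(seed))
}

#' Exact morphometrics of a phantom's ground truth
#'
#' Computes VL, NBP, MVD and VT directly from the generating centreline
#' graph (no imaging, no skeletonisation); these serve as the recovery
#' oracle for [computeMetrics()] run on reconstructed images.
#'
#' @param phantom a [VascularPhantom-class] object (or a
#'   [VesselGraph-class]).
#' @return list with components `VL` (mm), `NBP`, `MVD` (mm), `VT`.
#' @export
truthMetrics <- function(phantom) {
  g <- if (is(phantom, "VascularPhantom")) phantom@truthGraph else phantom
  stopifnot(is(g, "VesselGraph"))
  arcs <- vapply(g@segments, function(s) s$arcLength, 0)
  chords <- vapply(g@segments, function(s) s$chordLength, 0)
  dia <- unlist(lapply(g@segments, function(s) s$diameters))
  ok <- chords > 0
  list(VL = sum(arcs),
       NBP = sum(g@nodes$type == "branchpoint"),
       MVD = mean(dia),
       VT = if (any(ok)) mean(arcs[ok] / chords[ok]) else NA_real_)
}

## ---- accessors & show -----------------------------------------------

#' @rdname accessors
#' @export
setMethod("truthGraph", "VascularPhantom", function(object) object@truthGraph)

#' @rdname accessors
#' @export
setMethod("so2Map", "VascularPhantom", function(object) object@so2Map)

#' @rdname accessors
#' @export
setMethod("chbtMap", "VascularPhantom", function(object) object@chbtMap)

#' @rdname accessors
#' @export
setMethod("absorptionMap", "VascularPhantom",
          function(object, wavelength) object@muA[, , as.character(wavelength)])

#' @rdname accessors
#' @export
setMethod("vesselMask", "VascularPhantom",
          function(object) object@chbtMap > 0)

#' @rdname accessors
#' @export
setMethod("pixelSize", "VascularPhantom", function(object) object@pixelSize)

setMethod("show", "VascularPhantom", function(object) {
  d <- dim(object@so2Map)
  cat(sprintf(
    "VascularPhantom '%s': %dx%d px (%.4g mm/px), %d vessels, %.1f%% vessel pixels, seed %d\n",
    object@style, d[1], d[2], object@pixelSize,
    length(object@truthGraph@segments), 100 * mean(object@chbtMap > 0),
    object@rngSeed))
})
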
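## Neighbour shifts in the Zhang-Suen order P2..P9 (N, NE, E, SE, S, SW,
## W, NW) for a matrix whose row 1 is the image top.
.zsOffsets <- list(c(1, 0), c(1, -1), c(0, -1), c(-1, -1),
                   c(-1, 0), c(-1, 1), c(0, 1), c(1, 1))

.neighbourStack <- function(B) {
  lapply(.zsOffsets, function(o) .shiftMat(B, o[1], o[2], FALSE))
}

## Rutovitz crossing number: 0->1 transitions around each pixel.  A
## through-path pixel scores 2 regardless of staircase geometry, an end
## pixel 1, a branch pixel >= 3 — unlike the raw neighbour count, which
## over-reports at diagonal staircases.
.crossingNumber <- function(sk) {
  P <- .neighbourStack(sk)
  Reduce(`+`, lapply(1:8, function(k) {
    (!P[[k]]) & P[[if (k == 8) 1 else k + 1]]
  }))
}

## Topology-preserving thinning (Zhang & Suen 1984), vectorised over the
## whole raster; returns a 1-px-wide skeleton with the mask's topology.
.thinMask <- function(mask) {
  B <- mask
  repeat {
    changedAny <- FALSE
    for (pass in 1:2) {
      P <- .neighbourStack(B)
      nb <- Reduce(`+`, P)
      ## number of 0->1 transitions around the pixel
      A <- Reduce(`+`, lapply(1:8, function(k) {
        (!P[[k]]) & P[[if (k == 8) 1 else k + 1]]
      }))
      if (pass == 1)
        cond <- !(P[[1]] & P[[3]] & P[[5]]) & !(P[[3]] & P[[5]] & P[[7]])
      else
        cond <- !(P[[1]] & P[[3]] & P[[7]]) & !(P[[1]] & P[[5]] & P[[7]])
      del <- B & nb >= 2 & nb <= 6 & A == 1 & cond
      if (any(del)) {
        B[del] <- FALSE
        changedAny <- TRUE
      }
    }
    if (!changedAny) break
  }
  B
}

## 8-connected labelling of a sparse logical matrix (used for branch-
## pixel clusters; cluster sizes are tiny so simple propagation is fine).
.label8 <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  lab[mask] <- seq_len(sum(mask))
  repeat {
    new <- lab
    for (o in .zsOffsets) {
      s <- .shiftMat(lab, o[1], o[2], 0L)
      upd <- mask & s > 0L & (new == 0L | s < new)
      new[upd] <- s[upd]
    }
    if (identical(new, lab)) break
    lab <- new
  }
  lab
}

## Remove terminal spurs: endpoint chains shorter than maxLen px that
## run into a branch pixel.  Such spurs are thinning artifacts thrown
## off by boundary bumps of the mask, not vessel branches.
.pruneSpurs <- function(sk, maxLen) {
  nr <- nrow(sk); nc <- ncol(sk)
  repeat {
    cross <- .crossingNumber(sk); cross[!sk] <- 0L
    nb <- Reduce(`+`, .neighbourStack(sk))
    eps <- which(sk & cross == 1 & nb >= 1, arr.ind = TRUE)
    removed <- FALSE
    if (nrow(eps)) for (q in seq_len(nrow(eps))) {
      path <- eps[q, , drop = FALSE]
      prev <- c(-1L, -1L); cur <- eps[q, ]
      hitBranch <- FALSE
      while (nrow(path) <= maxLen) {
        nbs <- NULL
        for (o in .zsOffsets) {
          ii <- cur[1] - o[1]; jj <- cur[2] - o[2]
          if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc && sk[ii, jj] &&
              !(ii == prev[1] && jj == prev[2]))
            nbs <- rbind(nbs, c(ii, jj))
        }
        if (is.null(nbs) || nrow(nbs) != 1) { hitBranch <- !is.null(nbs); break }
        nxt <- nbs[1, ]
        if (cross[nxt[1], nxt[2]] >= 3) { hitBranch <- TRUE; break }
        path <- rbind(path, nxt)
        prev <- cur; cur <- nxt
      }
      if (hitBranch && nrow(path) <= maxLen) {
        sk[path] <- FALSE
        removed <- TRUE
      }
    }
    if (!removed) break
  }
  sk
}

## Light smoothing of a pixel chain before measuring its arc length:
## moving average (window 5) with fixed endpoints, which removes most of
## the chain-code staircase bias on smooth curves.
.smoothChain <- function(pts) {
  n <- nrow(pts)
  if (n < 5) return(pts)
  sm <- pts
  f <- stats::filter(pts, rep(1 / 5, 5), sides = 2)
  mid <- 3:(n - 2)
  sm[mid, ] <- f[mid, ]
  sm
}

## Per-point vessel diameter by marching along the local normal until the
## mask is left on both sides (the literal normal-line definition; used
## for validation, the distance-transform route is the default).
.normalDiameters <- function(chain, mask) {
  n <- nrow(chain)
  out <- numeric(n)
  inMask <- function(p) {
    i <- round(p[1]); j <- round(p[2])
    i >= 1 && i <= nrow(mask) && j >= 1 && j <= ncol(mask) && mask[i, j]
  }
  for (k in seq_len(n)) {
    a <- chain[max(1, k - 2), ]; b <- chain[min(n, k + 2), ]
    tg <- b - a
    if (all(tg == 0)) { out[k] <- NA_real_; next }
    tg <- tg / sqrt(sum(tg^2))
    nv <- c(-tg[2], tg[1])
    march <- function(dir) {
      s <- 0
      while (inMask(chain[k, ] + (s + 0.25) * dir) && s < 1e3) s <- s + 0.25
      s
    }
    out[k] <- march(nv) + march(-nv) + 1  # + centre pixel
  }
  out
}

#' Skeletonise a vessel mask and trace its graph
#'
#' Thins the binary mask to a one-pixel-wide, topology-preserving
#' skeleton (Zhang-Suen thinning), classifies skeleton pixels by their
#' 8-neighbourhood degree (endpoints: 1; branch pixels: >= 3, merged
#' into branch-point clusters), traces the ordered pixel chains between
#' nodes, and attaches per-point diameters — by default twice the
#' Euclidean distance transform of the mask at the skeleton point
#' (equivalent to the normal-line definition for locally straight tubes
#' and far more robust; `diameterMethod = "normal"` marches the literal
#' normal rays instead).
#'
#' @param mask logical (or 0/1) matrix, the segmented vessel raster.
#' @param pixelSize mm per pixel.
#' @param diameterMethod `"distmap"` (default) or `"normal"`.
#' @param pruneLength terminal spurs up to this many skeleton pixels long
#'   (thinning artifacts of boundary roughness) are removed before the
#'   graph is traced; 0 disables pruning.
#' @return a [VesselGraph-class] object; node and segment coordinates
#'   are in FOV-centred mm.
#' @seealso [segmentVessels()], [computeMetrics()]
#' @export
skeletonizeGraph <- function(mask, pixelSize = 1,
                             diameterMethod = c("distmap", "normal"),
                             pruneLength = 10L) {
  diameterMethod <- match.arg(diameterMethod)
  mask <- mask > 0
  if (!any(mask)) stop("empty mask")
  sk <- .thinMask(mask)
  if (pruneLength > 0) sk <- .pruneSpurs(sk, as.integer(pruneLength))
  nr <- nrow(sk); nc <- ncol(sk)
  toXY <- function(ij) cbind((ij[, 2] - 0.5) * pixelSize - nc * pixelSize / 2,
                             nr * pixelSize / 2 - (ij[, 1] - 0.5) * pixelSize)
  nb <- Reduce(`+`, .neighbourStack(sk))
  nb[!sk] <- 0L
  cross <- .crossingNumber(sk)
  cross[!sk] <- 0L
  Dm <- as.matrix(EBImage::distmap(mask + 0))
  ## boundary (half-pixel) correction: the distance transform measures
  ## centre-to-centre, but the mask edge lies half a pixel before the
  ## first background centre on either side
  diaAt <- function(chain) {
    if (diameterMethod == "distmap") (2 * Dm[chain] - 1) * pixelSize
    else .normalDiameters(chain, mask) * pixelSize
  }

  endpoint <- sk & cross == 1 & nb >= 1
  branch <- sk & cross >= 3
  isolated <- sk & nb == 0
  isNode <- endpoint | branch | isolated
  blab <- .label8(branch)

  nodes <- data.frame(x = numeric(0), y = numeric(0), type = character(0),
                      stringsAsFactors = FALSE)
  if (any(endpoint)) {
    ij <- which(endpoint, arr.ind = TRUE)
    xy <- toXY(ij)
    nodes <- rbind(nodes, data.frame(x = xy[, 1], y = xy[, 2],
                                     type = "endpoint"))
  }
  for (l in setdiff(unique(as.vector(blab)), 0L)) {
    ij <- which(blab == l, arr.ind = TRUE)
    xy <- toXY(ij)
    nodes <- rbind(nodes, data.frame(x = mean(xy[, 1]), y = mean(xy[, 2]),
                                     type = "branchpoint"))
  }
  if (any(isolated)) {
    ij <- which(isolated, arr.ind = TRUE)
    xy <- toXY(ij)
    nodes <- rbind(nodes, data.frame(x = xy[, 1], y = xy[, 2],
                                     type = "isolated"))
  }

  walkOffsets <- .zsOffsets[c(1, 3, 5, 7, 2, 4, 6, 8)]
  nbrOf <- function(i, j) {
    out <- NULL
    for (o in walkOffsets) {
      ii <- i - o[1]; jj <- j - o[2]
      if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc && sk[ii, jj])
        out <- rbind(out, c(ii, jj))
    }
    out
  }

  visited <- matrix(FALSE, nr, nc)   # regular pixels consumed by a trace
  edgeSeen <- character(0)           # direct node-node adjacencies
  segments <- list()
  addSegment <- function(chain) {
    chmm <- toXY(chain)
    smm <- .smoothChain(chmm)
    d <- diaAt(chain)
    ## diameters inside a bifurcation zone reflect the union of the
    ## merging tubes, not any one vessel: blank them out to the local
    ## radius around branch-cluster chain ends
    n <- nrow(chain)
    for (endRow in c(1L, n)) {
      if (branch[chain[endRow, 1], chain[endRow, 2]]) {
        k <- min(ceiling(Dm[chain[endRow, , drop = FALSE]]),
                 max(0L, n - 2L))
        if (k > 0) {
          idx <- if (endRow == 1L) seq_len(k) else n - seq_len(k) + 1L
          d[idx] <- NA_real_
        }
      }
    }
    segments[[length(segments) + 1L]] <<- list(
      points = chmm,
      arcLength = .polyArcLength(smm),
      chordLength = .chord(chmm),
      diameters = d)
  }

  nodeIdx <- which(isNode & !isolated, arr.ind = TRUE)
  for (q in seq_len(nrow(nodeIdx))) {
    i0 <- nodeIdx[q, 1]; j0 <- nodeIdx[q, 2]
    nbs <- nbrOf(i0, j0)
    for (b in seq_len(nrow(nbs))) {
      i <- nbs[b, 1]; j <- nbs[b, 2]
      if (isNode[i, j]) {
        ## direct node-node contact: keep once, skip contacts inside one
        ## branch cluster
        if (branch[i0, j0] && branch[i, j] &&
            blab[i0, j0] == blab[i, j]) next
        key <- paste(sort(c(i0 * nc + j0, i * nc + j)), collapse = "-")
        if (key %in% edgeSeen) next
        edgeSeen <- c(edgeSeen, key)
        addSegment(rbind(c(i0, j0), c(i, j)))
        next
      }
      if (visited[i, j]) next
      chain <- rbind(c(i0, j0), c(i, j))
      visited[i, j] <- TRUE
      prev <- c(i0, j0); cur <- c(i, j)
      repeat {
        cand <- nbrOf(cur[1], cur[2])
        cand <- cand[!(cand[, 1] == prev[1] & cand[, 2] == prev[2]), ,
                     drop = FALSE]
        if (nrow(cand) > 1) {
          ## prefer a node ending; otherwise an unvisited regular pixel
          nd <- cand[isNode[cand], , drop = FALSE]
          cand <- if (nrow(nd)) nd[1, , drop = FALSE]
                  else cand[!visited[cand], , drop = FALSE]
        }
        if (nrow(cand) == 0) break
        nxt <- cand[1, ]
        chain <- rbind(chain, nxt)
        if (isNode[nxt[1], nxt[2]]) break
        if (visited[nxt[1], nxt[2]]) break
        visited[nxt[1], nxt[2]] <- TRUE
        prev <- cur; cur <- nxt
      }
      addSegment(chain)
    }
  }

  ## closed loops with no node pixel: every pixel has degree 2
  left <- sk & !isNode & !visited
  while (any(left)) {
    start <- which(left, arr.ind = TRUE)[1, , drop = FALSE]
    chain <- start
    visited[start] <- TRUE; left[start] <- FALSE
    prev <- c(-1L, -1L); cur <- start[1, ]
    repeat {
      cand <- nbrOf(cur[1], cur[2])
      cand <- cand[!(cand[, 1] == prev[1] & cand[, 2] == prev[2]), ,
                   drop = FALSE]
      cand <- cand[!visited[cand] | FALSE, , drop = FALSE]
      if (nrow(cand) == 0) break
      nxt <- cand[1, ]
      chain <- rbind(chain, nxt)
      visited[nxt[1], nxt[2]] <- TRUE; left[nxt[1], nxt[2]] <- FALSE
      prev <- cur; cur <- nxt
    }
    chain <- rbind(chain, chain[1, ])  # close the loop
    addSegment(chain)
  }

  new("VesselGraph", nodes = nodes, segments = segments,
      pixelSize = pixelSize)
}

#' @rdname accessors
#' @export
setMethod("graphNodes", "VesselGraph", function(object) object@nodes)

#' @rdname accessors
#' @export
setMethod("vesselSegments", "VesselGraph", function(object) object@segments)

#' @rdname accessors
#' @export
setMethod("pixelSize", "VesselGraph", function(object) object@pixelSize)

setMethod("show", "VesselGraph", function(object) {
  cat(sprintf("VesselGraph: %d segments; nodes: %s\n",
              length(object@segments),
              paste(sprintf("%s=%d", names(table(object@nodes$type)),
                            table(object@nodes$type)), collapse = ", ")))
})
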
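#' Construct spiral scan parameters
#'
#' Builds a validated [SpiralParams-class] object.  Defaults follow the
#' reference operating point of the scanner: a 2-mm circular field of
#' view scanned with a 200-kHz pulsed laser at 6 volumes per second,
#' i.e. 33,332 pulses per frame (the nearest even budget to
#' 200 kHz / 6 Hz), with 16 spiral revolutions per one-way pass.
#'
#' @param pattern `"AS"` (Archimedes, r = a*theta), `"FS"` (Fermat,
#'   r = a*sqrt(theta)) or `"AFS"` (compound Archimedes-Fermat).
#' @param fovDiameter field-of-view diameter in mm.
#' @param nPoints even integer, laser pulses per frame.
#' @param nTurns integer, spiral revolutions per one-way pass.
#' @param prf laser pulse repetition frequency in Hz.
#' @param startPhase angular phase of the first pulse (rad).
#' @param composition for `"AFS"`: `"as_out_fs_in"` joins an AS outward
#'   pass to an FS inward pass (one continuous out-and-back frame, no
#'   flyback); `"as_roundtrip_fs_roundtrip"` runs full AS and FS round
#'   trips back to back (four passes).
#' @param passOffset angular offset (rad) accrued by each return pass so
#'   its turns fall between those of the preceding pass; default half the
#'   inter-turn angle, `pi / nTurns`.
#' @param rngSeed optional integer, carried for provenance.
#' @return a [SpiralParams-class] object.
#' @examples
#' p <- SpiralParams("AFS", nPoints = 8192L, nTurns = 16L)
#' frameRate(p)
#' @export
SpiralParams <- function(pattern = c("AS", "FS", "AFS"),
                         fovDiameter = 2,
                         nPoints = 33332L,
                         nTurns = 16L,
                         prf = 2e5,
                         startPhase = 0,
                         composition = c("as_out_fs_in",
                                         "as_roundtrip_fs_roundtrip"),
                         passOffset = NULL,
                         rngSeed = NA_integer_) {
  pattern <- match.arg(pattern)
  composition <- match.arg(composition)
  if (is.null(passOffset)) passOffset <- pi / nTurns
  new("SpiralParams", pattern = pattern, fovDiameter = fovDiameter,
      nPoints = as.integer(nPoints), nTurns = as.integer(nTurns),
      prf = prf, startPhase = startPhase, composition = composition,
      passOffset = passOffset, rngSeed = as.integer(rngSeed))
}

#' Frame rate and frame period
#'
#' The frame rate is derived exactly from the pulse budget:
#' `prf / nPoints` (Hz); the frame period is its reciprocal.
#'
#' @param params a [SpiralParams-class] object.
#' @return frame rate in Hz / frame period in s.
#' @export
frameRate <- function(params) params@prf / params@nPoints

#' @rdname frameRate
#' @export
framePeriod <- function(params) params@nPoints / params@prf

## Radial profile of one pass as a function of local unwrapped angle
## thetaLoc in [0, Theta].  a is chosen so r reaches R at the pass end.
.passRadius <- function(label, thetaLoc, Theta, R) {
  switch(label,
    AS_out = R * thetaLoc / Theta,
    AS_in  = R * (Theta - thetaLoc) / Theta,
    FS_out = R * sqrt(thetaLoc / Theta),
    FS_in  = R * sqrt((Theta - thetaLoc) / Theta),
    stop("unknown pass label: ", label))
}

.passPlan <- function(params) {
  switch(params@pattern,
    AS  = c("AS_out", "AS_in"),
    FS  = c("FS_out", "FS_in"),
    AFS = if (params@composition == "as_out_fs_in")
            c("AS_out", "FS_in")
          else c("AS_out", "AS_in", "FS_out", "FS_in"))
}

#' Generate a double-spiral scan trajectory
#'
#' Synthesises the time-ordered pulse positions of one scan frame under
#' constant angular velocity and uniform angular sampling.  Every frame
#' is a sequence of passes, each spanning `nTurns` revolutions and
#' carrying an equal share of the pulse budget: `AS` runs an Archimedes
#' spiral out to the FOV edge and back, `FS` a Fermat spiral out and
#' back, and `AFS` (default composition) joins an Archimedes outward pass
#' to a Fermat inward pass at the FOV edge so that the frame is one
#' continuous out-and-back sweep with no flyback.
#'
#' The unwrapped angle advances monotonically through all passes (the
#' resonant-scanning constraint); each return pass additionally accrues
#' the configured `passOffset` linearly over its course, so the trajectory
#' stays continuous at pass junctions while the return turns fall
#' angularly between the outgoing ones.
#'
#' @param params a [SpiralParams-class] object.
#' @return a [ScanTrajectory-class] object.
#' @examples
#' tr <- makeTrajectory(SpiralParams("AS", nPoints = 4096L))
#' mean(radii(tr) <= fovDiameter(tr) / 32)  # ~ 1/16: centre oversampling
#' @seealso [makeArchimedes()], [makeFermat()], [makeCompound()],
#'   [drivingWaveforms()]
#' @export
makeTrajectory <- function(params) {
  stopifnot(is(params, "SpiralParams"))
  validObject(params)
  plan <- .passPlan(params)
  nPass <- length(plan)
  n <- params@nPoints
  m <- n %/% nPass
  R <- params@fovDiameter / 2
  Theta <- 2 * pi * params@nTurns

  theta <- numeric(0); r <- numeric(0); segment <- character(0)
  for (k in seq_along(plan)) {
    theta0 <- (k - 1) * Theta
    if (k == 1) {
      ## first pass includes both endpoints: r = 0 at the first pulse,
      ## r = R at the last
      thLoc <- seq(0, Theta, length.out = m)
    } else {
      thLoc <- seq_len(m) * (Theta / m)
    }
    theta <- c(theta, theta0 + thLoc)
    r <- c(r, .passRadius(plan[k], thLoc, Theta, R))
    segment <- c(segment, rep(plan[k], m))
  }
  ## interleaving offset, accrued linearly past the first pass so the
  ## position stays continuous at every junction
  offset <- params@passOffset * pmax(0, theta - Theta) / Theta
  phi <- theta + offset + params@startPhase
  t <- (seq_len(n) - 1) / params@prf
  new("ScanTrajectory", params = params, t = t,
      x = r * cos(phi), y = r * sin(phi),
      r = r, theta = phi, segment = segment)
}

#' @rdname makeTrajectory
#' @param ... passed to [SpiralParams()] when `params` is missing.
#' @export
makeArchimedes <- function(params = SpiralParams("AS", ...), ...) {
  if (params@pattern != "AS") stop("params@pattern must be 'AS'")
  makeTrajectory(params)
}

#' @rdname makeTrajectory
#' @export
makeFermat <- function(params = SpiralParams("FS", ...), ...) {
  if (params@pattern != "FS") stop("params@pattern must be 'FS'")
  makeTrajectory(params)
}

#' @rdname makeTrajectory
#' @export
makeCompound <- function(params = SpiralParams("AFS", ...), ...) {
  if (params@pattern != "AFS") stop("params@pattern must be 'AFS'")
  makeTrajectory(params)
}

#' Reverse a trajectory in time
#'
#' Returns the same spatial path traversed in the opposite order, with
#' times re-issued forward from zero at the original pulse spacing.
#' Reversing twice restores the original trajectory.
#'
#' @param traj a [ScanTrajectory-class] object.
#' @return a [ScanTrajectory-class] object.
#' @export
reverseTrajectory <- function(traj) {
  i <- rev(seq_along(traj@t))
  new("ScanTrajectory", params = traj@params, t = traj@t,
      x = traj@x[i], y = traj@y[i], r = traj@r[i],
      theta = traj@theta[i], segment = traj@segment[i])
}

## ---- accessors & show -----------------------------------------------

#' @rdname accessors
#' @export
setMethod("spiralParams", "ScanTrajectory", function(object) object@params)

#' @rdname accessors
#' @export
setMethod("radii", "ScanTrajectory", function(object) object@r)

#' @rdname accessors
#' @export
setMethod("segmentLabels", "ScanTrajectory", function(object) object@segment)

#' @rdname accessors
#' @export
setMethod("positions", "ScanTrajectory", function(object)
  data.frame(t = object@t, x = object@x, y = object@y,
             r = object@r, theta = object@theta,
             segment = object@segment))

#' Field-of-view diameter of a trajectory or its parameters
#' @param object a [SpiralParams-class] or [ScanTrajectory-class] object.
#' @return numeric, mm.
#' @export
fovDiameter <- function(object) {
  if (is(object, "ScanTrajectory")) object <- object@params
  object@fovDiameter
}

#' Number of pulses in a trajectory or parameter set
#' @param object a [SpiralParams-class] or [ScanTrajectory-class] object.
#' @return integer.
#' @export
numPoints <- function(object) {
  if (is(object, "ScanTrajectory")) object <- object@params
  object@nPoints
}

setMethod("show", "SpiralParams", function(object) {
  cat(sprintf(
    "SpiralParams: %s | FOV %.3g mm | %d pulses, %d turns/pass | PRF %.4g Hz -> %.3g Hz frame rate\n",
    object@pattern, object@fovDiameter, object@nPoints, object@nTurns,
    object@prf, object@prf / object@nPoints))
  if (object@pattern == "AFS")
    cat(sprintf("  composition: %s, pass offset %.4g rad\n",
                object@composition, object@passOffset))
})

setMethod("show", "ScanTrajectory", function(object) {
  cat(sprintf("ScanTrajectory (%s): %d pulses over %.4g s, max radius %.4g mm\n",
              object@params@pattern, length(object@t),
              framePeriod(object@params), max(object@r)))
  tab <- table(object@segment)
  cat("  passes:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
})
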
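#' Mirror driving waveforms of a trajectory
#'
#' Returns the x and y position command series sampled at the pulse
#' repetition frequency (what a resonant MEMS mirror would be driven
#' with), together with a smoothness report at every pass junction: the
#' Euclidean first difference across the junction and its ratio to the
#' median within-pass first difference.  A ratio near 1 means the
#' waveforms of consecutive passes align smoothly, the property that
#' allows Archimedes and Fermat passes to be joined into one continuous
#' compound sweep.
#'
#' @param traj a [ScanTrajectory-class] object.
#' @return a list with components `t`, `x`, `y` (numeric vectors) and
#'   `junctions`, a data.frame with one row per pass junction
#'   (`index`, `from`, `to`, `jump`, `medianStep`, `ratio`).
#' @examples
#' wf <- drivingWaveforms(makeTrajectory(SpiralParams("AFS", nPoints = 8192L)))
#' wf$junctions
#' @export
drivingWaveforms <- function(traj) {
  stopifnot(is(traj, "ScanTrajectory"))
  dx <- diff(traj@x); dy <- diff(traj@y)
  step <- sqrt(dx^2 + dy^2)
  seg <- traj@segment
  cut <- which(seg[-1] != seg[-length(seg)])  # step i crosses a junction
  med <- median(step[setdiff(seq_along(step), cut)])
  junctions <- data.frame(
    index = cut,
    from = seg[cut], to = seg[cut + 1L],
    jump = step[cut],
    medianStep = rep(med, length(cut)),
    ratio = step[cut] / med,
    stringsAsFactors = FALSE)
  list(t = traj@t, x = traj@x, y = traj@y, junctions = junctions)
}
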
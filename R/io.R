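## Raster I/O.  Float TIFF storage is [0, 1]-ranged, so rasters are
## written normalised by their maximum with the scale recorded in a JSON
## sidecar (<path>.json); readers reapply it.

#' Write / read a raster as 32-bit TIFF with a scale sidecar
#'
#' @param m numeric matrix.
#' @param path output `.tif` path; a `<path>.json` sidecar records the
#'   normalisation scale.
#' @return `writeRasterTIFF` returns `path` invisibly; `readRasterTIFF`
#'   the rescaled matrix.
#' @export
writeRasterTIFF <- function(m, path) {
  sc <- max(m, 0)
  tiff::writeTIFF((if (sc > 0) m / sc else m), path,
                  bits.per.sample = 32L, compression = "none")
  jsonlite::write_json(list(scale = sc), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeRasterTIFF
#' @export
readRasterTIFF <- function(path) {
  m <- tiff::readTIFF(path)
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    sc <- jsonlite::read_json(side)$scale
    if (sc > 0) m <- m * sc
  }
  m
}

.paramsToList <- function(p) list(
  pattern = p@pattern, fovDiameter = p@fovDiameter, nPoints = p@nPoints,
  nTurns = p@nTurns, prf = p@prf, startPhase = p@startPhase,
  composition = p@composition, passOffset = p@passOffset,
  rngSeed = if (is.na(p@rngSeed)) NULL else p@rngSeed)

.paramsFromList <- function(l) SpiralParams(
  pattern = l$pattern, fovDiameter = l$fovDiameter,
  nPoints = as.integer(l$nPoints), nTurns = as.integer(l$nTurns),
  prf = l$prf, startPhase = l$startPhase, composition = l$composition,
  passOffset = l$passOffset,
  rngSeed = if (is.null(l$rngSeed)) NA_integer_ else as.integer(l$rngSeed))

#' Trajectory CSV export / import
#'
#' Writes the pulse table (`t_s`, `x_mm`, `y_mm`, `r_mm`, `theta_rad`,
#' `segment`) with a `<path>.json` sidecar holding the generating
#' parameters; `readTrajectoryCSV` reassembles and validates the object.
#'
#' @param traj a [ScanTrajectory-class] object.
#' @param path CSV path.
#' @return the path / the [ScanTrajectory-class] object.
#' @export
writeTrajectoryCSV <- function(traj, path) {
  df <- data.frame(t_s = traj@t, x_mm = traj@x, y_mm = traj@y,
                   r_mm = traj@r, theta_rad = traj@theta,
                   segment = traj@segment)
  write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(.paramsToList(traj@params), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeTrajectoryCSV
#' @export
readTrajectoryCSV <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  p <- .paramsFromList(jsonlite::read_json(paste0(path, ".json"),
                                           simplifyVector = TRUE))
  new("ScanTrajectory", params = p, t = df$t_s, x = df$x_mm, y = df$y_mm,
      r = df$r_mm, theta = df$theta_rad, segment = df$segment)
}

#' Pulse record CSV export / import
#'
#' Columns `t_s`, `x_mm`, `y_mm`, `wavelength_nm`, `amplitude`.
#'
#' @param prs a [PulseRecordSet-class] object.
#' @param path CSV path.
#' @return the path / the [PulseRecordSet-class] object.
#' @export
writePulseRecordsCSV <- function(prs, path) {
  r <- prs@records
  write.csv(data.frame(t_s = r$t, x_mm = r$x, y_mm = r$y,
                       wavelength_nm = r$wavelength, amplitude = r$amplitude),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname writePulseRecordsCSV
#' @export
readPulseRecordsCSV <- function(path) {
  df <- read.csv(path)
  new("PulseRecordSet",
      records = data.frame(t = df$t_s, x = df$x_mm, y = df$y_mm,
                           wavelength = df$wavelength_nm,
                           amplitude = df$amplitude),
      noiseSigma = NA_real_, rngSeed = NA_integer_)
}

#' Rigid transform JSON export / import
#'
#' @param transforms list of [RigidTransform2D-class] objects.
#' @param path JSON path.
#' @return the path / a list of [RigidTransform2D-class] objects.
#' @export
writeTransformsJSON <- function(transforms, path) {
  jsonlite::write_json(lapply(transforms, function(tr)
    list(rotation = tr@rotation, translation = tr@translation)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeTransformsJSON
#' @export
readTransformsJSON <- function(path) {
  lapply(jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE),
         function(l) RigidTransform2D(l$rotation, unlist(l$translation)))
}

#' Save a phantom to a directory
#'
#' Writes a 4-page TIFF (mu_a 532, mu_a 558, sO2, C_HbT; each page
#' max-normalised, scales recorded in the provenance JSON), the ground
#' truth graph as JSON, and a provenance JSON (style, seed, pixel size).
#'
#' @param phantom a [VascularPhantom-class] object.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
writePhantom <- function(phantom, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  chans <- list(mu_a_532 = phantom@muA[, , "532"],
                mu_a_558 = phantom@muA[, , "558"],
                so2 = phantom@so2Map, chbt = phantom@chbtMap)
  scales <- vapply(chans, max, 0)
  pages <- lapply(seq_along(chans), function(i)
    if (scales[i] > 0) chans[[i]] / scales[i] else chans[[i]])
  tiff::writeTIFF(pages, file.path(dir, "phantom.tif"),
                  bits.per.sample = 32L, compression = "none")
  g <- phantom@truthGraph
  jsonlite::write_json(list(
    nodes = g@nodes,
    segments = lapply(g@segments, function(s)
      list(arcLength = s$arcLength, chordLength = s$chordLength,
           meanDiameter = mean(s$diameters)))),
    file.path(dir, "truth_graph.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(list(style = phantom@style, seed = phantom@rngSeed,
                            pixelSize = phantom@pixelSize,
                            pageOrder = names(chans),
                            pageScales = as.list(scales)),
                       file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
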
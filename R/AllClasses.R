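#' @import methods
#' @importFrom stats median mad rnorm runif spline lm coef setNames
#' @importFrom utils read.csv write.csv head tail
NULL

.SPIRAL_PATTERNS <- c("AS", "FS", "AFS")
.COMPOSITIONS <- c("as_out_fs_in", "as_roundtrip_fs_roundtrip")
.SEGMENT_LABELS <- c("AS_out", "AS_in", "FS_out", "FS_in")
.WAVELENGTHS <- c(532, 558)

#' Spiral scan parameters
#'
#' Parameter set describing one frame of a double-spiral resonant scan:
#' the pattern (Archimedes `"AS"`, Fermat `"FS"`, or the compound
#' Archimedes-Fermat `"AFS"`), the circular field of view, the per-frame
#' laser-pulse budget, the number of spiral revolutions per one-way pass,
#' and the laser pulse repetition frequency.  The frame rate is derived
#' as `prf / nPoints` and is not stored.
#'
#' @slot pattern character, one of `"AS"`, `"FS"`, `"AFS"`.
#' @slot fovDiameter numeric, field-of-view diameter in mm.
#' @slot nPoints integer, laser pulses per frame (even; the frame is split
#'   into equal passes).
#' @slot nTurns integer, spiral revolutions per one-way pass.
#' @slot prf numeric, laser pulse repetition frequency in Hz.
#' @slot startPhase numeric, angular phase of the first pulse in rad.
#' @slot composition character, how the compound pattern assembles its
#'   passes: `"as_out_fs_in"` (default, one out-and-back frame) or
#'   `"as_roundtrip_fs_roundtrip"` (four passes per frame).
#' @slot passOffset numeric, angular offset (rad) accrued by each return
#'   pass so that its turns interleave with the preceding pass.
#' @slot rngSeed integer or NA; carried for provenance only (trajectory
#'   synthesis is deterministic).
#' @exportClass SpiralParams
setClass("SpiralParams",
  representation(
    pattern = "character",
    fovDiameter = "numeric",
    nPoints = "integer",
    nTurns = "integer",
    prf = "numeric",
    startPhase = "numeric",
    composition = "character",
    passOffset = "numeric",
    rngSeed = "integer"
  )
)

setValidity("SpiralParams", function(object) {
  msg <- character()
  if (!object@pattern %in% .SPIRAL_PATTERNS)
    msg <- c(msg, sprintf("pattern must be one of %s",
                          paste(.SPIRAL_PATTERNS, collapse = ", ")))
  if (object@fovDiameter <= 0) msg <- c(msg, "fovDiameter must be > 0")
  if (object@nPoints < 2L) msg <- c(msg, "nPoints must be >= 2")
  if (object@nPoints %% 2L != 0L)
    msg <- c(msg, "nPoints must be even: a double spiral splits its pulses equally between passes")
  if (object@nTurns < 1L) msg <- c(msg, "nTurns must be >= 1")
  if (object@prf <= 0) msg <- c(msg, "prf must be > 0")
  if (!object@composition %in% .COMPOSITIONS)
    msg <- c(msg, sprintf("composition must be one of %s",
                          paste(.COMPOSITIONS, collapse = ", ")))
  if (object@composition == "as_roundtrip_fs_roundtrip" &&
      object@nPoints %% 4L != 0L)
    msg <- c(msg, "nPoints must be divisible by 4 for the four-pass composition")
  if (length(msg)) msg else TRUE
})

#' Time-ordered scan trajectory
#'
#' Planar sample positions of one scan frame, pulse by pulse.  Times are
#' spaced exactly `1/prf`; `theta` is the unwrapped position angle so that
#' its increments are constant in magnitude within each pass (constant
#' angular velocity); `segment` labels each pulse with its pass
#' (`AS_out`, `AS_in`, `FS_out`, `FS_in`).
#'
#' @slot params the generating [SpiralParams-class].
#' @slot t numeric, pulse times in s (starting at 0).
#' @slot x,y numeric, FOV-centred Cartesian positions in mm.
#' @slot r numeric, radius in mm.
#' @slot theta numeric, unwrapped position angle in rad.
#' @slot segment character, pass label per pulse.
#' @exportClass ScanTrajectory
setClass("ScanTrajectory",
  representation(
    params = "SpiralParams",
    t = "numeric", x = "numeric", y = "numeric",
    r = "numeric", theta = "numeric",
    segment = "character"
  )
)

setValidity("ScanTrajectory", function(object) {
  msg <- character()
  n <- object@params@nPoints
  lens <- c(length(object@t), length(object@x), length(object@y),
            length(object@r), length(object@theta), length(object@segment))
  if (any(lens != n))
    msg <- c(msg, "all trajectory arrays must have length params@nPoints")
  if (!all(object@segment %in% .SEGMENT_LABELS))
    msg <- c(msg, "unknown segment label")
  R <- object@params@fovDiameter / 2
  if (length(object@r) && max(object@r) > R + 1e-9)
    msg <- c(msg, "radius exceeds fovDiameter/2")
  if (n >= 2) {
    dt <- diff(object@t)
    if (any(abs(dt - 1 / object@params@prf) > 1e-6 / object@params@prf))
      msg <- c(msg, "t must increase with spacing exactly 1/prf")
    step <- sqrt(diff(object@x)^2 + diff(object@y)^2)
    ## steps touching the central 1% radius are exempt: a Fermat pass
    ## necessarily takes one longer radial hop into/out of the centre
    inner <- pmin(head(object@r, -1), tail(object@r, -1)) < R / 100
    if (any(!inner) && max(step[!inner]) > 4 * median(step) + 1e-12)
      msg <- c(msg, "trajectory not continuous: a step exceeds 4x the median step")
  }
  if (length(msg)) msg else TRUE
})

#' Per-pixel sampling density and energy factor
#'
#' Pulse counts of a trajectory binned onto a reconstruction grid, plus
#' the derived energy factor `log10(counts + 1)` normalised by its grid
#' maximum, a proxy for local laser-energy deposition (range \[0, 1\],
#' exactly 0 where no pulse landed).
#'
#' @slot counts integer matrix of pulses per pixel (row = y from the top,
#'   column = x; the grid is FOV-centred).
#' @slot energyFactor numeric matrix in \[0, 1\].
#' @slot pixelSize numeric, pixel edge length in mm.
#' @exportClass SamplingDensityMap
setClass("SamplingDensityMap",
  representation(counts = "matrix", energyFactor = "matrix",
                 pixelSize = "numeric")
)

setValidity("SamplingDensityMap", function(object) {
  msg <- character()
  if (any(object@counts < 0)) msg <- c(msg, "counts must be non-negative")
  ef <- object@energyFactor
  if (any(ef < -1e-12) || any(ef > 1 + 1e-12))
    msg <- c(msg, "energyFactor must lie in [0, 1]")
  if (any((object@counts == 0) != (ef == 0)))
    msg <- c(msg, "energyFactor must be zero exactly where counts are zero")
  if (object@pixelSize <= 0) msg <- c(msg, "pixelSize must be > 0")
  if (length(msg)) msg else TRUE
})

#' Vessel centreline graph
#'
#' Skeleton (or ground-truth centreline) geometry of a vascular network:
#' typed nodes (endpoints, branch points, isolated points) and ordered
#' point chains between nodes, each carrying its arc length, chord length
#' and per-point diameters.  Coordinates are in mm.
#'
#' @slot nodes data.frame with columns `x`, `y` (mm) and `type`
#'   (`"endpoint"`, `"branchpoint"`, `"isolated"`).
#' @slot segments list; each element a list with `points` (n x 2 matrix,
#'   mm), `arcLength` (mm), `chordLength` (mm), `diameters` (numeric, mm).
#' @slot pixelSize numeric, mm per pixel of the raster the graph was
#'   traced from (NA for analytic ground truth).
#' @exportClass VesselGraph
setClass("VesselGraph",
  representation(nodes = "data.frame", segments = "list",
                 pixelSize = "numeric")
)

setValidity("VesselGraph", function(object) {
  msg <- character()
  if (!all(c("x", "y", "type") %in% names(object@nodes)))
    msg <- c(msg, "nodes must have columns x, y, type")
  for (s in object@segments) {
    if (s$arcLength < s$chordLength - 1e-9)
      msg <- c(msg, "segment arc length must be >= chord length")
  }
  if (length(msg)) msg else TRUE
})

#' Synthetic vascular phantom with known ground truth
#'
#' A seeded, fully synthetic stand-in for an in vivo vascular scene: the
#' generating centreline graph (exact arc/chord lengths, diameters),
#' per-pixel oxygen saturation and relative total-hemoglobin rasters, and
#' the implied dual-wavelength absorption rasters
#' `mu_a(lambda) = (eps_HbO2(lambda) sO2 + eps_Hb(lambda) (1 - sO2)) C_HbT`
#' on a dark (zero-hemoglobin) background.
#'
#' @slot truthGraph [VesselGraph-class] ground truth (mm coordinates).
#' @slot so2Map numeric matrix in \[0, 1\] (0 on background).
#' @slot chbtMap numeric matrix >= 0, relative hemoglobin concentration.
#' @slot muA 3-d array (rows, cols, 2) with absorption rasters at 532 and
#'   558 nm in relative units; `dimnames[[3]] = c("532","558")`.
#' @slot pixelSize numeric, mm per pixel.
#' @slot style character, generator style.
#' @slot rngSeed integer seed that reproduces the phantom bit-for-bit.
#' @exportClass VascularPhantom
setClass("VascularPhantom",
  representation(truthGraph = "VesselGraph",
                 so2Map = "matrix", chbtMap = "matrix", muA = "array",
                 pixelSize = "numeric", style = "character",
                 rngSeed = "integer")
)

setValidity("VascularPhantom", function(object) {
  msg <- character()
  if (length(dim(object@muA)) != 3 || dim(object@muA)[3] != 2)
    msg <- c(msg, "muA must be a (rows, cols, 2) array")
  if (any(object@chbtMap < 0)) msg <- c(msg, "chbtMap must be >= 0")
  if (any(object@so2Map < 0 | object@so2Map > 1))
    msg <- c(msg, "so2Map must lie in [0, 1]")
  bg <- object@chbtMap == 0
  if (any(bg)) {
    ij <- which(bg, arr.ind = TRUE)
    if (any(object@muA[cbind(ij, 1L)] != 0) ||
        any(object@muA[cbind(ij, 2L)] != 0))
      msg <- c(msg, "background pixels must have zero absorption")
  }
  if (length(msg)) msg else TRUE
})

#' Per-pulse acquisition records
#'
#' One row per detected laser pulse: firing time, beam position,
#' excitation wavelength and the photoacoustic amplitude sampled from the
#' phantom (plus additive Gaussian noise, clipped at zero).
#'
#' @slot records data.frame with columns `t`, `x`, `y`, `wavelength`,
#'   `amplitude`.
#' @slot noiseSigma numeric, standard deviation of the additive noise.
#' @slot rngSeed integer seed used for the noise draw.
#' @exportClass PulseRecordSet
setClass("PulseRecordSet",
  representation(records = "data.frame", noiseSigma = "numeric",
                 rngSeed = "integer")
)

setValidity("PulseRecordSet", function(object) {
  msg <- character()
  need <- c("t", "x", "y", "wavelength", "amplitude")
  if (!all(need %in% names(object@records)))
    msg <- c(msg, sprintf("records must have columns %s",
                          paste(need, collapse = ", ")))
  else {
    if (any(object@records$amplitude < 0))
      msg <- c(msg, "amplitudes must be non-negative")
    if (!all(object@records$wavelength %in% .WAVELENGTHS))
      msg <- c(msg, "wavelength must be 532 or 558")
  }
  if (length(msg)) msg else TRUE
})

#' Gridded image reconstructed from scattered pulse records
#'
#' @slot pixels numeric matrix of amplitudes (row = y from top).
#' @slot fillMask logical matrix, TRUE where at least one pulse landed.
#' @slot inpainted logical matrix, TRUE where an empty pixel was filled by
#'   scattered interpolation rather than by direct samples.
#' @slot pixelSize numeric, mm per pixel.
#' @slot origin numeric length 2: world coordinates (mm) of the top-left
#'   pixel corner, `c(xLeft, yTop)`.
#' @slot wavelength numeric, excitation wavelength tag (nm; NA if n/a).
#' @exportClass ReconstructedImage
setClass("ReconstructedImage",
  representation(pixels = "matrix", fillMask = "matrix",
                 inpainted = "matrix", pixelSize = "numeric",
                 origin = "numeric", wavelength = "numeric")
)

setValidity("ReconstructedImage", function(object) {
  msg <- character()
  if (!identical(dim(object@pixels), dim(object@fillMask)) ||
      !identical(dim(object@pixels), dim(object@inpainted)))
    msg <- c(msg, "pixels, fillMask and inpainted must share dimensions")
  if (any(object@inpainted & object@fillMask))
    msg <- c(msg, "a pixel cannot be both directly filled and inpainted")
  if (length(object@origin) != 2) msg <- c(msg, "origin must have length 2")
  if (length(msg)) msg else TRUE
})

#' Planar rigid-body transform
#'
#' Rotation plus translation (determinant +1, no scaling), mapping moving
#' coordinates into the fixed frame, as used to stitch adjacent fields of
#' view by matched anatomical landmarks.
#'
#' @slot rotation numeric, angle in rad (counter-clockwise).
#' @slot translation numeric length 2, mm.
#' @slot residualRMS numeric, RMS landmark misfit after alignment (NA when
#'   the transform was not fitted).
#' @exportClass RigidTransform2D
setClass("RigidTransform2D",
  representation(rotation = "numeric", translation = "numeric",
                 residualRMS = "numeric")
)

#' Functional (sO2 / C_HbT) maps
#'
#' Output of two-wavelength linear unmixing: per-pixel oxygen saturation
#' `sO2 = C_HbO2 / (C_HbO2 + C_Hb)` and relative total hemoglobin, valid
#' only on the mask where both wavelengths were sampled and the 532-nm
#' amplitude clears the noise threshold.
#'
#' @slot so2 numeric matrix in \[0, 1\] (NA off-mask).
#' @slot chbtRel numeric matrix >= 0 (NA off-mask), relative units.
#' @slot mask logical matrix.
#' @slot clampCount integer, number of pixels whose component estimates
#'   were negative and were clamped.
#' @slot pixelSize numeric, mm per pixel.
#' @exportClass FunctionalMaps
setClass("FunctionalMaps",
  representation(so2 = "matrix", chbtRel = "matrix", mask = "matrix",
                 clampCount = "integer", pixelSize = "numeric")
)

setValidity("FunctionalMaps", function(object) {
  msg <- character()
  v <- object@so2[object@mask]
  if (length(v) && any(!is.na(v) & (v < 0 | v > 1)))
    msg <- c(msg, "masked sO2 values must lie in [0, 1]")
  if (any(!is.na(object@so2) & !object@mask))
    msg <- c(msg, "sO2 must be NA outside the mask")
  if (length(msg)) msg else TRUE
})

#' Molar extinction table for hemoglobin
#'
#' Packaged molar extinction coefficients of oxy- and deoxyhemoglobin at
#' the two excitation wavelengths.  At 532 nm the two species are nearly
#' isosbestic, which is what makes the 532-nm amplitude a proxy for total
#' hemoglobin.
#'
#' @slot table data.frame with columns `wavelength`, `epsHbO2`, `epsHb`
#'   (cm^-1 / M) and `source`.
#' @exportClass ExtinctionTable
setClass("ExtinctionTable", representation(table = "data.frame"))

setValidity("ExtinctionTable", function(object) {
  tb <- object@table
  msg <- character()
  if (!all(c("wavelength", "epsHbO2", "epsHb") %in% names(tb)))
    return("table must have columns wavelength, epsHbO2, epsHb")
  if (any(tb$epsHbO2 <= 0) || any(tb$epsHb <= 0))
    msg <- c(msg, "extinction coefficients must be strictly positive")
  i <- match(532, tb$wavelength)
  if (!is.na(i) &&
      abs(tb$epsHbO2[i] - tb$epsHb[i]) / tb$epsHbO2[i] > 0.1)
    msg <- c(msg, "532 nm must be near-isosbestic (relative difference <= 10%)")
  if (length(msg)) msg else TRUE
})

#' Vessel morphometry report
#'
#' The five summary metrics of a planar vascular network: total vessel
#' length (VL), number of branch points (NBP), mean vessel diameter
#' (MVD), mean vessel tortuosity (VT = arc length / chord length) and
#' box-counting fractal dimension (FD), plus the provenance of their
#' computation.
#'
#' @slot VL numeric, mm. @slot NBP integer. @slot MVD numeric, mm.
#' @slot VT numeric (>= 1 when at least one segment exists).
#' @slot FD numeric.
#' @slot provenance list (thresholds, box sizes, options).
#' @exportClass MorphometryReport
setClass("MorphometryReport",
  representation(VL = "numeric", NBP = "integer", MVD = "numeric",
                 VT = "numeric", FD = "numeric", provenance = "list")
)

setValidity("MorphometryReport", function(object) {
  msg <- character()
  if (object@VL < 0) msg <- c(msg, "VL must be >= 0")
  if (object@NBP < 0L) msg <- c(msg, "NBP must be >= 0")
  if (!is.na(object@VT) && object@VT < 1 - 1e-9)
    msg <- c(msg, "VT must be >= 1")
  if (length(msg)) msg else TRUE
})
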
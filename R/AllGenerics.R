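#' Accessor generics
#'
#' Small accessor family used across the package's S4 classes instead of
#' direct slot access.
#'
#' @param object an object of one of the package's S4 classes.
#' @param ... further arguments for methods.
#' @return The slot value the accessor names (see the class pages).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("pixelSize", function(object) standardGeneric("pixelSize"))

#' @rdname accessors
#' @export
setGeneric("spiralParams", function(object) standardGeneric("spiralParams"))

#' @rdname accessors
#' @export
setGeneric("segmentLabels", function(object) standardGeneric("segmentLabels"))

#' @rdname accessors
#' @export
setGeneric("radii", function(object) standardGeneric("radii"))

#' @rdname accessors
#' @export
setGeneric("positions", function(object) standardGeneric("positions"))

#' @rdname accessors
#' @export
setGeneric("pulseCounts", function(object) standardGeneric("pulseCounts"))

#' @rdname accessors
#' @export
setGeneric("energyFactor", function(object) standardGeneric("energyFactor"))

#' @rdname accessors
#' @export
setGeneric("truthGraph", function(object) standardGeneric("truthGraph"))

#' @rdname accessors
#' @export
setGeneric("so2Map", function(object) standardGeneric("so2Map"))

#' @rdname accessors
#' @export
setGeneric("chbtMap", function(object) standardGeneric("chbtMap"))

#' @rdname accessors
#' @export
setGeneric("absorptionMap",
           function(object, wavelength) standardGeneric("absorptionMap"))

#' @rdname accessors
#' @export
setGeneric("vesselMask", function(object) standardGeneric("vesselMask"))

#' @rdname accessors
#' @export
setGeneric("pulseRecords", function(object) standardGeneric("pulseRecords"))

#' @rdname accessors
#' @export
setGeneric("imagePixels", function(object) standardGeneric("imagePixels"))

#' @rdname accessors
#' @export
setGeneric("fillMask", function(object) standardGeneric("fillMask"))

#' @rdname accessors
#' @export
setGeneric("vesselSegments", function(object) standardGeneric("vesselSegments"))

#' @rdname accessors
#' @export
setGeneric("graphNodes", function(object) standardGeneric("graphNodes"))

#' @rdname accessors
#' @export
setGeneric("metricValues", function(object) standardGeneric("metricValues"))

#' @rdname accessors
#' @export
setGeneric("extinctionValues",
           function(object, wavelength) standardGeneric("extinctionValues"))
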
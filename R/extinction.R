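#' Packaged hemoglobin extinction table
#'
#' Loads the molar extinction coefficients of oxy- and deoxyhemoglobin at
#' the two excitation wavelengths (532 and 558 nm) packaged with
#' spiralscan.  The values come from a standard literature tabulation
#' (recorded in the file's `source` column).  532 nm is near-isosbestic
#' (the two species differ by under 10%), which is why the 532-nm
#' photoacoustic amplitude tracks total hemoglobin; 558 nm separates the
#' species and enables the sO2 computation.
#'
#' @param path optional path to an alternative CSV with columns
#'   `wavelength`, `epsHbO2`, `epsHb`.
#' @return an [ExtinctionTable-class] object.
#' @examples
#' ext <- hemoglobinExtinction()
#' extinctionValues(ext, 532)
#' @export
hemoglobinExtinction <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "hemoglobin_extinction.csv",
                        package = "spiralscan", mustWork = TRUE)
  tb <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  new("ExtinctionTable", table = tb)
}

#' @rdname accessors
#' @param wavelength 532 or 558 (nm).
#' @export
setMethod("extinctionValues", "ExtinctionTable",
  function(object, wavelength) {
    i <- match(wavelength, object@table$wavelength)
    if (is.na(i)) stop("wavelength not in extinction table: ", wavelength)
    c(epsHbO2 = object@table$epsHbO2[i], epsHb = object@table$epsHb[i])
  })

#' Forward absorption model
#'
#' Relative optical absorption of blood at one excitation wavelength:
#' `mu_a = (eps_HbO2 sO2 + eps_Hb (1 - sO2)) C_HbT`, the model inverted
#' by [unmix()].  Vectorised over `so2` and `chbt`.
#'
#' @param so2 oxygen saturation in \[0, 1\].
#' @param chbt relative total hemoglobin concentration (>= 0).
#' @param ext an [ExtinctionTable-class] object.
#' @param wavelength 532 or 558 (nm).
#' @return relative absorption (same shape as `so2`).
#' @export
forwardAbsorption <- function(so2, chbt, ext, wavelength) {
  e <- extinctionValues(ext, wavelength)
  (e[["epsHbO2"]] * so2 + e[["epsHb"]] * (1 - so2)) * chbt
}

setMethod("show", "ExtinctionTable", function(object) {
  cat("ExtinctionTable (cm^-1/M):\n")
  print(object@table[, c("wavelength", "epsHbO2", "epsHb")],
        row.names = FALSE)
})
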
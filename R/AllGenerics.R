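#' Accessors for seedsqi classes
#'
#' Small accessor generics for the package's S4 containers.
#'
#' @param x an object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("wavelengths", function(x) standardGeneric("wavelengths"))

#' @rdname accessors
#' @export
setGeneric("cubeData", function(x) standardGeneric("cubeData"))

#' @rdname accessors
#' @export
setGeneric("cubeKind", function(x) standardGeneric("cubeKind"))

#' @rdname accessors
#' @export
setGeneric("nBands", function(x) standardGeneric("nBands"))

#' @rdname accessors
#' @export
setGeneric("regionMask", function(x) standardGeneric("regionMask"))

#' @rdname accessors
#' @export
setGeneric("analysisMask", function(x) standardGeneric("analysisMask"))

#' @rdname accessors
#' @export
setGeneric("regionLabel", function(x) standardGeneric("regionLabel"))

#' @rdname accessors
#' @export
setGeneric("isValidRegion", function(x) standardGeneric("isValidRegion"))

#' @rdname accessors
#' @export
setGeneric("sqiValues", function(x) standardGeneric("sqiValues"))

#' @rdname accessors
#' @export
setGeneric("sqiArealValue", function(x) standardGeneric("sqiArealValue"))

#' @rdname accessors
#' @export
setGeneric("truthClass", function(x) standardGeneric("truthClass"))

#' @rdname accessors
#' @export
setGeneric("seedIds", function(x) standardGeneric("seedIds"))

#' @rdname accessors
#' @export
setGeneric("chosenParams", function(x) standardGeneric("chosenParams"))

#' @rdname accessors
#' @export
setGeneric("minTER", function(x) standardGeneric("minTER"))

#' @rdname accessors
#' @export
setGeneric("terCurve", function(x) standardGeneric("terCurve"))

#' @rdname accessors
#' @export
setGeneric("optimalParams", function(x) standardGeneric("optimalParams"))

setMethod("wavelengths", "SpectralCube", function(x) x@wavelengths)
setMethod("cubeData", "SpectralCube", function(x) x@data)
setMethod("cubeKind", "SpectralCube", function(x) x@kind)
setMethod("nBands", "SpectralCube", function(x) dim(x@data)[3L])

#' @export
setMethod("dim", "SpectralCube", function(x) dim(x@data))

setMethod("regionMask", "SeedRegion", function(x) x@mask)
setMethod("analysisMask", "SeedRegion", function(x) x@analysisMask)
setMethod("regionLabel", "SeedRegion", function(x) x@label)
setMethod("isValidRegion", "SeedRegion", function(x) x@valid)

setMethod("sqiValues", "SQIMap", function(x) x@values)
setMethod("regionMask", "SQIMap", function(x) x@mask)
setMethod("sqiArealValue", "SQIMap", function(x) x@sqiAreal)

setMethod("truthClass", "SeedLot", function(x) x@truthClass)
setMethod("seedIds", "SeedLot", function(x) x@seedId)
setMethod("sqiArealValue", "SeedLot", function(x) x@sqiAreal)
setMethod("length", "SeedLot", function(x) length(x@seedId))

setMethod("chosenParams", "CalibrationResult", function(x) x@chosen)
setMethod("minTER", "CalibrationResult", function(x) x@minTER)
setMethod("terCurve", "CalibrationResult", function(x) x@curve)
setMethod("optimalParams", "CalibrationResult", function(x) x@optimal)

setMethod("show", "SpectralCube", function(object) {
  d <- dim(object@data)
  cat(sprintf("SpectralCube: %d x %d pixels, %d bands (%.1f-%.1f nm), %s\n",
              d[1L], d[2L], d[3L], min(object@wavelengths),
              max(object@wavelengths), object@kind))
})

setMethod("show", "SeedRegion", function(object) {
  cat(sprintf(
    "SeedRegion %d: area %d px, analysis area %d px (margin %d), centroid (%.1f, %.1f)%s%s\n",
    object@label, sum(object@mask), sum(object@analysisMask),
    object@marginPx, object@centroid[1L], object@centroid[2L],
    if (object@touchesBorder) ", touches border" else "",
    if (object@valid) "" else ", INVALID"))
})

setMethod("show", "SQIMap", function(object) {
  v <- object@values[object@mask]
  cat(sprintf(
    "SQIMap: %d px, SQI_pixel range %.1f-%.1f deg, SQI_areal %.1f deg%s\n",
    length(v), min(v), max(v), object@sqiAreal,
    if (object@smoothed) " (smoothed)" else ""))
})

setMethod("show", "SelectionStats", function(object) {
  fmt <- function(x) if (is.na(x)) "NA" else sprintf("%.1f%%", 100 * x)
  cat(sprintf("SelectionStats: N=%d, N_OK=%d, N_get=%d, N_get|OK=%d\n",
              object@n, object@nOK, object@nGet, object@nGetOK))
  cat(sprintf("  SR_init=%s RR=%s SR=%s YR=%s TER=%s\n",
              fmt(object@srInit), fmt(object@rr), fmt(object@sr),
              fmt(object@yr), fmt(object@ter)))
})

setMethod("show", "CalibrationResult", function(object) {
  cat(sprintf("CalibrationResult (%s): min TER %.3f at %s (%d optimum/a)\n",
              object@method, object@minTER,
              paste(sprintf("%s=%.4g", names(object@chosen), object@chosen),
                    collapse = ", "),
              nrow(object@optimal)))
})

setMethod("show", "SeedLot", function(object) {
  tab <- table(factor(object@truthClass,
                      levels = c("sound", "shibudane", "other", "unknown")))
  cat(sprintf("SeedLot: %d seeds (%s); %d SQI maps\n",
              length(object@seedId),
              paste(sprintf("%s %d", names(tab), tab), collapse = ", "),
              length(object@maps)))
})

setMethod("show", "PlateConfig", function(object) {
  cat(sprintf(
    "PlateConfig: %d x %d px, %d bands (%.0f-%.0f nm), %d x %d seeds, noise sd %.2f%%\n",
    object@rows, object@cols, length(object@wavelengths),
    min(object@wavelengths), max(object@wavelengths),
    object@gridRows, object@gridCols, object@noiseSD))
})
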
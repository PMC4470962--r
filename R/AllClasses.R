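#' @import methods
NULL

#' SpectralCube: a hyperspectral image cube
#'
#' A 3-D raster of shape (rows, cols, bands) with one wavelength centre per
#' band, carrying either raw radiance counts or calibrated reflectance in
#' percent. Reflectance is always stored in percent (0-100+), never as a
#' fraction: the angular seed-quality index is not scale invariant, so the
#' unit is part of the data contract.
#'
#' @slot data numeric 3-D array, dimensions (rows, cols, bands).
#' @slot wavelengths numeric vector of band centres in nm, strictly
#'   increasing, one per band.
#' @slot kind either \code{"radiance"} or \code{"reflectance_percent"}.
#' @slot meta free-form list of header key-value pairs.
#' @exportClass SpectralCube
setClass("SpectralCube",
  representation(
    data = "array",
    wavelengths = "numeric",
    kind = "character",
    meta = "list"
  )
)

setValidity("SpectralCube", function(object) {
  d <- dim(object@data)
  if (length(d) != 3L)
    return("data must be a 3-D array (rows, cols, bands)")
  if (any(d < 1L))
    return("all cube dimensions must be >= 1")
  if (length(object@wavelengths) != d[3L])
    return(sprintf("length(wavelengths) [%d] != number of bands [%d]",
                   length(object@wavelengths), d[3L]))
  if (any(!is.finite(object@wavelengths)) || any(diff(object@wavelengths) <= 0))
    return("wavelengths must be finite and strictly increasing")
  if (length(object@kind) != 1L ||
      !object@kind %in% c("radiance", "reflectance_percent"))
    return("kind must be 'radiance' or 'reflectance_percent'")
  if (object@kind == "reflectance_percent") {
    v <- object@data
    if (anyNA(v) || any(!is.finite(v)))
      return("reflectance_percent cube must be finite")
    if (any(v < 0))
      return("reflectance_percent cube must be non-negative")
  }
  TRUE
})

#' Construct a SpectralCube
#'
#' @param data numeric 3-D array (rows, cols, bands).
#' @param wavelengths band centres in nm, strictly increasing.
#' @param kind \code{"radiance"} (default) or \code{"reflectance_percent"}.
#' @param meta optional list of header metadata.
#' @return A \linkS4class{SpectralCube}.
#' @examples
#' cube <- SpectralCube(array(1, c(4, 3, 5)), wavelengths = seq(1500, 1900, 100))
#' dim(cube)
#' @export
SpectralCube <- function(data, wavelengths,
                         kind = c("radiance", "reflectance_percent"),
                         meta = list()) {
  kind <- match.arg(kind)
  new("SpectralCube", data = data, wavelengths = as.numeric(wavelengths),
      kind = kind, meta = meta)
}

#' SeedRegion: a labelled seed area on a plate image
#'
#' Holds the full (hole-filled) pixel mask of one detected seed together
#' with its margin-eroded analysis mask. Coordinates are 1-based
#' (row, col).
#'
#' @slot label positive integer region label.
#' @slot mask logical matrix, the full seed area.
#' @slot analysisMask logical matrix, subset of \code{mask} after margin
#'   erosion.
#' @slot marginPx non-negative integer margin used for \code{analysisMask}.
#' @slot centroid numeric (row, col) of the mask centroid.
#' @slot touchesBorder logical, TRUE if the mask touches the image border.
#' @slot valid logical, FALSE when the analysis mask is empty.
#' @exportClass SeedRegion
setClass("SeedRegion",
  representation(
    label = "integer",
    mask = "matrix",
    analysisMask = "matrix",
    marginPx = "integer",
    centroid = "numeric",
    touchesBorder = "logical",
    valid = "logical"
  )
)

setValidity("SeedRegion", function(object) {
  if (length(object@label) != 1L || object@label < 1L)
    return("label must be a single positive integer")
  if (!is.logical(object@mask) || !is.logical(object@analysisMask))
    return("mask and analysisMask must be logical matrices")
  if (!identical(dim(object@mask), dim(object@analysisMask)))
    return("mask and analysisMask must share dimensions")
  if (any(object@analysisMask & !object@mask))
    return("analysisMask must be a subset of mask")
  if (object@marginPx < 0L)
    return("marginPx must be >= 0")
  if (object@marginPx == 0L && !identical(object@analysisMask, object@mask))
    return("marginPx == 0 requires analysisMask == mask")
  if (object@valid && !any(object@analysisMask))
    return("valid region must have a nonempty analysisMask")
  TRUE
})

#' BandTriplet: the three index bands of the seed-quality index
#'
#' Resolved band indices nearest to the nominal 1637/1734/1854 nm index
#' wavelengths of a given cube.
#'
#' @slot indices integer(3), strictly increasing band indices.
#' @slot centers numeric(3), the wavelength centres of those bands (nm).
#' @slot targets numeric(3), the requested wavelengths (nm).
#' @exportClass BandTriplet
setClass("BandTriplet",
  representation(indices = "integer", centers = "numeric",
                 targets = "numeric")
)

setValidity("BandTriplet", function(object) {
  if (length(object@indices) != 3L || length(object@centers) != 3L)
    return("indices and centers must have length 3")
  if (any(diff(object@indices) <= 0))
    return("band indices must be strictly increasing")
  TRUE
})

#' SQIMap: pixelwise seed-quality index over one seed region
#'
#' @slot values numeric matrix of SQI degrees, NA outside \code{mask}.
#' @slot mask logical matrix the values are defined on.
#' @slot sqiAreal SQI of the region's mean spectrum (degrees).
#' @slot smoothed logical, TRUE if band images were smoothed first.
#' @exportClass SQIMap
setClass("SQIMap",
  representation(values = "matrix", mask = "matrix",
                 sqiAreal = "numeric", smoothed = "logical")
)

setValidity("SQIMap", function(object) {
  if (!identical(dim(object@values), dim(object@mask)))
    return("values and mask must share dimensions")
  v <- object@values[object@mask]
  if (anyNA(v) || any(v <= 0) || any(v >= 360))
    return("SQI values on the mask must lie in (0, 360)")
  if (any(!is.na(object@values[!object@mask])))
    return("values must be NA off the mask")
  TRUE
})

#' SelectionStats: counts and rates of a sound-seed selection
#'
#' Counts of a selection outcome against cutting-test truth, with the five
#' derived statistics: initial sound-seed rate, recovery rate, sound-seed
#' rate, yield rate and total error rate. Undefined rates (zero
#' denominator) are NA.
#'
#' @slot n total number of seeds.
#' @slot nOK number of sound seeds.
#' @slot nNG number of unsound seeds (n - nOK).
#' @slot nGet number of selected ("recovered") seeds.
#' @slot nGetOK number of selected seeds that are sound.
#' @slot srInit,rr,sr,yr,ter the derived rates, as fractions.
#' @exportClass SelectionStats
setClass("SelectionStats",
  representation(
    n = "integer", nOK = "integer", nNG = "integer",
    nGet = "integer", nGetOK = "integer",
    srInit = "numeric", rr = "numeric", sr = "numeric",
    yr = "numeric", ter = "numeric"
  )
)

setValidity("SelectionStats", function(object) {
  with_slots <- c(object@n, object@nOK, object@nNG, object@nGet, object@nGetOK)
  if (any(with_slots < 0L)) return("counts must be non-negative")
  if (object@nNG != object@n - object@nOK) return("nNG must equal n - nOK")
  if (object@nGetOK > min(object@nGet, object@nOK))
    return("nGetOK cannot exceed min(nGet, nOK)")
  TRUE
})

#' CalibrationResult: outcome of a TER-minimizing threshold search
#'
#' @slot method \code{"single"} or \code{"dual"}.
#' @slot optimal data.frame of all parameter settings attaining the minimum
#'   total error rate (columns \code{max_sqi} and, for dual, \code{min_pbr}).
#' @slot chosen named numeric, the single setting picked by the tie-break
#'   rule (smallest for single; per-coordinate mode, then smallest, for
#'   dual).
#' @slot minTER the minimum total error rate (fraction).
#' @slot curve data.frame of the full TER curve (single) or grid (dual).
#' @exportClass CalibrationResult
setClass("CalibrationResult",
  representation(method = "character", optimal = "data.frame",
                 chosen = "numeric", minTER = "numeric",
                 curve = "data.frame")
)

setValidity("CalibrationResult", function(object) {
  if (!object@method %in% c("single", "dual"))
    return("method must be 'single' or 'dual'")
  if (nrow(object@optimal) < 1L)
    return("optimal must contain at least one row")
  TRUE
})

#' SeedLot: per-seed index values and truth labels for one seed lot
#'
#' Container tying together, for every seed of a plate or lot, its areal
#' SQI, its pixelwise SQI map (optional, needed for the dual-parameter
#' method) and its cutting-test class.
#'
#' @slot seedId character seed identifiers.
#' @slot sqiAreal numeric areal SQI in degrees, one per seed.
#' @slot maps list of \linkS4class{SQIMap} (may be empty).
#' @slot truthClass character: "sound", "shibudane", "other" or "unknown".
#' @exportClass SeedLot
setClass("SeedLot",
  representation(seedId = "character", sqiAreal = "numeric",
                 maps = "list", truthClass = "character")
)

setValidity("SeedLot", function(object) {
  n <- length(object@seedId)
  if (length(object@sqiAreal) != n)
    return("sqiAreal must have one value per seed")
  if (any(object@sqiAreal <= 0 | object@sqiAreal >= 360, na.rm = TRUE))
    return("sqiAreal must lie in (0, 360)")
  if (length(object@truthClass) != n)
    return("truthClass must have one value per seed")
  if (!all(object@truthClass %in% c("sound", "shibudane", "other", "unknown")))
    return("truthClass values must be sound/shibudane/other/unknown")
  if (length(object@maps) && length(object@maps) != n)
    return("maps must be empty or have one entry per seed")
  TRUE
})

#' Construct a SeedLot
#'
#' @param seedId seed identifiers (coerced to character).
#' @param sqiAreal areal SQI values in degrees.
#' @param truthClass cutting-test classes ("sound", "shibudane", "other",
#'   "unknown"); default all "unknown".
#' @param maps optional list of \linkS4class{SQIMap}, one per seed.
#' @return A \linkS4class{SeedLot}.
#' @export
SeedLot <- function(seedId, sqiAreal, truthClass = rep("unknown", length(seedId)),
                    maps = list()) {
  new("SeedLot", seedId = as.character(seedId), sqiAreal = as.numeric(sqiAreal),
      maps = maps, truthClass = as.character(truthClass))
}

#' PlateConfig: parameters of the synthetic plate generator
#'
#' Describes a synthetic 18-seed plate (6 x 3 grid) imaged by a SWIR
#' line-scanning camera: image and band geometry, seed layout, the
#' spectral model (linear baseline ramp with a Gaussian absorption dip
#' near 1,730 nm whose depth encodes soundness), class mixture and sensor
#' noise. See \code{\link{plateConfig}}.
#'
#' @slot rows,cols image size in pixels.
#' @slot wavelengths full band grid in nm.
#' @slot gridRows,gridCols seed grid layout.
#' @slot radiusRange numeric(2), seed semi-axis range in px.
#' @slot background numeric(2), background reflectance ramp start/end (%).
#' @slot baseline numeric(2), seed baseline reflectance ramp start/end (%).
#' @slot dipCenter dip centre (nm).
#' @slot dipWidth dip Gaussian sigma (nm).
#' @slot soundDepth,shibudaneDepth,otherDepth numeric(2) signed dip depth
#'   ranges in percent reflectance (positive = dip, negative = bump).
#' @slot unsoundRadial logical: do unsound seeds get the radial depth
#'   gradient too (hinoki-like) or a spatially flat depth (sugi-like)?
#' @slot radialExponent exponent gamma of the radial factor 1 - (r/R)^gamma.
#' @slot proportions named numeric(3), class mixture (sound, shibudane,
#'   other), summing to 1.
#' @slot noiseSD additive Gaussian noise sd in percent reflectance.
#' @slot referenceLevel radiance counts of the reference target.
#' @slot referencePercent known reflectance of the reference target (%).
#' @slot gainField logical, add a multiplicative vignetting field to both
#'   raw and reference cubes (cancelled exactly by calibration).
#' @slot seed integer RNG seed.
#' @exportClass PlateConfig
setClass("PlateConfig",
  representation(
    rows = "integer", cols = "integer", wavelengths = "numeric",
    gridRows = "integer", gridCols = "integer", radiusRange = "numeric",
    background = "numeric", baseline = "numeric",
    dipCenter = "numeric", dipWidth = "numeric",
    soundDepth = "numeric", shibudaneDepth = "numeric",
    otherDepth = "numeric",
    unsoundRadial = "logical", radialExponent = "numeric",
    proportions = "numeric", noiseSD = "numeric",
    referenceLevel = "numeric", referencePercent = "numeric",
    gainField = "logical", seed = "integer"
  )
)

setValidity("PlateConfig", function(object) {
  if (object@rows < 1L || object@cols < 1L)
    return("rows and cols must be >= 1")
  if (any(diff(object@wavelengths) <= 0))
    return("band grid must be strictly ascending")
  if (length(object@proportions) != 3L ||
      abs(sum(object@proportions) - 1) > 1e-8)
    return("class proportions must have length 3 and sum to 1")
  if (any(object@proportions < 0))
    return("class proportions must be non-negative")
  if (object@soundDepth[1L] < 0)
    return("sound dip depth must be >= 0")
  if (object@noiseSD < 0)
    return("noiseSD must be >= 0")
  if (object@radiusRange[1L] <= 0 ||
      object@radiusRange[2L] < object@radiusRange[1L])
    return("radiusRange must be positive and non-decreasing")
  TRUE
})
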
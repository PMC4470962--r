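# End-to-end plate scoring: reflectance cube -> seed regions -> areal SQI
# and pixelwise SQI maps -> SeedLot.

#' Score all seeds of a reflectance cube
#'
#' Runs the full analysis: spectral-angle segmentation against a
#' reference spectrum, region detection with hole filling and border
#' exclusion, optional margin erosion, then areal SQI and (optionally)
#' pixelwise SQI maps per seed.
#'
#' @param cube a reflectance \linkS4class{SpectralCube}.
#' @param referenceSpectrum reference spectrum for segmentation (e.g.
#'   \code{\link{rectMeanSpectrum}} of a pre-assigned seed area, or
#'   \code{\link{seedBaselineSpectrum}} for synthetic plates).
#' @param angleThreshold SAM angle threshold in radians (default 0.1).
#' @param minAreaPx minimum region area in pixels.
#' @param connectivity component connectivity, 4 or 8.
#' @param marginPx margin eroded off each region for the areal-SQI
#'   analysis mask (default 0).
#' @param bands a \linkS4class{BandTriplet}.
#' @param smooth smooth band images before pixelwise SQI.
#' @param withMaps also compute per-seed SQI maps (needed for the dual
#'   method; default TRUE).
#' @param truthLabels optional integer truth-label matrix (e.g.
#'   \code{generatePlate()$truthLabels}); regions are then matched to
#'   truth seeds by majority overlap and reported under the truth ids.
#' @param truthClass optional truth classes indexed by truth id (with
#'   \code{truthLabels}) or by region label (without).
#' @return A list: \code{lot} (a \linkS4class{SeedLot}), \code{regions}
#'   (list of \linkS4class{SeedRegion}, including any invalid ones
#'   excluded from the lot) and \code{excluded} (labels of regions
#'   dropped because margin erosion emptied them).
#' @export
scorePlate <- function(cube, referenceSpectrum, angleThreshold = 0.1,
                       minAreaPx = 10L, connectivity = 8L, marginPx = 0L,
                       bands = bandTriplet(cube), smooth = FALSE,
                       withMaps = TRUE, truthLabels = NULL,
                       truthClass = NULL) {
  sam <- spectralAngleMap(cube, referenceSpectrum)
  mask <- thresholdSimilarity(sam, angleThreshold, "max_angle")
  regions <- detectRegions(mask, minAreaPx = minAreaPx,
                           connectivity = connectivity)
  if (marginPx > 0)
    regions <- lapply(regions, erodeMargin, marginPx = marginPx)
  keep <- vapply(regions, isValidRegion, logical(1))
  kept <- regions[keep]
  ids <- if (is.null(truthLabels)) vapply(kept, regionLabel, integer(1))
         else matchTruth(kept, truthLabels)
  ord <- order(ids)
  kept <- kept[ord]; ids <- ids[ord]
  sqi <- vapply(kept, function(r) sqiAreal(cube, r, bands), numeric(1))
  maps <- if (withMaps)
    lapply(kept, sqiPixelMap, cube = cube, bands = bands, smooth = smooth)
  else list()
  tc <- if (is.null(truthClass)) rep("unknown", length(kept))
        else as.character(truthClass)[ids]
  list(lot = SeedLot(ids, sqi, truthClass = tc, maps = maps),
       regions = regions,
       excluded = vapply(regions[!keep], regionLabel, integer(1)))
}

#' Match detected regions to truth seeds by majority overlap
#'
#' @param regions list of \linkS4class{SeedRegion}.
#' @param truthLabels integer matrix of ground-truth seed labels (0 =
#'   background).
#' @return Integer vector: for each region, the truth id most of its
#'   pixels fall on (0 if the region lies entirely on background).
#' @export
matchTruth <- function(regions, truthLabels) {
  vapply(regions, function(r) {
    lab <- truthLabels[regionMask(r)]
    lab <- lab[lab > 0]
    if (!length(lab)) return(0L)
    as.integer(names(which.max(table(lab))))
  }, integer(1))
}
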
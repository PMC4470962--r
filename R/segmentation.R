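# Seed-area detection by spectral similarity to a reference spectrum,
# connected-component extraction and margin erosion.

#' Spectral angle mapper (SAM) image
#'
#' Per-pixel angle between each pixel spectrum and a reference spectrum,
#' viewing spectra as vectors: theta = arccos(s . r / (|s||r|)), in
#' [0, pi]. SAM is invariant to positive scaling of either spectrum.
#' Zero-norm pixels are assigned pi (maximally dissimilar).
#'
#' @param cube a \linkS4class{SpectralCube}.
#' @param referenceSpectrum numeric vector, one value per band.
#' @return Numeric matrix (rows x cols) of angles in radians.
#' @seealso \code{\link{crossCorrelationMap}}, \code{\link{thresholdSimilarity}}
#' @export
spectralAngleMap <- function(cube, referenceSpectrum) {
  stopifnot(is(cube, "SpectralCube"))
  if (length(referenceSpectrum) != nBands(cube))
    stop(sprintf("reference spectrum length [%d] != band count [%d]",
                 length(referenceSpectrum), nBands(cube)))
  rnorm2 <- sqrt(sum(referenceSpectrum^2))
  if (rnorm2 == 0) stop("reference spectrum has zero norm")
  X <- .cube_matrix(cube)
  norms <- sqrt(rowSums(X^2))
  cosv <- as.vector(X %*% referenceSpectrum) / (norms * rnorm2)
  cosv <- pmin(1, pmax(-1, cosv))
  theta <- acos(cosv)
  theta[norms == 0] <- pi
  matrix(theta, dim(cube@data)[1L], dim(cube@data)[2L])
}

#' Cross-correlation matching image
#'
#' Per-pixel Pearson correlation between each pixel spectrum and a
#' reference spectrum across bands, in [-1, 1]. Invariant to positive
#' affine transforms of either spectrum. Zero-variance pixels get 0.
#'
#' @inheritParams spectralAngleMap
#' @return Numeric matrix (rows x cols) of correlations.
#' @export
crossCorrelationMap <- function(cube, referenceSpectrum) {
  stopifnot(is(cube, "SpectralCube"))
  b <- nBands(cube)
  if (b < 2L) stop("at least two bands are required")
  if (length(referenceSpectrum) != b)
    stop(sprintf("reference spectrum length [%d] != band count [%d]",
                 length(referenceSpectrum), b))
  r <- referenceSpectrum - mean(referenceSpectrum)
  rss <- sqrt(sum(r^2))
  if (rss == 0) stop("reference spectrum is constant (zero variance)")
  X <- .cube_matrix(cube)
  X <- X - rowMeans(X)
  sds <- sqrt(rowSums(X^2))
  cc <- as.vector(X %*% r) / (sds * rss)
  cc[sds == 0] <- 0
  cc <- pmin(1, pmax(-1, cc))
  matrix(cc, dim(cube@data)[1L], dim(cube@data)[2L])
}

#' Threshold a similarity image into a foreground mask
#'
#' @param simImage matrix from \code{\link{spectralAngleMap}} (mode
#'   \code{"max_angle"}) or \code{\link{crossCorrelationMap}} (mode
#'   \code{"min_correlation"}).
#' @param threshold angle threshold in [0, pi] or correlation threshold in
#'   [-1, 1], according to \code{mode}.
#' @param mode \code{"max_angle"} keeps pixels with angle <= threshold;
#'   \code{"min_correlation"} keeps pixels with correlation >= threshold.
#' @return Logical matrix.
#' @export
thresholdSimilarity <- function(simImage, threshold,
                                mode = c("max_angle", "min_correlation")) {
  mode <- match.arg(mode)
  if (mode == "max_angle") {
    if (threshold < 0 || threshold > pi)
      stop("angle threshold must lie in [0, pi]")
    simImage <= threshold
  } else {
    if (threshold < -1 || threshold > 1)
      stop("correlation threshold must lie in [-1, 1]")
    simImage >= threshold
  }
}

# Connected-component labelling with 4- or 8-connectivity by iterative
# minimum-label propagation (vectorized over the whole image). Returns an
# integer matrix; labels are in raster-scan (row-major) order of each
# component's first pixel.
.label_components <- function(mask, connectivity = 8L) {
  stopifnot(connectivity %in% c(4L, 8L))
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(Inf, nr, nc)
  lab[mask] <- which(mask)  # provisional labels: linear indices
  shifts <- list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))
  if (connectivity == 8L)
    shifts <- c(shifts, list(c(1L, 1L), c(1L, -1L), c(-1L, 1L), c(-1L, -1L)))
  repeat {
    new <- lab
    for (s in shifts) {
      src_r <- seq_len(nr) - s[1L]; keep_r <- src_r >= 1L & src_r <= nr
      src_c <- seq_len(nc) - s[2L]; keep_c <- src_c >= 1L & src_c <= nc
      shifted <- matrix(Inf, nr, nc)
      shifted[keep_r, keep_c] <- lab[src_r[keep_r], src_c[keep_c]]
      shifted[!mask] <- Inf
      new <- pmin(new, shifted)
    }
    new[!mask] <- Inf
    if (identical(new, lab)) break
    lab <- new
  }
  out <- matrix(0L, nr, nc)
  if (any(mask)) {
    ids <- lab[mask]
    # order components by raster-scan position of their first pixel
    key <- (row(mask)[mask] - 1L) * nc + col(mask)[mask]
    first <- tapply(key, ids, min)
    ord <- names(sort(first))
    out[mask] <- match(as.character(ids), ord)
  }
  out
}

.region_from_mask <- function(mask, label) {
  rc <- which(mask, arr.ind = TRUE)
  touches <- any(rc[, 1L] == 1L | rc[, 1L] == nrow(mask) |
                 rc[, 2L] == 1L | rc[, 2L] == ncol(mask))
  new("SeedRegion", label = as.integer(label), mask = mask,
      analysisMask = mask, marginPx = 0L,
      centroid = c(mean(rc[, 1L]), mean(rc[, 2L])),
      touchesBorder = touches, valid = any(mask))
}

#' Detect seed regions in a foreground mask
#'
#' Extracts connected components, fills interior holes (seed areas are
#' closed), drops components smaller than \code{minAreaPx}, flags (and by
#' default drops) components touching the image border, and labels the
#' survivors 1, 2, ... in raster-scan order of each component's top-left
#' pixel.
#'
#' @param mask logical matrix.
#' @param minAreaPx minimum component area in pixels (default 10).
#' @param connectivity 4 or 8 (default 8).
#' @param excludeBorder drop border-touching components (default TRUE);
#'   their spectra are unreliable.
#' @return List of \linkS4class{SeedRegion}.
#' @export
detectRegions <- function(mask, minAreaPx = 10L, connectivity = 8L,
                          excludeBorder = TRUE) {
  stopifnot(is.logical(mask), is.matrix(mask))
  lab <- .label_components(mask, as.integer(connectivity))
  nlab <- max(lab)
  regions <- list()
  for (i in seq_len(nlab)) {
    m <- lab == i
    m <- .fill_holes(m)
    if (sum(m) < minAreaPx) next
    reg <- .region_from_mask(m, label = length(regions) + 1L)
    if (excludeBorder && reg@touchesBorder) next
    regions[[length(regions) + 1L]] <- reg
  }
  regions
}

.fill_holes <- function(mask) {
  filled <- EBImage::fillHull(matrix(as.integer(mask), nrow(mask), ncol(mask)))
  matrix(as.logical(filled), nrow(mask), ncol(mask))
}

#' Erode a margin off a seed region
#'
#' Builds the analysis mask by excluding every mask pixel whose Euclidean
#' distance to the nearest background pixel is <= \code{marginPx},
#' using the Euclidean distance transform (exact at diagonal boundaries,
#' unlike iterated structuring elements). The margin setting concentrates
#' the analysis on pixels free of background contamination.
#'
#' @param region a \linkS4class{SeedRegion}.
#' @param marginPx non-negative margin in pixels.
#' @return A new \linkS4class{SeedRegion} with updated
#'   \code{analysisMask}, \code{marginPx} and \code{valid} flag.
#' @export
erodeMargin <- function(region, marginPx) {
  stopifnot(is(region, "SeedRegion"), marginPx >= 0)
  if (marginPx == 0) {
    am <- region@mask
  } else {
    d <- EBImage::distmap(
      matrix(as.integer(region@mask), nrow(region@mask), ncol(region@mask)))
    am <- matrix(as.numeric(d) > marginPx, nrow(region@mask), ncol(region@mask))
  }
  new("SeedRegion", label = region@label, mask = region@mask,
      analysisMask = am, marginPx = as.integer(marginPx),
      centroid = region@centroid, touchesBorder = region@touchesBorder,
      valid = any(am))
}

#' Mean reflectance spectrum of a seed region
#'
#' Unweighted mean over the region's analysis-mask pixels, per band.
#'
#' @param cube a reflectance \linkS4class{SpectralCube}.
#' @param region a valid \linkS4class{SeedRegion}.
#' @return Numeric vector of percent reflectance, one value per band.
#' @export
regionMeanSpectrum <- function(cube, region) {
  stopifnot(is(cube, "SpectralCube"), is(region, "SeedRegion"))
  if (!region@valid) stop("region is invalid (empty analysis mask)")
  if (cube@kind != "reflectance_percent")
    stop("cube must be calibrated to reflectance_percent first")
  X <- .cube_matrix(cube)
  colMeans(X[as.vector(region@analysisMask), , drop = FALSE])
}

#' Mean spectrum over a rectangle (reference-area helper)
#'
#' Convenience for building a reference spectrum from a pre-assigned
#' rectangular area of the image, e.g. a known seed or target patch.
#'
#' @param cube a \linkS4class{SpectralCube}.
#' @param rows,cols integer ranges of the rectangle (1-based, inclusive).
#' @return Numeric vector, one value per band.
#' @export
rectMeanSpectrum <- function(cube, rows, cols) {
  sub <- cube@data[rows, cols, , drop = FALSE]
  apply(sub, 3L, mean)
}

#' Tabulate detected regions
#'
#' @param regions list of \linkS4class{SeedRegion}.
#' @return data.frame with label, area_px, analysis_area_px, centroid_row,
#'   centroid_col, touches_border, valid.
#' @export
regionTable <- function(regions) {
  do.call(rbind, lapply(regions, function(r) data.frame(
    label = r@label, area_px = sum(r@mask),
    analysis_area_px = sum(r@analysisMask),
    centroid_row = r@centroid[1L], centroid_col = r@centroid[2L],
    touches_border = r@touchesBorder, valid = r@valid)))
}

#' Write a label map as a grayscale PNG
#'
#' Region labels are stored as 8-bit gray levels (label value = gray
#' level, background 0), so up to 255 regions are representable.
#'
#' @param regions list of \linkS4class{SeedRegion} (sharing image shape).
#' @param path output PNG path.
#' @return Invisibly, the path.
#' @export
writeLabelMapPNG <- function(regions, path) {
  stopifnot(length(regions) > 0)
  lab <- matrix(0L, nrow(regions[[1]]@mask), ncol(regions[[1]]@mask))
  for (r in regions) lab[r@mask] <- r@label
  if (max(lab) > 255L) stop("more than 255 regions cannot be encoded")
  png::writePNG(lab / 255, path)
  invisible(path)
}
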
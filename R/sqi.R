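# The seed quality index (SQI): an angular three-band reflectance index
# quantifying the depth of the ~1,730 nm lipid absorption dip.

#' Resolve the three SQI index bands of a cube
#'
#' Maps the nominal index wavelengths (1637, 1734, 1854 nm by default) to
#' the nearest instrument bands of \code{cube}.
#'
#' @param cube a \linkS4class{SpectralCube}.
#' @param targetsNm the three nominal wavelengths in nm, increasing.
#' @param maxOffsetNm largest tolerated centre offset in nm (see
#'   \code{\link{nearestBand}}).
#' @return A \linkS4class{BandTriplet}.
#' @export
bandTriplet <- function(cube, targetsNm = c(1637, 1734, 1854),
                        maxOffsetNm = 5.0) {
  stopifnot(length(targetsNm) == 3L, all(diff(targetsNm) > 0))
  idx <- vapply(targetsNm, function(t) nearestBand(cube, t, maxOffsetNm), 1L)
  new("BandTriplet", indices = as.integer(idx),
      centers = cube@wavelengths[idx], targets = as.numeric(targetsNm))
}

#' Seed quality index from a three-band reflectance triplet
#'
#' Place the three reflectances (in percent) at unit x-steps:
#' A = (-1, r1637), B = (0, r1734), C = (1, r1854). The SQI is the
#' clockwise angle in degrees at B between segments BA and BC:
#' \deqn{\alpha = \frac{(r_{1637}-r_{1734})(r_{1854}-r_{1734}) - 1}
#'   {\sqrt{(r_{1637}-r_{1734})^2+1}\sqrt{(r_{1854}-r_{1734})^2+1}}}
#' with SQI = (180/pi) arccos(alpha) when r1734 <= (r1637 + r1854)/2
#' (the centre band sits at or below the flank mean) and 360 minus that
#' otherwise. A flat or collinear triplet gives exactly 180; an absorption
#' dip ("m-shaped" spectrum) gives SQI < 180, a peak ("n-shaped") > 180.
#'
#' The unit x-steps make the index scale dependent: reflectance must be in
#' percent, never as a fraction. alpha is clamped to [-1, 1] before
#' arccos to absorb floating-point overshoot. All arguments are
#' vectorized.
#'
#' @param r1637,r1734,r1854 reflectance in percent at the three index
#'   bands.
#' @return SQI in degrees, in (0, 360).
#' @examples
#' sqiFromTriplet(50, 50, 50)   # flat: 180
#' sqiFromTriplet(50, 10, 50)   # deep symmetric dip: ~2.86
#' sqiFromTriplet(10, 50, 10)   # symmetric peak: ~357.1
#' @export
sqiFromTriplet <- function(r1637, r1734, r1854) {
  if (any(!is.finite(r1637)) || any(!is.finite(r1734)) || any(!is.finite(r1854)))
    stop("all three reflectances must be finite")
  d1 <- r1637 - r1734
  d2 <- r1854 - r1734
  alpha <- (d1 * d2 - 1) / (sqrt(d1^2 + 1) * sqrt(d2^2 + 1))
  alpha <- pmin(1, pmax(-1, alpha))
  ang <- acos(alpha) * 180 / pi
  ifelse(r1734 <= (r1637 + r1854) / 2, ang, 360 - ang)
}

#' Areal SQI of a seed region
#'
#' SQI of the region's mean reflectance spectrum: the spectra are averaged
#' over the analysis mask first and the index computed second. Because the
#' index is nonlinear, this is generally not the mean of the pixelwise
#' SQI values.
#'
#' @param cube reflectance \linkS4class{SpectralCube}.
#' @param region valid \linkS4class{SeedRegion}.
#' @param bands a \linkS4class{BandTriplet} (default: resolved from
#'   \code{cube}).
#' @return SQI in degrees.
#' @export
sqiAreal <- function(cube, region, bands = bandTriplet(cube)) {
  spec <- regionMeanSpectrum(cube, region)
  i <- bands@indices
  sqiFromTriplet(spec[i[1L]], spec[i[2L]], spec[i[3L]])
}

# 3x3 distance-weighted kernel: weight 2^(-d), d = Euclidean offset
# distance (centre 1, edge 1/2, corner 2^(-sqrt(2))).
.smooth_kernel <- local({
  d <- sqrt(outer((-1:1)^2, (-1:1)^2, "+"))
  2^(-d)
})

#' Distance-weighted 3x3 smoothing within a mask
#'
#' Denoises a band image with the 3 x 3 kernel whose weight is two to the
#' negative power of the Euclidean offset distance (centre 1, edge 0.5,
#' corner 2^(-sqrt 2)). At each mask pixel the weighted mean is taken over
#' the kernel's in-mask pixels only, with weights renormalized to the
#' included pixels, so a constant image is preserved exactly and mask
#' edges are not diluted by background.
#'
#' @param image numeric matrix.
#' @param mask logical matrix of pixels to smooth over (and within).
#' @return Numeric matrix; off-mask pixels are returned unchanged.
#' @export
smoothBandImage <- function(image, mask) {
  stopifnot(is.matrix(image), is.logical(mask),
            identical(dim(image), dim(mask)))
  if (!any(mask)) stop("mask is empty")
  nr <- nrow(image); nc <- ncol(image)
  num <- matrix(0, nr, nc); den <- matrix(0, nr, nc)
  vals <- ifelse(mask, image, 0)
  m01 <- ifelse(mask, 1, 0)
  for (dr in -1:1) for (dc in -1:1) {
    w <- .smooth_kernel[dr + 2L, dc + 2L]
    src_r <- seq_len(nr) - dr; keep_r <- src_r >= 1L & src_r <= nr
    src_c <- seq_len(nc) - dc; keep_c <- src_c >= 1L & src_c <= nc
    num[keep_r, keep_c] <- num[keep_r, keep_c] +
      w * vals[src_r[keep_r], src_c[keep_c]]
    den[keep_r, keep_c] <- den[keep_r, keep_c] +
      w * m01[src_r[keep_r], src_c[keep_c]]
  }
  out <- image
  out[mask] <- num[mask] / den[mask]
  out
}

#' Pixelwise SQI map of a seed region
#'
#' Computes the SQI independently at every pixel of the region's mask (the
#' full seed mask by default; margin exploration uses the analysis mask).
#' Optionally the three band images are smoothed within the mask first
#' (\code{\link{smoothBandImage}}); in routine scoring smoothing is off
#' and is intended for rendering.
#'
#' @inheritParams sqiAreal
#' @param smooth smooth band images before computing SQI (default FALSE).
#' @param useAnalysisMask compute over the margin-eroded analysis mask
#'   instead of the full mask (default FALSE).
#' @return An \linkS4class{SQIMap}; its \code{sqiAreal} slot records the
#'   region's areal SQI.
#' @export
sqiPixelMap <- function(cube, region, bands = bandTriplet(cube),
                        smooth = FALSE, useAnalysisMask = FALSE) {
  stopifnot(is(cube, "SpectralCube"), is(region, "SeedRegion"))
  if (!region@valid) stop("region is invalid (empty analysis mask)")
  mask <- if (useAnalysisMask) region@analysisMask else region@mask
  i <- bands@indices
  b1 <- cube@data[, , i[1L]]
  b2 <- cube@data[, , i[2L]]
  b3 <- cube@data[, , i[3L]]
  if (smooth) {
    b1 <- smoothBandImage(b1, mask)
    b2 <- smoothBandImage(b2, mask)
    b3 <- smoothBandImage(b3, mask)
  }
  vals <- matrix(NA_real_, nrow(mask), ncol(mask))
  vals[mask] <- sqiFromTriplet(b1[mask], b2[mask], b3[mask])
  new("SQIMap", values = vals, mask = mask,
      sqiAreal = sqiAreal(cube, region, bands), smoothed = smooth)
}

#' Peak-to-base area ratio (PBR)
#'
#' Fraction of a seed's map pixels whose pixelwise SQI is strictly lower
#' than \code{maxSqi} (the "peak" area of low-SQI pixels over the whole
#' seed area). Strict "lower than" is used throughout the package for
#' both selection rules.
#'
#' @param map an \linkS4class{SQIMap}.
#' @param maxSqi the SQI threshold in degrees.
#' @return Fraction in [0, 1].
#' @export
pbr <- function(map, maxSqi) {
  stopifnot(is(map, "SQIMap"))
  v <- map@values[map@mask]
  if (!length(v)) stop("SQI map is empty")
  mean(v < maxSqi)
}

#' Export an SQI map as TSV
#'
#' Writes rows (row, col, sqi) for every mask pixel.
#'
#' @param map an \linkS4class{SQIMap}.
#' @param path output path.
#' @return Invisibly, the path.
#' @export
writeSQIMapTSV <- function(map, path) {
  rc <- which(map@mask, arr.ind = TRUE)
  df <- data.frame(row = rc[, 1L], col = rc[, 2L],
                   sqi = map@values[map@mask])
  df <- df[order(df$row, df$col), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Render an SQI map (or any SQI image) as a PNG heat map
#'
#' Fixed colour scale over [0, 360] degrees with warm colours for low SQI
#' (likely sound tissue) and cool colours for high SQI; NA/off-mask pixels
#' are black.
#'
#' @param map an \linkS4class{SQIMap} or a numeric matrix of SQI degrees
#'   (NA = background).
#' @param path output PNG path.
#' @return Invisibly, the path.
#' @export
renderSQIHeatmap <- function(map, path) {
  vals <- if (is(map, "SQIMap")) map@values else map
  ramp <- grDevices::colorRamp(c("#a50026", "#f46d43", "#fee090",
                                 "#e0f3f8", "#74add1", "#313695"))
  rgbv <- array(0, dim = c(nrow(vals), ncol(vals), 3L))
  ok <- !is.na(vals)
  if (any(ok)) {
    cols <- ramp(pmin(pmax(vals[ok] / 360, 0), 1)) / 255
    for (k in 1:3) {
      ch <- rgbv[, , k]
      ch[ok] <- cols[, k]
      rgbv[, , k] <- ch
    }
  }
  png::writePNG(rgbv, path)
  invisible(path)
}
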
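# Synthetic SWIR seed plates: the spectral/spatial phenomenology the
# method assumes (m-shaped sound spectra with a central dip gradient,
# n-shaped unsound spectra, dark background, sensor noise), generated so
# that every pipeline stage is testable without instrument data.

#' Build a synthetic plate configuration
#'
#' Defaults emulate the SWIR camera and plate of the reference setup: a
#' 320 x 200 pixel image, 163 bands spanning 1,250-2,500 nm (7.7 nm
#' spacing), and 18 seeds laid out on a 6 x 3 grid of wells. Seeds are
#' axis-aligned ellipses whose reflectance follows a linear baseline ramp
#' (default 55-70\%) minus a Gaussian absorption dip centred at 1,730 nm;
#' sound seeds carry a deep dip (15-25\% reflectance) whose depth fades
#' radially as 1 - (r/R)^gamma (strongest at the seed centre), shibudane
#' a mild central bump, and "other" unsound seeds an at-most-faint dip.
#' The background is a dim ramp around 5\% reflectance, spectrally
#' distinct from seeds. Raw radiance is defined as
#' reflectance / referencePercent * referenceLevel (optionally vignetted),
#' so \code{\link{calibrateReflectance}} inverts the construction exactly.
#'
#' @param rows,cols image size in pixels.
#' @param wavelengths band grid in nm (ascending).
#' @param gridRows,gridCols seed grid layout (3 x 6 by default).
#' @param radiusRange seed semi-axis range in pixels.
#' @param background background reflectance ramp (start, end) in percent.
#' @param baseline seed baseline reflectance ramp (start, end) in percent.
#' @param dipCenter absorption dip centre in nm.
#' @param dipWidth dip Gaussian sigma in nm.
#' @param soundDepth,shibudaneDepth,otherDepth dip-depth ranges in percent
#'   reflectance per class; shibudane depths are bump magnitudes.
#' @param unsoundRadial apply the radial depth gradient to unsound seeds
#'   too (hinoki-like) instead of a spatially flat depth (sugi-like).
#' @param radialExponent exponent gamma of 1 - (r/R)^gamma.
#' @param proportions named class mixture (sound, shibudane, other),
#'   summing to 1.
#' @param noiseSD additive Gaussian sensor noise sd in percent
#'   reflectance.
#' @param referenceLevel reference-target radiance level (counts).
#' @param referencePercent known target reflectance in percent.
#' @param gainField add multiplicative vignetting to raw and reference
#'   cubes (exercises the pixelwise calibration; cancelled exactly).
#' @param seed RNG seed.
#' @return A \linkS4class{PlateConfig}.
#' @export
plateConfig <- function(rows = 200L, cols = 320L,
                        wavelengths = seq(1250, 2500, length.out = 163),
                        gridRows = 3L, gridCols = 6L,
                        radiusRange = c(7, 10),
                        background = c(8, 2), baseline = c(55, 70),
                        dipCenter = 1730, dipWidth = 35,
                        soundDepth = c(15, 25),
                        shibudaneDepth = c(4, 7),
                        otherDepth = c(0, 1),
                        unsoundRadial = FALSE, radialExponent = 2,
                        proportions = c(sound = 0.5, shibudane = 1/3,
                                        other = 1/6),
                        noiseSD = 0, referenceLevel = 1000,
                        referencePercent = 50, gainField = FALSE,
                        seed = 1L) {
  new("PlateConfig", rows = as.integer(rows), cols = as.integer(cols),
      wavelengths = wavelengths, gridRows = as.integer(gridRows),
      gridCols = as.integer(gridCols), radiusRange = radiusRange,
      background = background, baseline = baseline,
      dipCenter = dipCenter, dipWidth = dipWidth,
      soundDepth = soundDepth, shibudaneDepth = shibudaneDepth,
      otherDepth = otherDepth, unsoundRadial = unsoundRadial,
      radialExponent = radialExponent, proportions = proportions,
      noiseSD = noiseSD, referenceLevel = referenceLevel,
      referencePercent = referencePercent, gainField = gainField,
      seed = as.integer(seed))
}

#' Sugi-like plate preset
#'
#' Unsound seeds are spatially flat: their (at most faint) dip or bump has
#' no radial gradient, so their areal SQI is independent of the margin
#' setting while sound seeds' areal SQI decreases as the margin grows.
#'
#' @param ... overrides passed to \code{\link{plateConfig}}.
#' @return A \linkS4class{PlateConfig}.
#' @export
sugiPlateConfig <- function(...) {
  plateConfig(unsoundRadial = FALSE, ...)
}

#' Hinoki-like plate preset
#'
#' Unsound seeds also show a small central dip gradient (so their
#' pixelwise SQI has a low-SQI core and nonzero PBR at permissive
#' thresholds), making areal-SQI separation narrower; the dual-parameter
#' method is designed for this regime.
#'
#' @param ... overrides passed to \code{\link{plateConfig}}.
#' @return A \linkS4class{PlateConfig}.
#' @export
hinokiPlateConfig <- function(...) {
  plateConfig(unsoundRadial = TRUE, otherDepth = c(3, 6),
              shibudaneDepth = c(2, 4), ...)
}

.ramp <- function(range, wl) {
  range[1L] + (wl - wl[1L]) / (wl[length(wl)] - wl[1L]) * (range[2L] - range[1L])
}

.dip_profile <- function(config) {
  exp(-(config@wavelengths - config@dipCenter)^2 / (2 * config@dipWidth^2))
}

#' Seed baseline spectrum of a plate configuration
#'
#' The dip-free seed reflectance ramp, usable as the pre-assigned
#' reference spectrum for spectral-similarity segmentation.
#'
#' @param config a \linkS4class{PlateConfig}.
#' @return Numeric vector of percent reflectance per band.
#' @export
seedBaselineSpectrum <- function(config) {
  .ramp(config@baseline, config@wavelengths)
}

#' Generate one synthetic seed spectrum
#'
#' Baseline ramp minus a Gaussian dip at the configured centre: sound and
#' "other" seeds get a dip of the given depth (deep for sound, zero to
#' faint for other), shibudane a bump of the given magnitude, plus
#' additive Gaussian noise per band. Uses the current RNG state; seed the
#' generator for reproducibility.
#'
#' @param class one of \code{"sound"}, \code{"shibudane"}, \code{"other"}.
#' @param depthPercent dip depth (sound/other) or bump magnitude
#'   (shibudane) in percent reflectance, >= 0.
#' @param config a \linkS4class{PlateConfig} providing the band grid,
#'   baseline, dip shape and noise sd.
#' @return Numeric reflectance spectrum in percent, one value per band.
#' @export
generateSeedSpectrum <- function(class = c("sound", "shibudane", "other"),
                                 depthPercent, config = plateConfig()) {
  class <- match.arg(class)
  stopifnot(depthPercent >= 0)
  signed <- if (class == "shibudane") -depthPercent else depthPercent
  sp <- seedBaselineSpectrum(config) - signed * .dip_profile(config)
  if (config@noiseSD > 0)
    sp <- sp + stats::rnorm(length(sp), 0, config@noiseSD)
  pmax(sp, 0)
}

.class_counts <- function(proportions, n) {
  # largest-remainder apportionment so counts always sum to n
  raw <- proportions * n
  cnt <- floor(raw)
  rem <- n - sum(cnt)
  if (rem > 0) {
    ord <- order(raw - cnt, decreasing = TRUE)
    cnt[ord[seq_len(rem)]] <- cnt[ord[seq_len(rem)]] + 1
  }
  as.integer(cnt)
}

#' Generate a synthetic seed plate
#'
#' Lays elliptical seeds on the configured grid, draws each seed's class
#' and dip depth, writes per-pixel reflectance spectra (sound seeds' dip
#' depth scaled by 1 - (r/R)^gamma so the lowest pixelwise SQI sits at
#' the seed centre), adds sensor noise, and converts to raw radiance
#' against a constant (optionally vignetted) reference cube so that
#' \code{\link{calibrateReflectance}} recovers the reflectance exactly.
#' Seeds are numbered 1..n in raster order of the grid, matching the
#' label order of \code{\link{detectRegions}}.
#'
#' @param config a \linkS4class{PlateConfig}.
#' @return A list: \code{raw} and \code{reference} radiance
#'   \linkS4class{SpectralCube}s, \code{reflectance} (the noiseless-of-gain
#'   ground-truth reflectance cube), \code{truthLabels} (integer label
#'   matrix), \code{truthTable} (data.frame: seed_id, class, centroid_row,
#'   centroid_col, radius_row, radius_col, depth, area_px) and
#'   \code{config}.
#' @export
generatePlate <- function(config = plateConfig()) {
  validObject(config)
  set.seed(config@seed)
  wl <- config@wavelengths
  nb <- length(wl)
  nr <- config@rows; nc <- config@cols
  npx <- nr * nc
  spacingR <- nr / config@gridRows
  spacingC <- nc / config@gridCols
  if (2 * config@radiusRange[2L] + 2 > min(spacingR, spacingC))
    stop("seeds would overlap or touch at the requested radii; ",
         "use a smaller radiusRange")
  gauss <- .dip_profile(config)
  baseSpec <- seedBaselineSpectrum(config)
  bgSpec <- .ramp(config@background, wl)

  refl <- array(rep(bgSpec, each = npx), dim = c(nr, nc, nb))
  labels <- matrix(0L, nr, nc)

  nSeeds <- config@gridRows * config@gridCols
  counts <- .class_counts(config@proportions, nSeeds)
  classes <- sample(rep(c("sound", "shibudane", "other"), counts))
  depthRange <- list(sound = config@soundDepth,
                     shibudane = config@shibudaneDepth,
                     other = config@otherDepth)

  tab <- vector("list", nSeeds)
  id <- 0L
  for (gr in seq_len(config@gridRows)) for (gc in seq_len(config@gridCols)) {
    id <- id + 1L
    cy <- spacingR * (gr - 0.5)
    cx <- spacingC * (gc - 0.5)
    a <- stats::runif(1, config@radiusRange[1L], config@radiusRange[2L])
    b <- stats::runif(1, config@radiusRange[1L], config@radiusRange[2L])
    cls <- classes[id]
    dr <- depthRange[[cls]]
    depth <- stats::runif(1, dr[1L], dr[2L])
    signed <- if (cls == "shibudane") -depth else depth
    rows_i <- max(1L, floor(cy - a)):min(nr, ceiling(cy + a))
    cols_i <- max(1L, floor(cx - b)):min(nc, ceiling(cx + b))
    rho <- sqrt(outer(((rows_i - cy) / a)^2, ((cols_i - cx) / b)^2, "+"))
    inside <- rho <= 1
    cells <- as.matrix(expand.grid(row = rows_i, col = cols_i))[inside, ,
                                                                drop = FALSE]
    rhoIn <- rho[inside]
    radial <- cls == "sound" || config@unsoundRadial
    depthPx <- if (radial) signed * (1 - rhoIn^config@radialExponent)
               else rep(signed, length(rhoIn))
    lin <- cells[, 1L] + (cells[, 2L] - 1L) * nr
    for (k in seq_len(nb))
      refl[lin + (k - 1L) * npx] <- baseSpec[k] - depthPx * gauss[k]
    labels[lin] <- id
    tab[[id]] <- data.frame(seed_id = id, class = cls,
                            centroid_row = cy, centroid_col = cx,
                            radius_row = a, radius_col = b,
                            depth = depth, area_px = length(rhoIn))
  }
  if (config@noiseSD > 0)
    refl <- refl + stats::rnorm(length(refl), 0, config@noiseSD)
  refl[refl < 0] <- 0

  gain <- matrix(1, nr, nc)
  if (config@gainField) {
    rr <- (seq_len(nr) - (nr + 1) / 2) / nr
    cc <- (seq_len(nc) - (nc + 1) / 2) / nc
    gain <- 1 - 0.25 * outer(rr^2, cc^2, "+") / 0.5
  }
  raw <- refl * (config@referenceLevel / config@referencePercent)
  raw <- raw * as.vector(gain)  # gain recycles over bands
  reference <- array(config@referenceLevel * as.vector(gain),
                     dim = c(nr, nc, nb))

  list(raw = SpectralCube(raw, wl, kind = "radiance"),
       reference = SpectralCube(reference, wl, kind = "radiance"),
       reflectance = SpectralCube(refl, wl, kind = "reflectance_percent"),
       truthLabels = labels,
       truthTable = do.call(rbind, tab),
       config = config)
}

#' Write a synthetic plate to disk
#'
#' ENVI cubes for raw and reference, a truth TSV and a label-map PNG, so
#' command-line runs can work from on-disk fixtures.
#'
#' @param plate result of \code{\link{generatePlate}}.
#' @param dir output directory (created if missing).
#' @return Invisibly, the directory.
#' @export
writePlate <- function(plate, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeENVICube(plate$raw, file.path(dir, "raw.hdr"))
  writeENVICube(plate$reference, file.path(dir, "reference.hdr"))
  utils::write.table(plate$truthTable, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  png::writePNG(plate$truthLabels / 255, file.path(dir, "labels.png"))
  invisible(dir)
}
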
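# ENVI cube input/output and radiance-to-reflectance calibration.
#
# ENVI files are an ASCII header (.hdr) next to a flat little-endian binary
# raster. Header keys used: samples (cols), lines (rows), bands, data type,
# interleave (bsq/bil/bip), byte order, wavelength = { ... }.

.envi_types <- list(
  `1` = list(what = "integer", size = 1L, signed = FALSE),
  `2` = list(what = "integer", size = 2L, signed = TRUE),
  `3` = list(what = "integer", size = 4L, signed = TRUE),
  `4` = list(what = "numeric", size = 4L, signed = TRUE),
  `5` = list(what = "numeric", size = 8L, signed = TRUE),
  `12` = list(what = "integer", size = 2L, signed = FALSE)
)

.parse_envi_header <- function(headerPath) {
  txt <- readLines(headerPath, warn = FALSE)
  txt <- paste(txt, collapse = "\n")
  # join { ... } groups onto single logical entries
  fields <- list()
  # match "key = value" and "key = { multi, line, list }"
  pat <- "(?m)^\\s*([a-zA-Z][a-zA-Z0-9 _]*?)\\s*=\\s*(\\{[^}]*\\}|[^\n]*)"
  m <- gregexpr(pat, txt, perl = TRUE)[[1]]
  if (m[1] == -1) stop("no key = value entries found in ENVI header: ",
                       headerPath)
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  for (i in seq_along(starts)) {
    entry <- substr(txt, starts[i], starts[i] + lens[i] - 1L)
    key <- tolower(trimws(sub("=.*", "", entry)))
    val <- trimws(sub("^[^=]*=", "", entry))
    fields[[key]] <- val
  }
  fields
}

.parse_envi_list <- function(val) {
  val <- gsub("[{}]", "", val)
  as.numeric(trimws(strsplit(val, ",")[[1]]))
}

#' Read an ENVI hyperspectral cube
#'
#' Reads an ENVI header plus binary raster into a
#' \linkS4class{SpectralCube}, normalizing any interleave (BSQ, BIL, BIP)
#' to (rows, cols, bands) order. The binary file is looked up as the
#' header path without its \code{.hdr} extension, or with \code{.dat},
#' \code{.raw} or \code{.img} appended.
#'
#' @param headerPath path to the \code{.hdr} file.
#' @param kind stored quantity; defaults to the header's
#'   \code{data kind} entry if present, else \code{"radiance"}.
#' @return A \linkS4class{SpectralCube}.
#' @seealso \code{\link{writeENVICube}}
#' @export
readENVICube <- function(headerPath, kind = NULL) {
  if (!file.exists(headerPath)) stop("header not found: ", headerPath)
  h <- .parse_envi_header(headerPath)
  need <- c("samples", "lines", "bands", "data type", "interleave")
  miss <- setdiff(need, names(h))
  if (length(miss))
    stop("ENVI header is missing required field(s): ",
         paste(miss, collapse = ", "))
  if (is.null(h[["wavelength"]]))
    stop("ENVI header is missing the 'wavelength' field; ",
         "band centres in nm are required")
  samples <- as.integer(h[["samples"]])  # columns
  lines <- as.integer(h[["lines"]])      # rows
  bands <- as.integer(h[["bands"]])
  wl <- .parse_envi_list(h[["wavelength"]])
  if (length(wl) != bands)
    stop(sprintf("wavelength list length [%d] != bands [%d]",
                 length(wl), bands))
  dtype <- .envi_types[[as.character(as.integer(h[["data type"]]))]]
  if (is.null(dtype))
    stop("unsupported ENVI data type: ", h[["data type"]])
  byte_order <- if (!is.null(h[["byte order"]])) as.integer(h[["byte order"]]) else 0L
  endian <- if (byte_order == 0L) "little" else "big"
  interleave <- tolower(h[["interleave"]])
  if (!interleave %in% c("bsq", "bil", "bip"))
    stop("unsupported interleave: ", interleave)

  base <- sub("\\.hdr$", "", headerPath, ignore.case = TRUE)
  cand <- c(base, paste0(base, c(".dat", ".raw", ".img")))
  dataPath <- cand[file.exists(cand)][1]
  if (is.na(dataPath)) stop("binary raster not found next to header: ", base)

  nvals <- samples * lines * bands
  expected_bytes <- as.numeric(nvals) * dtype$size
  actual_bytes <- file.size(dataPath)
  if (actual_bytes != expected_bytes)
    stop(sprintf(
      "raster size mismatch: header implies %d bytes but file has %d bytes",
      expected_bytes, actual_bytes))
  con <- file(dataPath, "rb")
  on.exit(close(con))
  v <- readBin(con, what = dtype$what, n = nvals, size = dtype$size,
               signed = dtype$signed, endian = endian)
  # fastest-varying dimension first per interleave, then permute to
  # (rows, cols, bands)
  arr <- switch(interleave,
    bsq = aperm(array(v, dim = c(samples, lines, bands)), c(2L, 1L, 3L)),
    bil = aperm(array(v, dim = c(samples, bands, lines)), c(3L, 1L, 2L)),
    bip = aperm(array(v, dim = c(bands, samples, lines)), c(3L, 2L, 1L)))
  if (is.null(kind)) {
    kind <- if (!is.null(h[["data kind"]])) h[["data kind"]] else "radiance"
  }
  SpectralCube(arr, wl, kind = kind, meta = h)
}

#' Write an ENVI hyperspectral cube
#'
#' Writes \code{cube} as an ASCII ENVI header plus a little-endian binary
#' raster (\code{<base>.dat}) such that \code{\link{readENVICube}} is the
#' exact inverse. Data are written as 8-byte IEEE doubles (ENVI data type
#' 5), so the round trip is bit-exact.
#'
#' @param cube a \linkS4class{SpectralCube}.
#' @param headerPath output \code{.hdr} path.
#' @param interleave one of \code{"bsq"}, \code{"bil"}, \code{"bip"}.
#' @return Invisibly, the header path.
#' @export
writeENVICube <- function(cube, headerPath, interleave = c("bsq", "bil", "bip")) {
  stopifnot(is(cube, "SpectralCube"))
  validObject(cube)
  interleave <- match.arg(interleave)
  d <- dim(cube@data)
  base <- sub("\\.hdr$", "", headerPath, ignore.case = TRUE)
  dataPath <- paste0(base, ".dat")
  hdr <- c(
    "ENVI",
    "description = { seedsqi SpectralCube }",
    sprintf("samples = %d", d[2L]),
    sprintf("lines = %d", d[1L]),
    sprintf("bands = %d", d[3L]),
    "header offset = 0",
    "file type = ENVI Standard",
    "data type = 5",
    sprintf("interleave = %s", interleave),
    "byte order = 0",
    sprintf("data kind = %s", cube@kind),
    sprintf("wavelength = { %s }",
            paste(format(cube@wavelengths, trim = TRUE, digits = 15),
                  collapse = ", "))
  )
  writeLines(hdr, headerPath)
  arr <- switch(interleave,
    bsq = aperm(cube@data, c(2L, 1L, 3L)),
    bil = aperm(cube@data, c(2L, 3L, 1L)),
    bip = aperm(cube@data, c(3L, 2L, 1L)))
  con <- file(dataPath, "wb")
  on.exit(close(con))
  writeBin(as.numeric(arr), con, size = 8L, endian = "little")
  invisible(headerPath)
}

#' Convert raw radiance to percent reflectance
#'
#' Pixelwise linear calibration against a reference target of known
#' reflectance: \code{R = (raw - dark) / (reference - dark) * referencePercent},
#' with the dark frame taken as zero when absent. Negative results are
#' clipped to 0; pixels where the denominator is <= 0 are set to 0 and
#' counted (the count is stored in \code{meta$invalid_pixels} and
#' reported via \code{message}).
#'
#' @param raw radiance \linkS4class{SpectralCube}.
#' @param reference radiance cube of the reference target (same
#'   dimensions and wavelengths as \code{raw}).
#' @param referencePercent known reflectance of the target in percent
#'   (> 0; e.g. 50 for a grey Spectralon target, 90 for PTFE).
#' @param dark optional dark-current cube, same geometry.
#' @return A \linkS4class{SpectralCube} of kind
#'   \code{"reflectance_percent"}.
#' @examples
#' wl <- seq(1500, 1900, 100)
#' ref <- SpectralCube(array(200, c(2, 2, 5)), wl)
#' raw <- SpectralCube(array(100, c(2, 2, 5)), wl)
#' calibrateReflectance(raw, ref, 50)  # 25% everywhere
#' @export
calibrateReflectance <- function(raw, reference, referencePercent, dark = NULL) {
  stopifnot(is(raw, "SpectralCube"), is(reference, "SpectralCube"))
  if (referencePercent <= 0)
    stop("referencePercent must be > 0")
  if (!identical(dim(raw@data), dim(reference@data)))
    stop("raw and reference cube dimensions differ")
  if (!isTRUE(all.equal(raw@wavelengths, reference@wavelengths)))
    stop("raw and reference wavelength grids differ")
  darkData <- 0
  if (!is.null(dark)) {
    stopifnot(is(dark, "SpectralCube"))
    if (!identical(dim(dark@data), dim(raw@data)))
      stop("dark cube dimensions differ from raw")
    darkData <- dark@data
  }
  denom <- reference@data - darkData
  bad <- denom <= 0
  nbad <- sum(bad)
  denom[bad] <- 1  # placeholder; flagged pixels are zeroed below
  refl <- (raw@data - darkData) / denom * referencePercent
  refl[bad] <- 0
  refl[refl < 0] <- 0
  if (nbad > 0)
    message(nbad, " pixel value(s) had non-positive reference signal; set to 0")
  SpectralCube(refl, raw@wavelengths, kind = "reflectance_percent",
               meta = c(raw@meta, list(invalid_pixels = nbad)))
}

#' Find the band nearest a target wavelength
#'
#' Index wavelengths are nominal; instrument band centres rarely coincide
#' with them, so a request is resolved to the band whose centre minimizes
#' the absolute offset. Ties break toward the lower wavelength.
#'
#' @param cube a \linkS4class{SpectralCube}.
#' @param targetNm requested wavelength in nm.
#' @param maxOffsetNm largest acceptable offset in nm (default 5, just
#'   above half the 7.7 nm band spacing of the SWIR camera emulated here).
#' @return Integer band index.
#' @export
nearestBand <- function(cube, targetNm, maxOffsetNm = 5.0) {
  stopifnot(is(cube, "SpectralCube"), maxOffsetNm > 0)
  off <- abs(cube@wavelengths - targetNm)
  idx <- which.min(off)  # first minimum = lower wavelength on ties
  if (off[idx] > maxOffsetNm)
    stop(sprintf(
      "no band within %.2f nm of %.1f nm (nearest centre: %.1f nm)",
      maxOffsetNm, targetNm, cube@wavelengths[idx]))
  idx
}

#' Export one band image as TSV
#'
#' Writes a tab-separated table (row, col, value) of one band of the cube.
#'
#' @param cube a \linkS4class{SpectralCube}.
#' @param band band index.
#' @param path output file path.
#' @return Invisibly, the path.
#' @export
writeBandTSV <- function(cube, band, path) {
  stopifnot(band >= 1L, band <= nBands(cube))
  img <- cube@data[, , band]
  df <- data.frame(row = as.vector(row(img)), col = as.vector(col(img)),
                   value = as.vector(img))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# flatten (rows, cols, bands) cube data to a (pixels x bands) matrix;
# pixel order is column-major over (row, col), matching R's linear indexing
.cube_matrix <- function(cube) {
  d <- dim(cube@data)
  matrix(cube@data, nrow = d[1L] * d[2L], ncol = d[3L])
}
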
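# Independent oracles and small fixture builders used across the suite.

# Clockwise angle at B between segments BA and BC for the three-point
# polyline A=(-1, r1), B=(0, r2), C=(1, r3), via atan2 of cross/dot
# products (a construction independent of the arccos + branch formula).
clockwise_angle_deg <- function(r1, r2, r3) {
  ba <- c(-1, r1 - r2)
  bc <- c(1, r3 - r2)
  cross <- ba[1] * bc[2] - ba[2] * bc[1]
  dot <- sum(ba * bc)
  ((-atan2(cross, dot)) %% (2 * pi)) * 180 / pi
}

# 3x3 distance-weighted kernel recomputed from first principles
kernel_oracle <- function() {
  2^(-sqrt(outer((-1:1)^2, (-1:1)^2, "+")))
}

# Exhaustive minimum TER over all selections realizable by a strict
# threshold rule (enumerates all 2^n subsets; n <= 12).
brute_force_min_ter <- function(sqi, truth) {
  n <- length(sqi)
  stopifnot(n <= 12)
  best <- Inf
  for (m in 0:(2^n - 1)) {
    sel <- bitwAnd(m, 2^(seq_len(n) - 1)) > 0
    if (any(sel) && any(!sel) && max(sqi[sel]) >= min(sqi[!sel])) next
    ter <- (sum(sel) + sum(truth) - 2 * sum(sel & truth)) / n
    best <- min(best, ter)
  }
  best
}

# Cube with a single flat spectrum per pixel, given as a matrix of
# pixel values and a per-band offset of zero (each band = pixel image).
flat_cube <- function(img, nbands, wl = seq(1500, 1500 + 10 * (nbands - 1), 10)) {
  SpectralCube(array(rep(img, nbands), dim = c(dim(img), nbands)), wl,
               kind = "reflectance_percent")
}

# Cube whose every pixel carries the same three-band triplet, on the
# nominal index wavelengths.
triplet_cube <- function(nr, nc, r1, r2, r3) {
  arr <- array(0, dim = c(nr, nc, 3))
  arr[, , 1] <- r1; arr[, , 2] <- r2; arr[, , 3] <- r3
  SpectralCube(arr, c(1637, 1734, 1854), kind = "reflectance_percent")
}

# SeedRegion from a bare mask (margin 0)
region_from_mask <- function(mask, label = 1L) {
  rc <- which(mask, arr.ind = TRUE)
  new("SeedRegion", label = as.integer(label), mask = mask,
      analysisMask = mask, marginPx = 0L,
      centroid = c(mean(rc[, 1]), mean(rc[, 2])),
      touchesBorder = FALSE, valid = any(mask))
}

# SQIMap holding given values on a trivial mask
map_from_values <- function(values) {
  v <- matrix(values, nrow = 1)
  new("SQIMap", values = v, mask = matrix(TRUE, 1, length(values)),
      sqiAreal = mean(values), smoothed = FALSE)
}

# A small, quick plate configuration used by most pipeline tests
# (identical physics to the default, smaller field of view).
small_plate_config <- function(...) {
  args <- utils::modifyList(
    list(rows = 72L, cols = 120L, radiusRange = c(5, 7)), list(...))
  do.call(plateConfig, args)
}

# Build a SeedLot directly from a plate's ground truth (bypasses
# segmentation; used where only the downstream statistics are under test).
lot_from_truth <- function(plate, withMaps = TRUE, marginPx = 0L) {
  refl <- plate$reflectance
  b <- bandTriplet(refl)
  n <- nrow(plate$truthTable)
  regs <- lapply(seq_len(n), function(i) {
    r <- region_from_mask(plate$truthLabels == i, i)
    if (marginPx > 0) erodeMargin(r, marginPx) else r
  })
  sqi <- vapply(regs, function(r) sqiAreal(refl, r, b), numeric(1))
  maps <- if (withMaps) lapply(regs, sqiPixelMap, cube = refl, bands = b)
          else list()
  SeedLot(seq_len(n), sqi, truthClass = plate$truthTable$class, maps = maps)
}
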
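test_that("synthetic seed spectra carry the class-specific dip and are RNG-reproducible", {
  cfg <- plateConfig(noiseSD = 0)
  wl <- cfg@wavelengths
  b2 <- which.min(abs(wl - 1734))
  base <- seedBaselineSpectrum(cfg)

  sound <- generateSeedSpectrum("sound", 20, cfg)
  dipAt1734 <- base[b2] - sound[b2]
  expect_equal(dipAt1734, 20, tolerance = 0.2)  # ~20% below local baseline
  tri <- bandTriplet(SpectralCube(array(sound, c(1, 1, length(wl))), wl))
  expect_lt(sqiFromTriplet(sound[tri@indices[1]], sound[tri@indices[2]],
                           sound[tri@indices[3]]), 180)

  shib <- generateSeedSpectrum("shibudane", 5, cfg)
  expect_gt(shib[b2], base[b2])   # bump, n-shaped
  expect_gt(sqiFromTriplet(shib[tri@indices[1]], shib[tri@indices[2]],
                           shib[tri@indices[3]]), 180)

  other <- generateSeedSpectrum("other", 0, cfg)
  sq <- sqiFromTriplet(other[tri@indices[1]], other[tri@indices[2]],
                       other[tri@indices[3]])
  expect_lt(abs(sq - 180), 25)    # collinear up to baseline ramp curvature

  cfgN <- plateConfig(noiseSD = 1)
  set.seed(99); s1 <- generateSeedSpectrum("sound", 20, cfgN)
  set.seed(99); s2 <- generateSeedSpectrum("sound", 20, cfgN)
  expect_identical(s1, s2)
  set.seed(100)
  expect_false(identical(s1, generateSeedSpectrum("sound", 20, cfgN)))
})

test_that("plate configuration invariants are enforced", {
  expect_error(plateConfig(proportions = c(sound = 0.5, shibudane = 0.5,
                                           other = 0.5)), "sum to 1")
  expect_error(plateConfig(soundDepth = c(-5, 10)), "depth")
  expect_error(plateConfig(wavelengths = c(1300, 1200, 1400)), "ascending")
  expect_error(generatePlate(small_plate_config(radiusRange = c(11, 12))),
               "smaller radius")
  expect_true(validObject(sugiPlateConfig(), complete = TRUE))
  expect_true(validObject(hinokiPlateConfig(), complete = TRUE))
})

test_that("generated plates have 18 labelled seeds and are seed-reproducible", {
  plate <- generatePlate(small_plate_config())
  expect_equal(nrow(plate$truthTable), 18)
  expect_setequal(unique(plate$truthLabels[plate$truthLabels > 0]), 1:18)
  expect_setequal(plate$truthTable$seed_id, 1:18)
  expect_equal(as.vector(table(plate$truthTable$class)[c("sound", "shibudane",
                                                         "other")]),
               c(9, 6, 3))
  for (i in 1:18)
    expect_equal(sum(plate$truthLabels == i), plate$truthTable$area_px[i])

  p2 <- generatePlate(small_plate_config())
  expect_identical(cubeData(plate$raw), cubeData(p2$raw))
  p3 <- generatePlate(small_plate_config(seed = 2L, noiseSD = 1))
  p4 <- generatePlate(small_plate_config(seed = 2L, noiseSD = 1))
  expect_identical(cubeData(p3$raw), cubeData(p4$raw))
})

test_that("calibration inverts the synthetic radiance construction exactly, gain field included", {
  plate <- generatePlate(small_plate_config(gainField = TRUE, noiseSD = 0.5))
  refl <- calibrateReflectance(plate$raw, plate$reference,
                               plate$config@referencePercent)
  expect_equal(cubeData(refl), cubeData(plate$reflectance), tolerance = 1e-12)
})

test_that("zero-noise closure: segmentation recovers truth masks and classes order by SQI", {
  plate <- generatePlate(small_plate_config())
  refl <- calibrateReflectance(plate$raw, plate$reference, 50)
  scored <- scorePlate(refl, seedBaselineSpectrum(plate$config),
                       truthLabels = plate$truthLabels,
                       truthClass = plate$truthTable$class)
  lot <- scored$lot
  expect_equal(length(lot), 18)
  regs <- Filter(isValidRegion, scored$regions)
  ids <- matchTruth(regs, plate$truthLabels)
  for (i in seq_along(regs))
    expect_identical(regionMask(regs[[i]]), plate$truthLabels == ids[i])

  sqi <- sqiArealValue(lot)
  cls <- truthClass(lot)
  expect_lt(max(sqi[cls == "sound"]), min(sqi[cls != "sound"]))
  expect_equal(minTER(calibrateSingle(lot)), 0)
})

test_that("sugi-like unsound seeds are margin-invariant while sound seeds sharpen with margin", {
  plate <- generatePlate(sugiPlateConfig(rows = 72L, cols = 120L,
                                         radiusRange = c(5, 7)))
  refl <- plate$reflectance
  b <- bandTriplet(refl)
  cls <- plate$truthTable$class
  sqiAt <- function(margin) vapply(1:18, function(i) {
    r <- erodeMargin(region_from_mask(plate$truthLabels == i, i), margin)
    sqiAreal(refl, r, b)
  }, numeric(1))
  sweep <- vapply(0:3, sqiAt, numeric(18))
  for (i in which(cls != "sound"))  # identical pixels: any submask mean agrees
    expect_lt(diff(range(sweep[i, ])), 1e-6)
  soundMeans <- colMeans(sweep[cls == "sound", ])
  expect_true(all(diff(soundMeans) < 0))
})

test_that("hinoki-like plates give unsound seeds nonzero PBR and favour the dual method", {
  plate <- generatePlate(hinokiPlateConfig(rows = 72L, cols = 120L,
                                           radiusRange = c(5, 7)))
  lot <- lot_from_truth(plate)
  cls <- truthClass(lot)
  p <- pbrAt(lot, 150)  # permissive maxSQI: unsound cores show up too
  expect_true(all(p[cls == "other"] > 0))
  # at a stricter maxSQI only the deep sound cores qualify broadly
  p60 <- pbrAt(lot, 60)
  expect_gt(min(p60[cls == "sound"]), max(p60[cls != "sound"]))
  single <- calibrateSingle(lot)
  dual <- calibrateDual(lot)
  expect_lte(minTER(dual), minTER(single))
})

test_that("minimum TER grows in expectation as class depth distributions overlap", {
  overlapTER <- function(otherMax, seeds) {
    mean(vapply(seeds, function(s) {
      plate <- generatePlate(small_plate_config(
        otherDepth = c(0, otherMax),
        proportions = c(sound = 0.5, shibudane = 0, other = 0.5),
        noiseSD = 0.25, seed = s))
      minTER(suppressWarnings(calibrateSingle(lot_from_truth(plate,
                                                             withMaps = FALSE))))
    }, numeric(1)))
  }
  seeds <- 1:6
  ters <- vapply(c(1, 8, 20), overlapTER, numeric(1), seeds = seeds)
  expect_true(all(diff(ters) >= 0))
  expect_equal(ters[1], 0)
})

test_that("plates round-trip to disk with truth tables and label maps", {
  plate <- generatePlate(small_plate_config())
  dir <- file.path(tempdir(), "plate_out")
  writePlate(plate, dir)
  expect_true(all(file.exists(file.path(dir, c("raw.hdr", "raw.dat",
                                               "reference.hdr", "truth.tsv",
                                               "labels.png")))))
  back <- readENVICube(file.path(dir, "raw.hdr"))
  expect_equal(cubeData(back), cubeData(plate$raw))
  tt <- utils::read.delim(file.path(dir, "truth.tsv"))
  expect_equal(nrow(tt), 18)
})
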
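test_that("selection statistics implement the five rate definitions", {
  # a 180-seed lot: 120 sound, 120 selected of which 119 sound
  truth <- rep(c(TRUE, FALSE), c(120, 60))
  sel <- c(rep(TRUE, 119), FALSE, TRUE, rep(FALSE, 59))
  st <- selectionStats(truth, sel)
  expect_equal(st@srInit, 120 / 180)
  expect_equal(st@rr, 120 / 180)
  expect_equal(st@sr, 119 / 120)
  expect_equal(st@yr, 119 / 120)
  expect_equal(st@ter, 2 / 180)

  # 31 sound of 180, 29 selected of which 27 sound
  truth <- rep(c(TRUE, FALSE), c(31, 149))
  sel <- c(rep(TRUE, 27), rep(FALSE, 4), rep(TRUE, 2), rep(FALSE, 147))
  st <- selectionStats(truth, sel)
  expect_equal(st@ter, 6 / 180)
  expect_equal(st@sr, 27 / 29)
  expect_equal(st@yr, 27 / 31)

  # degenerate: nothing selected
  st0 <- selectionStats(truth, rep(FALSE, 180))
  expect_equal(st0@rr, 0)
  expect_equal(st0@ter, 31 / 180)
  expect_true(is.na(st0@sr))
  # perfect selection
  stp <- selectionStats(truth, truth)
  expect_equal(stp@ter, 0)
  expect_equal(stp@sr, 1)
  expect_equal(stp@yr, 1)
  # all-unsound lot: YR undefined
  expect_true(is.na(selectionStats(rep(FALSE, 5), rep(TRUE, 5))@yr))
  expect_error(selectionStats(c(TRUE, FALSE), TRUE), "length")
})

test_that("RR*SR equals YR*SR_init and TER*N counts misclassifications, over random selections", {
  set.seed(41)
  for (i in 1:50) {
    n <- sample(2:40, 1)
    truth <- sample(c(TRUE, FALSE), n, replace = TRUE)
    sel <- sample(c(TRUE, FALSE), n, replace = TRUE)
    st <- selectionStats(truth, sel)
    if (!is.na(st@sr) && !is.na(st@yr))
      expect_equal(st@rr * st@sr, st@yr * st@srInit, tolerance = 1e-12)
    expect_equal(st@ter * st@n, sum(sel != truth))
  }
})

test_that("both selection rules use strict inequalities at the boundary", {
  expect_identical(selectSingle(c(100, 122, 150), 122),
                   c(TRUE, FALSE, FALSE))
  expect_true(all(selectSingle(c(100, 122, 150), 360)))
  expect_false(any(selectSingle(c(100, 122, 150), 0)))

  maps <- lapply(list(rep(c(10, 50), c(1, 9)),
                      rep(c(10, 50), c(27, 73)),
                      rep(c(10, 50), c(40, 60))),
                 map_from_values)
  expect_equal(pbrAt(maps, 30), c(0.10, 0.27, 0.40))
  expect_identical(selectDual(maps, 30, 0.27), c(FALSE, FALSE, TRUE))
  expect_identical(selectDual(maps, 30, 0), rep(TRUE, 3))
  expect_identical(selectDual(maps, 30, 1), rep(FALSE, 3))
})

test_that("single-parameter calibration finds the exact TER optimum", {
  # separable lot: sound below, unsound above
  cal <- calibrateSingle(c(100, 110, 120, 130, 140),
                         c(TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_equal(minTER(cal), 0)
  expect_true(125 %in% optimalParams(cal)$max_sqi)
  expect_equal(chosenParams(cal)[["max_sqi"]], 125)

  # interleaved: best achievable is 1/3
  cal2 <- calibrateSingle(c(100, 130, 120), c(TRUE, TRUE, FALSE))
  expect_equal(minTER(cal2), 1 / 3)

  # single-class lot: optimum above the maximum, with a warning
  expect_warning(cal3 <- calibrateSingle(c(10, 20, 30), rep(TRUE, 3)),
                 "single class")
  expect_equal(minTER(cal3), 0)
  expect_gt(chosenParams(cal3)[["max_sqi"]], 30)
  expect_error(calibrateSingle(c(1, 2)), "truth")
})

test_that("threshold-sweep calibration equals exhaustive enumeration on small lots", {
  set.seed(47)
  for (i in 1:30) {
    n <- sample(2:8, 1)
    sqi <- round(runif(n, 0, 360), 1)
    truth <- sample(c(TRUE, FALSE), n, replace = TRUE)
    cal <- suppressWarnings(calibrateSingle(sqi, truth))
    expect_equal(minTER(cal), brute_force_min_ter(sqi, truth))
    # every reported optimum attains the minimum
    for (t in optimalParams(cal)$max_sqi)
      expect_equal(totalErrorRate(truth, sqi < t), minTER(cal))
  }
})

test_that("dual-parameter grid search equals a double-loop oracle on a toy lot", {
  set.seed(53)
  maps <- lapply(1:5, function(i) map_from_values(runif(30, 5, 200)))
  truth <- c(TRUE, TRUE, FALSE, FALSE, TRUE)
  cal <- calibrateDual(maps, truth)

  allv <- unlist(lapply(maps, function(m) sqiValues(m)[regionMask(m)]))
  best <- Inf; cells <- NULL
  for (m in seq(floor(min(allv)), ceiling(max(allv)), by = 1)) {
    for (p in seq(0, 1, by = 0.01)) {
      sel <- selectDual(maps, m, p)
      ter <- totalErrorRate(truth, sel)
      if (ter < best - 1e-15) { best <- ter; cells <- NULL }
      if (abs(ter - best) < 1e-15) cells <- rbind(cells, c(m, p))
    }
  }
  expect_equal(minTER(cal), best)
  expect_equal(nrow(optimalParams(cal)), nrow(cells))
  # the chosen pair is the modal maxSQI among optima and is itself optimal
  expect_equal(chosenParams(cal)[["max_sqi"]],
               min(as.numeric(names(sort(-table(cells[, 1]))[1]))))
  expect_true(any(optimalParams(cal)$max_sqi == chosenParams(cal)[["max_sqi"]] &
                  optimalParams(cal)$min_pbr == chosenParams(cal)[["min_pbr"]]))
  sel <- selectDual(maps, chosenParams(cal)[["max_sqi"]],
                    chosenParams(cal)[["min_pbr"]])
  expect_equal(totalErrorRate(truth, sel), best)

  # single-seed sound lot: any selecting cell reaches TER 0
  cal1 <- suppressWarnings(calibrateDual(maps[1], TRUE))
  expect_equal(minTER(cal1), 0)
})

test_that("N_get under the dual rule is non-decreasing in maxSQI at fixed minPBR", {
  set.seed(59)
  maps <- lapply(1:6, function(i) map_from_values(runif(40, 5, 350)))
  for (p in c(0.1, 0.4, 0.7)) {
    ngets <- vapply(seq(0, 360, by = 10),
                    function(m) sum(selectDual(maps, m, p)), numeric(1))
    expect_true(all(diff(ngets) >= 0))
  }
})

test_that("along the maxSQI sweep, SR falls, YR rises and the TER minimum is attained", {
  set.seed(61)
  sqi <- c(runif(12, 20, 90), runif(8, 120, 300))
  truth <- rep(c(TRUE, FALSE), c(12, 8))
  cal <- calibrateSingle(sqi, truth)
  curve <- terCurve(cal)
  sweep <- lapply(curve$max_sqi, function(t) selectionStats(truth, sqi < t))
  sr <- vapply(sweep, function(s) s@sr, numeric(1))
  yr <- vapply(sweep, function(s) s@yr, numeric(1))
  expect_true(all(diff(sr[!is.na(sr)]) <= 1e-12))
  expect_true(all(diff(yr) >= 0))
  expect_equal(min(curve$ter), minTER(cal))
})

test_that("cross-lot validation applies calibrated parameters unchanged", {
  set.seed(67)
  mk <- function(seed) {
    set.seed(seed)
    sqi <- c(runif(10, 10, 80), runif(8, 120, 300))
    SeedLot(1:18, sqi, rep(c("sound", "shibudane"), c(10, 8)))
  }
  a <- mk(1); b <- mk(2)
  cv <- crossValidate(a, b, "single")
  expect_equal(cv$calibrationTER, minTER(cv$calibration))
  expect_equal(cv$validationTER,
               totalErrorRate(truthClass(b) == "sound",
                              selectSingle(b, cv$params[["max_sqi"]])))
  # identical lots: validation error equals calibration error
  cvSame <- crossValidate(a, a, "single")
  expect_equal(cvSame$validationTER, cvSame$calibrationTER)
  # swapping roles transposes the report
  cvBA <- crossValidate(b, a, "single")
  calB <- calibrateSingle(b)
  expect_equal(cvBA$calibrationTER, minTER(calB))
  expect_equal(cvBA$params, chosenParams(calB))
})
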
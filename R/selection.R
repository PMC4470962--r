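# Sound-seed selection rules, their performance statistics and
# TER-minimizing threshold calibration with cross-lot validation.

#' Selection performance statistics
#'
#' Counts a selection outcome against cutting-test truth and derives the
#' five rates: initial sound-seed rate SR_init = N_OK/N, recovery rate
#' RR = N_get/N, sound-seed rate SR = N_get|OK/N_get, yield rate
#' YR = N_get|OK/N_OK, and total error rate
#' TER = (N_get + N_OK - 2 N_get|OK)/N, whose numerator is the number of
#' selected unsound plus excluded sound seeds. SR and YR are NA when
#' their denominators are zero.
#'
#' @param truthSound logical vector, TRUE for sound seeds.
#' @param selected logical vector of the same length, TRUE for selected
#'   seeds.
#' @return A \linkS4class{SelectionStats}.
#' @examples
#' truth <- rep(c(TRUE, FALSE), c(120, 60))
#' sel <- rep(c(TRUE, FALSE, TRUE, FALSE), c(119, 1, 1, 59))
#' selectionStats(truth, sel)  # the TER here is 2/180
#' @export
selectionStats <- function(truthSound, selected) {
  if (length(truthSound) != length(selected))
    stop(sprintf("flag vectors differ in length: %d vs %d",
                 length(truthSound), length(selected)))
  stopifnot(is.logical(truthSound), is.logical(selected),
            length(truthSound) >= 1L, !anyNA(truthSound), !anyNA(selected))
  n <- length(truthSound)
  nOK <- sum(truthSound)
  nGet <- sum(selected)
  nGetOK <- sum(truthSound & selected)
  new("SelectionStats",
      n = n, nOK = nOK, nNG = n - nOK, nGet = nGet, nGetOK = nGetOK,
      srInit = nOK / n,
      rr = nGet / n,
      sr = if (nGet > 0) nGetOK / nGet else NA_real_,
      yr = if (nOK > 0) nGetOK / nOK else NA_real_,
      ter = (nGet + nOK - 2 * nGetOK) / n)
}

#' Total error rate of a selection
#'
#' @inheritParams selectionStats
#' @return The TER fraction.
#' @export
totalErrorRate <- function(truthSound, selected) {
  selectionStats(truthSound, selected)@ter
}

#' Single-parameter selection rule
#'
#' Selects every seed whose areal SQI is strictly lower than
#' \code{maxSqi}.
#'
#' @param sqiAreal numeric vector of areal SQI values (degrees), or a
#'   \linkS4class{SeedLot}.
#' @param maxSqi the maxSQI threshold in degrees.
#' @return Logical selection flags.
#' @export
selectSingle <- function(sqiAreal, maxSqi) {
  if (is(sqiAreal, "SeedLot")) sqiAreal <- sqiAreal@sqiAreal
  sqiAreal < maxSqi
}

#' PBR of every seed of a lot at a given maxSQI
#'
#' @param maps list of \linkS4class{SQIMap}, or a \linkS4class{SeedLot}
#'   carrying maps.
#' @param maxSqi the maxSQI threshold in degrees.
#' @return Numeric vector of PBR fractions.
#' @export
pbrAt <- function(maps, maxSqi) {
  if (is(maps, "SeedLot")) maps <- maps@maps
  if (!length(maps)) stop("no SQI maps available")
  vapply(maps, pbr, numeric(1), maxSqi = maxSqi)
}

#' Dual-parameter selection rule
#'
#' Selects every seed whose peak-to-base area ratio at \code{maxSqi} is
#' strictly greater than \code{minPbr}; \code{maxSqi} acts only through
#' the PBR here.
#'
#' @inheritParams pbrAt
#' @param minPbr the minPBR threshold, a fraction in [0, 1].
#' @return Logical selection flags.
#' @export
selectDual <- function(maps, maxSqi, minPbr) {
  pbrAt(maps, maxSqi) > minPbr
}

.truth_sound <- function(lot) {
  if (is(lot, "SeedLot")) lot@truthClass == "sound" else as.logical(lot)
}

#' Calibrate the single-parameter threshold by TER minimization
#'
#' Sweeps candidate maxSQI thresholds over the midpoints between
#' consecutive sorted distinct areal-SQI values, plus one sentinel below
#' the minimum (select nothing) and one above the maximum (select
#' everything); this covers every distinct selection a strict threshold
#' rule can produce, so the minimum found is exact. All TER-minimizing
#' candidates are returned; the chosen threshold is the smallest.
#'
#' @param sqiAreal numeric areal SQI values, or a \linkS4class{SeedLot}
#'   with truth labels (then \code{truthSound} is taken from it).
#' @param truthSound logical truth flags (ignored when a SeedLot is
#'   given).
#' @return A \linkS4class{CalibrationResult} with the TER curve in
#'   \code{terCurve()}.
#' @export
calibrateSingle <- function(sqiAreal, truthSound = NULL) {
  if (is(sqiAreal, "SeedLot")) {
    truthSound <- .truth_sound(sqiAreal)
    sqiAreal <- sqiAreal@sqiAreal
  }
  if (is.null(truthSound)) stop("truth labels are required for calibration")
  stopifnot(length(sqiAreal) == length(truthSound), length(sqiAreal) >= 1L)
  if (all(truthSound) || !any(truthSound))
    warning("calibration lot contains a single class; ",
            "the threshold is only bounded on one side")
  v <- sort(unique(sqiAreal))
  cands <- c(v[1L] - 1,
             if (length(v) > 1L) (v[-length(v)] + v[-1L]) / 2,
             v[length(v)] + 1)
  ter <- vapply(cands, function(t) totalErrorRate(truthSound, sqiAreal < t),
                numeric(1))
  minTer <- min(ter)
  opt <- cands[ter == minTer]
  new("CalibrationResult", method = "single",
      optimal = data.frame(max_sqi = opt),
      chosen = c(max_sqi = min(opt)), minTER = minTer,
      curve = data.frame(max_sqi = cands, ter = ter))
}

.stat_mode <- function(x) {
  tab <- table(x)
  m <- names(tab)[tab == max(tab)]
  min(as.numeric(m))  # ties toward the smaller value
}

#' Calibrate the dual parameters by grid search
#'
#' Evaluates the TER of the dual rule on the full grid
#' maxSQI in [floor(min SQI_pixel), ceil(max SQI_pixel)] at steps of
#' \code{sqiStep} (default 1 degree) by minPBR in [0, 1] at steps of
#' \code{pbrStep} (default 1\%). All TER-minimizing grid cells are
#' returned; the chosen pair takes, per coordinate, the mode of the
#' optimal candidates, with ties broken toward the smaller value.
#'
#' @param maps list of \linkS4class{SQIMap}, or a \linkS4class{SeedLot}
#'   carrying maps and truth labels.
#' @param truthSound logical truth flags (ignored when a SeedLot is
#'   given).
#' @param sqiStep grid step for maxSQI in degrees (default 1).
#' @param pbrStep grid step for minPBR as a fraction (default 0.01).
#' @return A \linkS4class{CalibrationResult}; \code{terCurve()} holds the
#'   full (max_sqi, min_pbr, ter) grid.
#' @export
calibrateDual <- function(maps, truthSound = NULL, sqiStep = 1.0,
                          pbrStep = 0.01) {
  if (is(maps, "SeedLot")) {
    truthSound <- .truth_sound(maps)
    maps <- maps@maps
  }
  if (is.null(truthSound)) stop("truth labels are required for calibration")
  if (!length(maps)) stop("no SQI maps available")
  stopifnot(length(maps) == length(truthSound))
  allv <- unlist(lapply(maps, function(m) m@values[m@mask]))
  sqiGrid <- seq(floor(min(allv)), ceiling(max(allv)), by = sqiStep)
  pbrGrid <- seq(0, 1, by = pbrStep)
  if (!length(sqiGrid)) stop("empty maxSQI grid")
  nSeed <- length(maps)
  sorted <- lapply(maps, function(m) sort(m@values[m@mask]))
  sizes <- vapply(sorted, length, 1L)
  best <- Inf
  optRows <- list()
  curve <- vector("list", length(sqiGrid))
  for (gi in seq_along(sqiGrid)) {
    m <- sqiGrid[gi]
    pbrSeed <- vapply(seq_len(nSeed),
                      function(s) sum(sorted[[s]] < m) / sizes[s], numeric(1))
    sel <- outer(pbrSeed, pbrGrid, ">")            # seeds x pbr candidates
    mis <- colSums(sel != truthSound)
    ter <- mis / nSeed
    curve[[gi]] <- data.frame(max_sqi = m, min_pbr = pbrGrid, ter = ter)
    best <- min(best, min(ter))
  }
  curve <- do.call(rbind, curve)
  opt <- curve[curve$ter == best, c("max_sqi", "min_pbr")]
  rownames(opt) <- NULL
  # per-coordinate mode of the optima, constrained to an optimal pair:
  # the modal maxSQI first, then the modal minPBR among optima at it
  mSqi <- .stat_mode(opt$max_sqi)
  mPbr <- .stat_mode(opt$min_pbr[opt$max_sqi == mSqi])
  chosen <- c(max_sqi = mSqi, min_pbr = mPbr)
  new("CalibrationResult", method = "dual", optimal = opt,
      chosen = chosen, minTER = best, curve = curve)
}

#' Cross-lot validation of a calibrated selection rule
#'
#' Calibrates the selection rule on one seed lot by TER minimization and
#' applies the chosen parameter(s) unchanged to a second, independent
#' lot: the minimum TER on the first lot is the calibration error and the
#' TER obtained on the second is the validation error.
#'
#' @param calibLot,validLot \linkS4class{SeedLot} objects with truth
#'   labels (and SQI maps, for the dual method).
#' @param method \code{"single"} or \code{"dual"}.
#' @param ... passed to \code{\link{calibrateSingle}} or
#'   \code{\link{calibrateDual}}.
#' @return A list with elements \code{method}, \code{calibration}
#'   (the \linkS4class{CalibrationResult}), \code{params} (chosen),
#'   \code{calibrationStats} and \code{validationStats}
#'   (\linkS4class{SelectionStats} for self-application and for the
#'   validation lot), and \code{calibrationTER}, \code{validationTER}.
#' @export
crossValidate <- function(calibLot, validLot, method = c("single", "dual"),
                          ...) {
  method <- match.arg(method)
  stopifnot(is(calibLot, "SeedLot"), is(validLot, "SeedLot"))
  if (method == "single") {
    cal <- calibrateSingle(calibLot, ...)
    p <- cal@chosen[["max_sqi"]]
    selfSel <- selectSingle(calibLot, p)
    valSel <- selectSingle(validLot, p)
  } else {
    cal <- calibrateDual(calibLot, ...)
    p <- cal@chosen
    selfSel <- selectDual(calibLot, p[["max_sqi"]], p[["min_pbr"]])
    valSel <- selectDual(validLot, p[["max_sqi"]], p[["min_pbr"]])
  }
  calStats <- selectionStats(.truth_sound(calibLot), selfSel)
  valStats <- selectionStats(.truth_sound(validLot), valSel)
  list(method = method, calibration = cal, params = cal@chosen,
       calibrationStats = calStats, validationStats = valStats,
       calibrationTER = calStats@ter, validationTER = valStats@ter)
}

#' Write a per-seed table as TSV
#'
#' Columns: seed_id, sqi_areal, pbr (at \code{maxSqi}, NA when no maps),
#' truth_class, selected.
#'
#' @param lot a \linkS4class{SeedLot}.
#' @param path output path.
#' @param selected optional logical selection flags.
#' @param maxSqi optional maxSQI at which to tabulate PBR.
#' @return Invisibly, the path.
#' @export
writeSeedTable <- function(lot, path, selected = NA, maxSqi = NULL) {
  p <- if (!is.null(maxSqi) && length(lot@maps)) pbrAt(lot, maxSqi)
       else NA_real_
  df <- data.frame(seed_id = lot@seedId,
                   sqi_areal = lot@sqiAreal,
                   pbr = p,
                   truth_class = lot@truthClass,
                   selected = selected)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a seed truth table
#'
#' Expects a TSV with columns \code{seed_id} and \code{class} (one of
#' sound/shibudane/other/unknown).
#'
#' @param path TSV path.
#' @return data.frame with character seed_id and class.
#' @export
readTruthTable <- function(path) {
  df <- utils::read.delim(path, colClasses = "character")
  if (!all(c("seed_id", "class") %in% names(df)))
    stop("truth table must have columns 'seed_id' and 'class'")
  df
}
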
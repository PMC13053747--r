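#' @include fit.R
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames colData rowData
#' @importFrom utils read.csv write.csv
NULL

# Canonical sample ordering (row-major by y then x) so that mirrored and
# native maps on the same symmetric grid share one geometry.
.canonicalOrder <- function(map) {
  o <- order(map@y, map@x)
  initialize(map, x = map@x[o], y = map@y[o],
             thickness = map@thickness[o], mask = map@mask[o])
}

#' Normalize a map to the right-eye frame
#'
#' Left (OS) and right (OD) eyes are nasal-temporal mirror images about
#' the vertical meridian. To pool laterality, OS maps are mirror-imaged
#' (x to -x, thickness untouched) into the right-eye frame, where +x is
#' nasal and +y superior; OD maps pass through unchanged. Samples are
#' re-ordered canonically by (y, x) so mirrored and native maps on a
#' symmetric grid align. Applying it twice is an error (double-mirroring
#' guard).
#'
#' @param x A [ThicknessMap-class] or [EyeRecord-class] with frame
#'   `"native"`.
#' @return The object with every map in the `"right-eye-frame"`.
#' @export
setMethod("mirrorToRightFrame", "ThicknessMap", function(x) {
  if (x@frame != "native") {
    stop(sprintf(
      "map %s %s %s is already in the right-eye frame; refusing to mirror twice",
      x@subject, x@eye, x@date))
  }
  if (x@eye == "OS") x@x <- -x@x
  x@frame <- "right-eye-frame"
  .canonicalOrder(x)
})

#' @rdname mirrorToRightFrame
#' @export
setMethod("mirrorToRightFrame", "EyeRecord", function(x) {
  x@maps <- lapply(x@maps, mirrorToRightFrame)
  x
})

#' Average same-day scans into one map per eye-date
#'
#' Pointwise mean over masked-in values: a position is masked-in in the
#' average iff it is masked-in for at least one scan, and its value is the
#' mean over the scans where it is available.
#'
#' @param maps A list of [ThicknessMap-class] scans, or an
#'   [EyeRecord-class]; all scans must share grid geometry and identity.
#' @return A single [ThicknessMap-class] (for an EyeRecord input, the
#'   record with its maps replaced by the average).
#' @export
averageSameDay <- function(maps) {
  if (is(maps, "EyeRecord")) {
    maps@maps <- list(averageSameDay(maps@maps))
    return(maps)
  }
  stopifnot(length(maps) >= 1)
  first <- maps[[1]]
  if (length(maps) == 1) return(first)
  for (m in maps[-1]) {
    if (length(m@x) != length(first@x) ||
        !isTRUE(all.equal(m@x, first@x, tolerance = 1e-9)) ||
        !isTRUE(all.equal(m@y, first@y, tolerance = 1e-9))) {
      stop(sprintf(
        "cannot average scans with mismatched grids for %s %s %s",
        first@subject, first@eye, first@date))
    }
    if (m@subject != first@subject || m@eye != first@eye ||
        m@date != first@date || m@frame != first@frame) {
      stop("same-day averaging requires scans from one (subject, eye, date) in one frame")
    }
  }
  vals <- vapply(maps, function(m) {
    v <- m@thickness
    v[!m@mask] <- NA_real_
    v
  }, numeric(length(first@x)))
  avg <- rowMeans(vals, na.rm = TRUE)
  mask <- rowSums(!is.na(vals)) > 0
  avg[!mask] <- NA_real_
  initialize(first, thickness = avg, mask = mask)
}

#' Crop a map to the central optical zone
#'
#' Masks out every sample whose pixel-center radius exceeds half the given
#' diameter (closed disk: centers exactly on the rim participate).
#'
#' @param x A [ThicknessMap-class] or [EyeRecord-class].
#' @param diameter Zone diameter in mm (default 5, the central 5-mm
#'   optical zone).
#' @return The object with out-of-zone samples masked out.
#' @export
setMethod("cropZone", "ThicknessMap", function(x, diameter = 5) {
  stopifnot(diameter > 0)
  keep <- sqrt(x@x^2 + x@y^2) <= diameter / 2 + 1e-9
  newMask <- x@mask & keep
  if (!any(newMask)) {
    stop(sprintf("cropping to %.3g mm removed every sample of %s %s %s",
                 diameter, x@subject, x@eye, x@date))
  }
  x@mask <- newMask
  x
})

#' @rdname cropZone
#' @export
setMethod("cropZone", "EyeRecord", function(x, diameter = 5) {
  x@maps <- lapply(x@maps, cropZone, diameter = diameter)
  x
})

#' Read and write the long-format map table
#'
#' The interchange format is a long CSV with columns `subject_id`, `eye`,
#' `date`, `device`, `scan`, `x_mm`, `y_mm`, `thickness_um` (NA/NaN
#' allowed and masked out). `readMapTable()` returns a list of
#' [EyeRecord-class] objects, one per (subject, eye, date), each holding
#' its same-day scans; nonpositive thickness values are rejected.
#'
#' @param path CSV path.
#' @param records For `writeMapTable()`, a list of [EyeRecord-class].
#' @return `readMapTable()`: list of [EyeRecord-class];
#'   `writeMapTable()`: the path, invisibly.
#' @export
readMapTable <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "eye", "date", "device", "x_mm", "y_mm",
            "thickness_um")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("map table is missing columns: ", paste(miss, collapse = ", "))
  }
  if (is.null(df$scan)) df$scan <- 1L
  bad <- is.finite(df$thickness_um) & df$thickness_um <= 0
  if (any(bad)) {
    stop(sprintf("%d thickness value(s) are nonpositive; epithelial thickness must be > 0 um",
                 sum(bad)))
  }
  keys <- interaction(df$subject_id, df$eye, df$date, drop = TRUE)
  lapply(split(df, keys), function(d) {
    maps <- lapply(split(d, d$scan), function(s) {
      thicknessMap(s$x_mm, s$y_mm, s$thickness_um,
                   mask = is.finite(s$thickness_um),
                   subject = s$subject_id[1], eye = s$eye[1],
                   date = s$date[1], device = s$device[1], frame = "native")
    })
    eyeRecord(d$subject_id[1], d$eye[1], d$date[1], d$device[1],
              unname(maps))
  })
}

#' @rdname readMapTable
#' @export
writeMapTable <- function(records, path) {
  rows <- lapply(records, function(rec) {
    do.call(rbind, lapply(seq_along(rec@maps), function(i) {
      m <- rec@maps[[i]]
      th <- m@thickness
      th[!m@mask] <- NA_real_
      data.frame(subject_id = rec@subject, eye = rec@eye, date = rec@date,
                 device = rec@device, scan = i, x_mm = m@x, y_mm = m@y,
                 thickness_um = th)
    }))
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE, na = "NaN")
  invisible(path)
}

#' Assemble a cohort coefficient table
#'
#' @param fits List of [ZernikeCoefficients-class], one per eye-date.
#' @param info data.frame with one row per fit: `subject`, `eye`, `date`,
#'   `device`.
#' @return A [CohortCoefficients-class] (terms x eyes
#'   SummarizedExperiment).
#' @export
cohortCoefficients <- function(fits, info) {
  stopifnot(length(fits) == nrow(info))
  M <- vapply(fits, coef, numeric(length(coef(fits[[1]]))))
  colnames(M) <- sprintf("%s_%s_%s", info$subject, info$eye, info$date)
  terms <- zernikeTermTable(fits[[1]]@maxOrder)
  cd <- DataFrame(subject = info$subject, eye = info$eye, date = info$date,
                  device = info$device,
                  rmse = vapply(fits, fitRMSE, numeric(1)),
                  n_samples = vapply(fits, nSamples, numeric(1)),
                  row.names = colnames(M))
  se <- SummarizedExperiment(assays = list(coefficients = M),
                             rowData = DataFrame(terms), colData = cd)
  out <- new("CohortCoefficients", se)
  metadata(out)$zoneRadius <- fits[[1]]@zoneRadius
  metadata(out)$maxOrder <- fits[[1]]@maxOrder
  out
}

#' @describeIn accessors The terms x eyes coefficient matrix (um) of a
#'   cohort.
#' @export
setMethod("coefMatrix", "CohortCoefficients", function(x) {
  assay(x, "coefficients")
})

#' @rdname accessors
#' @export
setMethod("zoneRadius", "CohortCoefficients", function(x) {
  metadata(x)$zoneRadius
})

#' Run the map-processing pipeline over a cohort
#'
#' For each eye-date record: normalize laterality to the right-eye frame,
#' average same-day scans into one map, crop to the analytical zone, and
#' fit the Zernike expansion. Records sharing grid geometry are fitted in
#' one batched solve.
#'
#' @param records List of [EyeRecord-class] (e.g. from [readMapTable()] or
#'   [generateCohort()]).
#' @param zoneDiameter Analytical zone diameter (mm).
#' @param maxOrder Maximum radial order of the fit.
#' @param exclude Optional data.frame with columns `subject`, `eye`,
#'   `date` (and optionally `reason`) of eye-dates to drop before fitting,
#'   e.g. after artifact review.
#' @return A [CohortCoefficients-class].
#' @export
fitCohort <- function(records, zoneDiameter = 5, maxOrder = 5,
                      exclude = NULL) {
  if (!is.null(exclude) && nrow(exclude)) {
    keys <- vapply(records, function(r)
      paste(r@subject, r@eye, r@date, sep = "|"), character(1))
    drop <- paste(exclude$subject, exclude$eye, exclude$date, sep = "|")
    missing <- setdiff(drop, keys)
    if (length(missing)) {
      stop("exclusion list names eye-dates absent from the cohort: ",
           paste(missing, collapse = "; "))
    }
    records <- records[!keys %in% drop]
  }
  if (length(records) == 0) stop("no eye records to fit")
  maps <- lapply(records, function(rec) {
    rec <- mirrorToRightFrame(rec)
    rec <- averageSameDay(rec)
    cropZone(rec@maps[[1]], diameter = zoneDiameter)
  })
  fits <- fitMaps(maps, zoneRadius = zoneDiameter / 2, maxOrder = maxOrder)
  info <- data.frame(
    subject = vapply(records, function(r) r@subject, character(1)),
    eye = vapply(records, function(r) r@eye, character(1)),
    date = vapply(records, function(r) r@date, character(1)),
    device = vapply(records, function(r) r@device, character(1)))
  cohortCoefficients(fits, info)
}

#' Flag eyes with outlying Zernike coefficients
#'
#' Advisory quality-control screen mirroring a manual artifact review: an
#' eye is flagged when any of the listed terms deviates from the cohort
#' mean by more than `k` cohort SDs. Flags never exclude by themselves;
#' exclusion happens through the `exclude` argument of [fitCohort()].
#'
#' @param cohort A [CohortCoefficients-class] with at least 3 eyes.
#' @param terms ANSI j indices to screen (default the single-angular-
#'   frequency terms of interest: tilt j = 1, 2 and primary coma j = 7, 8).
#' @param k SD multiple (default 3).
#' @return data.frame of flagged eyes with columns `subject`, `eye`,
#'   `date`, `term`, `value`, `zscore`; zero rows when nothing is
#'   flagged.
#' @export
flagOutliers <- function(cohort, terms = c(1, 2, 7, 8), k = 3) {
  M <- coefMatrix(cohort)
  if (ncol(M) < 3) stop("outlier screening needs at least 3 eyes")
  cd <- colData(cohort)
  out <- list()
  for (j in terms) {
    v <- M[j + 1, ]
    s <- stats::sd(v)
    if (s == 0) next
    z <- (v - mean(v)) / s
    hit <- which(abs(z) > k)
    if (length(hit)) {
      out[[length(out) + 1]] <- data.frame(
        subject = cd$subject[hit], eye = cd$eye[hit], date = cd$date[hit],
        term = sprintf("c_j%d", j), value = unname(v[hit]),
        zscore = unname(z[hit]))
    }
  }
  if (length(out) == 0) {
    return(data.frame(subject = character(), eye = character(),
                      date = character(), term = character(),
                      value = numeric(), zscore = numeric()))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write the per-eye coefficient table
#'
#' One row per eye-date with columns `subject_id`, `eye`, `date`,
#' `device`, `c_j0`..`c_jK` (um), `rmse_um`, `n_samples`.
#'
#' @param cohort A [CohortCoefficients-class].
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
writeCoefficientTable <- function(cohort, path) {
  M <- t(coefMatrix(cohort))
  cd <- as.data.frame(colData(cohort))
  df <- cbind(data.frame(subject_id = cd$subject, eye = cd$eye,
                         date = cd$date, device = cd$device),
              as.data.frame(M),
              data.frame(rmse_um = cd$rmse, n_samples = cd$n_samples))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a coefficient table written by [writeCoefficientTable()]
#'
#' @param path CSV path.
#' @param zoneRadius,maxOrder Fit geometry recorded with the table.
#' @return A [CohortCoefficients-class].
#' @export
readCoefficientTable <- function(path, zoneRadius = 2.5, maxOrder = 5) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  jcols <- grep("^c_j[0-9]+$", names(df), value = TRUE)
  jcols <- jcols[order(as.integer(sub("c_j", "", jcols)))]
  fits <- lapply(seq_len(nrow(df)), function(i) {
    zernikeCoefficients(as.numeric(df[i, jcols]), zoneRadius = zoneRadius,
                        maxOrder = maxOrder, rmse = df$rmse_um[i],
                        nSamples = df$n_samples[i])
  })
  cohortCoefficients(fits, data.frame(subject = as.character(df$subject_id),
                                      eye = df$eye,
                                      date = as.character(df$date),
                                      device = df$device))
}
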
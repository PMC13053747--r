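#' @include stats.R
#' @importFrom MASS mvrnorm
NULL

#' Default population parameters of the synthetic cohort
#'
#' The simulated healthy-eye population matches the published normative
#' cohort: 135 eyes of 69 subjects, mean single-angular-frequency
#' coefficients (um) Y-tilt -1.13, X-tilt 0.60, Y-coma 0.16, X-coma
#' -0.14 with SDs 1.55, 0.76, 0.62, 0.38, mixed OD/OS laterality and
#' multiple same-day scans per eye. All other terms default to mean 0;
#' only the four reported terms carry variance by default. A correlation
#' of 0.27 between tilt and sign-flipped coma components emulates the
#' reported biomarker correlation.
#'
#' @param nSubjects Number of subjects (default 69).
#' @param eyesPerSubject 1 or 2 (default 2).
#' @param nEyes Eyes kept after truncating the roster (default 135).
#' @param scansPerEye Same-day scans per eye (default 2).
#' @param meanCoefficients 21-vector of coefficient means (um).
#' @param sds 21-vector of coefficient SDs (um), used when `covariance`
#'   is not supplied.
#' @param tiltComaCor Correlation applied between each tilt component and
#'   the corresponding sign-flipped coma component (default 0.27).
#' @param covariance Full 21 x 21 covariance; overrides `sds` and
#'   `tiltComaCor`.
#' @param pixelNoiseSD Per-pixel, per-scan noise SD (um, default 0.5:
#'   with two same-day scans averaged, Zernike fits to the averaged maps
#'   then leave a residual RMSE of about 0.5/sqrt(2) ~ 0.35 um, the level
#'   typical of spectral-domain OCT epithelium maps).
#' @param baselineThickness Central thickness (um) placed in the piston
#'   term (default 53).
#' @param gridExtent,gridSpacing Square pixel grid (mm), default 6 mm at
#'   0.05 mm pitch (the devices' 6-mm scan extent).
#' @param seed RNG seed (default 1).
#' @return A [PopulationSpec-class].
#' @export
populationSpec <- function(nSubjects = 69, eyesPerSubject = 2, nEyes = 135,
                           scansPerEye = 2,
                           meanCoefficients = NULL, sds = NULL,
                           tiltComaCor = 0.27, covariance = NULL,
                           pixelNoiseSD = 0.5, baselineThickness = 53,
                           gridExtent = 6, gridSpacing = 0.05, seed = 1) {
  if (is.null(meanCoefficients)) {
    meanCoefficients <- numeric(21)
    meanCoefficients[0 + 1] <- baselineThickness  # c_j0
    meanCoefficients[1 + 1] <- -1.13              # c_j1 Y-tilt
    meanCoefficients[2 + 1] <- 0.60               # c_j2 X-tilt
    meanCoefficients[7 + 1] <- 0.16               # c_j7 Y-coma
    meanCoefficients[8 + 1] <- -0.14              # c_j8 X-coma
  }
  k <- length(meanCoefficients)
  if (is.null(covariance)) {
    if (is.null(sds)) {
      sds <- numeric(k)
      sds[1 + 1] <- 1.55  # Y-tilt
      sds[2 + 1] <- 0.76  # X-tilt
      sds[7 + 1] <- 0.62  # Y-coma
      sds[8 + 1] <- 0.38  # X-coma
    }
    covariance <- diag(sds^2, k)
    # coma vectors are sign-flipped downstream, so a positive biomarker
    # correlation corresponds to negative raw tilt-coma covariance
    covariance[2, 8] <- covariance[8, 2] <- -tiltComaCor * sds[2] * sds[8]
    covariance[3, 9] <- covariance[9, 3] <- -tiltComaCor * sds[3] * sds[9]
  }
  new("PopulationSpec", nSubjects = nSubjects,
      eyesPerSubject = eyesPerSubject, nEyes = nEyes,
      scansPerEye = scansPerEye, meanCoefficients = meanCoefficients,
      covariance = covariance, pixelNoiseSD = pixelNoiseSD,
      gridExtent = gridExtent, gridSpacing = gridSpacing, seed = seed)
}

setMethod("show", "PopulationSpec", function(object) {
  cat(sprintf(
    "PopulationSpec: %d eyes of %d subjects, %d scan(s)/eye, %g x %g mm grid @ %g mm, pixel noise SD %g um, seed %d\n",
    object@nEyes, object@nSubjects, object@scansPerEye, object@gridExtent,
    object@gridExtent, object@gridSpacing, object@pixelNoiseSD,
    as.integer(object@seed)))
})

#' Generate a synthetic cohort of thickness maps
#'
#' Draws one true coefficient vector per eye from the multivariate normal
#' of the [PopulationSpec-class], renders each eye's map on the Cartesian
#' grid in the right-eye frame, mirrors x for eyes assigned OS (so the
#' processing pipeline must undo the mirroring), and adds i.i.d. per-pixel
#' noise independently to each same-day scan. Laterality alternates
#' OD/OS: two-eye subjects contribute one of each. Deterministic under a
#' fixed seed.
#'
#' @param spec A [PopulationSpec-class].
#' @return A list with `records` (list of [EyeRecord-class], frame
#'   `"native"`) and `truth` (data.frame: subject, eye, date and the true
#'   `c_j0`..`c_j20` per eye).
#' @examples
#' sim <- generateCohort(populationSpec(nSubjects = 3, nEyes = 5,
#'                                      gridSpacing = 0.5))
#' length(sim$records)  # 5
#' @export
generateCohort <- function(spec) {
  stopifnot(is(spec, "PopulationSpec"))
  .withSeed(spec@seed, {
    roster <- .eyeRoster(spec)
    n <- nrow(roster)
    k <- length(spec@meanCoefficients)
    truthM <- MASS::mvrnorm(n, mu = spec@meanCoefficients,
                            Sigma = spec@covariance)
    truthM <- matrix(truthM, nrow = n, ncol = k)
    g <- mapGrid(spec@gridExtent, spec@gridSpacing)
    # coefficients are defined on the 2.5 mm analytical zone; the grid
    # extends beyond it, so render with the polynomially extended basis
    B <- .renderBasis(g$x, g$y, maxOrder = 5)
    clean <- truthM %*% t(B)  # eyes x pixels, right-eye frame
    records <- vector("list", n)
    for (i in seq_len(n)) {
      xs <- if (roster$eye[i] == "OS") -g$x else g$x
      maps <- lapply(seq_len(spec@scansPerEye), function(s) {
        th <- clean[i, ] + stats::rnorm(ncol(clean), 0, spec@pixelNoiseSD)
        thicknessMap(xs, g$y, th, mask = rep(TRUE, length(xs)),
                     subject = roster$subject[i], eye = roster$eye[i],
                     date = roster$date[i], device = roster$device[i],
                     frame = "native")
      })
      records[[i]] <- eyeRecord(roster$subject[i], roster$eye[i],
                                roster$date[i], roster$device[i], maps)
    }
    colnames(truthM) <- sprintf("c_j%d", seq_len(k) - 1)
    truth <- cbind(roster[, c("subject", "eye", "date")],
                   as.data.frame(truthM))
    list(records = records, truth = truth)
  })
}

# The rendering basis: Zernike terms normalized on the 2.5 mm analytical
# zone, evaluated on the full grid by plain polynomial extension (the
# radial polynomials are defined for rho > 1 as well; fitting only ever
# sees rho <= 1).
.renderBasis <- function(x, y, zoneRadius = 2.5, maxOrder = 5) {
  rho <- sqrt(x^2 + y^2) / zoneRadius
  theta <- atan2(y, x)
  terms <- zernikeTermTable(maxOrder)
  B <- matrix(NA_real_, length(x), nrow(terms))
  for (i in seq_len(nrow(terms))) {
    n <- terms$n[i]; m <- terms$m[i]
    nf <- sqrt(2 * (n + 1) / (1 + (m == 0)))
    ang <- if (m > 0) cos(m * theta)
           else if (m < 0) sin(-m * theta)
           else rep(1, length(theta))
    B[, i] <- nf * .zernikeRadial(n, abs(m), rho) * ang
  }
  colnames(B) <- sprintf("c_j%d", terms$j)
  B
}

.eyeRoster <- function(spec) {
  subjects <- sprintf("sub%03d", seq_len(spec@nSubjects))
  if (spec@eyesPerSubject == 2) {
    roster <- data.frame(
      subject = rep(subjects, each = 2),
      eye = rep(c("OD", "OS"), spec@nSubjects))
  } else {
    roster <- data.frame(subject = subjects,
                         eye = rep(c("OD", "OS"),
                                   length.out = spec@nSubjects))
  }
  roster <- roster[seq_len(min(spec@nEyes, nrow(roster))), , drop = FALSE]
  roster$date <- "2024-01-01"
  roster$device <- rep(c("Avanti", "Solix"), length.out = nrow(roster))
  rownames(roster) <- NULL
  roster
}

#' Inject segmentation-artifact-like corruption into a cohort
#'
#' Emulates identifiable segmentation artifacts for quality-control
#' testing: a random subset of eyes receives a uniform thickness offset
#' over a 90-degree wedge at a random orientation, on every scan. The
#' wedge projects onto the tilt terms with gain 2*sqrt(2)/(3*pi) ~ 0.30,
#' so the default 50 um amplitude shifts the fitted tilt by roughly ten
#' population SDs - far outside the healthy distribution, as a
#' segmentation failure would be.
#'
#' @param records List of [EyeRecord-class].
#' @param fraction Fraction of eyes to corrupt, in [0, 1].
#' @param amplitude Wedge thickness offset (um, default 50).
#' @param seed RNG seed for the selection and orientations.
#' @return A list with `records` (modified) and `corrupted` (data.frame
#'   of subject, eye, date, wedge orientation) naming the ground truth.
#' @export
degradeWithArtifacts <- function(records, fraction, amplitude = 50,
                                 seed = 1) {
  stopifnot(fraction >= 0, fraction <= 1)
  n <- length(records)
  nBad <- round(fraction * n)
  if (nBad == 0) {
    return(list(records = records,
                corrupted = data.frame(subject = character(),
                                       eye = character(),
                                       date = character(),
                                       wedge_deg = numeric())))
  }
  .withSeed(seed, {
    idx <- sort(sample.int(n, nBad))
    wedge <- stats::runif(nBad, 0, 360)
    for (q in seq_along(idx)) {
      i <- idx[q]
      rec <- records[[i]]
      rec@maps <- lapply(rec@maps, function(m) {
        ang <- wrapAngle(.rad2deg(atan2(m@y, m@x)))
        hit <- abs(angularDifference(ang, wedge[q])) <= 45
        m@thickness[hit] <- m@thickness[hit] + amplitude
        m
      })
      records[[i]] <- rec
    }
    corrupted <- data.frame(
      subject = vapply(records[idx], function(r) r@subject, character(1)),
      eye = vapply(records[idx], function(r) r@eye, character(1)),
      date = vapply(records[idx], function(r) r@date, character(1)),
      wedge_deg = wedge)
    list(records = records, corrupted = corrupted)
  })
}
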
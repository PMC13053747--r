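#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' Corneal epithelial thickness map
#'
#' A scalar field of epithelial thickness samples (um) at Cartesian
#' positions (mm) relative to the zone center, with a per-sample validity
#' mask and acquisition metadata. Positions use the analysis convention:
#' degrees counterclockwise from +x, +x nasal and +y superior once the map
#' is in the right-eye frame.
#'
#' @slot x,y Sample positions in mm relative to the zone center.
#' @slot thickness Thickness values in um (NaN allowed where masked out).
#' @slot mask Logical validity flag per sample; only masked-in samples
#'   participate in fitting.
#' @slot subject,eye,date,device Acquisition metadata; `eye` is "OD" or "OS".
#' @slot frame Either `"native"` (as acquired) or `"right-eye-frame"`
#'   (after laterality normalization).
#'
#' @seealso [thicknessMap()], [mirrorToRightFrame()], [cropZone()], [fitMap()]
#' @export
setClass("ThicknessMap",
  representation(
    x = "numeric", y = "numeric", thickness = "numeric", mask = "logical",
    subject = "character", eye = "character", date = "character",
    device = "character", frame = "character"
  )
)

setValidity("ThicknessMap", function(object) {
  n <- length(object@x)
  msg <- character()
  if (length(object@y) != n || length(object@thickness) != n ||
      length(object@mask) != n) {
    msg <- c(msg, "x, y, thickness and mask must have equal length")
  }
  if (!object@eye %in% c("OD", "OS")) {
    msg <- c(msg, "eye must be 'OD' or 'OS'")
  }
  if (!object@frame %in% c("native", "right-eye-frame")) {
    msg <- c(msg, "frame must be 'native' or 'right-eye-frame'")
  }
  if (length(object@mask) == n && n > 0) {
    v <- object@thickness[object@mask]
    if (anyNA(v) || any(!is.finite(v))) {
      msg <- c(msg, "masked-in thickness values must be finite")
    }
    if (anyNA(object@x) || anyNA(object@y)) {
      msg <- c(msg, "sample positions must be finite")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a ThicknessMap
#'
#' @param x,y Sample positions (mm).
#' @param thickness Thickness values (um).
#' @param mask Logical validity flags; defaults to finite thickness.
#' @param subject,eye,date,device Metadata strings.
#' @param frame `"native"` or `"right-eye-frame"`.
#' @return A [ThicknessMap-class] object.
#' @examples
#' g <- mapGrid(6, 0.5)
#' m <- thicknessMap(g$x, g$y, rep(53, nrow(g)), subject = "s1")
#' @export
thicknessMap <- function(x, y, thickness, mask = is.finite(thickness),
                         subject = "unknown", eye = "OD",
                         date = "1970-01-01", device = "synthetic",
                         frame = "native") {
  new("ThicknessMap",
    x = as.numeric(x), y = as.numeric(y),
    thickness = as.numeric(thickness), mask = as.logical(mask),
    subject = as.character(subject), eye = as.character(eye),
    date = as.character(date), device = as.character(device),
    frame = as.character(frame)
  )
}

#' One eye on one day: a set of same-day scans
#'
#' @slot subject,eye,date,device Identity of the eye-date.
#' @slot maps List of [ThicknessMap-class] scans acquired that day.
#' @export
setClass("EyeRecord",
  representation(
    subject = "character", eye = "character", date = "character",
    device = "character", maps = "list"
  )
)

setValidity("EyeRecord", function(object) {
  ok <- vapply(object@maps, is, logical(1), class2 = "ThicknessMap")
  if (length(object@maps) < 1) return("an EyeRecord needs at least one map")
  if (!all(ok)) return("maps must all be ThicknessMap objects")
  TRUE
})

#' Construct an EyeRecord
#'
#' @param subject,eye,date,device Identity metadata.
#' @param maps List of [ThicknessMap-class] scans.
#' @return An [EyeRecord-class] object.
#' @export
eyeRecord <- function(subject, eye, date, device, maps) {
  new("EyeRecord", subject = as.character(subject), eye = as.character(eye),
      date = as.character(date), device = as.character(device), maps = maps)
}

#' Zernike coefficient vector for one fitted map
#'
#' Holds the ANSI-ordered (single index j = (n(n+2)+m)/2) Zernike
#' coefficients of a thickness map over a circular analytical zone,
#' together with the fit residual.
#'
#' @slot coefficients Named numeric vector (um), names `c_j0`..`c_jK`.
#' @slot zoneRadius Zone radius in mm (2.5 for the 5-mm optical zone).
#' @slot maxOrder Maximum radial order fitted.
#' @slot rmse Root mean square residual of the fit (um).
#' @slot nSamples Number of masked-in samples used.
#' @export
setClass("ZernikeCoefficients",
  representation(
    coefficients = "numeric", zoneRadius = "numeric", maxOrder = "numeric",
    rmse = "numeric", nSamples = "numeric"
  )
)

setValidity("ZernikeCoefficients", function(object) {
  k <- (object@maxOrder + 1) * (object@maxOrder + 2) / 2
  msg <- character()
  if (length(object@coefficients) != k) {
    msg <- c(msg, sprintf(
      "expected %d coefficients for max radial order %d, got %d",
      k, object@maxOrder, length(object@coefficients)))
  }
  if (object@zoneRadius <= 0) msg <- c(msg, "zoneRadius must be > 0")
  if (object@rmse < 0) msg <- c(msg, "rmse must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct a ZernikeCoefficients object
#'
#' @param coefficients Numeric vector of length (maxOrder+1)(maxOrder+2)/2,
#'   ANSI order j = 0, 1, ....
#' @param zoneRadius Zone radius (mm).
#' @param maxOrder Maximum radial order.
#' @param rmse Fit root-mean-square residual (um).
#' @param nSamples Number of samples used in the fit.
#' @return A [ZernikeCoefficients-class] object.
#' @examples
#' z <- zernikeCoefficients(c(53, -1.13, 0.60, rep(0, 18)))
#' coef(z)[["c_j1"]]
#' @export
zernikeCoefficients <- function(coefficients, zoneRadius = 2.5, maxOrder = 5,
                                rmse = 0, nSamples = length(coefficients)) {
  coefficients <- as.numeric(coefficients)
  names(coefficients) <- sprintf("c_j%d", seq_along(coefficients) - 1)
  new("ZernikeCoefficients", coefficients = coefficients,
      zoneRadius = zoneRadius, maxOrder = maxOrder, rmse = rmse,
      nSamples = nSamples)
}

#' Cohort-level Zernike coefficient table
#'
#' A [SummarizedExperiment-class] subclass holding one fitted coefficient
#' vector per eye-date: the `"coefficients"` assay is terms x eyes (um),
#' `rowData` carries the ANSI index table (j, n, m, label), and `colData`
#' carries subject, eye, date, device, fit RMSE and sample counts.
#'
#' @seealso [fitCohort()], [coefMatrix()], [lidWiperAxes()]
#' @export
setClass("CohortCoefficients", contains = "SummarizedExperiment")

setValidity("CohortCoefficients", function(object) {
  if (!"coefficients" %in% SummarizedExperiment::assayNames(object)) {
    return("assay 'coefficients' is required")
  }
  cd <- SummarizedExperiment::colData(object)
  need <- c("subject", "eye", "date", "device", "rmse", "n_samples")
  miss <- setdiff(need, colnames(cd))
  if (length(miss)) {
    return(paste("missing colData columns:", paste(miss, collapse = ", ")))
  }
  TRUE
})

#' Polar representation of a 2-D vector
#'
#' Magnitude (um) and angle (degrees counterclockwise from +x, wrapped to
#' [0, 360)). A zero vector is representable: it carries `degenerate = TRUE`
#' and reports angle 0 rather than an arbitrary direction.
#'
#' @slot magnitude Vector length (um), >= 0.
#' @slot angle Direction in degrees, [0, 360).
#' @slot degenerate TRUE when the underlying vector is exactly zero.
#' @export
setClass("PolarVector",
  representation(magnitude = "numeric", angle = "numeric",
                 degenerate = "logical")
)

setValidity("PolarVector", function(object) {
  msg <- character()
  if (object@magnitude < 0) msg <- c(msg, "magnitude must be >= 0")
  if (object@angle < 0 || object@angle >= 360) {
    msg <- c(msg, "angle must lie in [0, 360)")
  }
  if (length(msg)) msg else TRUE
})

#' Population lid-wiper axes
#'
#' Directions (degrees) of the cohort mean tilt vector and the cohort mean
#' sign-flipped coma vector, with the circular standard deviations of the
#' per-eye vector angles.
#'
#' @slot tiltLWA,comaLWA Axis angles in degrees, [0, 360).
#' @slot tiltCircSD,comaCircSD Circular SDs of per-eye angles (degrees).
#' @export
setClass("LidWiperAxes",
  representation(tiltLWA = "numeric", comaLWA = "numeric",
                 tiltCircSD = "numeric", comaCircSD = "numeric")
)

setValidity("LidWiperAxes", function(object) {
  a <- c(object@tiltLWA, object@comaLWA)
  if (any(a < 0 | a >= 360)) return("axis angles must lie in [0, 360)")
  if (any(c(object@tiltCircSD, object@comaCircSD) < 0)) {
    return("circular SDs must be >= 0")
  }
  TRUE
})

#' Bivariate confidence ellipse
#'
#' @slot center Ellipse center (2-vector).
#' @slot semiAxes Semi-axis lengths, major first.
#' @slot orientation Major-axis direction in degrees, [0, 180).
#' @slot level Confidence level in (0, 1).
#' @slot ofMean TRUE for the centroid (standard-error) ellipse, FALSE for
#'   the data ellipse.
#' @slot n Number of points the ellipse summarizes.
#' @export
setClass("EllipseSpec",
  representation(center = "numeric", semiAxes = "numeric",
                 orientation = "numeric", level = "numeric",
                 ofMean = "logical", n = "numeric")
)

setValidity("EllipseSpec", function(object) {
  msg <- character()
  if (length(object@center) != 2) msg <- c(msg, "center must be a 2-vector")
  if (any(object@semiAxes <= 0)) msg <- c(msg, "semi-axes must be > 0")
  if (object@level <= 0 || object@level >= 1) {
    msg <- c(msg, "level must lie in (0, 1)")
  }
  if (length(msg)) msg else TRUE
})

#' Result of a normality-gated location test
#'
#' @slot label Term or comparison label.
#' @slot test Chosen test name.
#' @slot statistic Test statistic.
#' @slot p Raw p value.
#' @slot pAdjusted Bonferroni-adjusted p value, min(1, p * familySize).
#' @slot normalityP Shapiro-Wilk p value used for the gate.
#' @slot n Sample size.
#' @slot degenerate TRUE when the comparison was degenerate (e.g. all
#'   paired differences zero) and no test was run.
#' @export
setClass("TestResult",
  representation(label = "character", test = "character",
                 statistic = "numeric", p = "numeric", pAdjusted = "numeric",
                 normalityP = "numeric", n = "numeric",
                 degenerate = "logical")
)

setValidity("TestResult", function(object) {
  if (!object@degenerate && !is.na(object@p) && !is.na(object@pAdjusted) &&
      object@pAdjusted < object@p - 1e-12) {
    return("adjusted p must be >= raw p")
  }
  TRUE
})

#' Simple linear regression summary for biomarker correlations
#'
#' @slot slope Slope of y on x (units of y per unit of x).
#' @slot intercept Intercept.
#' @slot r Pearson correlation coefficient.
#' @slot r2 Coefficient of determination; equals r^2 for simple OLS.
#' @slot p Two-sided p value for zero slope.
#' @slot n Number of (x, y) pairs.
#' @export
setClass("RegressionResult",
  representation(slope = "numeric", intercept = "numeric", r = "numeric",
                 r2 = "numeric", p = "numeric", n = "numeric")
)

setValidity("RegressionResult", function(object) {
  msg <- character()
  if (abs(object@r) > 1 + 1e-12) msg <- c(msg, "|r| must be <= 1")
  if (abs(object@r2 - object@r^2) > 1e-8) {
    msg <- c(msg, "r2 must equal r squared")
  }
  if (length(msg)) msg else TRUE
})

#' Synthetic cohort population specification
#'
#' Distributional description of a simulated healthy-eye cohort: eye-level
#' Zernike coefficients are multivariate normal across eyes, maps are
#' rendered on a Cartesian grid in the right-eye frame (then mirrored for
#' OS eyes), and each scan receives i.i.d. per-pixel measurement noise.
#'
#' @slot nSubjects Number of subjects.
#' @slot eyesPerSubject 1 or 2 eyes contributed per subject.
#' @slot nEyes Total eyes kept (truncates the subject x eye roster).
#' @slot scansPerEye Same-day scans per eye.
#' @slot meanCoefficients Mean coefficient vector (um), ANSI order, 21 terms.
#' @slot covariance 21 x 21 between-eye coefficient covariance (um^2).
#' @slot pixelNoiseSD Per-pixel measurement noise SD (um).
#' @slot gridExtent,gridSpacing Square grid extent and pixel pitch (mm).
#' @slot seed RNG seed for reproducible generation.
#' @export
setClass("PopulationSpec",
  representation(
    nSubjects = "numeric", eyesPerSubject = "numeric", nEyes = "numeric",
    scansPerEye = "numeric", meanCoefficients = "numeric",
    covariance = "matrix", pixelNoiseSD = "numeric",
    gridExtent = "numeric", gridSpacing = "numeric", seed = "numeric"
  )
)

setValidity("PopulationSpec", function(object) {
  msg <- character()
  if (!object@eyesPerSubject %in% c(1, 2)) {
    msg <- c(msg, "eyesPerSubject must be 1 or 2")
  }
  if (object@gridSpacing <= 0) msg <- c(msg, "gridSpacing must be > 0")
  if (object@pixelNoiseSD < 0) msg <- c(msg, "pixelNoiseSD must be >= 0")
  k <- length(object@meanCoefficients)
  if (!all(dim(object@covariance) == c(k, k))) {
    msg <- c(msg, "covariance must be square and match meanCoefficients")
  } else {
    if (max(abs(object@covariance - t(object@covariance))) > 1e-8) {
      msg <- c(msg, "covariance must be symmetric")
    } else if (min(eigen(object@covariance, symmetric = TRUE,
                         only.values = TRUE)$values) < -1e-8) {
      msg <- c(msg, "covariance must be positive semi-definite")
    }
  }
  if (object@nEyes > object@nSubjects * object@eyesPerSubject) {
    msg <- c(msg, "nEyes exceeds nSubjects * eyesPerSubject")
  }
  if (length(msg)) msg else TRUE
})
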
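#' @include pipeline.R
NULL

#' Polar / Cartesian conversion for analysis vectors
#'
#' `polarVector()` builds a [PolarVector-class] directly; `asPolar()`
#' converts a Cartesian 2-vector, flagging an exactly-zero vector as
#' degenerate (angle reported as 0 rather than an arbitrary direction);
#' `asCartesian()` inverts the conversion.
#'
#' @param magnitude,angle Polar components (um, degrees in [0, 360)).
#' @param v Cartesian 2-vector (x, y).
#' @param p A [PolarVector-class].
#' @return `polarVector()`/`asPolar()`: a [PolarVector-class];
#'   `asCartesian()`: a numeric 2-vector.
#' @examples
#' asPolar(c(0.60, -1.13))   # the mean tilt vector, ~1.28 um at ~298 deg
#' @export
polarVector <- function(magnitude, angle, degenerate = magnitude == 0) {
  new("PolarVector", magnitude = magnitude, angle = wrapAngle(angle),
      degenerate = degenerate)
}

#' @rdname polarVector
#' @param degenerate Zero-vector flag.
#' @export
asPolar <- function(v) {
  stopifnot(length(v) == 2, all(is.finite(v)))
  v <- unname(v)
  mag <- sqrt(sum(v^2))
  if (mag == 0) return(polarVector(0, 0, degenerate = TRUE))
  polarVector(mag, wrapAngle(.rad2deg(atan2(v[2], v[1]))))
}

#' @rdname polarVector
#' @export
asCartesian <- function(p) {
  stopifnot(is(p, "PolarVector"))
  p@magnitude * c(cos(.deg2rad(p@angle)), sin(.deg2rad(p@angle)))
}

#' @rdname accessors
#' @export
setMethod("magnitude", "PolarVector", function(x) x@magnitude)

#' @rdname accessors
#' @export
setMethod("angleDegrees", "PolarVector", function(x) x@angle)

#' @rdname accessors
#' @export
setMethod("isDegenerate", "PolarVector", function(x) x@degenerate)

setMethod("show", "PolarVector", function(object) {
  if (object@degenerate) cat("PolarVector: zero vector (degenerate)\n")
  else cat(sprintf("PolarVector: %.4g um at %.2f deg\n", object@magnitude,
                   object@angle))
})

#' Per-eye tilt and coma vectors
#'
#' The tilt vector of an eye is (X-tilt, Y-tilt) = (c(1,1), c(1,-1)) =
#' (c_j2, c_j1). The coma vector is the sign-flipped primary coma,
#' (-X-coma, -Y-coma) = (-c_j8, -c_j7); the flip aligns the coma
#' convention with tilt, so that both vectors point toward the thicker
#' side of the map.
#'
#' For a [ZernikeCoefficients-class] the result is a single
#' [PolarVector-class]; for a [CohortCoefficients-class] it is a
#' data.frame with one row per eye (columns `x`, `y`, `magnitude`,
#' `angle`).
#'
#' @param coeffs A [ZernikeCoefficients-class] or
#'   [CohortCoefficients-class].
#' @return A [PolarVector-class] or data.frame (see Details).
#' @export
tiltVector <- function(coeffs) .termVector(coeffs, c(2, 1), flip = FALSE)

#' @rdname tiltVector
#' @export
comaVector <- function(coeffs) .termVector(coeffs, c(8, 7), flip = TRUE)

.termVector <- function(coeffs, jxy, flip) {
  sgn <- if (flip) -1 else 1
  if (is(coeffs, "ZernikeCoefficients")) {
    v <- coef(coeffs)[jxy + 1]
    return(asPolar(sgn * unname(v)))
  }
  if (is(coeffs, "CohortCoefficients")) {
    M <- coefMatrix(coeffs)
    xs <- sgn * M[jxy[1] + 1, ]
    ys <- sgn * M[jxy[2] + 1, ]
    ang <- wrapAngle(.rad2deg(atan2(ys, xs)))
    ang[xs == 0 & ys == 0] <- 0
    return(data.frame(x = unname(xs), y = unname(ys),
                      magnitude = unname(sqrt(xs^2 + ys^2)),
                      angle = unname(ang),
                      row.names = colnames(M)))
  }
  stop("coeffs must be ZernikeCoefficients or CohortCoefficients")
}

#' Population axis from mean component vectors
#'
#' The lid-wiper axis is the direction of the cohort mean vector:
#' atan2(mean y, mean x), in degrees wrapped to [0, 360). This is the
#' direction of the mean vector, not the circular mean of per-eye axes;
#' see [circularMeanAngle()] for the latter.
#'
#' @param vectors Matrix or data.frame of Cartesian vectors (columns
#'   `x`, `y`), one row per eye; a single 2-vector is accepted.
#' @return Axis angle in degrees, [0, 360).
#' @examples
#' lwaFromMeans(c(0.60, -1.13))   # 297.97, the tilt lid-wiper axis
#' @export
lwaFromMeans <- function(vectors) {
  m <- .meanVector(vectors)
  if (all(m == 0)) {
    stop("mean vector is zero: the lid-wiper axis is undefined")
  }
  wrapAngle(.rad2deg(atan2(m[2], m[1])))
}

.meanVector <- function(vectors) {
  if (is.numeric(vectors) && is.null(dim(vectors)) &&
      length(vectors) == 2) {
    return(unname(vectors))
  }
  if (is.data.frame(vectors)) {
    vectors <- as.matrix(vectors[, c("x", "y")])
  }
  stopifnot(is.matrix(vectors), ncol(vectors) >= 2, nrow(vectors) >= 1)
  unname(colMeans(vectors[, 1:2, drop = FALSE]))
}

#' Circular mean of a set of angles
#'
#' Direction of the mean unit vector of the given angles. Exposed as the
#' alternative population-axis definition; the default axis uses the
#' magnitude-weighted mean vector via [lwaFromMeans()].
#'
#' @param angles Angles in degrees.
#' @return Mean direction in degrees, [0, 360).
#' @export
circularMeanAngle <- function(angles) {
  th <- .deg2rad(angles)
  m <- c(mean(cos(th)), mean(sin(th)))
  if (sqrt(sum(m^2)) < 1e-12) {
    stop("mean resultant vector is zero: circular mean undefined")
  }
  wrapAngle(.rad2deg(atan2(m[2], m[1])))
}

#' Lid-wiper gradient of one eye
#'
#' Signed projection of the eye's tilt vector onto the population tilt
#' lid-wiper axis, scaled by the analytical-zone radius:
#' magnitude * cos(angle - lwa) / r, in um/mm. Positive values mean the
#' epithelium thickens along the axis (thins toward the antipode).
#'
#' @param tilt A [PolarVector-class] (or list/data.frame row with
#'   `magnitude` and `angle`).
#' @param lwa Population tilt lid-wiper axis (degrees).
#' @param zoneRadius Analytical zone radius r (mm); 2.5 for the 5-mm zone.
#' @return Signed gradient in um/mm (vectorized over `magnitude`/`angle`).
#' @examples
#' lidWiperGradient(polarVector(2.5, 45), lwa = 45)  # 1 um/mm
#' @export
lidWiperGradient <- function(tilt, lwa, zoneRadius = 2.5) {
  stopifnot(zoneRadius > 0)
  p <- .magAngle(tilt)
  p$magnitude * cos(.deg2rad(p$angle - lwa)) / zoneRadius
}

#' Lid-wiper coma of one eye
#'
#' Signed projection of the eye's (sign-flipped) coma vector onto the
#' population coma lid-wiper axis: magnitude * cos(angle - lwa), in um.
#'
#' @param coma A [PolarVector-class] (or list/data.frame row with
#'   `magnitude` and `angle`).
#' @param lwa Population coma lid-wiper axis (degrees).
#' @return Signed lid-wiper coma in um (vectorized).
#' @export
lidWiperComa <- function(coma, lwa) {
  p <- .magAngle(coma)
  p$magnitude * cos(.deg2rad(p$angle - lwa))
}

.magAngle <- function(v) {
  if (is(v, "PolarVector")) {
    list(magnitude = v@magnitude, angle = v@angle)
  } else {
    list(magnitude = v$magnitude, angle = v$angle)
  }
}

#' Centroid of a set of Cartesian vectors
#'
#' Componentwise mean, reported in polar form (magnitude and angle).
#'
#' @param vectors Matrix or data.frame with columns `x`, `y`.
#' @return A [PolarVector-class].
#' @export
vectorCentroid <- function(vectors) {
  asPolar(.meanVector(vectors))
}

#' Circular standard deviation
#'
#' Mardia's definition: sqrt(-2 ln Rbar) (radians, returned in degrees),
#' with Rbar the mean resultant length of unit vectors at the given
#' angles. Invariant under global rotation of the sample.
#'
#' @param angles Angles in degrees (>= 2 values).
#' @return Circular SD in degrees.
#' @examples
#' circularSD(c(0, 90))  # 47.70
#' @export
circularSD <- function(angles) {
  stopifnot(length(angles) >= 2)
  th <- .deg2rad(angles)
  rbar <- sqrt(mean(cos(th))^2 + mean(sin(th))^2)
  if (rbar < 1e-12) {
    stop("mean resultant length is zero: circular SD is undefined")
  }
  .rad2deg(sqrt(-2 * log(min(rbar, 1))))
}

#' Bivariate confidence ellipse
#'
#' Chi-square construction for bivariate-normal scatter: the ellipse is
#' the level set of the Mahalanobis distance at the chi-square(2 df)
#' quantile of the requested level, using the sample covariance S for the
#' data ellipse or S/n for the centroid (standard-error) ellipse.
#' Semi-axes are sqrt(q * eigenvalue); the orientation is the principal
#' eigenvector direction.
#'
#' @param points Matrix or data.frame of 2-D points (>= 3, columns x, y).
#' @param level Confidence level in (0, 1); default 0.95.
#' @param ofMean TRUE for the centroid ellipse, FALSE (default) for the
#'   data ellipse.
#' @return An [EllipseSpec-class].
#' @export
confidenceEllipse <- function(points, level = 0.95, ofMean = FALSE) {
  if (is.data.frame(points)) points <- as.matrix(points[, c("x", "y")])
  stopifnot(is.matrix(points), ncol(points) == 2)
  n <- nrow(points)
  if (n < 3) stop("confidence ellipse needs at least 3 points")
  S <- stats::cov(points)
  if (ofMean) S <- S / n
  e <- eigen(S, symmetric = TRUE)
  if (min(e$values) <= 1e-12 * max(abs(e$values), 1)) {
    stop("sample covariance is singular: the points are (nearly) collinear")
  }
  q <- stats::qchisq(level, df = 2)
  new("EllipseSpec", center = unname(colMeans(points)),
      semiAxes = sqrt(q * e$values),
      orientation = wrapAngle(.rad2deg(atan2(e$vectors[2, 1],
                                             e$vectors[1, 1]))) %% 180,
      level = level, ofMean = ofMean, n = n)
}

setMethod("show", "EllipseSpec", function(object) {
  cat(sprintf(
    "%.0f%% %s ellipse (n = %d): center (%.3g, %.3g), semi-axes (%.3g, %.3g), orientation %.1f deg\n",
    100 * object@level, if (object@ofMean) "centroid" else "data",
    object@n, object@center[1], object@center[2], object@semiAxes[1],
    object@semiAxes[2], object@orientation))
})

#' Population lid-wiper axes of a cohort
#'
#' The tilt lid-wiper axis is atan2(mean Y-tilt, mean X-tilt) over the
#' cohort; the coma lid-wiper axis is the same construction on the
#' sign-flipped coma vectors. Circular SDs of the per-eye vector angles
#' accompany each axis.
#'
#' @param cohort A [CohortCoefficients-class].
#' @return A [LidWiperAxes-class].
#' @export
lidWiperAxes <- function(cohort) {
  tv <- tiltVector(cohort)
  cv <- comaVector(cohort)
  new("LidWiperAxes",
      tiltLWA = lwaFromMeans(tv), comaLWA = lwaFromMeans(cv),
      tiltCircSD = circularSD(tv$angle), comaCircSD = circularSD(cv$angle))
}

#' @rdname accessors
#' @export
setMethod("tiltLWA", "LidWiperAxes", function(x) x@tiltLWA)

#' @rdname accessors
#' @export
setMethod("comaLWA", "LidWiperAxes", function(x) x@comaLWA)

#' @rdname accessors
#' @export
setMethod("tiltCircSD", "LidWiperAxes", function(x) x@tiltCircSD)

#' @rdname accessors
#' @export
setMethod("comaCircSD", "LidWiperAxes", function(x) x@comaCircSD)

setMethod("show", "LidWiperAxes", function(object) {
  cat(sprintf("LidWiperAxes: tilt %.2f deg (circ SD %.2f), coma %.2f deg (circ SD %.2f)\n",
              object@tiltLWA, object@tiltCircSD, object@comaLWA,
              object@comaCircSD))
  cat(sprintf("  thinning directions: %.2f deg (tilt), %.2f deg (coma)\n",
              wrapAngle(object@tiltLWA - 180),
              wrapAngle(object@comaLWA - 180)))
})

#' Per-eye lid-wiper biomarkers
#'
#' Projects each eye's tilt and coma vectors onto the population lid-wiper
#' axes, yielding the two scalar biomarkers: the lid-wiper gradient
#' (um/mm) and the lid-wiper coma (um).
#'
#' @param cohort A [CohortCoefficients-class].
#' @param axes A [LidWiperAxes-class]; defaults to the cohort's own axes.
#' @param zoneRadius Analytical zone radius (mm); defaults to the fit
#'   zone radius stored in the cohort.
#' @return data.frame with one row per eye: subject, eye, date, tilt and
#'   coma vector components (`tilt_mag_um`, `tilt_angle_deg`,
#'   `coma_mag_um`, `coma_angle_deg`) and the signed biomarkers
#'   (`lid_wiper_gradient_um_per_mm`, `lid_wiper_coma_um`).
#' @export
lidWiperBiomarkers <- function(cohort, axes = lidWiperAxes(cohort),
                               zoneRadius = NULL) {
  if (is.null(zoneRadius)) zoneRadius <- zoneRadius(cohort)
  if (is.null(zoneRadius)) zoneRadius <- 2.5
  tv <- tiltVector(cohort)
  cv <- comaVector(cohort)
  cd <- colData(cohort)
  data.frame(
    subject = cd$subject, eye = cd$eye, date = cd$date,
    tilt_mag_um = tv$magnitude, tilt_angle_deg = tv$angle,
    coma_mag_um = cv$magnitude, coma_angle_deg = cv$angle,
    lid_wiper_gradient_um_per_mm = lidWiperGradient(tv, tiltLWA(axes),
                                                    zoneRadius),
    lid_wiper_coma_um = lidWiperComa(cv, comaLWA(axes)),
    row.names = rownames(cd))
}

#' Population summary of the lid-wiper biomarkers
#'
#' Cohort-level summary in the form the analysis reports: the lid-wiper
#' axes with circular SDs, the centroids (magnitude at angle) of the
#' per-eye gradient and coma vector clouds with the SDs of the scalar
#' projections, the thinning directions (axis antipodes), and the 95%
#' confidence ellipses of each centroid and data cloud.
#'
#' @param cohort A [CohortCoefficients-class].
#' @param level Ellipse confidence level (default 0.95).
#' @return A nested list, directly serializable with
#'   [jsonlite::toJSON()]. Gradient vectors are the per-eye tilt vectors
#'   scaled by 1/r so that the gradient centroid magnitude is
#'   |mean tilt| / r (um/mm).
#' @export
populationSummary <- function(cohort, level = 0.95) {
  axes <- lidWiperAxes(cohort)
  bm <- lidWiperBiomarkers(cohort, axes)
  r <- zoneRadius(cohort)
  if (is.null(r)) r <- 2.5
  tv <- tiltVector(cohort)
  cv <- comaVector(cohort)
  gradPts <- data.frame(x = tv$x / r, y = tv$y / r)
  comaPts <- data.frame(x = cv$x, y = cv$y)
  gCent <- vectorCentroid(gradPts)
  cCent <- vectorCentroid(comaPts)
  ell <- function(pts) list(
    data = .ellipseList(confidenceEllipse(pts, level, ofMean = FALSE)),
    centroid = .ellipseList(confidenceEllipse(pts, level, ofMean = TRUE)))
  list(
    units = list(angles = "degrees CCW from nasal (+x), [0,360)",
                 gradient = "um/mm", coma = "um", lengths = "mm"),
    n_eyes = ncol(cohort),
    zone_radius_mm = r,
    axes = list(
      tilt_lwa_deg = tiltLWA(axes), tilt_circ_sd_deg = tiltCircSD(axes),
      coma_lwa_deg = comaLWA(axes), coma_circ_sd_deg = comaCircSD(axes),
      tilt_thinning_deg = wrapAngle(tiltLWA(axes) - 180),
      coma_thinning_deg = wrapAngle(comaLWA(axes) - 180)),
    gradient = list(
      centroid_magnitude_um_per_mm = magnitude(gCent),
      centroid_angle_deg = angleDegrees(gCent),
      projection_mean = mean(bm$lid_wiper_gradient_um_per_mm),
      projection_sd = stats::sd(bm$lid_wiper_gradient_um_per_mm),
      angle_circ_sd_deg = circularSD(tv$angle),
      ellipses = ell(gradPts)),
    coma = list(
      centroid_magnitude_um = magnitude(cCent),
      centroid_angle_deg = angleDegrees(cCent),
      projection_mean = mean(bm$lid_wiper_coma_um),
      projection_sd = stats::sd(bm$lid_wiper_coma_um),
      angle_circ_sd_deg = circularSD(cv$angle),
      ellipses = ell(comaPts)))
}

.ellipseList <- function(e) {
  list(center = e@center, semi_axes = e@semiAxes,
       orientation_deg = e@orientation, level = e@level, n = e@n)
}

#' Polar scatter of per-eye lid-wiper vectors
#'
#' Base-graphics rendering of the per-eye vector cloud with its centroid
#' and the data / centroid confidence ellipses, in the style used to
#' present the population biomarkers.
#'
#' @param cohort A [CohortCoefficients-class].
#' @param which `"gradient"` (tilt vectors / r, um/mm) or `"coma"`
#'   (sign-flipped coma vectors, um).
#' @param level Ellipse confidence level.
#' @return Invisibly, the plotted point matrix.
#' @export
plotLidWiper <- function(cohort, which = c("gradient", "coma"),
                         level = 0.95) {
  which <- match.arg(which)
  r <- zoneRadius(cohort); if (is.null(r)) r <- 2.5
  pts <- if (which == "gradient") {
    tv <- tiltVector(cohort); data.frame(x = tv$x / r, y = tv$y / r)
  } else {
    cv <- comaVector(cohort); data.frame(x = cv$x, y = cv$y)
  }
  lim <- max(abs(unlist(pts))) * 1.1
  unit <- if (which == "gradient") "um/mm" else "um"
  graphics::plot(pts$x, pts$y, asp = 1, xlim = c(-lim, lim),
                 ylim = c(-lim, lim), pch = 16,
                 col = grDevices::adjustcolor("goldenrod", 0.6),
                 xlab = sprintf("nasal component (%s)", unit),
                 ylab = sprintf("superior component (%s)", unit),
                 main = sprintf("lid-wiper %s", which))
  graphics::abline(h = 0, v = 0, col = "grey70")
  cen <- .meanVector(pts)
  graphics::points(cen[1], cen[2], pch = 15, cex = 1.3)
  for (ofMean in c(FALSE, TRUE)) {
    e <- confidenceEllipse(pts, level, ofMean)
    tt <- seq(0, 2 * pi, length.out = 181)
    phi <- .deg2rad(e@orientation)
    xy <- cbind(e@semiAxes[1] * cos(tt), e@semiAxes[2] * sin(tt)) %*%
      rbind(c(cos(phi), sin(phi)), c(-sin(phi), cos(phi)))
    graphics::lines(xy[, 1] + e@center[1], xy[, 2] + e@center[2],
                    col = if (ofMean) "red" else "blue")
  }
  invisible(as.matrix(pts))
}
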
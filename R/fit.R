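#' @include AllGenerics.R zernike.R
NULL

# Indices of samples that participate in a fit: masked-in, finite, and
# with pixel-center radius <= zoneRadius (closed disk).
.fitRows <- function(map, zoneRadius) {
  r <- sqrt(map@x^2 + map@y^2)
  which(map@mask & is.finite(map@thickness) & r <= zoneRadius + 1e-9)
}

.solveFit <- function(B, yvals) {
  qrB <- qr(B)
  if (qrB$rank < ncol(B)) {
    stop(sprintf(
      "rank-deficient Zernike design matrix (rank %d < %d terms); sample the zone more densely or reduce maxOrder",
      qrB$rank, ncol(B)))
  }
  qr.coef(qrB, yvals)
}

#' Fit a thickness map with Zernike polynomials
#'
#' Ordinary least squares of the masked-in thickness samples inside the
#' analytical zone on the ANSI-ordered normalized Zernike basis. Masks and
#' irregular sampling break disk orthogonality, so coefficients come from
#' the sampled-point least-squares problem rather than analytic inner
#' products; for in-span signals the two agree exactly. Samples that are
#' masked out or non-finite are dropped row-wise.
#'
#' @param x A [ThicknessMap-class].
#' @param zoneRadius Analytical zone radius (mm); 2.5 mm is the 5-mm
#'   optical zone.
#' @param maxOrder Maximum radial order (5 gives 21 terms).
#' @return A [ZernikeCoefficients-class] with coefficients in um and
#'   `fitRMSE()` the root mean square residual over the fitted samples.
#' @examples
#' g <- mapGrid(6, 0.25)
#' m <- thicknessMap(g$x, g$y, rep(50, nrow(g)))
#' fit <- fitMap(m)
#' coef(fit)[["c_j0"]]  # 50
#' @export
setMethod("fitMap", "ThicknessMap", function(x, zoneRadius = 2.5,
                                             maxOrder = 5) {
  rows <- .fitRows(x, zoneRadius)
  nTerms <- (maxOrder + 1) * (maxOrder + 2) / 2
  if (length(rows) <= nTerms) {
    stop(sprintf(
      "only %d valid sample(s) inside the %.3g mm zone; need more than %d to fit %d coefficients",
      length(rows), zoneRadius, nTerms, nTerms))
  }
  B <- zernikeBasis(x@x[rows], x@y[rows], zoneRadius, maxOrder)
  yvals <- x@thickness[rows]
  beta <- .solveFit(B, yvals)
  resid <- yvals - as.vector(B %*% beta)
  zernikeCoefficients(beta, zoneRadius = zoneRadius, maxOrder = maxOrder,
                      rmse = sqrt(mean(resid^2)), nSamples = length(rows))
})

#' Fit many maps sharing one grid in a single solve
#'
#' When every map in `maps` has identical positions and mask (the common
#' case for device exports and simulated cohorts), the design matrix is
#' factorized once and all maps are solved together. Maps with differing
#' geometry fall back to per-map [fitMap()].
#'
#' @param maps List of [ThicknessMap-class] objects.
#' @inheritParams fitMap
#' @return List of [ZernikeCoefficients-class], one per map.
#' @export
fitMaps <- function(maps, zoneRadius = 2.5, maxOrder = 5) {
  if (length(maps) == 0) return(list())
  first <- maps[[1]]
  shared <- all(vapply(maps, function(m) {
    length(m@x) == length(first@x) &&
      isTRUE(all.equal(m@x, first@x, tolerance = 1e-12)) &&
      isTRUE(all.equal(m@y, first@y, tolerance = 1e-12)) &&
      identical(m@mask & is.finite(m@thickness),
                first@mask & is.finite(first@thickness))
  }, logical(1)))
  if (!shared) {
    return(lapply(maps, fitMap, zoneRadius = zoneRadius,
                  maxOrder = maxOrder))
  }
  rows <- .fitRows(first, zoneRadius)
  nTerms <- (maxOrder + 1) * (maxOrder + 2) / 2
  if (length(rows) <= nTerms) {
    stop(sprintf(
      "only %d valid sample(s) inside the %.3g mm zone; need more than %d",
      length(rows), zoneRadius, nTerms))
  }
  B <- zernikeBasis(first@x[rows], first@y[rows], zoneRadius, maxOrder)
  Y <- vapply(maps, function(m) m@thickness[rows], numeric(length(rows)))
  qrB <- qr(B)
  if (qrB$rank < ncol(B)) {
    stop("rank-deficient Zernike design matrix; sample the zone more densely")
  }
  beta <- qr.coef(qrB, Y)
  resid <- Y - B %*% beta
  rmse <- sqrt(colMeans(resid^2))
  lapply(seq_along(maps), function(i) {
    zernikeCoefficients(beta[, i], zoneRadius = zoneRadius,
                        maxOrder = maxOrder, rmse = rmse[i],
                        nSamples = length(rows))
  })
}

#' Reconstruct a thickness map from Zernike coefficients
#'
#' Pointwise sum of coefficient times basis value at the requested
#' positions (normalized by the fit's zone radius). Used to assess fit
#' quality and to render the population-average map.
#'
#' @param coeffs A [ZernikeCoefficients-class].
#' @param x,y Positions (mm); all must lie within the zone radius.
#' @param ... Metadata passed to [thicknessMap()] (subject, eye, ...).
#' @return A [ThicknessMap-class] in the right-eye frame.
#' @examples
#' z <- zernikeCoefficients(c(53, rep(0, 20)))
#' g <- mapGrid(5, 0.5)
#' inside <- sqrt(g$x^2 + g$y^2) <= 2.5
#' rec <- reconstructMap(z, g$x[inside], g$y[inside])
#' @export
reconstructMap <- function(coeffs, x, y, ...) {
  stopifnot(is(coeffs, "ZernikeCoefficients"))
  r <- sqrt(x^2 + y^2)
  if (any(r > coeffs@zoneRadius + 1e-9)) {
    stop(sprintf("%d position(s) lie outside the %.3g mm zone radius",
                 sum(r > coeffs@zoneRadius + 1e-9), coeffs@zoneRadius))
  }
  B <- zernikeBasis(x, y, coeffs@zoneRadius, coeffs@maxOrder)
  vals <- as.vector(B %*% coeffs@coefficients)
  thicknessMap(x, y, vals, mask = rep(TRUE, length(x)),
               frame = "right-eye-frame", ...)
}

#' @describeIn accessors Coefficients of a fitted map (named numeric, um).
#' @export
setMethod("coef", "ZernikeCoefficients", function(object, ...) {
  object@coefficients
})

#' @rdname accessors
#' @export
setMethod("zoneRadius", "ZernikeCoefficients", function(x) x@zoneRadius)

#' @rdname accessors
#' @export
setMethod("fitRMSE", "ZernikeCoefficients", function(x) x@rmse)

#' @rdname accessors
#' @export
setMethod("nSamples", "ZernikeCoefficients", function(x) x@nSamples)

setMethod("show", "ZernikeCoefficients", function(object) {
  cat(sprintf(
    "ZernikeCoefficients: %d terms (max order %d), %.3g mm zone\n",
    length(object@coefficients), object@maxOrder, object@zoneRadius))
  cat(sprintf("  fit RMSE %.4g um over %d samples\n", object@rmse,
              object@nSamples))
  cat(sprintf(
    "  tilt (c_j1, c_j2) = (%.3g, %.3g) um; coma (c_j7, c_j8) = (%.3g, %.3g) um\n",
    object@coefficients[2], object@coefficients[3],
    object@coefficients[8], object@coefficients[9]))
})

setMethod("show", "ThicknessMap", function(object) {
  cat(sprintf(
    "ThicknessMap %s %s %s [%s, %s]: %d samples (%d masked-in)\n",
    object@subject, object@eye, object@date, object@device, object@frame,
    length(object@x), sum(object@mask)))
})
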
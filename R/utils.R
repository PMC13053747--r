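#' Angle helpers
#'
#' All angles in this package are degrees, measured counterclockwise from
#' +x (nasal in the right-eye frame) and wrapped to [0, 360).
#' `wrapAngle()` wraps to that range; `angularDifference(a, b)` returns the
#' signed difference a - b wrapped to (-180, 180].
#'
#' @param deg,a,b Angles in degrees.
#' @return Numeric vector of angles (degrees).
#' @examples
#' wrapAngle(-62.03)        # 297.97
#' angularDifference(10, 350)  # 20
#' @export
wrapAngle <- function(deg) deg %% 360

#' @rdname wrapAngle
#' @export
angularDifference <- function(a, b) {
  d <- (a - b) %% 360
  ifelse(d > 180, d - 360, d)
}

.deg2rad <- function(d) d * pi / 180
.rad2deg <- function(r) r * 180 / pi

# Run code under a temporary RNG seed, restoring the caller's RNG state.
.withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Build a square Cartesian pixel grid
#'
#' Pixel centers of a square grid of the given extent and pitch, centered
#' on the origin (the corneal vertex / zone center).
#'
#' @param extent Side length of the square grid (mm).
#' @param spacing Pixel pitch (mm).
#' @return A data.frame with columns `x` and `y` (mm), ordered by (y, x).
#' @examples
#' nrow(mapGrid(6, 0.05))  # 120^2 pixel centers
#' @export
mapGrid <- function(extent = 6, spacing = 0.05) {
  half <- extent / 2
  centers <- seq(-half + spacing / 2, half - spacing / 2, by = spacing)
  g <- expand.grid(x = centers, y = centers)
  g[order(g$y, g$x), , drop = FALSE]
}
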
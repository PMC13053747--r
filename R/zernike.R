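#' ANSI (OSA) single-index Zernike ordering
#'
#' Converts between the double index (n = radial order, m = signed
#' azimuthal frequency) and the ANSI/OSA single index
#' j = (n(n + 2) + m) / 2. `ansiIndex()` validates (n, m) and returns the
#' triple; `ansiFromIndex()` inverts j. Both are vectorized.
#'
#' @param n Radial order(s), integer >= 0.
#' @param m Signed azimuthal frequency(ies); |m| <= n and n - |m| even.
#' @param j ANSI single index(es), integer >= 0.
#' @return A data.frame with columns `n`, `m`, `j` and a human-readable
#'   `label` (e.g. `"Z(1,-1)"`).
#' @examples
#' ansiIndex(1, -1)$j        # 1 (Y-tilt)
#' ansiIndex(3, 1)$j         # 8 (X-coma)
#' ansiFromIndex(0:5)$n
#' @export
ansiIndex <- function(n, m) {
  n <- as.integer(n); m <- as.integer(m)
  bad <- n < 0 | abs(m) > n | (n - abs(m)) %% 2 != 0
  if (any(bad)) {
    i <- which(bad)[1]
    stop(sprintf("invalid Zernike index pair (n = %d, m = %d): need n >= 0, |m| <= n and n - |m| even",
                 n[i], m[i]))
  }
  j <- (n * (n + 2) + m) %/% 2
  data.frame(n = n, m = m, j = j, label = sprintf("Z(%d,%d)", n, m))
}

#' @rdname ansiIndex
#' @export
ansiFromIndex <- function(j) {
  j <- as.integer(j)
  if (any(j < 0)) stop("ANSI index j must be >= 0")
  n <- as.integer(ceiling((-3 + sqrt(9 + 8 * j)) / 2))
  m <- as.integer(2L * j - n * (n + 2L))
  ansiIndex(n, m)
}

#' Zernike term table up to a maximal radial order
#'
#' @param maxOrder Maximum radial order.
#' @return A data.frame of all (n, m, j, label) with n <= maxOrder, in
#'   ANSI order (one row per term; 21 rows for `maxOrder = 5`).
#' @export
zernikeTermTable <- function(maxOrder = 5) {
  nTerms <- (maxOrder + 1) * (maxOrder + 2) / 2
  ansiFromIndex(seq_len(nTerms) - 1L)
}

# Radial polynomial R_n^{|m|}(rho) via the standard factorial sum.
.zernikeRadial <- function(n, mabs, rho) {
  out <- numeric(length(rho))
  for (k in 0:((n - mabs) / 2)) {
    num <- (-1)^k * factorial(n - k)
    den <- factorial(k) * factorial((n + mabs) / 2 - k) *
      factorial((n - mabs) / 2 - k)
    out <- out + (num / den) * rho^(n - 2 * k)
  }
  out
}

#' Evaluate a normalized Zernike basis function
#'
#' ANSI Z80.28 / OSA normalized form: N(n, m) R_n^{|m|}(rho) *
#' cos(m theta) for m > 0, sin(|m| theta) for m < 0, 1 for m = 0, with
#' N(n, m) = sqrt(2(n + 1) / (1 + [m == 0])). With this normalization the
#' basis is orthonormal under the area-average inner product on the unit
#' disk.
#'
#' @param n,m Radial order and signed frequency (validated via
#'   [ansiIndex()]).
#' @param rho Normalized radius in [0, 1].
#' @param theta Azimuth in radians, counterclockwise from +x.
#' @return Dimensionless basis values, recycled over `rho` / `theta`.
#' @examples
#' zernikeValue(0, 0, 0.3, 1)            # 1 (piston)
#' zernikeValue(1, 1, 1, 0)              # 2 (X-tilt at the nasal rim)
#' zernikeValue(1, -1, 1, pi / 2)        # 2 (Y-tilt at the superior rim)
#' @export
zernikeValue <- function(n, m, rho, theta) {
  ansiIndex(n, m)  # validates
  if (any(rho < 0 | rho > 1 + 1e-12)) {
    stop("rho must lie in [0, 1]: the basis is defined on the unit disk")
  }
  nf <- sqrt(2 * (n + 1) / (1 + (m == 0)))
  ang <- if (m > 0) cos(m * theta)
         else if (m < 0) sin(-m * theta)
         else rep(1, length(theta))
  nf * .zernikeRadial(n, abs(m), rho) * ang
}

#' Zernike design matrix at Cartesian sample positions
#'
#' Evaluates all ANSI-ordered terms up to `maxOrder` at positions (x, y)
#' mm, normalized by the zone radius. Rows are samples, columns are terms
#' j = 0 .. K in ANSI order.
#'
#' @param x,y Sample positions (mm).
#' @param zoneRadius Analytical zone radius (mm); positions must satisfy
#'   sqrt(x^2 + y^2) <= zoneRadius.
#' @param maxOrder Maximum radial order.
#' @return Numeric matrix, one column per term, colnames `c_j0`...
#' @export
zernikeBasis <- function(x, y, zoneRadius = 2.5, maxOrder = 5) {
  rho <- sqrt(x^2 + y^2) / zoneRadius
  if (any(rho > 1 + 1e-9)) {
    stop(sprintf("%d position(s) lie outside the %.3g mm zone radius",
                 sum(rho > 1 + 1e-9), zoneRadius))
  }
  rho <- pmin(rho, 1)
  theta <- atan2(y, x)
  terms <- zernikeTermTable(maxOrder)
  B <- matrix(NA_real_, length(x), nrow(terms))
  for (i in seq_len(nrow(terms))) {
    B[, i] <- zernikeValue(terms$n[i], terms$m[i], rho, theta)
  }
  colnames(B) <- sprintf("c_j%d", terms$j)
  B
}
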
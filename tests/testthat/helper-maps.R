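# Fixture builders: maps rendered from known coefficient vectors.

# In-zone pixel centers of a square grid.
diskGrid <- function(spacing = 0.2, zoneRadius = 2.5) {
  g <- mapGrid(2 * zoneRadius + spacing, spacing)
  g[sqrt(g$x^2 + g$y^2) <= zoneRadius, , drop = FALSE]
}

# Render a 21-coefficient vector on in-zone points (exported basis path).
renderField <- function(coeffs, g, zoneRadius = 2.5) {
  B <- zernikeBasis(g$x, g$y, zoneRadius = zoneRadius, maxOrder = 5)
  as.vector(B %*% coeffs)
}

# A native-frame map whose right-eye-frame expansion is `coeffs`.
# For OS eyes the stored positions are the mirror image (x -> -x) of the
# right-eye-frame field, exactly as a left-eye acquisition would be.
makeNativeMap <- function(coeffs, eye = "OD", spacing = 0.2, noise = 0,
                          subject = "s1", date = "2024-01-01",
                          device = "Avanti", seed = NULL) {
  g <- diskGrid(spacing)
  th <- renderField(coeffs, g)
  if (noise > 0) {
    if (!is.null(seed)) set.seed(seed)
    th <- th + rnorm(length(th), 0, noise)
  }
  xs <- if (eye == "OS") -g$x else g$x
  thicknessMap(xs, g$y, th, subject = subject, eye = eye, date = date,
               device = device, frame = "native")
}

# Random smooth coefficient vector with |c_j| <= 10 um.
randomCoeffs <- function(seed = 1, scale = 5) {
  set.seed(seed)
  c(50, runif(20, -scale, scale))
}

# Fit a single-eye map through the full pipeline surface.
fitOne <- function(map, zoneDiameter = 5, maxOrder = 5) {
  fitMap(cropZone(mirrorToRightFrame(map), zoneDiameter),
         zoneRadius = zoneDiameter / 2, maxOrder = maxOrder)
}

# Small cohort of ZernikeCoefficients around given means (no map render).
coeffCohort <- function(n, means, sds, seed = 1, device = "Avanti") {
  set.seed(seed)
  fits <- lapply(seq_len(n), function(i) {
    v <- numeric(21)
    v[seq_along(means)] <- means + rnorm(length(means), 0, sds)
    zernikeCoefficients(v)
  })
  cohortCoefficients(fits, data.frame(
    subject = sprintf("s%03d", seq_len(n)),
    eye = rep(c("OD", "OS"), length.out = n),
    date = "2024-01-01", device = device))
}

# Published population means in ANSI slots (c_j0..c_j20): Y-tilt c_j1,
# X-tilt c_j2, Y-coma c_j7, X-coma c_j8.
table1Means <- function(baseline = 53) {
  v <- numeric(21)
  v[0 + 1] <- baseline
  v[1 + 1] <- -1.13
  v[2 + 1] <- 0.60
  v[7 + 1] <- 0.16
  v[8 + 1] <- -0.14
  v
}
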
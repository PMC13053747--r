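test_that("polar and Cartesian forms round-trip", {
  set.seed(14)
  for (i in 1:50) {
    v <- runif(2, -3, 3)
    p <- asPolar(v)
    expect_equal(asCartesian(p), v, tolerance = 1e-9)
  }
  expect_equal(angleDegrees(asPolar(c(1, 0))), 0)
  z <- asPolar(c(0, 0))
  expect_true(isDegenerate(z))
  expect_equal(magnitude(z), 0)
  expect_equal(angleDegrees(z), 0)
})

test_that("tilt and coma vectors realize the published conventions", {
  means <- zernikeCoefficients(table1Means())

  tv <- tiltVector(means)
  expect_equal(magnitude(tv), 1.279414, tolerance = 1e-6)
  expect_equal(angleDegrees(tv), 297.9671, tolerance = 1e-4)

  # coma vector is sign-flipped to match the tilt convention
  cv <- comaVector(means)
  expect_equal(magnitude(cv), 0.2126029, tolerance = 1e-6)
  expect_equal(angleDegrees(cv), 311.1859, tolerance = 1e-4)

  pure <- numeric(21); pure[8] <- -1   # Y-coma = -1
  expect_equal(angleDegrees(comaVector(zernikeCoefficients(pure))), 90)

  none <- zernikeCoefficients(numeric(21))
  expect_true(isDegenerate(tiltVector(none)))

  # mirrored pure X-coma: fitted x-component flips, so the flipped coma
  # vector points the opposite way along x
  cj <- numeric(21); cj[9] <- 0.5      # X-coma
  od <- fitOne(makeNativeMap(cj, eye = "OD"))
  os <- makeNativeMap(cj, eye = "OD"); os@eye <- "OS"
  osFit <- fitOne(os)
  vOD <- asCartesian(comaVector(od))
  vOS <- asCartesian(comaVector(osFit))
  expect_equal(vOS[1], -vOD[1], tolerance = 1e-8)
  expect_equal(vOS[2], vOD[2], tolerance = 1e-8)
})

test_that("the population axis is the direction of the mean vector", {
  expect_equal(lwaFromMeans(c(0.60, -1.13)), 297.9671, tolerance = 1e-4)
  expect_equal(lwaFromMeans(c(0.14, -0.16)), 311.1859, tolerance = 1e-4)
  expect_equal(lwaFromMeans(c(1, 1)), 45)
  expect_error(lwaFromMeans(rbind(c(1, 0), c(-1, 0))), "undefined")
  # matrix input averages rows
  m <- rbind(c(2, 0), c(0, 2))
  expect_equal(lwaFromMeans(m), 45)
})

test_that("lid-wiper gradient and coma are signed axis projections", {
  expect_equal(lidWiperGradient(polarVector(2.5, 45), 45, 2.5), 1)
  expect_equal(lidWiperGradient(polarVector(1, 135), 45), 0,
               tolerance = 1e-12)
  expect_equal(lidWiperComa(polarVector(1, 225), 45), -1)
  expect_equal(lidWiperComa(polarVector(0, 0, TRUE), 10), 0)

  # Table-1 mean vectors projected on their own axes reproduce the
  # published centroid magnitudes
  tilt <- asPolar(c(0.60, -1.13))
  expect_equal(lidWiperGradient(tilt, 297.9671, 2.5), 0.5117656,
               tolerance = 1e-5)
  coma <- asPolar(c(0.14, -0.16))
  expect_equal(lidWiperComa(coma, 311.1859), 0.2126029, tolerance = 1e-5)

  # projection identity: parallel^2 + perpendicular^2 = magnitude^2
  set.seed(3)
  for (i in 1:25) {
    v <- asPolar(runif(2, -2, 2))
    lwa <- runif(1, 0, 360)
    par <- lidWiperGradient(v, lwa, 2.5) * 2.5
    perp <- lidWiperComa(v, lwa + 90)
    expect_equal(par^2 + perp^2, magnitude(v)^2, tolerance = 1e-9)
  }
})

test_that("vector centroids equal componentwise means", {
  same <- rbind(c(1, 2), c(1, 2), c(1, 2))
  colnames(same) <- c("x", "y")
  expect_equal(asCartesian(vectorCentroid(same)), c(1, 2),
               tolerance = 1e-12)
  anti <- rbind(c(1, 1), c(-1, -1))
  expect_true(isDegenerate(vectorCentroid(anti)))

  set.seed(8)
  cloud <- matrix(rnorm(200), ncol = 2)
  colnames(cloud) <- c("x", "y")
  expect_equal(asCartesian(vectorCentroid(cloud)),
               unname(colMeans(cloud)), tolerance = 1e-12)
})

test_that("circular SD follows sqrt(-2 ln Rbar) and is rotation-invariant", {
  expect_equal(circularSD(c(77, 77, 77)), 0, tolerance = 1e-6)
  expect_equal(circularSD(c(0, 90)), 47.70187, tolerance = 1e-4)
  set.seed(4)
  a <- runif(40, 0, 360)
  for (shift in c(13, 181, 300)) {
    expect_equal(circularSD(a), circularSD(wrapAngle(a + shift)),
                 tolerance = 1e-9)
  }
  expect_error(circularSD(c(0, 180)), "undefined")
  expect_error(circularSD(5), "length")
})

test_that("confidence ellipses follow the chi-square construction", {
  # exact check: force the sample covariance to the target
  set.seed(9)
  iso <- MASS::mvrnorm(10000, c(0, 0), diag(2), empirical = TRUE)
  e <- confidenceEllipse(iso, level = 0.95)
  expect_equal(unname(e@semiAxes), rep(sqrt(qchisq(0.95, 2)), 2),
               tolerance = 1e-8)

  # centroid ellipse = data ellipse shrunk by sqrt(n)
  em <- confidenceEllipse(iso, level = 0.95, ofMean = TRUE)
  expect_equal(em@semiAxes, e@semiAxes / sqrt(10000), tolerance = 1e-8)

  # orientation recovers a constructed anisotropy
  phi <- 30 * pi / 180
  R <- rbind(c(cos(phi), -sin(phi)), c(sin(phi), cos(phi)))
  S <- R %*% diag(c(4, 1)) %*% t(R)
  cloud <- MASS::mvrnorm(500, c(1, -2), S, empirical = TRUE)
  ea <- confidenceEllipse(cloud, 0.95)
  expect_equal(ea@orientation, 30, tolerance = 1e-6)
  expect_equal(ea@center, c(1, -2), tolerance = 1e-9)
  expect_equal(unname(ea@semiAxes),
               sqrt(qchisq(0.95, 2) * c(4, 1)), tolerance = 1e-8)

  line <- cbind(1:10, 2 * (1:10))
  expect_error(confidenceEllipse(line), "singular|collinear")
  expect_error(confidenceEllipse(iso[1:2, ]), "at least 3")
})

test_that("cohort axes, biomarkers and summary are mutually consistent", {
  set.seed(21)
  cohort <- coeffCohort(120,
                        means = c(53, -1.13, 0.60, 0, 0, 0, 0, 0.16, -0.14),
                        sds = c(0, 1.55, 0.76, 0, 0, 0, 0, 0.62, 0.38))
  axes <- lidWiperAxes(cohort)
  tv <- tiltVector(cohort)
  expect_equal(tiltLWA(axes), lwaFromMeans(colMeans(tv[, c("x", "y")])),
               tolerance = 1e-9)

  bm <- lidWiperBiomarkers(cohort, axes)
  # centroid-of-projections consistency: the gradient-vector centroid
  # magnitude equals |mean tilt| / r
  ps <- populationSummary(cohort)
  expect_equal(ps$gradient$centroid_magnitude_um_per_mm,
               sqrt(sum(colMeans(tv[, c("x", "y")])^2)) / 2.5,
               tolerance = 1e-9)
  # the centroid direction is the axis itself, so the mean projection of
  # the gradient vectors onto the axis equals the centroid magnitude
  expect_equal(mean(bm$lid_wiper_gradient_um_per_mm),
               ps$gradient$centroid_magnitude_um_per_mm, tolerance = 1e-9)
  # thinning directions are the axis antipodes
  expect_equal(ps$axes$tilt_thinning_deg, wrapAngle(tiltLWA(axes) - 180))
  expect_equal(ps$axes$coma_thinning_deg, wrapAngle(comaLWA(axes) - 180))
  # |gradient| * r never exceeds the tilt magnitude; |coma| never
  # exceeds the coma magnitude
  expect_true(all(abs(bm$lid_wiper_gradient_um_per_mm) * 2.5 <=
                    bm$tilt_mag_um + 1e-12))
  expect_true(all(abs(bm$lid_wiper_coma_um) <= bm$coma_mag_um + 1e-12))
})

test_that("polar plotting runs headlessly", {
  cohort <- coeffCohort(30, means = c(53, -1, 0.6, 0, 0, 0, 0, 0.2, -0.1),
                        sds = c(0, 1.5, 0.8, 0, 0, 0, 0, 0.6, 0.4),
                        seed = 6)
  f <- tempfile(fileext = ".pdf")
  grDevices::pdf(f)
  pts <- plotLidWiper(cohort, "gradient")
  plotLidWiper(cohort, "coma")
  grDevices::dev.off()
  expect_equal(nrow(pts), 30)
  expect_true(file.exists(f))
  unlink(f)
})
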
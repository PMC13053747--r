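test_that("the normality gate routes to the right one-sample test", {
  set.seed(100)
  normal5 <- rnorm(200, mean = 5)
  r <- gatedOneSampleTest(normal5, label = "shifted-normal")
  expect_equal(r@test, "one-sample t")
  expect_lt(r@pAdjusted, 1e-3)
  expect_gte(r@pAdjusted, r@p)

  skewed <- rlnorm(135, 0, 1)
  rs <- gatedOneSampleTest(skewed, label = "lognormal")
  expect_equal(rs@test, "Wilcoxon signed-rank")
  expect_lt(rs@normalityP, 0.05)

  expect_error(gatedOneSampleTest(rep(1, 10)), "identical")
  expect_error(gatedOneSampleTest(c(1, 2)), "at least 3")

  # Bonferroni monotonicity and capping
  expect_equal(r@pAdjusted, min(1, r@p * 4))
  big <- gatedOneSampleTest(rnorm(20), familySize = 50)
  expect_lte(big@pAdjusted, 1)
})

test_that("a symmetric null sample rarely rejects", {
  keep <- 0
  for (seed in 1:20) {
    set.seed(2000 + seed)
    v <- rnorm(135)
    if (gatedOneSampleTest(v)@p > 0.05) keep <- keep + 1
  }
  expect_gte(keep, 16)  # >= 90% expected; allow sampling slack
})

test_that("RSS summaries select the right terms", {
  v <- numeric(21)
  v[ansiIndex(2, -2)$j + 1] <- 3
  v[ansiIndex(2, 2)$j + 1] <- 4
  expect_equal(rssAstigmatism(zernikeCoefficients(v)), 5)
  expect_equal(rssAstigmatism(zernikeCoefficients(numeric(21))), 0)

  tre <- numeric(21); tre[ansiIndex(3, -3)$j + 1] <- 2
  expect_equal(rssHoaExcludingComa(zernikeCoefficients(tre)), 2)
  comaOnly <- numeric(21)
  comaOnly[ansiIndex(3, -1)$j + 1] <- 1.5
  comaOnly[ansiIndex(3, 1)$j + 1] <- -0.7
  expect_equal(rssHoaExcludingComa(zernikeCoefficients(comaOnly)), 0)

  # enumeration oracle over the explicit (n, m) list
  set.seed(50)
  w <- runif(21, -2, 2)
  tt <- zernikeTermTable(5)
  keep <- tt$n >= 3 & !(tt$n == 3 & abs(tt$m) == 1)
  expect_equal(rssHoaExcludingComa(zernikeCoefficients(w)),
               sqrt(sum(w[keep]^2)), tolerance = 1e-12)

  # RSS astigmatism is mirror-invariant (only Z(2,-2) flips sign)
  cj <- randomCoeffs(13)
  od <- fitOne(makeNativeMap(cj, eye = "OD"))
  os <- makeNativeMap(cj, eye = "OD"); os@eye <- "OS"
  expect_equal(rssAstigmatism(fitOne(os)), rssAstigmatism(od),
               tolerance = 1e-8)
})

test_that("biomarker regression reports slope, r, R^2 and p coherently", {
  x <- seq(0, 1, length.out = 30)
  # noiseless input: lm's "essentially perfect fit" warning is expected
  ex <- suppressWarnings(biomarkerRegression(x, 2 * x))
  expect_equal(ex@slope, 2, tolerance = 1e-10)
  expect_equal(ex@r, 1, tolerance = 1e-10)
  expect_equal(ex@r2, 1, tolerance = 1e-10)

  set.seed(61)
  y <- rnorm(60); x2 <- rnorm(60)
  rr <- biomarkerRegression(x2, y)
  expect_equal(rr@r2, rr@r^2, tolerance = 1e-12)
  expect_equal(rr@r2, summary(lm(y ~ x2))$r.squared, tolerance = 1e-12)

  expect_error(biomarkerRegression(rep(1, 10), rnorm(10)), "constant")

  # null calibration: independent x, y at n = 135
  set.seed(62)
  ps <- replicate(200, biomarkerRegression(rnorm(135), rnorm(135))@p)
  expect_lt(mean(ps < 0.05), 0.12)
  expect_gt(mean(ps < 0.5), 0.35)  # roughly uniform
})

test_that("a true correlation of 0.27 is recovered across replicates", {
  n <- 135; rho <- 0.27
  covered <- 0
  reps <- 300
  for (i in seq_len(reps)) {
    set.seed(7000 + i)
    xy <- MASS::mvrnorm(n, c(0, 0), rbind(c(1, rho), c(rho, 1)))
    r <- biomarkerRegression(xy[, 1], xy[, 2])@r
    # Fisher-z 95% CI around the estimate must cover the truth
    z <- atanh(r); half <- 1.96 / sqrt(n - 3)
    if (atanh(rho) > z - half && atanh(rho) < z + half) covered <- covered + 1
  }
  expect_gte(covered / reps, 0.90)
})

test_that("device compatibility matches eyes and gates per-term tests", {
  A <- coeffCohort(40, means = c(53, -1, 0.6, 0, 0, 0, 0, 0.2, -0.1),
                   sds = c(0.3, 1.5, 0.8, 0.2, 0.2, 0.2, 0.1, 0.6, 0.4),
                   seed = 81, device = "Avanti")
  # same eyes, same values: all degenerate, poolable
  ident <- deviceCompatibility(A, A)
  expect_true(ident$poolable)
  expect_true(all(ident$table$degenerate))

  # offset one term by 1 um on device B
  MB <- coefMatrix(A)
  MB[2, ] <- MB[2, ] + 1
  set.seed(82)
  MB <- MB + matrix(rnorm(length(MB), 0, 0.05), nrow(MB))
  cdA <- as.data.frame(SummarizedExperiment::colData(A))
  B <- cohortCoefficients(
    lapply(seq_len(ncol(MB)), function(i) zernikeCoefficients(MB[, i])),
    data.frame(subject = cdA$subject, eye = cdA$eye, date = cdA$date,
               device = "Solix"))
  comp <- deviceCompatibility(A, B)
  expect_false(comp$poolable)
  j1 <- comp$table[comp$table$term == "c_j1", ]
  expect_lt(j1$p_adjusted, 1e-6)

  # pairing is by (subject, eye); dropping an eye must error
  Bshort <- B[, -1]
  expect_error(deviceCompatibility(A, Bshort), "unpaired")

  # false-positive rate of the gated paired test sits near alpha
  set.seed(83)
  hits <- 0; reps <- 300
  for (i in seq_len(reps)) {
    d <- rnorm(60)  # paired differences under the null
    sw <- shapiro.test(d)
    p <- if (sw$p.value >= 0.05) t.test(d)$p.value else
      wilcox.test(d, exact = FALSE)$p.value
    if (p < 0.05) hits <- hits + 1
  }
  analytic <- hits / reps
  set.seed(83)
  hits2 <- 0
  for (i in seq_len(reps)) {
    base <- matrix(rnorm(21 * 60, 0, 0.5), 21)
    MA <- base + matrix(rnorm(21 * 60, 0, 0.1), 21)
    MBn <- base + matrix(rnorm(21 * 60, 0, 0.1), 21)
    mk <- function(M, dev) cohortCoefficients(
      lapply(seq_len(ncol(M)), function(k) zernikeCoefficients(M[, k])),
      data.frame(subject = sprintf("p%02d", seq_len(ncol(M))),
                 eye = "OD", date = "d", device = dev))
    res <- deviceCompatibility(mk(MA, "A"), mk(MBn, "B"), terms = 1)
    if (res$table$p[1] < 0.05) hits2 <- hits2 + 1
  }
  expect_lt(abs(hits2 / reps - 0.05), 0.05)
  expect_gt(hits2 / reps, 0.005)
  expect_true(abs(analytic - 0.05) < 0.05)  # sanity on the oracle itself
})

test_that("the cohort battery reproduces its own ingredients", {
  set.seed(90)
  cohort <- coeffCohort(135,
                        means = c(53, -1.13, 0.60, 0, 0, 0, 0, 0.16, -0.14),
                        sds = c(0.3, 1.55, 0.76, 0.2, 0.2, 0.2, 0.1, 0.62,
                                0.38))
  st <- cohortStats(cohort)
  expect_named(st$termTests, c("Y-tilt (c_j1)", "X-tilt (c_j2)",
                               "Y-coma (c_j7)", "X-coma (c_j8)"))
  # tilt means of ~1 um at n = 135 are overwhelmingly nonzero
  expect_lt(st$termTests[["Y-tilt (c_j1)"]]@pAdjusted, 0.01)
  expect_lt(st$termTests[["X-tilt (c_j2)"]]@pAdjusted, 0.01)
  bm <- lidWiperBiomarkers(cohort)
  direct <- biomarkerRegression(bm$lid_wiper_gradient_um_per_mm,
                                bm$lid_wiper_coma_um)
  expect_equal(st$regressions$coma_on_gradient@slope, direct@slope,
               tolerance = 1e-12)
})
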
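test_that("ANSI single index follows j = (n(n+2)+m)/2 and round-trips", {
  expect_equal(ansiIndex(0, 0)$j, 0)
  expect_equal(ansiIndex(1, -1)$j, 1)
  expect_equal(ansiIndex(1, 1)$j, 2)
  expect_equal(ansiIndex(3, -1)$j, 7)
  expect_equal(ansiIndex(3, 1)$j, 8)

  # enumeration oracle: terms listed in (n, then m ascending) order must
  # receive consecutive j starting at 0
  enum <- do.call(rbind, lapply(0:5, function(n) {
    m <- seq(-n, n, by = 2)
    data.frame(n = n, m = m)
  }))
  idx <- ansiIndex(enum$n, enum$m)
  expect_equal(idx$j, seq_len(nrow(enum)) - 1L)

  back <- ansiFromIndex(idx$j)
  expect_equal(back$n, idx$n)
  expect_equal(back$m, idx$m)

  expect_error(ansiIndex(2, 1), "n = 2, m = 1")
  expect_error(ansiIndex(1, 2), "invalid")
  expect_error(ansiFromIndex(-1), ">= 0")
})

test_that("normalized basis takes its reference values on the rim", {
  expect_equal(zernikeValue(0, 0, 0.37, 2.1), 1)      # piston
  expect_equal(zernikeValue(1, 1, 1, 0), 2)           # X-tilt, nasal rim
  expect_equal(zernikeValue(1, -1, 1, pi / 2), 2)     # Y-tilt, superior rim
  expect_error(zernikeValue(1, 1, 1.2, 0), "unit disk")
})

test_that("noiseless in-span maps are fitted exactly", {
  g <- diskGrid(0.2)

  flat <- thicknessMap(g$x, g$y, rep(50, nrow(g)))
  f <- fitMap(flat)
  expect_equal(unname(coef(f)[1]), 50)
  expect_lt(max(abs(coef(f)[-1])), 1e-10)
  expect_equal(fitRMSE(f), 0, tolerance = 1e-10)

  # pure Y-tilt of 2 um
  cj <- numeric(21); cj[2] <- 2
  tiltMap <- thicknessMap(g$x, g$y, renderField(cj, g))
  ft <- fitMap(tiltMap)
  expect_equal(unname(coef(ft)[2]), 2, tolerance = 1e-8)
  expect_lt(max(abs(coef(ft)[-2])), 1e-8)
  expect_lt(fitRMSE(ft), 1e-8)

  # round-trip fit(reconstruct(c)) = c for random coefficients
  cj <- randomCoeffs(11)
  rec <- reconstructMap(zernikeCoefficients(cj), g$x, g$y)
  expect_lt(max(abs(coef(fitMap(rec)) - cj)), 1e-8)
})

test_that("least-squares fitting is linear in the map", {
  g <- diskGrid(0.25)
  a <- renderField(randomCoeffs(1), g) + sin(3 * g$x) # out-of-span part
  b <- renderField(randomCoeffs(2), g) + cos(2 * g$y)
  fa <- coef(fitMap(thicknessMap(g$x, g$y, a)))
  fb <- coef(fitMap(thicknessMap(g$x, g$y, b)))
  fab <- coef(fitMap(thicknessMap(g$x, g$y, 0.7 * a - 1.3 * b)))
  expect_equal(fab, 0.7 * fa - 1.3 * fb, tolerance = 1e-9)
})

test_that("fit failures are reported with actionable messages", {
  g <- diskGrid(0.95)  # 20 in-zone samples: not more than the 21 terms
  expect_error(fitMap(thicknessMap(g$x, g$y, rep(50, nrow(g)))),
               "valid sample")
  # collinear samples: rank-deficient design
  x <- seq(-2, 2, length.out = 60)
  expect_error(fitMap(thicknessMap(x, rep(0, 60), rep(50, 60))),
               "rank-deficient")
})

test_that("masked and out-of-zone samples never influence the fit", {
  g <- diskGrid(0.2)
  cj <- randomCoeffs(3)
  th <- renderField(cj, g)
  poisoned <- th
  bad <- seq(1, nrow(g), by = 7)
  poisoned[bad] <- 1e6
  m <- thicknessMap(g$x, g$y, poisoned,
                    mask = !(seq_len(nrow(g)) %in% bad))
  expect_lt(max(abs(coef(fitMap(m)) - cj)), 1e-8)

  # NaN samples are masked by the constructor default and dropped row-wise
  withNaN <- th
  withNaN[bad] <- NaN
  m2 <- thicknessMap(g$x, g$y, withNaN)
  expect_lt(max(abs(coef(fitMap(m2)) - cj)), 1e-8)
})

test_that("white noise propagates into coefficients at the OLS rate", {
  set.seed(42)
  g <- diskGrid(0.04)          # ~ 1.2e4 in-zone samples
  n <- nrow(g)
  expect_gt(n, 1e4)
  sigma <- 0.3
  cj <- randomCoeffs(4)
  clean <- renderField(cj, g)
  B <- zernikeBasis(g$x, g$y, 2.5, 5)
  se <- sigma * sqrt(diag(solve(crossprod(B))))

  f <- fitMap(thicknessMap(g$x, g$y, clean + rnorm(n, 0, sigma)))
  expect_true(all(abs(coef(f) - cj) < 4 * se))
  # residual RMSE approaches sigma * sqrt(1 - 21/N)
  expect_equal(fitRMSE(f), sigma * sqrt(1 - 21 / n), tolerance = 0.02)
  expect_lt(fitRMSE(f), sigma * 1.02)

  # Monte-Carlo: over 200 replicate noise draws, the rate of coefficient
  # errors beyond 3 analytic SEs stays near the nominal 0.27%
  reps <- 200
  noise <- matrix(rnorm(n * reps, 0, sigma), n, reps)
  qrB <- qr(B)
  err <- qr.coef(qrB, noise)     # coefficient error due to noise alone
  exceed <- mean(abs(err / se) > 3)
  expect_lt(exceed, 0.01)
})

test_that("reconstruction is the exact inverse view of the fit", {
  g <- diskGrid(0.25)
  zero <- reconstructMap(zernikeCoefficients(numeric(21)), g$x, g$y)
  expect_true(all(zero@thickness == 0))

  set.seed(5)
  th <- 50 + sin(g$x * 2) + rnorm(nrow(g), 0, 0.5)  # not in span
  m <- thicknessMap(g$x, g$y, th)
  f <- fitMap(m)
  rec <- reconstructMap(f, g$x, g$y)
  expect_equal(sqrt(mean((th - rec@thickness)^2)), fitRMSE(f),
               tolerance = 1e-10)

  expect_error(reconstructMap(f, 3, 0), "outside")
})

test_that("the population-mean map thins superotemporally", {
  f <- zernikeCoefficients(table1Means())
  rim <- function(angle) {
    p <- 2.45 * c(cos(angle * pi / 180), sin(angle * pi / 180))
    reconstructMap(f, p[1], p[2])@thickness
  }
  # thinner toward the superotemporal antipode of the tilt axis than
  # toward the inferonasal axis direction
  expect_lt(rim(118.06), rim(298.06))
})
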
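#' @include metrics.R
NULL

.testResult <- function(label, test, statistic, p, familySize, normalityP,
                        n, degenerate = FALSE) {
  new("TestResult", label = label, test = test,
      statistic = as.numeric(statistic), p = as.numeric(p),
      pAdjusted = if (is.na(p)) NA_real_ else min(1, p * familySize),
      normalityP = as.numeric(normalityP), n = as.numeric(n),
      degenerate = degenerate)
}

setMethod("show", "TestResult", function(object) {
  if (object@degenerate) {
    cat(sprintf("TestResult %s: degenerate (no variation), n = %d\n",
                object@label, as.integer(object@n)))
  } else {
    cat(sprintf(
      "TestResult %s: %s, statistic %.4g, p %.3g (adjusted %.3g), Shapiro-Wilk p %.3g, n %d\n",
      object@label, object@test, object@statistic, object@p,
      object@pAdjusted, object@normalityP, as.integer(object@n)))
  }
})

#' @rdname accessors
#' @export
setMethod("isDegenerate", "TestResult", function(x) x@degenerate)

#' Normality-gated one-sample location test
#'
#' Tests whether a coefficient's population mean (or median) differs from
#' zero. The Shapiro-Wilk test at `alphaNormality` selects the branch:
#' one-sample t-test when normality is not rejected, Wilcoxon signed-rank
#' against location zero otherwise (exact for n <= 25 without ties,
#' normal approximation beyond). Raw and Bonferroni-adjusted p values are
#' both reported; the default family is the four single-angular-frequency
#' terms (X/Y tilt and X/Y coma).
#'
#' @param values Numeric sample (n >= 3).
#' @param mu Null location (default 0).
#' @param alphaNormality Shapiro-Wilk gate level (default 0.05).
#' @param familySize Bonferroni family size (default 4).
#' @param label Term label carried into the result.
#' @return A [TestResult-class].
#' @export
gatedOneSampleTest <- function(values, mu = 0, alphaNormality = 0.05,
                               familySize = 4, label = "term") {
  values <- as.numeric(values)
  if (length(values) < 3) stop("need at least 3 values")
  if (stats::sd(values) == 0) {
    stop(sprintf(
      "all %d values of '%s' are identical; the normality gate (and any location test) is undefined",
      length(values), label))
  }
  sw <- stats::shapiro.test(values)
  if (sw$p.value >= alphaNormality) {
    tt <- stats::t.test(values, mu = mu)
    .testResult(label, "one-sample t", tt$statistic, tt$p.value,
                familySize, sw$p.value, length(values))
  } else {
    wt <- stats::wilcox.test(values, mu = mu,
                             exact = length(values) <= 25, correct = TRUE)
    .testResult(label, "Wilcoxon signed-rank", wt$statistic, wt$p.value,
                familySize, sw$p.value, length(values))
  }
}

#' Root-sum-square aberration summaries
#'
#' `rssAstigmatism()` is the RSS of the primary astigmatism pair,
#' sqrt(c(2,-2)^2 + c(2,2)^2) (j = 3 and 5). `rssHoaExcludingComa()` is
#' the RSS over all higher-order terms (radial order 3 to 5) excluding
#' primary coma Z(3,-1) and Z(3,1).
#'
#' @param coeffs A [ZernikeCoefficients-class] or
#'   [CohortCoefficients-class].
#' @return Scalar (um), or a per-eye named vector for a cohort.
#' @examples
#' z <- zernikeCoefficients(replace(numeric(21), c(4, 6), c(3, 4)))
#' rssAstigmatism(z)  # 5
#' @export
rssAstigmatism <- function(coeffs) .rssTerms(coeffs, c(3, 5))

#' @rdname rssAstigmatism
#' @export
rssHoaExcludingComa <- function(coeffs) {
  terms <- zernikeTermTable(5)
  j <- terms$j[terms$n >= 3 & terms$n <= 5 & !(terms$n == 3 & abs(terms$m) == 1)]
  .rssTerms(coeffs, j)
}

.rssTerms <- function(coeffs, j) {
  if (is(coeffs, "ZernikeCoefficients")) {
    return(sqrt(sum(coef(coeffs)[j + 1]^2)))
  }
  if (is(coeffs, "CohortCoefficients")) {
    M <- coefMatrix(coeffs)
    return(sqrt(colSums(M[j + 1, , drop = FALSE]^2)))
  }
  stop("coeffs must be ZernikeCoefficients or CohortCoefficients")
}

#' Simple regression between lid-wiper biomarkers
#'
#' Ordinary least squares of y on x with the Pearson correlation, R^2
#' (equal to r^2 for simple OLS) and the two-sided p value for zero
#' slope. The conventional orientation regresses the partner biomarker
#' (um) on the lid-wiper gradient (um/mm), giving slopes in mm.
#'
#' @param x Predictor values (e.g. lid-wiper gradient, um/mm).
#' @param y Response values (e.g. lid-wiper coma, um).
#' @return A [RegressionResult-class].
#' @export
biomarkerRegression <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("need at least 3 pairs")
  if (stats::sd(x) == 0) stop("x is constant: the slope is undefined")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  r <- stats::cor(x, y)
  new("RegressionResult", slope = unname(stats::coef(fit)[2]),
      intercept = unname(stats::coef(fit)[1]), r = r, r2 = r^2,
      p = unname(sm$coefficients[2, 4]), n = length(x))
}

setMethod("show", "RegressionResult", function(object) {
  cat(sprintf(
    "RegressionResult: slope %.4g, r %.3f, R^2 %.3f, p %.3g, n %d\n",
    object@slope, object@r, object@r2, object@p, as.integer(object@n)))
})

#' Device-compatibility comparison of paired coefficient tables
#'
#' Per-term paired comparison of two cohorts of the same eyes imaged on
#' two devices, used to decide whether the devices' maps may be pooled.
#' Eyes are matched by (subject, eye); per term, the paired differences
#' are tested with the normality-gated paired test (paired t when
#' Shapiro-Wilk does not reject, Wilcoxon signed-rank otherwise). Terms
#' whose differences are all zero are flagged degenerate and treated as
#' evidence of agreement.
#'
#' @param cohortA,cohortB [CohortCoefficients-class] tables covering the
#'   same (subject, eye) pairs.
#' @param alphaNormality Shapiro-Wilk gate level.
#' @param familySize Bonferroni family (default: number of terms tested).
#' @param terms ANSI j indices to compare (default all terms).
#' @return A list with `results` (list of [TestResult-class], one per
#'   term), `table` (data.frame summary) and `poolable` (TRUE when no
#'   adjusted p < 0.05).
#' @export
deviceCompatibility <- function(cohortA, cohortB, alphaNormality = 0.05,
                                familySize = NULL, terms = NULL) {
  keyOf <- function(ch) {
    cd <- colData(ch)
    paste(cd$subject, cd$eye, sep = "|")
  }
  ka <- keyOf(cohortA); kb <- keyOf(cohortB)
  missA <- setdiff(kb, ka); missB <- setdiff(ka, kb)
  if (length(missA) || length(missB)) {
    stop("unpaired eyes: ",
         paste(c(sprintf("absent from A: %s", missA),
                 sprintf("absent from B: %s", missB)), collapse = "; "))
  }
  MB <- coefMatrix(cohortB)[, match(ka, kb), drop = FALSE]
  MA <- coefMatrix(cohortA)
  if (is.null(terms)) terms <- seq_len(nrow(MA)) - 1L
  if (is.null(familySize)) familySize <- length(terms)
  results <- lapply(terms, function(j) {
    d <- MA[j + 1, ] - MB[j + 1, ]
    label <- sprintf("c_j%d", j)
    if (all(d == 0) || stats::sd(d) == 0) {
      return(.testResult(label, "none (degenerate)", NA_real_, NA_real_,
                         familySize, NA_real_, length(d),
                         degenerate = TRUE))
    }
    sw <- stats::shapiro.test(d)
    if (sw$p.value >= alphaNormality) {
      tt <- stats::t.test(d, mu = 0)
      .testResult(label, "paired t", tt$statistic, tt$p.value, familySize,
                  sw$p.value, length(d))
    } else {
      wt <- stats::wilcox.test(d, mu = 0, exact = length(d) <= 25,
                               correct = TRUE)
      .testResult(label, "paired Wilcoxon signed-rank", wt$statistic,
                  wt$p.value, familySize, sw$p.value, length(d))
    }
  })
  tab <- data.frame(
    term = vapply(results, function(r) r@label, character(1)),
    test = vapply(results, function(r) r@test, character(1)),
    statistic = vapply(results, function(r) r@statistic, numeric(1)),
    p = vapply(results, function(r) r@p, numeric(1)),
    p_adjusted = vapply(results, function(r) r@pAdjusted, numeric(1)),
    normality_p = vapply(results, function(r) r@normalityP, numeric(1)),
    degenerate = vapply(results, function(r) r@degenerate, logical(1)))
  pool <- all(is.na(tab$p_adjusted) | tab$p_adjusted >= 0.05)
  list(results = results, table = tab, poolable = pool)
}

#' The full statistical battery of a cohort
#'
#' Runs the published analysis end to end on a fitted cohort: gated
#' one-sample tests of the four single-angular-frequency terms against
#' zero (Bonferroni family 4), and the three biomarker regressions of the
#' partner quantities on the lid-wiper gradient (lid-wiper coma, RSS
#' primary astigmatism, RSS higher-order aberrations excluding coma).
#'
#' @param cohort A [CohortCoefficients-class].
#' @param alphaNormality Shapiro-Wilk gate level.
#' @return A list with `termTests` (list of [TestResult-class] for Y-tilt,
#'   X-tilt, Y-coma, X-coma), `regressions` (list of
#'   [RegressionResult-class]), and `rmse` (mean and SD of per-eye fit
#'   RMSE, um).
#' @export
cohortStats <- function(cohort, alphaNormality = 0.05) {
  M <- coefMatrix(cohort)
  labels <- c("Y-tilt (c_j1)" = 1, "X-tilt (c_j2)" = 2,
              "Y-coma (c_j7)" = 7, "X-coma (c_j8)" = 8)
  termTests <- lapply(seq_along(labels), function(i) {
    gatedOneSampleTest(M[labels[i] + 1, ], alphaNormality = alphaNormality,
                       familySize = length(labels),
                       label = names(labels)[i])
  })
  names(termTests) <- names(labels)
  bm <- lidWiperBiomarkers(cohort)
  g <- bm$lid_wiper_gradient_um_per_mm
  regressions <- list(
    coma_on_gradient = biomarkerRegression(g, bm$lid_wiper_coma_um),
    astig_on_gradient = biomarkerRegression(g, rssAstigmatism(cohort)),
    hoa_on_gradient = biomarkerRegression(g, rssHoaExcludingComa(cohort)))
  cd <- colData(cohort)
  list(termTests = termTests, regressions = regressions,
       rmse = list(mean = mean(cd$rmse), sd = stats::sd(cd$rmse)))
}
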
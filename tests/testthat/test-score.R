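# Scoring: transform, standardization, AHP weights, composite score,
# logistic combination, ROC.

test_that("log2(x+1) transform", {
  expect_equal(transformCounts(c(0, 7, 1023)),
               c(0, 3, log2(1024)), tolerance = 1e-9)
  expect_error(transformCounts(-1), "nonnegative")
})

test_that("Z-standardization: reference stats, degenerate columns, idempotence", {
  set.seed(5)
  m <- matrix(rnorm(60, 10, 3), 20, 3,
              dimnames = list(NULL, c("a", "b", "c")))
  zs <- zscoreMatrix(m)
  expect_equal(unname(colMeans(zs$z)), rep(0, 3), tolerance = 1e-12)
  expect_equal(unname(apply(zs$z, 2, sd)), rep(1, 3), tolerance = 1e-12)
  # x = mu + 2 sigma maps to z = 2
  x2 <- zs$mu["a"] + 2 * zs$sigma["a"]
  expect_equal(unname((x2 - zs$mu["a"]) / zs$sigma["a"]), 2)

  mc <- cbind(m, d = 7)
  expect_warning(zc <- zscoreMatrix(mc), "constant")
  expect_true(all(zc$z[, "d"] == 0))

  # z-scoring an already z-scored matrix is the identity
  expect_equal(zscoreMatrix(zs$z)$z, zs$z, tolerance = 1e-12)

  # subset reference
  zr <- zscoreMatrix(m, reference = 1:10)
  expect_equal(unname(colMeans(zr$z[1:10, ])), rep(0, 3),
               tolerance = 1e-12)
})

test_that("AHP weights: eigenvector identity, consistency ratio, guards", {
  aw <- ahpWeights(matrix(1, 6, 6))
  expect_equal(unname(aw$weights), rep(1 / 6, 6), tolerance = 1e-12)
  expect_lt(aw$cr, 1e-10)

  w <- c(0.5, 0.3, 0.2)
  A <- outer(w, w, "/")
  res <- ahpWeights(A)
  expect_equal(unname(res$weights), w, tolerance = 1e-8)
  expect_lt(res$cr, 1e-8)

  # weights invariant to a w-consistent rescaling of the matrix
  expect_equal(ahpWeights(outer(2 * w / sum(2 * w), 2 * w / sum(2 * w),
                                "/"))$weights,
               res$weights, tolerance = 1e-8)

  # mildly inconsistent 3x3: CR must match a dense eigendecomposition
  B <- matrix(c(1, 2, 4,
                1/2, 1, 3,
                1/4, 1/3, 1), 3, 3, byrow = TRUE)
  rb <- ahpWeights(B)
  lam <- max(Re(eigen(B)$values))
  crOracle <- ((lam - 3) / 2) / 0.58
  expect_equal(rb$cr, crOracle, tolerance = 1e-8)

  # strongly inconsistent matrix errors unless overridden
  C <- matrix(c(1, 9, 1/9,
                1/9, 1, 9,
                9, 1/9, 1), 3, 3, byrow = TRUE)
  expect_error(ahpWeights(C), "consistency")
  expect_silent(ahpWeights(C, allowInconsistent = TRUE))

  expect_error(ahpWeights(matrix(c(1, 2, 3, 1), 2, 2)), "reciprocal")
})

test_that("composite score is the weighted Z sum, permutation invariant", {
  z <- matrix(1, 3, 6, dimnames = list(NULL, ctcMarkers()))
  w <- setNames(rep(1 / 6, 6), ctcMarkers())
  expect_equal(unname(compositeScore(z, w)), rep(1, 3))

  w1 <- setNames(c(1, 0, 0, 0, 0, 0), ctcMarkers())
  set.seed(2)
  z2 <- matrix(rnorm(18), 3, 6, dimnames = list(NULL, ctcMarkers()))
  expect_equal(unname(compositeScore(z2, w1)), unname(z2[, 1]))

  perm <- sample(6)
  expect_equal(compositeScore(z2[, perm], w[perm]), compositeScore(z2, w))
  expect_error(compositeScore(z2, setNames(rep(1/6, 6), letters[1:6])),
               "names")
})

test_that("scoreCohort standardizes, weights and records metadata", {
  ce <- simulateCohort(cohortDesign(nHD = 10, nEarly = 10, nAdvanced = 10),
                       seed = 31)
  sr <- scoreCohort(ce)
  expect_equal(unname(colMeans(markerZ(sr))), rep(0, 6), tolerance = 1e-10)
  expect_equal(sum(scoreWeights(sr)), 1)
  expect_equal(unname(compositeScores(sr)),
               unname(compositeScore(markerZ(sr), scoreWeights(sr))))
  srH <- scoreCohort(ce, reference = "healthy")
  hd <- cohortLabels(ce) == "HD"
  expect_equal(unname(colMeans(markerZ(srH)[hd, ])), rep(0, 6),
               tolerance = 1e-10)
  expect_identical(srH@reference, "HD")
})

test_that("ridge logistic: separation flag, null feature, oracle agreement", {
  # perfect 1-D separation: flagged, AUC on probabilities = 1
  x <- c(1, 2, 3, 10, 11, 12)
  y <- c(0, 0, 0, 1, 1, 1)
  fit <- logisticCombine(x, y)
  expect_true(fit$separation)
  expect_equal(rocAnalysis(fit$probabilities, y)$auc, 1.0)

  # constant feature: coefficient ~0, probabilities ~ prevalence
  set.seed(3)
  y2 <- rep(c(0, 1), c(30, 20))
  fc <- logisticCombine(rep(4, 50), y2)
  expect_lt(abs(fc$coefficients[[2]]), 1e-3)
  expect_equal(unname(fc$probabilities), rep(0.4, 50), tolerance = 1e-6)

  # recovery of a known log-odds model at n = 5000
  set.seed(4)
  n <- 5000
  X <- cbind(rnorm(n), rnorm(n))
  beta <- c(-0.5, 1.2, -0.8)
  yk <- rbinom(n, 1, plogis(beta[1] + X %*% beta[2:3]))
  fk <- logisticCombine(X, yk)
  expect_equal(unname(fk$coefficients), beta, tolerance = 0.1)

  # with a vanishing ridge the ML fit agrees with glm
  fg <- glm(yk ~ X, family = binomial)
  f0 <- logisticCombine(X, yk, ridge = 1e-10)
  expect_equal(unname(f0$coefficients), unname(coef(fg)), tolerance = 1e-6)

  expect_error(logisticCombine(1:4, c(1, 1, 1, 1)), "both classes")
})

test_that("ROC: rank AUC, Youden cutoff, symmetry, pROC oracle", {
  r <- rocAnalysis(c(1, 2, 3, 4), c(0, 0, 1, 1))
  expect_equal(r$auc, 1.0)
  expect_equal(r$sensitivity, 1.0)
  expect_equal(r$specificity, 1.0)

  expect_equal(rocAnalysis(c(1, 2, 3, 4), c(0, 1, 0, 1))$auc, 0.75)

  set.seed(6)
  s <- c(rnorm(40), rnorm(40, 1))
  lab <- rep(c(0, 1), each = 40)
  expect_equal(rocAnalysis(s, lab)$auc, 1 - rocAnalysis(s, 1 - lab)$auc,
               tolerance = 1e-12)

  # ties get half credit, matching the Mann-Whitney convention
  st <- c(1, 2, 2, 3)
  expect_equal(rocAnalysis(st, c(0, 0, 1, 1))$auc, 0.875)

  skip_if_not_installed("pROC")
  po <- pROC::roc(lab, s, quiet = TRUE, direction = "<")
  expect_equal(rocAnalysis(s, lab)$auc, as.numeric(pROC::auc(po)),
               tolerance = 1e-12)
})
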
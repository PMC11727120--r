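# 2D profiling: ASGPR calibration, region classifier, proportions,
# efficacy vectors, Spearman correlation.

blobCohort <- function(n = 40, gap = 6, seed = 1) {
  set.seed(seed)
  pts <- rbind(cbind(rnorm(n, 1, 0.4), rnorm(n, 1, 0.4)),
               cbind(rnorm(n, 1 + gap, 0.4), rnorm(n, 1 + gap, 0.4)))
  list(points = pts, labels = rep(c("HD", "HCC"), each = n))
}

test_that("ASGPR calibration is the ratio-with-pseudocount rule", {
  v <- setNames(c(100, 40, 49, 80, 20, 5), ctcMarkers())
  cal <- asgprCalibrate(v)
  expect_equal(cal$y[cal$marker == "EpCAM"], 2.0)      # 100 / (49 + 1)
  expect_equal(cal$x[cal$marker == "EpCAM"], 80 / 50)
  expect_equal(cal$x[cal$marker == "GPC3"], 20 / 50)

  # zero ASGPR with pseudocount 1 leaves raw copies
  v0 <- v; v0["ASGPR_protein"] <- 0
  cal0 <- asgprCalibrate(v0)
  expect_equal(cal0$y[cal0$marker == "EpCAM"], 100)

  # scaling all markers by c preserves EpCAM : GPC3 coordinate ratios
  calC <- asgprCalibrate(v * 10)
  expect_equal(calC$x[1] / calC$x[2], cal$x[1] / cal$x[2],
               tolerance = 1e-12)
  expect_error(asgprCalibrate(c(a = 1)), "named")
})

test_that("separable blobs: perfect training accuracy for every kernel", {
  bc <- blobCohort()
  for (kn in c("poly", "linear", "radial", "gnb")) {
    m <- fitRegionClassifier(bc$points, bc$labels, kernel = kn, seed = 1)
    expect_equal(m@trainAccuracy, 1.0, info = kn)
  }
})

test_that("P1 contains the healthy centroid; distant points fall in P2", {
  bc <- blobCohort()
  m <- fitRegionClassifier(bc$points, bc$labels, kernel = "poly", seed = 1)
  centroid <- colMeans(bc$points[bc$labels == "HD", ])
  expect_equal(assignRegions(m, rbind(centroid)), "P1")
  expect_equal(assignRegions(m, rbind(c(10, 10))), "P2")
  # all healthy training points on separable data sit in P1
  expect_true(all(assignRegions(m, bc$points[bc$labels == "HD", ]) == "P1"))
  # determinism: identical data and seed give identical model outputs
  m2 <- fitRegionClassifier(bc$points, bc$labels, kernel = "poly", seed = 1)
  expect_identical(m@cv, m2@cv)
  expect_identical(assignRegions(m, bc$points),
                   assignRegions(m2, bc$points))
})

test_that("shuffled labels give chance-level cross-validated accuracy", {
  set.seed(9)
  pts <- cbind(rnorm(400), rnorm(400))
  lab <- sample(rep(c("HD", "HCC"), each = 200))
  m <- fitRegionClassifier(pts, lab, kernel = "poly", seed = 9)
  expect_lt(abs(m@cv$accuracy - 0.5), 0.08)
})

test_that("region proportions sum to one per cohort and ignore order", {
  rp <- regionProportions(c("P1", "P2", "P2", "P2"), rep("early", 4))
  expect_equal(c(rp$P1, rp$P2), c(0.25, 0.75))
  r <- c("P1", "P1", "P2", "P1", "P2", "P2")
  co <- c("a", "a", "a", "b", "b", "b")
  o <- sample(6)
  expect_equal(regionProportions(r, co),
               regionProportions(r[o], co[o])[order(unique(co[o])), ],
               ignore_attr = TRUE)
  expect_error(regionProportions("P3", "a"), "P1/P2")
})

test_that("P2 fraction is non-decreasing across worsening cohorts", {
  set.seed(12)
  mk <- function(n, lo) cbind(runif(n, lo, lo + 1), runif(n, lo, lo + 1))
  hd <- mk(30, 0); early <- mk(30, 2); adv <- mk(30, 4)
  pts <- rbind(hd, early, adv)
  lab <- rep(c("HD", "HCC", "HCC"), each = 30)
  m <- fitRegionClassifier(pts, lab, kernel = "poly", seed = 2)
  reg <- assignRegions(m, pts)
  props <- regionProportions(reg, rep(c("HD", "early", "advanced"),
                                      each = 30))
  p2 <- setNames(props$P2, props$cohort)
  expect_true(p2[["HD"]] <= p2[["early"]])
  expect_true(p2[["early"]] <= p2[["advanced"]])
})

test_that("efficacy vectors: closed-form cases, additivity, degeneracy", {
  v <- efficacyVector(c(2, 3), c(0, 3))
  expect_equal(c(v$dx, v$dy, v$magnitude, v$angle), c(-2, 0, 2, 180))

  comb <- combineEfficacyVectors(efficacyVector(c(0, 0), c(-1, 0)),
                                 efficacyVector(c(0, 0), c(0, -1)))
  expect_equal(comb$magnitude, sqrt(2), tolerance = 1e-12)
  expect_equal(comb$angle, 225)

  z <- efficacyVector(c(1, 1), c(1, 1))
  expect_true(z$degenerate)
  expect_true(is.na(z$angle))

  # path additivity: pre->mid plus mid->post equals pre->post
  pre <- c(0.3, 2); mid <- c(1.5, 0.7); post <- c(-0.4, 1.1)
  ab <- efficacyVector(pre, mid); bc <- efficacyVector(mid, post)
  ac <- efficacyVector(pre, post)
  cmb <- combineEfficacyVectors(ab, bc)
  expect_equal(c(cmb$dx, cmb$dy), c(ac$dx, ac$dy), tolerance = 1e-12)
})

test_that("Spearman correlation: rank formula, invariance, permutation p", {
  expect_equal(spearmanCorr(1:10, (1:10)^3, seed = 1)$r, 1)
  expect_equal(spearmanCorr(1:10, -(1:10), seed = 1)$r, -1)
  sc <- spearmanCorr(1:4, c(2, 1, 4, 3), seed = 1)
  expect_equal(sc$r, 0.6, tolerance = 1e-12)   # 1 - 6*4/(4*15)

  # agreement with the built-in rank correlation, ties included
  set.seed(13)
  x <- sample(1:5, 30, replace = TRUE); y <- x + rnorm(30)
  expect_equal(spearmanCorr(x, y, nPerm = 99, seed = 1)$r,
               cor(x, y, method = "spearman"), tolerance = 1e-12)

  # invariant under strictly monotone transforms
  expect_equal(spearmanCorr(exp(x), y^3 + 5, nPerm = 99, seed = 1)$r,
               spearmanCorr(x, y^3 + 5, nPerm = 99, seed = 1)$r)

  # strong association is significant; constant input is flagged
  expect_lt(spearmanCorr(1:20, 1:20 + rnorm(20, 0, 0.1), seed = 2)$p, 0.01)
  expect_warning(scc <- spearmanCorr(rep(1, 5), 1:5), "constant")
  expect_true(is.na(scc$r))
})
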
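# Generator contracts: determinism, occupancy law, channel realism,
# cohort structure, dilution-series detection model.

test_that("zero template gives zero positive wells; load is conserved", {
  run <- miniPlate(nWells = 200, lambda = 0, seed = 3)
  tt <- truthTable(run)
  expect_equal(sum(tt$molecules), 0)
  run2 <- miniPlate(nWells = 500, lambda = 120, seed = 4)
  # multinomial placement conserves the realized template load exactly
  expect_equal(sum(truthTable(run2)$molecules), 120)
})

test_that("identical params and seed give bit-identical plates", {
  p <- plateSimParams(nWells = 150, targetCopies = 25, regions = "protein",
                      channels = c("FAM", "CY5"))
  a <- simulatePlate(p, seed = 11)
  b <- simulatePlate(p, seed = 11)
  expect_identical(traceMatrix(a), traceMatrix(b))
  expect_identical(truthTable(a), truthTable(b))
  c <- simulatePlate(p, seed = 12)
  expect_false(identical(traceMatrix(a), traceMatrix(c)))
})

test_that("occupancy matches the Poisson law 1 - exp(-lambda/N)", {
  N <- 20000; lambda <- 500
  p <- 1 - exp(-lambda / N)          # ~493.8 expected positives
  sdM <- sqrt(N * p * (1 - p))
  set.seed(42)
  Ms <- replicate(30, occupancyDraw(lambda, N))
  expect_true(all(abs(Ms - N * p) <= 4 * sdM))
  # and the full trace generator obeys the same law
  run <- miniPlate(nWells = N, lambda = lambda, seed = 5)
  M <- sum(truthTable(run)$molecules >= 1)
  expect_lt(abs(M - N * p), 4 * sdM)
})

test_that("drawn Ct and growth rates match the configured channel values", {
  run <- miniPlate(nWells = 20000, lambda = 2000, seed = 6)
  tt <- truthTable(run)
  ct <- tt$ct_true[!is.na(tt$ct_true)]
  se <- 0.88 / sqrt(length(ct))
  expect_lt(abs(mean(ct) - 26.83), 3 * se)
})

test_that("cohort generator: dropout, monotone cohorts, disjoint supports", {
  # dropout = 1 pins every marker at blank level
  allDrop <- newCohortDesign(list(
    list(label = "X", n = 30, meanlog = log(500), sdlog = 0.3, dropout = 1)),
    blank = list(meanlog = log(5), sdlog = 0.5))
  ce <- simulateCohort(allDrop, seed = 1)
  expect_lt(max(markerMatrix(ce)), 50)  # far below the cohort's 500-copy scale

  # default design: per-marker cohort means strictly increasing HD < early
  # < advanced at n = 200 per cohort
  ce2 <- simulateCohort(cohortDesign(nHD = 200, nEarly = 200,
                                     nAdvanced = 200), seed = 2)
  m <- markerMatrix(ce2)
  lab <- cohortLabels(ce2)
  for (mk in ctcMarkers()) {
    means <- tapply(m[, mk], lab, mean)[c("HD", "early", "advanced")]
    expect_true(all(diff(means) > 0), info = mk)
  }

  # disjoint supports give a perfectly separating marker
  disj <- newCohortDesign(list(
    list(label = "HD", n = 25, meanlog = log(10), sdlog = 0.1, dropout = 0),
    list(label = "HCC", n = 25, meanlog = log(1e4), sdlog = 0.1,
         dropout = 0)))
  ce3 <- simulateCohort(disj, seed = 3)
  roc <- rocAnalysis(markerMatrix(ce3)[, "EpCAM_protein"],
                     cohortLabels(ce3) == "HCC")
  expect_equal(roc$auc, 1.0)

  expect_identical(markerMatrix(simulateCohort(disj, seed = 3)),
                   markerMatrix(ce3))
})

test_that("treatment pairs shift calibrated coordinates by the effect", {
  # mRNA loads well above the ASGPR level so calibrated coordinates stay
  # positive after the shift
  loc <- log(c(EpCAM_protein = 400, GPC3_protein = 300,
               ASGPR_protein = 50, EpCAM_mRNA = 600, GPC3_mRNA = 500,
               PDL1_mRNA = 100))
  des <- newCohortDesign(
    list(list(label = "HCC", n = 3, meanlog = loc, sdlog = 0.3,
              dropout = 0)),
    treatments = list(list(patient = "P1", cohort = "HCC",
                           effect = list(EpCAM = c(-1, -0.5),
                                         GPC3 = c(-0.2, 0)))))
  ce <- simulateCohort(des, seed = 9)
  ev <- cohortEfficacyVectors(ce)
  ep <- ev[ev$marker == "EpCAM", ]
  expect_equal(c(ep$dx, ep$dy), c(-1, -0.5), tolerance = 1e-9)
  gp <- ev[ev$marker == "GPC3", ]
  expect_equal(c(gp$dx, gp$dy), c(-0.2, 0), tolerance = 1e-9)
})

test_that("dilution series follows the probit detection model", {
  # detection probability forced to ~1 everywhere
  ht <- simulateDilutionSeries(c(10, 100, 1000), reps = 50,
                               intercept = 50, slope = 0, seed = 1)
  expect_true(all(ht$n_detected == 50))
  # Phi(1) at conc 10 under a = 0, b = 1
  ht2 <- simulateDilutionSeries(10, reps = 1000, intercept = 0, slope = 1,
                                seed = 2)
  phat <- ht2$n_detected / 1000
  expect_lt(abs(phat - pnorm(1)), 3 * sqrt(pnorm(1) * (1 - pnorm(1)) / 1000))
  # determinism
  expect_identical(ht2,
                   simulateDilutionSeries(10, reps = 1000, intercept = 0,
                                          slope = 1, seed = 2))
  expect_error(simulateDilutionSeries(c(-1, 2, 3), 5, 0, 1, seed = 1),
               "positive")
})
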
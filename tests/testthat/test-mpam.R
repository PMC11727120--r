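# Amplification-curve analysis: smoothing, 4PL fitting, closed-form Ct and
# growth rate, the conjunctive calling rule, and plate-level accuracy
# against simulator ground truth.

test_that("smoother fixes constants and exact lines, reduces noise", {
  expect_equal(smoothTrace(rep(5, 20), 5), rep(5, 20))
  lin <- 2 * (1:30)
  expect_equal(smoothTrace(lin, 5), lin, tolerance = 1e-12)
  expect_error(smoothTrace(1:10, 4), "odd")
  expect_error(smoothTrace(1:4, 7), "exceeds")

  # on a normalized-amplitude amplification curve, smoothing must bring the
  # trace closer to the noiseless signal in every replicate
  clean <- logisticTrace(F0 = 0.1, A = 1, k = 1, c50 = 26, noiseSd = 0)
  worse <- 0L
  for (s in 1:100) {
    set.seed(s)
    noisy <- clean + rnorm(length(clean), 0, 0.05)
    rmseRaw <- sqrt(mean((noisy - clean)^2))
    rmseSm <- sqrt(mean((smoothTrace(noisy, 3) - clean)^2))
    if (rmseSm >= rmseRaw) worse <- worse + 1L
  }
  set.seed(NULL)
  expect_equal(worse, 0L)
})

test_that("4PL fit recovers noiseless parameters and flags degenerate input", {
  y <- logisticTrace(F0 = 1, drift = 0, A = 10, k = 1.2, c50 = 26)
  fit <- fitAmplificationCurve(y)
  expect_true(fit$converged)
  expect_gt(fit$r2, 0.9999)
  expect_equal(fit$A, 10, tolerance = 1e-3)
  expect_equal(fit$k, 1.2, tolerance = 1e-3)
  expect_equal(fit$c50, 26, tolerance = 1e-3)
  expect_equal(fit$F0, 1, tolerance = 1e-3)

  # constant trace: amplitude ~0 and/or non-convergence; negative downstream
  flat <- fitAmplificationCurve(rep(2, 40))
  expect_true(!flat$converged || flat$A < 1e-6)

  # drift-only trace: fitted amplitude below any reasonable floor
  driftOnly <- 0.1 + 0.002 * (1:40)
  fd <- fitAmplificationCurve(driftOnly)
  expect_lt(if (fd$converged) fd$A else 0, 0.05)

  expect_error(fitAmplificationCurve(1:5), "6 cycles")
})

test_that("Ct and growth rate match the logistic closed forms", {
  f <- structure(list(A = 1, k = 1, c50 = 26, converged = TRUE, r2 = 1),
                 class = "curveFit")
  expect_equal(computeCt(f, 0.1), 26 - log(9), tolerance = 1e-9)
  expect_equal(computeCt(f, 0.5), 26, tolerance = 1e-12)
  fSteep <- structure(list(A = 1, k = 100, c50 = 26, converged = TRUE),
                      class = "curveFit")
  expect_lt(abs(computeCt(fSteep, 0.1) - 26), 0.05)

  g <- structure(list(A = 2, k = 1.56, converged = TRUE),
                 class = "curveFit")
  gr <- computeGrowthRate(g)
  expect_equal(gr[["normalized"]], 0.39, tolerance = 1e-9)
  expect_equal(gr[["raw"]], 2 * 0.39, tolerance = 1e-9)
  g2 <- g; g2$k <- 2 * g$k
  expect_equal(computeGrowthRate(g2)[["normalized"]],
               2 * gr[["normalized"]])
  g0 <- g; g0$k <- 0
  expect_equal(computeGrowthRate(g0)[["normalized"]], 0)

  # closed-form agreement on an exact fit to 1e-9
  y <- logisticTrace(F0 = 0.5, A = 3, k = 1.5, c50 = 24)
  fit <- fitAmplificationCurve(y)
  expect_equal(computeCt(fit, 0.1), fit$c50 - log(9) / fit$k,
               tolerance = 1e-9)
})

test_that("classification applies each criterion and names failures", {
  crit <- callCriteria()
  set.seed(7)
  flat <- fitAmplificationCurve(rnorm(40, 0.1, 0.02))
  ctF <- computeCt(flat)
  rF <- if (flat$converged) flat$k / 4 else NA_real_
  call <- classifyWell(flat, ctF, rF, crit, channel = "FAM", noiseSd = 0.02)
  expect_false(call$positive)
  expect_true("amplitude" %in% call$reasons || "r2" %in% call$reasons)

  clean <- logisticTrace(F0 = 0.1, A = 1, k = 4 * 0.39,
                         c50 = 26 + log(9) / (4 * 0.39))
  fit <- fitAmplificationCurve(clean)
  ct <- computeCt(fit)
  call2 <- classifyWell(fit, ct, fit$k / 4, crit, channel = "FAM",
                        noiseSd = 0.01)
  expect_true(call2$positive)
  expect_length(call2$reasons, 0)

  # Ct beyond the window maximum (38) is negative for exactly that reason
  late <- logisticTrace(F0 = 0.1, A = 1, k = 1.56,
                        c50 = 39.5 + log(9) / 1.56, nCycles = 40)
  fitL <- fitAmplificationCurve(late)
  ctL <- computeCt(fitL)
  callL <- classifyWell(fitL, ctL, fitL$k / 4, crit, channel = "FAM",
                        noiseSd = 0.01)
  expect_false(callL$positive)
  expect_true("ct_window" %in% callL$reasons)
})

test_that("plate calling is accurate, deterministic and monotone", {
  run <- miniPlate(nWells = 4000, lambda = 150, seed = 8)
  calls <- callPlate(run)
  tt <- truthTable(run)
  pos <- tt$molecules >= 1
  wc <- wellCalls(calls)
  expect_gte(mean(wc$positive[pos]), 0.99)       # sensitivity
  expect_gte(mean(!wc$positive[!pos]), 0.99)     # specificity
  expect_equal(abs(sum(wc$positive) - sum(pos)) / sum(pos), 0,
               tolerance = 0.02)

  # byte-identical on a rerun
  calls2 <- callPlate(run)
  expect_identical(wellCalls(calls), wellCalls(calls2))

  # tightening criteria can only reduce the positive count
  M0 <- plateSummary(calls)$M
  Mstrict <- plateSummary(callPlate(run, callCriteria(minR2 = 0.995)))$M
  Mrate <- plateSummary(
    callPlate(run, callCriteria(minGrowthRate = c(FAM = 0.45, VIC = 0.7,
                                                  CY5 = 0.3))))$M
  expect_lte(Mstrict, M0)
  expect_lte(Mrate, M0)

  # zero-template plate: M = 0 everywhere
  empty <- miniPlate(nWells = 500, lambda = 0, seed = 2,
                     channels = c("FAM", "VIC"))
  expect_true(all(plateSummary(callPlate(empty))$M == 0))
})

test_that("positive-well Ct distribution matches the channel setting", {
  run <- miniPlate(nWells = 4000, lambda = 400, seed = 10)
  s <- plateSummary(callPlate(run))
  se <- 0.88 / sqrt(s$M)
  expect_lt(abs(s$ct_mean - 26.83), 3 * se)
})
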
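# Per-microwell amplification-curve analysis: smoothing, four-parameter
# logistic fitting, Ct and growth-rate extraction, and the conjunctive
# positive/negative rule.  A well is positive only if its curve fits a
# logistic shape well (r2), rises by a real amplitude relative to its own
# baseline noise, crosses threshold inside the Ct window, and amplifies at a
# plausible channel-specific rate.

#' Well-calling criteria
#'
#' The positivity rule is conjunctive: a well is positive iff the 4PL fit
#' converged, r2 >= `minR2`, fitted amplitude >= `minAmplitudeSd` x the
#' well's baseline noise sd, Ct lies inside `ctWindow`, and the normalized
#' growth rate reaches the channel minimum.  Comparisons are inclusive
#' (`>=`/`<=`): a well exactly at a threshold is positive.  The per-channel
#' growth-rate floors default to the channel mean minus three channel sds
#' (0.39/0.66/0.25 minus 3 x 0.07/0.15/0.07), i.e. the lower edge of the
#' rate distribution seen on positive wells.
#'
#' @param minR2 minimum coefficient of determination of the 4PL fit.
#' @param minAmplitudeSd amplitude floor as a multiple of the baseline
#'   noise sd (estimated from the first `baselineCycles` cycles).
#' @param ctWindow admissible Ct range in cycles.
#' @param minGrowthRate named per-channel normalized rate floor.
#' @param smoothWindow odd moving-average window length.
#' @param ctThresholdFrac amplitude fraction defining Ct.
#' @param baselineCycles number of leading cycles treated as baseline.
#' @return a `callCriteria` list.
#' @export
callCriteria <- function(minR2 = 0.98,
                         minAmplitudeSd = 5,
                         ctWindow = c(10, 38),
                         minGrowthRate = c(FAM = 0.18, VIC = 0.21,
                                           CY5 = 0.04),
                         smoothWindow = 5L,
                         ctThresholdFrac = 0.1,
                         baselineCycles = 8L) {
  stopifnot(minR2 <= 1, minAmplitudeSd >= 0, length(ctWindow) == 2L,
            ctWindow[1] < ctWindow[2], smoothWindow >= 3L,
            smoothWindow %% 2L == 1L, baselineCycles >= 3L,
            ctThresholdFrac > 0, ctThresholdFrac < 1)
  structure(list(minR2 = minR2, minAmplitudeSd = minAmplitudeSd,
                 ctWindow = ctWindow, minGrowthRate = minGrowthRate,
                 smoothWindow = as.integer(smoothWindow),
                 ctThresholdFrac = ctThresholdFrac,
                 baselineCycles = as.integer(baselineCycles)),
            class = "callCriteria")
}

# Moving average along rows of a matrix with symmetric shrinking windows at
# the edges: at column j the half-width is min(h, j-1, n-j).  Symmetric
# shrinkage keeps straight lines exact everywhere, including the edges.
.smoothMatrix <- function(X, window) {
  n <- ncol(X)
  h <- (window - 1L) %/% 2L
  S <- X
  for (j in seq_len(n)) {
    hj <- min(h, j - 1L, n - j)
    if (hj > 0L)
      S[, j] <- rowMeans(X[, (j - hj):(j + hj), drop = FALSE])
  }
  S
}

#' Smooth one fluorescence trace
#'
#' Centered moving average with symmetrically shrinking windows at the
#' edges, so the output has the same length as the input and exactly linear
#' signals (constants included) are fixed points.
#'
#' @param trace numeric vector of per-cycle intensities.
#' @param window odd window length, `3 <= window <= length(trace)`.
#' @return smoothed numeric vector, same length.
#' @examples
#' smoothTrace(c(1, 2, 3, 4, 5), 3)   # linear: unchanged
#' @export
smoothTrace <- function(trace, window = 5L) {
  window <- as.integer(window)
  if (window %% 2L == 0L) stop("smoothing window must be odd")
  if (window > length(trace)) stop("smoothing window exceeds trace length")
  if (window < 3L) stop("smoothing window must be >= 3")
  drop(.smoothMatrix(matrix(trace, nrow = 1L), window))
}

#' Fit the four-parameter logistic amplification model to a trace
#'
#' Least-squares fit of
#' \deqn{F(c) = F_0 + d\,c + A / (1 + e^{-k (c - c_{50})})}
#' by Levenberg-Marquardt, initialized from the data (F0 = minimum,
#' A = range, c50 = cycle of the largest first difference of the smoothed
#' trace, k = 0.5).  Non-convergence is not an error: the fit is returned
#' with `converged = FALSE` and `A = 0`, which downstream classification
#' treats as negative.
#'
#' @param trace numeric vector of per-cycle intensities (>= 6 cycles).
#' @param cycles cycle index vector (default `seq_along(trace)`).
#' @return an object of class `curveFit`: list with `F0`, `drift`, `A`,
#'   `k`, `c50`, `r2`, `converged`.
#' @examples
#' cyc <- 1:40
#' y <- 1 + 10 / (1 + exp(-1.2 * (cyc - 26)))
#' fitAmplificationCurve(y)$c50
#' @export
fitAmplificationCurve <- function(trace, cycles = seq_along(trace)) {
  if (length(trace) < 6L)
    stop("cannot fit an amplification curve to fewer than 6 cycles")
  stopifnot(length(cycles) == length(trace), all(is.finite(trace)))
  sm <- if (length(trace) >= 5L) smoothTrace(trace, 5L) else trace
  init <- list(F0 = min(trace), drift = 0,
               A = max(diff(range(trace)), 1e-8),
               k = 0.5,
               c50 = cycles[which.max(diff(sm))])
  fit <- tryCatch(suppressWarnings(
    minpack.lm::nlsLM(
      y ~ F0 + drift * x + A / (1 + exp(-k * (x - c50))),
      data = list(y = trace, x = cycles),
      start = init,
      lower = c(F0 = -Inf, drift = -Inf, A = 0, k = 0, c50 = -Inf),
      control = minpack.lm::nls.lm.control(maxiter = 100))),
    error = function(e) NULL)
  if (is.null(fit)) {
    out <- list(F0 = init$F0, drift = 0, A = 0, k = 0, c50 = NA_real_,
                r2 = 0, converged = FALSE)
  } else {
    cf <- as.list(stats::coef(fit))
    resid <- trace - stats::predict(fit)
    sst <- sum((trace - mean(trace))^2)
    r2 <- if (sst > 0) 1 - sum(resid^2) / sst else 0
    out <- c(cf, list(r2 = r2, converged = TRUE))
  }
  structure(out, class = "curveFit")
}

#' @export
print.curveFit <- function(x, ...) {
  cat(sprintf(
    "4PL fit: F0=%.4g drift=%.4g A=%.4g k=%.4g c50=%.4g r2=%.5f%s\n",
    x$F0, x$drift, x$A, x$k, x$c50, x$r2,
    if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' Threshold-crossing Ct of a fitted curve
#'
#' The Ct is the (fractional) cycle at which the drift-corrected fitted
#' logistic crosses `thresholdFrac` of its amplitude:
#' \deqn{Ct = c_{50} - \ln(1/f - 1)/k.}
#'
#' @param fit a `curveFit` from [fitAmplificationCurve()].
#' @param thresholdFrac amplitude fraction in (0, 1); default 0.1.
#' @return Ct in cycles, or `NA` if the fit did not converge or has zero
#'   amplitude.
#' @examples
#' f <- structure(list(A = 1, k = 1, c50 = 26, converged = TRUE),
#'                class = "curveFit")
#' computeCt(f)          # 26 - log(9)
#' computeCt(f, 0.5)     # exactly c50
#' @export
computeCt <- function(fit, thresholdFrac = 0.1) {
  stopifnot(thresholdFrac > 0, thresholdFrac < 1)
  if (!isTRUE(fit$converged) || fit$A <= 0 || fit$k <= 0) return(NA_real_)
  fit$c50 - log(1 / thresholdFrac - 1) / fit$k
}

#' Fluorescence growth rate of a fitted curve
#'
#' The maximum per-cycle slope of the logistic component.  On the
#' amplitude-normalized scale this is k/4 (the channel-level summaries the
#' instrument reports are on this scale); the un-normalized slope A k/4 is
#' returned alongside.
#'
#' @param fit a `curveFit`.
#' @return named numeric: `normalized` (k/4) and `raw` (A k/4).
#' @examples
#' f <- structure(list(A = 2, k = 1.56, converged = TRUE),
#'                class = "curveFit")
#' computeGrowthRate(f)[["normalized"]]   # 0.39
#' @export
computeGrowthRate <- function(fit) {
  if (!isTRUE(fit$converged)) stop("growth rate requires a converged fit")
  c(normalized = fit$k / 4, raw = fit$A * fit$k / 4)
}

#' Classify a single well from its fit, Ct and growth rate
#'
#' Applies the conjunctive positivity rule of [callCriteria()].  Degenerate
#' fits are never errors: they are negative calls whose `reasons` name every
#' failed criterion (`"converged"`, `"r2"`, `"amplitude"`, `"ct_window"`,
#' `"growth_rate"`).
#'
#' @param fit a `curveFit`.
#' @param ct Ct from [computeCt()] (NA allowed).
#' @param rate normalized growth rate (k/4).
#' @param criteria a [callCriteria()] list.
#' @param channel channel name used to select the growth-rate floor.
#' @param noiseSd baseline noise sd of this well.
#' @return list of class `wellCall`: `positive`, `reasons`, `ct`, `rate`.
#' @export
classifyWell <- function(fit, ct, rate, criteria = callCriteria(),
                         channel = "FAM", noiseSd) {
  reasons <- character(0)
  if (!isTRUE(fit$converged)) reasons <- c(reasons, "converged")
  if (fit$r2 < criteria$minR2) reasons <- c(reasons, "r2")
  if (fit$A < criteria$minAmplitudeSd * noiseSd)
    reasons <- c(reasons, "amplitude")
  if (is.na(ct) || ct < criteria$ctWindow[1] || ct > criteria$ctWindow[2])
    reasons <- c(reasons, "ct_window")
  minRate <- criteria$minGrowthRate[[channel]]
  if (is.null(minRate)) minRate <- min(criteria$minGrowthRate)
  if (is.na(rate) || rate < minRate) reasons <- c(reasons, "growth_rate")
  structure(list(positive = length(reasons) == 0L, reasons = reasons,
                 ct = ct, rate = rate), class = "wellCall")
}

# Vectorized per-trace statistics used by callPlate:
#  - baseline line (OLS on the first nb smoothed cycles) and residual noise
#    sd of the raw trace about that line over the baseline region;
#  - residual sd about the best straight line through the WHOLE trace.
# A trace that a straight line explains to within baseline noise has no
# amplification component above the amplitude floor, so only traces whose
# whole-trace line residuals clearly exceed baseline noise go to the full
# nonlinear fit.
.traceScreenStats <- function(X, S, nb) {
  n <- ncol(X)
  xb <- seq_len(nb)
  xbC <- xb - mean(xb)
  sb <- S[, xb, drop = FALSE]
  slopeB <- (sb %*% xbC) / sum(xbC^2)
  interceptB <- rowMeans(sb) - slopeB * mean(xb)
  fittedB <- interceptB %*% t(rep(1, nb)) + slopeB %*% t(xb)
  residB <- X[, xb, drop = FALSE] - fittedB
  noiseSd <- sqrt(pmax(rowSums(residB^2) / (nb - 2L), 0))

  xa <- seq_len(n)
  xaC <- xa - mean(xa)
  slopeA <- (X %*% xaC) / sum(xaC^2)
  fittedA <- rowMeans(X) %*% t(rep(1, n)) + slopeA %*% t(xaC)
  lineResidSd <- sqrt(rowSums((X - fittedA)^2) / (n - 2L))
  list(noiseSd = drop(noiseSd), lineResidSd = drop(lineResidSd))
}

#' Call every well of a plate
#'
#' Runs the smoothing - fitting - Ct - growth-rate - classification chain on
#' every trace and tabulates positive counts per (region, channel).  For
#' throughput on ~1e5-well plates, traces whose best straight-line fit
#' already explains them to within 3x their baseline noise are classified
#' negative (failed amplitude criterion) without the nonlinear fit; all
#' remaining traces get the full treatment.  Deterministic given the input
#' and criteria.
#'
#' @param run a \linkS4class{PlateRun}.
#' @param criteria a [callCriteria()] list.
#' @return a \linkS4class{PlateCalls}.
#' @examples
#' run <- simulatePlate(plateSimParams(nWells = 300, targetCopies = 30,
#'                                     regions = "protein",
#'                                     channels = "FAM"), seed = 1)
#' plateSummary(callPlate(run))
#' @export
callPlate <- function(run, criteria = callCriteria()) {
  stopifnot(is(run, "PlateRun"))
  X <- traceMatrix(run)
  if (nrow(X) == 0L) stop("empty plate: no traces to call")
  info <- traceInfo(run)
  n <- ncol(X)
  if (n < 6L) stop("plates with fewer than 6 cycles cannot be called")

  S <- .smoothMatrix(X, criteria$smoothWindow)
  st <- .traceScreenStats(X, S, criteria$baselineCycles)

  candidate <- st$lineResidSd > 3 * st$noiseSd
  nt <- nrow(X)
  positive <- logical(nt)
  ct <- rep(NA_real_, nt)
  rate <- rep(NA_real_, nt)
  r2 <- rep(NA_real_, nt)
  reasons <- character(nt)
  reasons[!candidate] <- "amplitude"

  for (i in which(candidate)) {
    fit <- fitAmplificationCurve(X[i, ])
    cti <- computeCt(fit, criteria$ctThresholdFrac)
    ri <- if (isTRUE(fit$converged)) fit$k / 4 else NA_real_
    call <- classifyWell(fit, cti, ri, criteria,
                         channel = info$channel[i],
                         noiseSd = st$noiseSd[i])
    positive[i] <- call$positive
    ct[i] <- cti
    rate[i] <- ri
    r2[i] <- fit$r2
    reasons[i] <- paste(call$reasons, collapse = ";")
  }

  calls <- data.frame(region = info$region, channel = info$channel,
                      well_id = info$well_id, positive = positive,
                      ct = ct, growth_rate = rate, r2 = r2,
                      reasons = reasons, stringsAsFactors = FALSE)

  grp <- interaction(calls$region, calls$channel, drop = TRUE)
  summ <- do.call(rbind, lapply(levels(grp), function(g) {
    idx <- grp == g
    pos <- idx & calls$positive
    data.frame(region = calls$region[idx][1L],
               channel = calls$channel[idx][1L],
               M = sum(pos), N = sum(idx),
               ct_mean = if (any(pos)) mean(calls$ct[pos]) else NA_real_,
               ct_sd = if (sum(pos) > 1L) stats::sd(calls$ct[pos])
                       else NA_real_,
               rate_mean = if (any(pos)) mean(calls$growth_rate[pos])
                           else NA_real_,
               rate_sd = if (sum(pos) > 1L) stats::sd(calls$growth_rate[pos])
                         else NA_real_,
               stringsAsFactors = FALSE)
  }))
  new("PlateCalls", calls = calls, summary = summ,
      criteria = unclass(criteria))
}
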
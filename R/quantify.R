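# Absolute quantification from partition counts and the surrounding assay
# analytics.  The digital PCR estimator inverts the Poisson occupancy law:
# with M of N equal partitions positive, the copies loaded per reaction are
# X = -N ln(1 - M/N).

#' Poisson absolute quantification from positive-partition counts
#'
#' \deqn{X = -N \ln(1 - M/N)}
#' The 95% interval is obtained from the Wilson score interval on the
#' positive fraction p = M/N, propagated through the (monotone) transform.
#' A saturated plate (M = N) has no finite estimate; it is reported at
#' M = N - 0.5 with `saturated = TRUE`.
#'
#' @param M positive wells (0 <= M <= N); vectorized.
#' @param N total analyzed wells (>= 1).
#' @param conf confidence level of the interval.
#' @return data.frame with columns `M`, `N`, `copies`, `ci_low`, `ci_high`,
#'   `saturated`.
#' @examples
#' poissonQuantify(507, 20000)$copies    # ~513.5
#' poissonQuantify(10000, 20000)$copies  # 20000 * log(2)
#' @export
poissonQuantify <- function(M, N, conf = 0.95) {
  if (any(N < 1)) stop("N must be >= 1")
  if (any(M < 0) || any(M > N)) stop("M must satisfy 0 <= M <= N")
  n <- max(length(M), length(N))
  M <- rep_len(M, n); N <- rep_len(N, n)
  saturated <- M == N
  Meff <- ifelse(saturated, N - 0.5, M)
  p <- Meff / N
  X <- -N * log1p(-p)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  # Wilson score interval on p, then through -N log(1 - p)
  denom <- 1 + z^2 / N
  centre <- (p + z^2 / (2 * N)) / denom
  half <- (z / denom) * sqrt(p * (1 - p) / N + z^2 / (4 * N^2))
  pLo <- pmax(centre - half, 0)
  pHi <- pmin(centre + half, 1 - 1e-12)
  data.frame(M = M, N = N, copies = X,
             ci_low = -N * log1p(-pLo), ci_high = -N * log1p(-pHi),
             saturated = saturated)
}

#' Nonparametric limit of blank
#'
#' Percentile of repeated blank measurements by the rank-interpolation
#' convention r = 0.5 + p n: the LOB is the linear interpolation between the
#' floor(r)-th and ceiling(r)-th order statistics, clipped to the observed
#' range.
#'
#' @param blanks numeric vector of blank-measurement copies (>= 2 values).
#' @param percentile percentile in (0, 1); default 0.95.
#' @return the LOB in the units of `blanks`.
#' @examples
#' limitOfBlank(1:12)          # rank 11.9 -> 11.9
#' limitOfBlank(rep(0, 12))    # 0
#' @export
limitOfBlank <- function(blanks, percentile = 0.95) {
  if (length(blanks) < 2L) stop("need at least 2 blank measurements")
  stopifnot(percentile > 0, percentile < 1)
  s <- sort(blanks)
  n <- length(s)
  r <- 0.5 + percentile * n
  lo <- floor(r); hi <- ceiling(r)
  if (lo < 1) return(s[1L])
  if (hi > n) return(s[n])
  v <- if (lo == hi) s[lo] else s[lo] + (r - lo) * (s[hi] - s[lo])
  min(max(v, s[1L]), s[n])
}

#' Probit limit of detection from a detection hit table
#'
#' Maximum-likelihood binomial regression of the detected fraction on
#' log10(concentration) with a probit link; the LOD at detection probability
#' `targetP` is
#' \deqn{LOD = 10^{(\Phi^{-1}(p) - a)/b}.}
#' If every row is fully detected the dose-response is uninformative: the
#' lowest tested concentration is returned with `converged = FALSE`.  A
#' non-positive slope (non-monotone detection) is likewise flagged.
#'
#' @param hits data.frame with columns `conc`, `n_replicates`, `n_detected`
#'   (as produced by [simulateDilutionSeries()]).
#' @param targetP target detection probability; default 0.95.
#' @return list of class `lodResult`: `lod`, `lob` slot left `NA` (see
#'   [limitOfBlank()]), `intercept`, `slope`, `converged`.
#' @examples
#' ht <- simulateDilutionSeries(10^seq(0.5, 3, by = 0.5), reps = 1000,
#'                              intercept = -2, slope = 2, seed = 1)
#' lodProbit(ht)$lod
#' @export
lodProbit <- function(hits, targetP = 0.95) {
  stopifnot(all(c("conc", "n_replicates", "n_detected") %in% names(hits)))
  if (length(unique(hits$conc)) < 3L)
    stop("need at least 3 distinct concentrations")
  if (any(hits$n_detected > hits$n_replicates) || any(hits$n_detected < 0))
    stop("0 <= n_detected <= n_replicates violated")
  res <- list(lod = NA_real_, intercept = NA_real_, slope = NA_real_,
              converged = FALSE)
  if (all(hits$n_detected == hits$n_replicates)) {
    res$lod <- min(hits$conc)
    class(res) <- "lodResult"
    return(res)
  }
  fit <- suppressWarnings(stats::glm(
    cbind(n_detected, n_replicates - n_detected) ~ log10(conc),
    family = stats::binomial(link = "probit"), data = hits))
  a <- stats::coef(fit)[[1L]]
  b <- stats::coef(fit)[[2L]]
  res$intercept <- a; res$slope <- b
  if (is.finite(b) && b > 0) {
    res$lod <- 10^((stats::qnorm(targetP) - a) / b)
    res$converged <- isTRUE(fit$converged)
  }
  class(res) <- "lodResult"
  res
}

#' @export
print.lodResult <- function(x, ...) {
  cat(sprintf("probit LOD: %.4g (intercept %.4g, slope %.4g)%s\n",
              x$lod, x$intercept, x$slope,
              if (x$converged) "" else " [not converged]"))
  invisible(x)
}

#' Percent coefficient of variation
#'
#' 100 x sample sd (n-1 denominator) / mean.
#'
#' @param values numeric vector, >= 2 values, nonzero mean.
#' @return %CV.
#' @examples
#' percentCV(c(8, 10, 12))   # 20
#' @export
percentCV <- function(values) {
  if (length(values) < 2L) stop("need at least 2 values")
  m <- mean(values)
  if (m == 0) stop("%CV undefined for zero mean")
  100 * stats::sd(values) / m
}

#' Standard curve of copies against cell count
#'
#' Ordinary least squares of measured copies on the number of cells, with
#' the coefficient of determination used to judge assay linearity.
#'
#' @param cells predictor (cell counts), >= 3 points, >= 2 distinct values.
#' @param copies response (measured copies).
#' @return list of class `standardCurve`: `slope`, `intercept`, `r2`,
#'   `range` (of the predictor).
#' @examples
#' standardCurve(c(0, 10, 20, 50), 10 * c(0, 10, 20, 50) + 5)
#' @export
standardCurve <- function(cells, copies) {
  stopifnot(length(cells) == length(copies))
  if (length(cells) < 3L) stop("need at least 3 points")
  if (length(unique(cells)) < 2L) stop("need at least 2 distinct cell counts")
  fit <- stats::lm(copies ~ cells)
  # exact fits trigger a harmless "essentially perfect fit" note
  r2 <- suppressWarnings(summary(fit)$r.squared)
  structure(list(slope = stats::coef(fit)[[2L]],
                 intercept = stats::coef(fit)[[1L]],
                 r2 = r2,
                 range = range(cells)),
            class = "standardCurve")
}

#' @export
print.standardCurve <- function(x, ...) {
  cat(sprintf("standard curve: y = %.4g x + %.4g, r2 = %.4f\n",
              x$slope, x$intercept, x$r2))
  invisible(x)
}

#' Amplification efficiency from a dilution series
#'
#' Fits Ct against log10(concentration); the per-cycle efficiency is
#' \deqn{E = (10^{-1/slope} - 1) \times 100\%}
#' (100% means perfect doubling, slope -1/log10(2) ~ -3.32).
#'
#' @param cts Ct values.
#' @param concentrations template concentrations spanning >= 2 logs.
#' @return efficiency in percent.
#' @examples
#' conc <- 10^(1:4)
#' qpcrEfficiency(30 - log2(10) * (1:4), conc)  # 100
#' @export
qpcrEfficiency <- function(cts, concentrations) {
  stopifnot(length(cts) == length(concentrations))
  if (length(cts) < 3L) stop("need at least 3 dilution points")
  lg <- log10(concentrations)
  if (diff(range(lg)) < 2) stop("dilution series must span >= 2 logs")
  slope <- stats::coef(stats::lm(cts ~ lg))[[2L]]
  if (slope >= 0) stop("non-negative slope: Ct must fall with concentration")
  (10^(-1 / slope) - 1) * 100
}

#' Fold change by the 2^-ddCt method
#'
#' Small comparison utility for relative quantification:
#' fold = 2^-((Ct_target,case - Ct_ref,case) - (Ct_target,ctrl - Ct_ref,ctrl)).
#'
#' @param ctTargetCase,ctRefCase,ctTargetCtrl,ctRefCtrl finite Ct values.
#' @return fold change.
#' @examples
#' ddctFoldChange(20, 15, 23, 15)   # ddCt = -3 -> 8
#' @export
ddctFoldChange <- function(ctTargetCase, ctRefCase, ctTargetCtrl, ctRefCtrl) {
  stopifnot(is.finite(ctTargetCase), is.finite(ctRefCase),
            is.finite(ctTargetCtrl), is.finite(ctRefCtrl))
  2^-((ctTargetCase - ctRefCase) - (ctTargetCtrl - ctRefCtrl))
}

#' Quantify a called plate
#'
#' Applies [poissonQuantify()] to each (region, channel) cell of a
#' \linkS4class{PlateCalls} summary and attaches the marker names from the
#' panel map.
#'
#' @param calls a \linkS4class{PlateCalls}.
#' @param panel a panel map as from [defaultPanel()].
#' @param dilutionFactor optional multiplier from copies per reaction to the
#'   reporting scale (e.g. copies per mL); default 1 (copies per reaction).
#' @return data.frame: `region`, `channel`, `marker`, `M`, `N`, `copies`,
#'   `ci_low`, `ci_high`, `saturated`.
#' @examples
#' run <- simulatePlate(plateSimParams(nWells = 300, targetCopies = 30,
#'                                     regions = "protein",
#'                                     channels = "FAM"), seed = 1)
#' quantifyPlate(callPlate(run))
#' @export
quantifyPlate <- function(calls, panel = defaultPanel(),
                          dilutionFactor = 1) {
  s <- plateSummary(calls)
  q <- poissonQuantify(s$M, s$N)
  q$copies <- q$copies * dilutionFactor
  q$ci_low <- q$ci_low * dilutionFactor
  q$ci_high <- q$ci_high * dilutionFactor
  out <- cbind(s[, c("region", "channel")], q)
  key <- paste(panel$region, panel$channel)
  out$marker <- panel$marker[match(paste(out$region, out$channel), key)]
  out[, c("region", "channel", "marker", "M", "N", "copies",
          "ci_low", "ci_high", "saturated")]
}
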
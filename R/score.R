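# Six-marker digital scoring: log2(x+1) transform, Z standardization
# against a declared reference population, AHP criterion weights with a
# consistency check, the composite weighted Z-score, a ridge-stabilized
# logistic combiner, and ROC diagnostics.

#' log2(x + 1) transform of a copy-number matrix
#'
#' @param x nonnegative numeric matrix (samples x markers) or vector.
#' @return elementwise log2(x + 1), same shape.
#' @examples
#' transformCounts(c(0, 7, 1023))
#' @export
transformCounts <- function(x) {
  if (any(x < 0)) stop("copy numbers must be nonnegative")
  log2(x + 1)
}

#' Z-standardize a marker matrix against a reference population
#'
#' z = (x - mu_ref) / sigma_ref per marker column, where mu/sigma are the
#' mean and sd over the reference rows.  A zero-sd (constant) reference
#' column yields all-zero z for that marker with a warning.
#'
#' @param x numeric matrix, samples x markers.
#' @param reference row selector (logical/integer) naming the reference
#'   population; default all rows.
#' @return list of class `zScore`: `z` (matrix), `mu`, `sigma` (named per
#'   marker), `reference` (a label).
#' @examples
#' m <- matrix(rnorm(20, 10), 10, 2, dimnames = list(NULL, c("a", "b")))
#' colMeans(zscoreMatrix(m)$z)   # ~0
#' @export
zscoreMatrix <- function(x, reference = NULL) {
  x <- as.matrix(x)
  if (is.null(reference)) {
    refRows <- seq_len(nrow(x)); label <- "all"
  } else {
    refRows <- reference; label <- "subset"
  }
  xr <- x[refRows, , drop = FALSE]
  if (nrow(xr) < 2L) stop("reference population needs >= 2 samples")
  mu <- colMeans(xr)
  sigma <- apply(xr, 2L, stats::sd)
  z <- sweep(sweep(x, 2L, mu, "-"), 2L, sigma, "/")
  if (any(sigma == 0)) {
    warning("constant reference column(s): ",
            paste(colnames(x)[sigma == 0], collapse = ", "),
            "; z set to 0")
    z[, sigma == 0] <- 0
  }
  structure(list(z = z, mu = mu, sigma = sigma, reference = label),
            class = "zScore")
}

# Saaty random consistency indices, n = 1..10.
.ahpRandomIndex <- c(0, 0, 0.58, 0.90, 1.12, 1.24, 1.32, 1.41, 1.45, 1.49)

#' AHP weights from a pairwise comparison matrix
#'
#' Criterion weights are the principal right eigenvector of the reciprocal
#' pairwise comparison matrix, obtained by power iteration (tolerance
#' 1e-10) and normalized to sum to 1.  Consistency is judged by
#' CI = (lambda_max - n)/(n - 1) and CR = CI/RI with Saaty's random indices
#' (RI = 0.58 at n = 3, 1.24 at n = 6); CR > 0.1 is an error unless
#' `allowInconsistent = TRUE`.
#'
#' @param A square reciprocal matrix, unit diagonal, entries in [1/9, 9].
#' @param allowInconsistent override the CR > 0.1 error.
#' @param tol power-iteration convergence tolerance.
#' @return list of class `ahp`: `weights` (sums to 1), `lambdaMax`, `ci`,
#'   `cr`.
#' @examples
#' ahpWeights(matrix(1, 6, 6))$weights   # 1/6 each
#' @export
ahpWeights <- function(A, allowInconsistent = FALSE, tol = 1e-10) {
  A <- as.matrix(A)
  n <- nrow(A)
  stopifnot(n == ncol(A), n >= 2L)
  if (any(A <= 0)) stop("comparison matrix entries must be positive")
  if (max(abs(A * t(A) - 1)) > 1e-9)
    stop("comparison matrix must be reciprocal (a_ji = 1/a_ij)")
  if (any(A < 1 / 9 - 1e-9) || any(A > 9 + 1e-9))
    stop("comparison entries must lie in [1/9, 9]")
  w <- rep(1 / n, n)
  for (it in seq_len(10000L)) {
    v <- drop(A %*% w)
    wNew <- v / sum(v)
    if (max(abs(wNew - w)) < tol) { w <- wNew; break }
    w <- wNew
  }
  lambdaMax <- mean(drop(A %*% w) / w)
  ci <- (lambdaMax - n) / (n - 1)
  ri <- if (n <= length(.ahpRandomIndex)) .ahpRandomIndex[n] else 1.49
  cr <- if (ri > 0) ci / ri else 0
  if (cr > 0.1 && !allowInconsistent)
    stop(sprintf(paste0("AHP consistency ratio %.3f exceeds 0.1; revise ",
                        "the comparison matrix or set ",
                        "allowInconsistent = TRUE"), cr))
  if (!is.null(rownames(A))) names(w) <- rownames(A)
  structure(list(weights = w, lambdaMax = lambdaMax, ci = ci, cr = cr),
            class = "ahp")
}

#' Composite weighted Z-score per sample
#'
#' The composite CTC score of a sample is the weighted sum of its per-marker
#' Z-scores.
#'
#' @param z samples x markers Z matrix.
#' @param weights named weight vector matching the marker columns.
#' @return named numeric vector, one score per sample.
#' @examples
#' z <- matrix(1, 2, 3, dimnames = list(NULL, c("a", "b", "c")))
#' compositeScore(z, c(a = 0.5, b = 0.3, c = 0.2))   # 1 1
#' @export
compositeScore <- function(z, weights) {
  z <- as.matrix(z)
  if (!is.null(colnames(z)) && !is.null(names(weights))) {
    if (!setequal(colnames(z), names(weights)))
      stop("weight names do not match the marker columns")
    weights <- weights[colnames(z)]
  } else if (ncol(z) != length(weights)) {
    stop("one weight per marker column required")
  }
  drop(z %*% weights)
}

#' Score a cohort: transform, standardize, weight, combine
#'
#' End-to-end digital scoring of a \linkS4class{CohortExperiment}: copies
#' are log2(x+1)-transformed, Z-standardized against the chosen reference
#' population, weighted by the AHP weights of `ahp` (the default all-ones
#' comparison matrix gives equal weights 1/6 -- the neutral choice when no
#' expert pairwise judgments are supplied) and summed into the composite
#' score.
#'
#' @param ce a \linkS4class{CohortExperiment}.
#' @param ahp pairwise comparison matrix over the six markers, or `NULL`
#'   for equal weights.
#' @param reference `"all"` (standardize within the analyzed batch, the
#'   default, matching how marker heatmaps are scaled) or `"healthy"`
#'   (standardize against the cohort named by `healthyLabel`, appropriate
#'   for diagnostic scoring).
#' @param healthyLabel cohort label of the healthy reference.
#' @param allowInconsistent passed to [ahpWeights()].
#' @return a \linkS4class{ScoreResult}.
#' @examples
#' ce <- simulateCohort(cohortDesign(nHD = 6, nEarly = 6, nAdvanced = 6),
#'                      seed = 2)
#' sr <- scoreCohort(ce)
#' head(compositeScores(sr))
#' @export
scoreCohort <- function(ce, ahp = NULL, reference = c("all", "healthy"),
                        healthyLabel = "HD", allowInconsistent = FALSE) {
  stopifnot(is(ce, "CohortExperiment"))
  reference <- match.arg(reference)
  m <- transformCounts(markerMatrix(ce))
  refRows <- if (reference == "healthy") {
    which(cohortLabels(ce) == healthyLabel)
  } else NULL
  zs <- zscoreMatrix(m, refRows)
  if (is.null(ahp)) ahp <- matrix(1, 6, 6,
                                  dimnames = list(ctcMarkers(), ctcMarkers()))
  aw <- ahpWeights(ahp, allowInconsistent = allowInconsistent)
  w <- aw$weights
  if (is.null(names(w))) names(w) <- colnames(zs$z)
  comp <- compositeScore(zs$z, w)
  names(comp) <- rownames(m)
  new("ScoreResult", z = zs$z, weights = w, composite = comp,
      mu = zs$mu, sigma = zs$sigma,
      reference = if (reference == "healthy") healthyLabel else "all",
      cr = aw$cr, cohort = as.character(cohortLabels(ce)))
}

#' Ridge-stabilized binary logistic regression
#'
#' Maximum-likelihood logistic fit by Newton-Raphson with a small L2
#' penalty (default 1e-6, not applied to the intercept) so that perfectly
#' separable cohorts still yield finite coefficients; separation is
#' detected and flagged rather than erroring.
#'
#' @param x feature matrix (or vector) of n samples.
#' @param y binary labels (0/1, logical, or 2-level factor).
#' @param ridge L2 penalty on the non-intercept coefficients.
#' @param maxit,tol Newton iteration controls.
#' @return list of class `logisticFit`: `coefficients` (incl. intercept),
#'   `probabilities`, `separation` flag, `converged`.
#' @examples
#' fit <- logisticCombine(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1))
#' fit$separation
#' @export
logisticCombine <- function(x, y, ridge = 1e-6, maxit = 100L, tol = 1e-10) {
  X <- as.matrix(x)
  if (is.factor(y)) y <- as.integer(y) - 1L
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("labels must be binary")
  if (length(unique(y)) < 2L) stop("both classes must be present")
  if (min(table(y)) < 2L) stop("need >= 2 samples per class")
  n <- nrow(X)
  Xd <- cbind(`(Intercept)` = 1, X)
  p <- ncol(Xd)
  pen <- c(0, rep(ridge, p - 1L))
  beta <- numeric(p)
  converged <- FALSE
  for (it in seq_len(maxit)) {
    eta <- drop(Xd %*% beta)
    mu <- stats::plogis(eta)
    wts <- pmax(mu * (1 - mu), 1e-12)
    grad <- drop(crossprod(Xd, y - mu)) - pen * beta
    H <- crossprod(Xd * wts, Xd) + diag(pen, p)
    step <- solve(H, grad)
    beta <- beta + step
    if (max(abs(step)) < tol) { converged <- TRUE; break }
  }
  eta <- drop(Xd %*% beta)
  prob <- stats::plogis(eta)
  separation <- all(prob[y == 1] > 1 - 1e-6) && all(prob[y == 0] < 1e-6)
  if (is.null(colnames(X))) {
    names(beta) <- c("(Intercept)", paste0("x", seq_len(p - 1L)))
  } else names(beta) <- c("(Intercept)", colnames(X))
  structure(list(coefficients = beta, probabilities = prob,
                 separation = separation, converged = converged),
            class = "logisticFit")
}

#' ROC analysis with Youden-optimal cutoff
#'
#' The AUC is the Mann-Whitney rank statistic (tied score pairs count
#' half), i.e. the probability a random positive outscores a random
#' negative.  Candidate cutoffs are the unique observed scores (rule: score
#' >= cutoff is called positive) plus +Inf; the reported cutoff maximizes
#' Youden's J = sensitivity + specificity - 1, ties broken toward the
#' higher-specificity (higher) cutoff.
#'
#' @param scores numeric scores, higher = more disease-like.
#' @param labels binary labels (0/1, logical, or 2-level factor whose
#'   second level is the positive class).
#' @return list of class `rocResult`: `auc`, `cutoff`, `sensitivity`,
#'   `specificity`, `curve` (data.frame of cutoff/sens/spec).
#' @examples
#' rocAnalysis(c(1, 2, 3, 4), c(0, 1, 0, 1))$auc   # 0.75
#' @export
rocAnalysis <- function(scores, labels) {
  if (is.factor(labels)) labels <- as.integer(labels) - 1L
  labels <- as.numeric(labels)
  if (!all(labels %in% c(0, 1))) stop("labels must be binary")
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores)
  auc <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  cutoffs <- c(sort(unique(scores)), Inf)
  sens <- vapply(cutoffs, function(ct) sum(scores >= ct & labels == 1) / n1,
                 0)
  spec <- vapply(cutoffs, function(ct) sum(scores < ct & labels == 0) / n0,
                 0)
  j <- sens + spec - 1
  best <- which(j == max(j))
  # ties in J -> higher specificity; cutoffs ascend so specificity ascends
  best <- best[which.max(spec[best])]
  structure(list(auc = auc, cutoff = cutoffs[best],
                 sensitivity = sens[best], specificity = spec[best],
                 curve = data.frame(cutoff = cutoffs, sensitivity = sens,
                                    specificity = spec)),
            class = "rocResult")
}

#' @export
print.rocResult <- function(x, ...) {
  cat(sprintf(
    "ROC: AUC = %.4f; Youden cutoff %.4g (sens %.3f, spec %.3f)\n",
    x$auc, x$cutoff, x$sensitivity, x$specificity))
  invisible(x)
}
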
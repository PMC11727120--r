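# 2D protein-mRNA molecular profiling.  Because the number of CTCs captured
# varies between samples, raw marker copies are not comparable across
# samples; dividing by the ASGPR protein signal (a hepatocyte-lineage
# capture surrogate, plus a pseudocount) rescales each sample to an
# approximately per-cell level.  On that calibrated plane a trained 2-class
# boundary splits samples into region P1 (the healthy-like side) and P2
# (marker-expressing CTC profiles), and pre/post-treatment displacements
# become efficacy vectors.

#' ASGPR calibration of one sample's marker copies
#'
#' calibrated level = marker copies / (ASGPR protein copies + pseudocount),
#' applied to EpCAM and GPC-3 at both the mRNA (x) and protein (y) level.
#'
#' @param copies named numeric vector of the six marker copies (names as
#'   [ctcMarkers()]).
#' @param pseudocount added to the ASGPR denominator; default 1, so samples
#'   with zero ASGPR keep their raw copies.
#' @return data.frame with one row per marker (EpCAM, GPC3) and columns
#'   `marker`, `x` (calibrated mRNA), `y` (calibrated protein).
#' @examples
#' v <- setNames(c(100, 40, 49, 80, 20, 5), ctcMarkers())
#' asgprCalibrate(v)   # EpCAM: x = 80/50, y = 100/50
#' @export
asgprCalibrate <- function(copies, pseudocount = 1) {
  if (!all(ctcMarkers() %in% names(copies)))
    stop("copies must be named by the six panel markers")
  asg <- copies[["ASGPR_protein"]]
  if (is.na(asg)) stop("ASGPR protein copies missing")
  denom <- asg + pseudocount
  data.frame(
    marker = c("EpCAM", "GPC3"),
    x = c(copies[["EpCAM_mRNA"]], copies[["GPC3_mRNA"]]) / denom,
    y = c(copies[["EpCAM_protein"]], copies[["GPC3_protein"]]) / denom,
    stringsAsFactors = FALSE)
}

#' Calibrate every sample of a cohort
#'
#' @param ce a \linkS4class{CohortExperiment}.
#' @param pseudocount see [asgprCalibrate()].
#' @return data.frame with columns `sample_id`, `cohort`, `timepoint`,
#'   `patient`, `marker`, `x`, `y`.
#' @export
calibrateCohort <- function(ce, pseudocount = 1) {
  stopifnot(is(ce, "CohortExperiment"))
  m <- markerMatrix(ce)
  cd <- as.data.frame(SummarizedExperiment::colData(ce))
  out <- do.call(rbind, lapply(seq_len(nrow(m)), function(i) {
    cal <- asgprCalibrate(m[i, ], pseudocount)
    cbind(sample_id = rownames(m)[i], cohort = cd$cohort[i],
          timepoint = cd$timepoint[i], patient = cd$patient[i], cal)
  }))
  rownames(out) <- NULL
  out
}

.standardize <- function(X, center, scale) {
  sweep(sweep(X, 2L, center, "-"), 2L, pmax(scale, 1e-12), "/")
}

.classifierMetrics <- function(truth, pred, positive) {
  tp <- sum(pred == positive & truth == positive)
  fp <- sum(pred == positive & truth != positive)
  fn <- sum(pred != positive & truth == positive)
  acc <- mean(pred == truth)
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  rec <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (is.na(prec) || is.na(rec) || prec + rec == 0) NA_real_
        else 2 * prec * rec / (prec + rec)
  c(accuracy = acc, precision = prec, recall = rec, f1 = f1)
}

#' Fit the P1/P2 region classifier on the calibrated plane
#'
#' Standardizes the 2D features with the training-set mean/sd, trains the
#' chosen classifier (support-vector classification with a linear,
#' polynomial degree-3 or radial kernel, C = 1, via \pkg{e1071}; or a
#' Gaussian naive Bayes baseline), and labels the boundary sides: P1 is the
#' side on which the healthy-cohort centroid falls, P2 the other.
#' Accuracy, precision, recall and F1 are reported from stratified k-fold
#' cross-validation (k reduced with a warning when a class is smaller
#' than k).
#'
#' @param points numeric matrix/data.frame with two columns (calibrated
#'   mRNA = x, protein = y).
#' @param labels two-class factor/character (e.g. HD vs HCC).
#' @param kernel `"poly"` (default), `"linear"`, `"radial"` or `"gnb"`.
#' @param healthyLabel the label whose centroid defines P1.
#' @param k cross-validation folds (default 5).
#' @param seed integer seed controlling fold assignment.
#' @param cost,degree SVC hyperparameters.
#' @return a \linkS4class{RegionModel}.
#' @examples
#' set.seed(1)
#' pts <- rbind(matrix(rnorm(40, 0), ncol = 2),
#'              matrix(rnorm(40, 5), ncol = 2))
#' lab <- rep(c("HD", "HCC"), each = 20)
#' fitRegionClassifier(pts, lab, seed = 1)
#' @export
fitRegionClassifier <- function(points, labels,
                                kernel = c("poly", "linear", "radial",
                                           "gnb"),
                                healthyLabel = "HD", k = 5L, seed = 1L,
                                cost = 1, degree = 3L) {
  kernel <- match.arg(kernel)
  X <- as.matrix(points)
  stopifnot(ncol(X) == 2L)
  labels <- as.character(labels)
  cls <- sort(unique(labels))
  if (length(cls) != 2L) stop("exactly two classes required")
  if (min(table(labels)) < 3L) stop("need >= 3 points per class")
  if (!healthyLabel %in% cls)
    stop("healthyLabel '", healthyLabel, "' not among the labels")
  center <- colMeans(X)
  scale <- apply(X, 2L, stats::sd)
  Xs <- .standardize(X, center, scale)
  y <- factor(labels, levels = cls)

  trainOne <- function(Xtr, ytr) {
    if (kernel == "gnb") {
      e1071::naiveBayes(x = as.data.frame(Xtr), y = droplevels(ytr))
    } else {
      svmKernel <- switch(kernel, poly = "polynomial", linear = "linear",
                          radial = "radial")
      e1071::svm(x = Xtr, y = droplevels(ytr), kernel = svmKernel,
                 cost = cost, degree = degree, scale = FALSE)
    }
  }
  predictOne <- function(model, Xnew) {
    if (kernel == "gnb")
      stats::predict(model, as.data.frame(Xnew))
    else stats::predict(model, Xnew)
  }

  model <- trainOne(Xs, y)
  trainAcc <- mean(as.character(predictOne(model, Xs)) == labels)

  # stratified k-fold CV
  kUse <- min(k, min(table(labels)))
  if (kUse < k) warning("k reduced to ", kUse, " (smallest class size)")
  set.seed(seed)
  fold <- integer(length(labels))
  for (cl in cls) {
    idx <- which(labels == cl)
    fold[idx] <- sample(rep_len(seq_len(kUse), length(idx)))
  }
  preds <- character(length(labels))
  for (f in seq_len(kUse)) {
    tr <- fold != f
    mf <- trainOne(Xs[tr, , drop = FALSE], y[tr])
    preds[!tr] <- as.character(predictOne(mf, Xs[!tr, , drop = FALSE]))
  }
  positive <- setdiff(cls, healthyLabel)
  cv <- as.data.frame(as.list(.classifierMetrics(labels, preds, positive)))

  centroid <- colMeans(X[labels == healthyLabel, , drop = FALSE])
  centroidS <- .standardize(matrix(centroid, 1L), center, scale)
  p1Class <- as.character(predictOne(model, centroidS))

  new("RegionModel", model = model, kernel = kernel, center = center,
      scale = scale, healthyLabel = healthyLabel, p1Class = p1Class,
      classes = cls, cv = cv, trainAccuracy = trainAcc,
      seed = as.numeric(seed))
}

#' Assign calibrated points to regions P1/P2
#'
#' Deterministic: a point is in P1 iff the trained boundary places it on
#' the same side as the healthy-cohort centroid (so the centroid itself is
#' always P1).
#'
#' @param model a \linkS4class{RegionModel}.
#' @param points two-column matrix/data.frame of calibrated coordinates.
#' @return character vector of `"P1"`/`"P2"`.
#' @export
assignRegions <- function(model, points) {
  stopifnot(is(model, "RegionModel"))
  X <- .standardize(as.matrix(points), model@center, model@scale)
  pred <- if (model@kernel == "gnb")
    stats::predict(model@model, as.data.frame(X))
  else stats::predict(model@model, X)
  ifelse(as.character(pred) == model@p1Class, "P1", "P2")
}

#' Per-cohort region proportions
#'
#' @param regions character vector of `"P1"`/`"P2"` assignments.
#' @param cohorts cohort label per sample.
#' @return data.frame with columns `cohort`, `P1`, `P2` (fractions summing
#'   to 1 per cohort).
#' @examples
#' regionProportions(c("P1", "P2", "P2", "P2"), rep("early", 4))
#' @export
regionProportions <- function(regions, cohorts) {
  stopifnot(length(regions) == length(cohorts))
  if (!all(regions %in% c("P1", "P2"))) stop("regions must be P1/P2")
  cohorts <- as.character(cohorts)
  out <- do.call(rbind, lapply(unique(cohorts), function(co) {
    idx <- cohorts == co
    if (!any(idx)) stop("empty cohort: ", co)
    data.frame(cohort = co, P1 = mean(regions[idx] == "P1"),
               P2 = mean(regions[idx] == "P2"), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Treatment efficacy vector between two calibrated points
#'
#' The displacement (dx, dy) = post - pre on the calibrated plane, its
#' Euclidean magnitude, and its direction in degrees counterclockwise from
#' the +x axis in [0, 360).  A zero displacement has undefined angle
#' (`NA`, `degenerate = TRUE`).
#'
#' @param pre,post numeric length-2 vectors `c(x, y)` of calibrated
#'   coordinates.
#' @param marker optional marker name carried through.
#' @return list of class `efficacyVector`: `marker`, `dx`, `dy`,
#'   `magnitude`, `angle`, `degenerate`.
#' @examples
#' efficacyVector(c(2, 3), c(0, 3))$angle    # 180
#' @export
efficacyVector <- function(pre, post, marker = NA_character_) {
  stopifnot(length(pre) == 2L, length(post) == 2L)
  dx <- post[[1L]] - pre[[1L]]
  dy <- post[[2L]] - pre[[2L]]
  mag <- sqrt(dx^2 + dy^2)
  ang <- if (mag == 0) NA_real_ else (atan2(dy, dx) * 180 / pi) %% 360
  structure(list(marker = marker, dx = dx, dy = dy, magnitude = mag,
                 angle = ang, degenerate = mag == 0),
            class = "efficacyVector")
}

#' Combine efficacy vectors componentwise
#'
#' The per-patient combined response is the componentwise sum of the
#' per-marker vectors (e.g. EpCAM + GPC-3).
#'
#' @param ... `efficacyVector` objects.
#' @return an `efficacyVector` with `marker = "combined"`.
#' @examples
#' v <- combineEfficacyVectors(efficacyVector(c(0, 0), c(-1, 0)),
#'                             efficacyVector(c(0, 0), c(0, -1)))
#' c(v$magnitude, v$angle)   # sqrt(2), 225
#' @export
combineEfficacyVectors <- function(...) {
  vs <- list(...)
  stopifnot(length(vs) >= 1L,
            all(vapply(vs, inherits, TRUE, "efficacyVector")))
  dx <- sum(vapply(vs, `[[`, 0, "dx"))
  dy <- sum(vapply(vs, `[[`, 0, "dy"))
  efficacyVector(c(0, 0), c(dx, dy), marker = "combined")
}

#' @export
print.efficacyVector <- function(x, ...) {
  cat(sprintf("efficacy vector%s: d = (%.4g, %.4g), |d| = %.4g, angle = %s\n",
              if (is.na(x$marker)) "" else paste0(" [", x$marker, "]"),
              x$dx, x$dy, x$magnitude,
              if (is.na(x$angle)) "undefined" else sprintf("%.1f deg",
                                                           x$angle)))
  invisible(x)
}

#' Efficacy vectors for all treated patients of a cohort
#'
#' Pairs each patient's pre/post samples, calibrates them, and returns the
#' per-marker and combined displacement vectors.
#'
#' @param ce a \linkS4class{CohortExperiment} containing samples annotated
#'   with `patient` and `timepoint` ("pre"/"post").
#' @param pseudocount see [asgprCalibrate()].
#' @return data.frame with columns `patient`, `marker`, `dx`, `dy`,
#'   `magnitude`, `angle_deg`.
#' @export
cohortEfficacyVectors <- function(ce, pseudocount = 1) {
  cal <- calibrateCohort(ce, pseudocount)
  cal <- cal[!is.na(cal$patient), , drop = FALSE]
  if (!nrow(cal)) return(data.frame(patient = character(0),
                                    marker = character(0), dx = numeric(0),
                                    dy = numeric(0), magnitude = numeric(0),
                                    angle_deg = numeric(0)))
  out <- list()
  for (pt in unique(cal$patient)) {
    sub <- cal[cal$patient == pt, ]
    vecs <- list()
    for (mk in c("EpCAM", "GPC3")) {
      pre <- sub[sub$marker == mk & sub$timepoint == "pre", c("x", "y")]
      post <- sub[sub$marker == mk & sub$timepoint == "post", c("x", "y")]
      if (nrow(pre) != 1L || nrow(post) != 1L)
        stop("patient ", pt, " lacks a pre/post pair for ", mk)
      vecs[[mk]] <- efficacyVector(unlist(pre), unlist(post), marker = mk)
    }
    vecs$combined <- combineEfficacyVectors(vecs$EpCAM, vecs$GPC3)
    for (v in vecs)
      out[[length(out) + 1L]] <- data.frame(
        patient = pt, marker = v$marker, dx = v$dx, dy = v$dy,
        magnitude = v$magnitude, angle_deg = v$angle,
        stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Spearman rank correlation with a permutation p-value
#'
#' r is the Pearson correlation of mid-ranks (average ranks on ties); the
#' two-sided p-value is estimated by randomly permuting one variable's
#' ranks (`nPerm` draws under `seed`), with the +1 correction so p is never
#' exactly 0.
#'
#' @param x,y paired numeric vectors, >= 3 observations.
#' @param nPerm number of permutations (default 9999).
#' @param seed integer seed for the permutations.
#' @return list of class `spearmanCorr`: `r`, `p`, `nPerm`.
#' @examples
#' spearmanCorr(1:4, c(2, 1, 4, 3), seed = 1)$r   # 0.6
#' @export
spearmanCorr <- function(x, y, nPerm = 9999L, seed = 1L) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3L) stop("need >= 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant input: Spearman correlation undefined")
    return(structure(list(r = NA_real_, p = NA_real_, nPerm = 0L),
                     class = "spearmanCorr"))
  }
  rx <- rank(x); ry <- rank(y)
  r <- stats::cor(rx, ry)
  set.seed(seed)
  n <- length(x)
  rxC <- rx - mean(rx); ryC <- ry - mean(ry)
  denom <- sqrt(sum(rxC^2) * sum(ryC^2))
  exceed <- 0L
  for (b in seq_len(nPerm)) {
    rp <- sum(rxC[sample.int(n)] * ryC) / denom
    if (abs(rp) >= abs(r) - 1e-12) exceed <- exceed + 1L
  }
  structure(list(r = r, p = (exceed + 1L) / (nPerm + 1L),
                 nPerm = as.integer(nPerm)),
            class = "spearmanCorr")
}

#' @export
print.spearmanCorr <- function(x, ...) {
  cat(sprintf("Spearman r = %.4f (permutation p = %.4g, %d permutations)\n",
              x$r, x$p, x$nPerm))
  invisible(x)
}
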
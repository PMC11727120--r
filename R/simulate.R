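# Synthetic plate / cohort / dilution-series generators.  These define the
# study conditions under which the calling, quantification, scoring and
# profiling stages are validated: every generator is a pure function of its
# parameters and an explicit seed, and every plate carries its ground truth.

#' Default plate simulation parameters
#'
#' Channel-level Ct and normalized fluorescence-growth-rate distributions
#' default to the values observed on the real instrument for the FAM, VIC
#' and CY5 channels (Ct 26.83 +/- 0.88, 26.46 +/- 0.86, 25.73 +/- 1.21
#' cycles; rates 0.39 +/- 0.07, 0.66 +/- 0.15, 0.25 +/- 0.07 per cycle on
#' the amplitude-1 scale).  Amplitude, baseline, drift and noise are in
#' normalized fluorescence units.
#'
#' @param nWells wells per chip region (default 20000).
#' @param nCycles thermal cycles (default 40).
#' @param channels,regions panel layout.
#' @param targetCopies template molecules loaded per region, as a named list
#'   `list(protein = c(FAM=, VIC=, CY5=), mrna = ...)`; a single number is
#'   recycled to every region x channel.
#' @param ctMean,ctSd per-channel Ct distribution of positive wells (cycles).
#' @param growthRateMean,growthRateSd per-channel normalized maximum slope
#'   distribution (intensity per cycle, amplitude-1 scale).
#' @param amplitudeMean,amplitudeSd logistic amplitude (normalized units).
#' @param baseline,baselineDrift baseline level and per-cycle drift.
#' @param noiseSd i.i.d. Gaussian read noise per cycle.
#' @param ctThresholdFrac amplitude fraction defining Ct (see [computeCt()]).
#' @return a validated parameter list of class `plateSimParams`.
#' @examples
#' p <- plateSimParams(nWells = 500, targetCopies = 20)
#' p$ctMean
#' @export
plateSimParams <- function(nWells = 20000L,
                           nCycles = 40L,
                           channels = c("FAM", "VIC", "CY5"),
                           regions = c("protein", "mrna"),
                           targetCopies = 500,
                           ctMean = c(FAM = 26.83, VIC = 26.46, CY5 = 25.73),
                           ctSd = c(FAM = 0.88, VIC = 0.86, CY5 = 1.21),
                           growthRateMean = c(FAM = 0.39, VIC = 0.66,
                                              CY5 = 0.25),
                           growthRateSd = c(FAM = 0.07, VIC = 0.15,
                                            CY5 = 0.07),
                           amplitudeMean = 1.0,
                           amplitudeSd = 0.05,
                           baseline = 0.1,
                           baselineDrift = 0.001,
                           noiseSd = 0.02,
                           ctThresholdFrac = 0.1) {
  stopifnot(nWells >= 1, nCycles >= 2, noiseSd >= 0, amplitudeSd >= 0,
            all(ctSd[channels] >= 0), all(growthRateSd[channels] >= 0),
            ctThresholdFrac > 0, ctThresholdFrac < 1)
  if (any(ctMean[channels] <= 1) || any(ctMean[channels] >= nCycles))
    stop("ctMean must lie within (1, nCycles)")
  if (as.double(nWells) * nCycles * length(channels) * length(regions) > 5e8)
    stop("plate too large: nWells x nCycles x channels x regions overflows")
  if (is.numeric(targetCopies) && is.null(names(targetCopies)) &&
      length(targetCopies) == 1L) {
    targetCopies <- stats::setNames(
      rep(list(stats::setNames(rep(targetCopies, length(channels)),
                               channels)), length(regions)), regions)
  }
  lam <- unlist(targetCopies)
  if (any(lam < 0)) stop("target copies must be nonnegative")
  structure(list(nWells = as.integer(nWells), nCycles = as.integer(nCycles),
                 channels = channels, regions = regions,
                 targetCopies = targetCopies,
                 ctMean = ctMean, ctSd = ctSd,
                 growthRateMean = growthRateMean,
                 growthRateSd = growthRateSd,
                 amplitudeMean = amplitudeMean, amplitudeSd = amplitudeSd,
                 baseline = baseline, baselineDrift = baselineDrift,
                 noiseSd = noiseSd, ctThresholdFrac = ctThresholdFrac),
            class = "plateSimParams")
}

# rnorm truncated below at `lo` by redraw; keeps the mean essentially
# unbiased when lo is several sd below the mean.
.rnormTrunc <- function(n, mean, sd, lo) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lo)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < lo]
  }
  x
}

#' Simulate one multiplex real-time digital PCR plate
#'
#' For each region x channel, `round(lambda)` template molecules are placed
#' into the `nWells` wells independently and uniformly (multinomial
#' occupancy, approximately Poisson(lambda/N) per well), so the realized
#' template load is conserved exactly.  Occupied wells receive a
#' four-parameter logistic trace
#' \deqn{F(c) = F_0 + d c + A / (1 + e^{-k(c - c_{50})})}
#' whose rate k is back-solved from a channel-drawn normalized growth rate
#' (maximum slope of the unit-amplitude logistic = k/4) and whose midpoint
#' c50 is back-solved from a channel-drawn Ct (threshold crossing at
#' `ctThresholdFrac` of the amplitude).  Empty wells receive baseline +
#' drift + noise only.  The same parameters and seed give bit-identical
#' output.
#'
#' @param params a [plateSimParams()] list.
#' @param seed integer; required, no global random state is consulted.
#' @return a \linkS4class{PlateRun}; `truthTable(x)` gives the per-well
#'   molecule counts and true Ct, `metadata(x)$params` the generator
#'   parameters.
#' @examples
#' run <- simulatePlate(plateSimParams(nWells = 200, targetCopies = 30,
#'                                     regions = "protein",
#'                                     channels = "FAM"), seed = 1)
#' sum(truthTable(run)$molecules >= 1)
#' @export
simulatePlate <- function(params = plateSimParams(), seed) {
  stopifnot(inherits(params, "plateSimParams"), !missing(seed))
  p <- params
  nW <- p$nWells; nC <- p$nCycles
  cellGrid <- expand.grid(channel = p$channels, region = p$regions,
                          stringsAsFactors = FALSE)[, 2:1]
  wellIds <- sprintf("W%05d", seq_len(nW))
  cyc <- seq_len(nC)

  set.seed(seed)
  traceList <- vector("list", nrow(cellGrid))
  truthList <- vector("list", nrow(cellGrid))
  for (i in seq_len(nrow(cellGrid))) {
    rg <- cellGrid$region[i]; ch <- cellGrid$channel[i]
    lambda <- p$targetCopies[[rg]][[ch]]
    m <- round(lambda)
    counts <- if (m >= 1L)
      tabulate(sample.int(nW, m, replace = TRUE), nbins = nW)
    else integer(nW)
    pos <- which(counts >= 1L)

    # baseline + drift + noise for every well
    X <- matrix(stats::rnorm(nW * nC, 0, p$noiseSd), nW, nC)
    X <- X + matrix(p$baseline + p$baselineDrift * cyc, nW, nC, byrow = TRUE)

    ctTrue <- rep(NA_real_, nW)
    if (length(pos)) {
      g <- .rnormTrunc(length(pos), p$growthRateMean[[ch]],
                       p$growthRateSd[[ch]], lo = 0.02)
      A <- .rnormTrunc(length(pos), p$amplitudeMean, p$amplitudeSd, lo = 0.2)
      ct <- .rnormTrunc(length(pos), p$ctMean[[ch]], p$ctSd[[ch]], lo = 2)
      k <- 4 * g
      c50 <- ct + log(1 / p$ctThresholdFrac - 1) / k
      # outer() over cycles for the positive subset only
      logi <- A / (1 + exp(-(k * (matrix(cyc, length(pos), nC,
                                         byrow = TRUE) - c50))))
      X[pos, ] <- X[pos, ] + logi
      ctTrue[pos] <- ct
    }
    traceList[[i]] <- X
    truthList[[i]] <- data.frame(region = rg, channel = ch,
                                 well_id = wellIds,
                                 molecules = counts, ct_true = ctTrue,
                                 lambda = lambda,
                                 stringsAsFactors = FALSE)
  }
  intensity <- do.call(rbind, traceList)
  truth <- do.call(rbind, truthList)
  PlateRun(intensity,
           region = truth$region, well_id = truth$well_id,
           channel = truth$channel,
           metadata = list(truth = truth, params = p, seed = seed))
}

#' Default cohort design for the six-marker panel
#'
#' The defaults emulate the clinical-style structure of the assay: a healthy
#' donor cohort at blank-level copy numbers, an early-stage HCC cohort with
#' intermediate marker loads, and an intermediate-advanced HCC cohort with
#' high loads.  Location parameters are anchored on representative healthy
#' and advanced-case positive-well counts (roughly 97/112/160/15/13/7 and
#' 507/224/437/234/120/89 copies for the six markers); the early cohort sits
#' at the geometric mean of the two.  Copies are log-normal per marker with
#' a zero-inflation (dropout) probability under which the marker falls to
#' blank-level background, exercising the limit-of-blank logic downstream.
#'
#' @param nHD,nEarly,nAdvanced samples per cohort (defaults 24/31/22).
#' @param sdlog log-normal scale parameter shared across markers.
#' @param dropout per-cohort dropout probability, named vector.
#' @return a `cohortDesign` list consumable by [simulateCohort()].
#' @export
cohortDesign <- function(nHD = 24L, nEarly = 31L, nAdvanced = 22L,
                         sdlog = 0.6,
                         dropout = c(HD = 0, early = 0.25, advanced = 0.1)) {
  hd  <- c(97, 112, 160, 15, 13, 7)
  adv <- c(507, 224, 437, 234, 120, 89)
  names(hd) <- names(adv) <- ctcMarkers()
  early <- sqrt(hd * adv)
  mk <- function(label, n, loc, drop)
    list(label = label, n = as.integer(n), meanlog = log(loc),
         sdlog = rep_len(sdlog, 6L), dropout = drop)
  structure(list(
    cohorts = list(mk("HD", nHD, hd, dropout[["HD"]]),
                   mk("early", nEarly, early, dropout[["early"]]),
                   mk("advanced", nAdvanced, adv, dropout[["advanced"]])),
    blank = list(meanlog = log(5), sdlog = 0.7),
    treatments = NULL
  ), class = "cohortDesign")
}

#' Build a custom cohort design
#'
#' @param cohorts list of cohorts; each a list with `label`, `n`, `meanlog`
#'   (length 6, named by [ctcMarkers()], or scalar), `sdlog` (recycled) and
#'   `dropout` probability in `[0, 1]`.
#' @param blank blank-level background model, `list(meanlog, sdlog)`; used
#'   for dropout draws.
#' @param treatments optional list of treatment pairs; each a list with
#'   `patient`, `cohort` (the cohort whose distribution the pre-treatment
#'   sample is drawn from) and `effect`, a list with `EpCAM = c(dx, dy)` and
#'   `GPC3 = c(dx, dy)` shifts applied on the ASGPR-calibrated (mRNA,
#'   protein) plane before back-transforming to copies.
#' @return a `cohortDesign`.
#' @export
newCohortDesign <- function(cohorts, blank = list(meanlog = log(5),
                                                  sdlog = 0.7),
                            treatments = NULL) {
  for (co in cohorts) {
    stopifnot(co$n >= 1, co$dropout >= 0, co$dropout <= 1,
              all(co$sdlog > 0) || all(co$sdlog == 0))
  }
  structure(list(cohorts = cohorts, blank = blank, treatments = treatments),
            class = "cohortDesign")
}

.drawCohortCopies <- function(n, meanlog, sdlog, dropout, blank) {
  meanlog <- if (length(meanlog) == 1L)
    stats::setNames(rep(meanlog, 6L), ctcMarkers()) else meanlog[ctcMarkers()]
  sdlog <- rep_len(sdlog, 6L)
  m <- matrix(NA_real_, n, 6L, dimnames = list(NULL, ctcMarkers()))
  for (j in seq_len(6L)) {
    x <- stats::rlnorm(n, meanlog[j], sdlog[j])
    drop <- stats::runif(n) < dropout
    x[drop] <- stats::rlnorm(sum(drop), blank$meanlog, blank$sdlog)
    m[, j] <- x
  }
  m
}

#' Simulate a clinical-style cohort of six-marker copy numbers
#'
#' Draws per-sample marker copies from the per-cohort log-normal models with
#' zero-inflation to blank-level background, then generates optional
#' pre/post treatment pairs whose post-treatment samples are shifted on the
#' ASGPR-calibrated 2D plane by the design's effect vectors (see
#' [asgprCalibrate()]) and back-transformed to copies.
#'
#' @param design a [cohortDesign()] / [newCohortDesign()] object.
#' @param seed integer seed; required.
#' @return a \linkS4class{CohortExperiment}.
#' @examples
#' ce <- simulateCohort(cohortDesign(nHD = 5, nEarly = 5, nAdvanced = 5),
#'                      seed = 7)
#' table(cohortLabels(ce))
#' @export
simulateCohort <- function(design = cohortDesign(), seed) {
  stopifnot(inherits(design, "cohortDesign"), !missing(seed))
  set.seed(seed)
  mats <- list(); labels <- character(0)
  for (co in design$cohorts) {
    mats[[co$label]] <- .drawCohortCopies(co$n, co$meanlog, co$sdlog,
                                          co$dropout, design$blank)
    labels <- c(labels, rep(co$label, co$n))
  }
  copies <- do.call(rbind, mats)
  timepoint <- rep(NA_character_, nrow(copies))
  patient <- rep(NA_character_, nrow(copies))

  if (length(design$treatments)) {
    byLabel <- stats::setNames(design$cohorts,
                               vapply(design$cohorts, `[[`, "", "label"))
    for (tr in design$treatments) {
      co <- byLabel[[tr$cohort]]
      if (is.null(co)) stop("unknown cohort in treatment spec: ", tr$cohort)
      pre <- .drawCohortCopies(1L, co$meanlog, co$sdlog, co$dropout,
                               design$blank)[1L, ]
      post <- pre
      asg <- pre[["ASGPR_protein"]] + 1
      for (mk in c("EpCAM", "GPC3")) {
        eff <- tr$effect[[mk]]
        if (is.null(eff)) next
        xy <- c(pre[[paste0(mk, "_mRNA")]], pre[[paste0(mk, "_protein")]]) /
          asg
        xy <- pmax(xy + eff, 0)
        post[[paste0(mk, "_mRNA")]] <- xy[1L] * asg
        post[[paste0(mk, "_protein")]] <- xy[2L] * asg
      }
      copies <- rbind(copies, pre, post)
      labels <- c(labels, rep(tr$cohort, 2L))
      timepoint <- c(timepoint, "pre", "post")
      patient <- c(patient, rep(tr$patient, 2L))
    }
  }
  rownames(copies) <- sprintf("S%03d", seq_len(nrow(copies)))
  CohortExperiment(t(copies), cohort = labels, timepoint = timepoint,
                   patient = patient,
                   metadata = list(design = design, seed = seed))
}

#' Simulate a detection dilution series
#'
#' Emulates replicate testing of decreasing CTC-standard concentrations: at
#' concentration c the number detected is Binomial(reps, Phi(a + b log10 c))
#' under a probit detection model, producing the hit table that probit LOD
#' estimation consumes.
#'
#' @param concs strictly positive, distinct concentrations
#'   (CTC-equivalents per mL).
#' @param reps replicates per concentration.
#' @param intercept,slope probit model coefficients on log10 concentration.
#' @param seed integer seed; required.
#' @return data.frame with columns `conc`, `n_replicates`, `n_detected`.
#' @examples
#' simulateDilutionSeries(c(5, 20, 80), reps = 12, intercept = -2,
#'                        slope = 2, seed = 3)
#' @export
simulateDilutionSeries <- function(concs, reps, intercept, slope, seed) {
  stopifnot(!missing(seed), reps >= 1)
  if (any(concs <= 0)) stop("concentrations must be positive")
  if (anyDuplicated(concs)) stop("concentrations must be distinct")
  set.seed(seed)
  p <- stats::pnorm(intercept + slope * log10(concs))
  data.frame(conc = concs, n_replicates = as.integer(reps),
             n_detected = stats::rbinom(length(concs), reps, p))
}
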
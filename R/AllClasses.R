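#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
NULL

#' Marker panel of the six-plex CTC assay
#'
#' The assay measures three surface proteins (via antibody-conjugated oligo
#' tags) and three mRNAs, read out in two chip regions (protein lysate vs
#' mRNA) and three dye channels.  `ctcMarkers()` returns the canonical marker
#' names in panel order; `defaultPanel()` returns the (region, channel) to
#' marker map.
#'
#' @return `ctcMarkers()`: character vector of six marker names.
#'   `defaultPanel()`: data.frame with columns `region`, `channel`, `marker`,
#'   `analyte`.
#' @examples
#' ctcMarkers()
#' defaultPanel()
#' @export
ctcMarkers <- function() {
  c("EpCAM_protein", "GPC3_protein", "ASGPR_protein",
    "EpCAM_mRNA", "GPC3_mRNA", "PDL1_mRNA")
}

#' @rdname ctcMarkers
#' @export
defaultPanel <- function() {
  data.frame(
    region  = rep(c("protein", "mrna"), each = 3L),
    channel = rep(c("FAM", "VIC", "CY5"), 2L),
    marker  = c("EpCAM_protein", "GPC3_protein", "ASGPR_protein",
                "EpCAM_mRNA", "GPC3_mRNA", "PDL1_mRNA"),
    analyte = rep(c("protein_oligo", "mRNA"), each = 3L),
    stringsAsFactors = FALSE
  )
}

# ---------------------------------------------------------------------------
# PlateRun: one dPCR chip run.  Rows are traces (well x channel x region),
# columns are thermal cycles; the single assay holds fluorescence intensity.
# Ground truth from the simulator, when present, lives in metadata()$truth.
# ---------------------------------------------------------------------------

#' PlateRun: per-microwell real-time fluorescence traces
#'
#' A \linkS4class{SummarizedExperiment} subclass holding one plate of
#' real-time digital PCR data.  Each row is one trace (a microwell observed
#' in one dye channel of one chip region); each column is one thermal cycle.
#' The `"intensity"` assay stores fluorescence in normalized units.
#' `rowData()` carries `region`, `well_id` and `channel`.  Simulated plates
#' additionally carry a truth table (see [truthTable()]) and the generator
#' parameters in `metadata()`.
#'
#' @seealso [simulatePlate()], [readTraces()], [callPlate()]
#' @export
setClass("PlateRun", contains = "SummarizedExperiment")

setValidity("PlateRun", function(object) {
  rd <- rowData(object)
  need <- c("region", "well_id", "channel")
  if (!all(need %in% colnames(rd)))
    return(paste("rowData must contain:", paste(need, collapse = ", ")))
  if (!"intensity" %in% SummarizedExperiment::assayNames(object))
    return("assay 'intensity' is required")
  if (ncol(object) < 2L)
    return("a PlateRun needs at least 2 cycles")
  x <- assay(object, "intensity")
  if (any(!is.finite(x)))
    return("intensities must be finite")
  TRUE
})

#' Construct a PlateRun from a trace matrix
#'
#' @param intensity numeric matrix, traces x cycles.
#' @param region,well_id,channel per-trace annotation vectors (recycled to
#'   `nrow(intensity)`).
#' @param metadata optional list stored in `metadata()`.
#' @return a \linkS4class{PlateRun}.
#' @examples
#' pr <- PlateRun(matrix(0.1, 2, 10), region = "protein",
#'                well_id = c("W1", "W2"), channel = "FAM")
#' nCycles(pr)
#' @export
PlateRun <- function(intensity, region, well_id, channel, metadata = list()) {
  intensity <- as.matrix(intensity)
  n <- nrow(intensity)
  rd <- DataFrame(region = rep_len(as.character(region), n),
                  well_id = rep_len(as.character(well_id), n),
                  channel = rep_len(as.character(channel), n))
  colnames(intensity) <- NULL
  se <- SummarizedExperiment(
    assays = list(intensity = intensity),
    rowData = rd,
    colData = DataFrame(cycle = seq_len(ncol(intensity))),
    metadata = metadata
  )
  new("PlateRun", se)
}

#' @rdname PlateRun-accessors
#' @export
setGeneric("traceMatrix", function(x) standardGeneric("traceMatrix"))

#' @rdname PlateRun-accessors
#' @export
setGeneric("traceInfo", function(x) standardGeneric("traceInfo"))

#' @rdname PlateRun-accessors
#' @export
setGeneric("nCycles", function(x) standardGeneric("nCycles"))

#' @rdname PlateRun-accessors
#' @export
setGeneric("truthTable", function(x) standardGeneric("truthTable"))

#' Accessors for PlateRun objects
#'
#' `traceMatrix()` returns the traces x cycles intensity matrix,
#' `traceInfo()` the per-trace annotation as a data.frame, `nCycles()` the
#' cycle count, and `truthTable()` the simulator ground truth (`NULL` for
#' plates read from disk).
#'
#' @param x a \linkS4class{PlateRun}.
#' @name PlateRun-accessors
#' @return See description.
NULL

#' @rdname PlateRun-accessors
#' @export
setMethod("traceMatrix", "PlateRun", function(x) assay(x, "intensity"))

#' @rdname PlateRun-accessors
#' @export
setMethod("traceInfo", "PlateRun",
          function(x) as.data.frame(rowData(x)))

#' @rdname PlateRun-accessors
#' @export
setMethod("nCycles", "PlateRun", function(x) ncol(x))

#' @rdname PlateRun-accessors
#' @export
setMethod("truthTable", "PlateRun", function(x) metadata(x)$truth)

setMethod("show", "PlateRun", function(object) {
  ti <- traceInfo(object)
  cat("PlateRun:", nrow(object), "traces x", ncol(object), "cycles\n")
  cat("  regions: ", paste(unique(ti$region), collapse = ", "),
      " | channels: ", paste(unique(ti$channel), collapse = ", "), "\n",
      sep = "")
  if (!is.null(truthTable(object)))
    cat("  simulated plate with ground truth (see truthTable())\n")
})

# ---------------------------------------------------------------------------
# PlateCalls: the result of well calling on a PlateRun.
# ---------------------------------------------------------------------------

#' PlateCalls: per-well positivity calls and plate summary
#'
#' Result of [callPlate()].  Slot `calls` holds one row per trace with the
#' fitted Ct, normalized growth rate, fit r-squared, the positive/negative
#' verdict and the names of any failed criteria; slot `summary` holds, per
#' (region, channel), the positive count M, analyzed count N and the Ct and
#' growth-rate distribution of the positives.
#'
#' @seealso [callPlate()], [wellCalls()], [plateSummary()]
#' @export
setClass("PlateCalls", representation(
  calls = "data.frame",
  summary = "data.frame",
  criteria = "list"
))

setValidity("PlateCalls", function(object) {
  s <- object@summary
  if (nrow(s) && any(s$M > s$N)) return("M cannot exceed N")
  TRUE
})

#' @rdname PlateCalls-accessors
#' @export
setGeneric("wellCalls", function(x) standardGeneric("wellCalls"))

#' @rdname PlateCalls-accessors
#' @export
setGeneric("plateSummary", function(x) standardGeneric("plateSummary"))

#' Accessors for PlateCalls
#'
#' @param x a \linkS4class{PlateCalls}.
#' @return `wellCalls()`: per-trace call table; `plateSummary()`: per
#'   (region, channel) summary with `M`, `N`, `ct_mean`, `ct_sd`,
#'   `rate_mean`, `rate_sd`.
#' @name PlateCalls-accessors
NULL

#' @rdname PlateCalls-accessors
#' @export
setMethod("wellCalls", "PlateCalls", function(x) x@calls)

#' @rdname PlateCalls-accessors
#' @export
setMethod("plateSummary", "PlateCalls", function(x) x@summary)

setMethod("show", "PlateCalls", function(object) {
  s <- object@summary
  cat("PlateCalls:", sum(s$N), "wells analyzed,", sum(s$M), "positive\n")
  print(s, row.names = FALSE, digits = 4)
})

# ---------------------------------------------------------------------------
# CohortExperiment: samples x 6-marker copy-number matrix with cohort labels.
# ---------------------------------------------------------------------------

#' CohortExperiment: six-marker copy numbers across a clinical-style cohort
#'
#' A \linkS4class{SummarizedExperiment} subclass whose `"copies"` assay holds
#' absolute copy numbers (markers x samples) for the six-plex CTC panel.
#' `colData()` carries `cohort` and, for treatment follow-up samples,
#' `patient` and `timepoint` ("pre"/"post").
#'
#' @seealso [simulateCohort()], [scoreCohort()], [calibrateCohort()]
#' @export
setClass("CohortExperiment", contains = "SummarizedExperiment")

setValidity("CohortExperiment", function(object) {
  if (!"copies" %in% SummarizedExperiment::assayNames(object))
    return("assay 'copies' is required")
  if (!setequal(rownames(object), ctcMarkers()))
    return(paste("rownames must be the six panel markers:",
                 paste(ctcMarkers(), collapse = ", ")))
  if (any(assay(object, "copies") < 0))
    return("copy numbers cannot be negative")
  if (!"cohort" %in% colnames(colData(object)))
    return("colData must contain 'cohort'")
  TRUE
})

#' Construct a CohortExperiment
#'
#' @param copies numeric matrix of copy numbers, either markers x samples or
#'   samples x markers (orientation is detected from dimnames).
#' @param cohort cohort label per sample.
#' @param timepoint,patient optional per-sample treatment annotation.
#' @param metadata optional list.
#' @return a \linkS4class{CohortExperiment}.
#' @examples
#' m <- matrix(10, 6, 4, dimnames = list(ctcMarkers(), paste0("S", 1:4)))
#' ce <- CohortExperiment(m, cohort = rep(c("HD", "HCC"), each = 2))
#' markerMatrix(ce)[1:2, ]
#' @export
CohortExperiment <- function(copies, cohort, timepoint = NA_character_,
                             patient = NA_character_, metadata = list()) {
  copies <- as.matrix(copies)
  if (!setequal(rownames(copies), ctcMarkers())) {
    if (setequal(colnames(copies), ctcMarkers())) copies <- t(copies)
    else stop("copies must have the six panel markers on one dimension")
  }
  copies <- copies[ctcMarkers(), , drop = FALSE]
  ns <- ncol(copies)
  if (is.null(colnames(copies))) colnames(copies) <- sprintf("S%03d", seq_len(ns))
  cd <- DataFrame(cohort = rep_len(as.character(cohort), ns),
                  timepoint = rep_len(as.character(timepoint), ns),
                  patient = rep_len(as.character(patient), ns),
                  row.names = colnames(copies))
  se <- SummarizedExperiment(assays = list(copies = copies),
                             colData = cd, metadata = metadata)
  new("CohortExperiment", se)
}

#' @rdname CohortExperiment-accessors
#' @export
setGeneric("markerMatrix", function(x) standardGeneric("markerMatrix"))

#' @rdname CohortExperiment-accessors
#' @export
setGeneric("cohortLabels", function(x) standardGeneric("cohortLabels"))

#' Accessors for CohortExperiment
#'
#' `markerMatrix()` returns the samples x markers copy matrix (the
#' orientation scoring functions expect); `cohortLabels()` the cohort label
#' per sample.
#'
#' @param x a \linkS4class{CohortExperiment}.
#' @name CohortExperiment-accessors
#' @return See description.
NULL

#' @rdname CohortExperiment-accessors
#' @export
setMethod("markerMatrix", "CohortExperiment",
          function(x) t(assay(x, "copies")))

#' @rdname CohortExperiment-accessors
#' @export
setMethod("cohortLabels", "CohortExperiment",
          function(x) colData(x)$cohort)

setMethod("show", "CohortExperiment", function(object) {
  cat("CohortExperiment:", ncol(object), "samples x", nrow(object),
      "markers\n")
  print(table(cohortLabels(object)))
})

# ---------------------------------------------------------------------------
# ScoreResult: composite digital Z-score of a cohort.
# ---------------------------------------------------------------------------

#' ScoreResult: per-marker Z-scores and the composite CTC score
#'
#' Result of [scoreCohort()]: the log2(x+1)-transformed and Z-standardized
#' marker matrix, the AHP weight vector, the per-sample composite score
#' (weighted sum of marker Z-scores), the reference statistics used for
#' standardization, and the AHP consistency ratio.
#'
#' @seealso [scoreCohort()], [ahpWeights()], [compositeScore()]
#' @export
setClass("ScoreResult", representation(
  z = "matrix",
  weights = "numeric",
  composite = "numeric",
  mu = "numeric",
  sigma = "numeric",
  reference = "character",
  cr = "numeric",
  cohort = "character"
))

setValidity("ScoreResult", function(object) {
  if (abs(sum(object@weights) - 1) > 1e-8) return("weights must sum to 1")
  if (any(object@weights < 0)) return("weights must be nonnegative")
  if (ncol(object@z) != length(object@weights))
    return("one weight per marker required")
  TRUE
})

#' @rdname ScoreResult-accessors
#' @export
setGeneric("compositeScores", function(x) standardGeneric("compositeScores"))

#' @rdname ScoreResult-accessors
#' @export
setGeneric("markerZ", function(x) standardGeneric("markerZ"))

#' @rdname ScoreResult-accessors
#' @export
setGeneric("scoreWeights", function(x) standardGeneric("scoreWeights"))

#' Accessors for ScoreResult
#'
#' @param x a \linkS4class{ScoreResult}.
#' @return `compositeScores()`: named numeric per sample; `markerZ()`: the
#'   samples x markers Z matrix; `scoreWeights()`: the AHP weight vector.
#' @name ScoreResult-accessors
NULL

#' @rdname ScoreResult-accessors
#' @export
setMethod("compositeScores", "ScoreResult", function(x) x@composite)

#' @rdname ScoreResult-accessors
#' @export
setMethod("markerZ", "ScoreResult", function(x) x@z)

#' @rdname ScoreResult-accessors
#' @export
setMethod("scoreWeights", "ScoreResult", function(x) x@weights)

setMethod("show", "ScoreResult", function(object) {
  cat("ScoreResult:", length(object@composite), "samples, reference =",
      object@reference, "\n")
  cat("  weights:", paste(sprintf("%s=%.3f", names(object@weights),
                                  object@weights), collapse = " "), "\n")
  cat("  AHP consistency ratio:", format(object@cr, digits = 3), "\n")
  cat("  composite score range:",
      paste(format(range(object@composite), digits = 3), collapse = " .. "),
      "\n")
})

# ---------------------------------------------------------------------------
# RegionModel: trained 2D classifier defining the P1/P2 boundary.
# ---------------------------------------------------------------------------

#' RegionModel: classifier boundary on the calibrated protein-mRNA plane
#'
#' Result of [fitRegionClassifier()].  Wraps the trained classifier together
#' with the feature standardization used at training time, the cohort side
#' assigned to region P1 (the side containing the healthy centroid), and
#' stratified cross-validation metrics.
#'
#' @seealso [fitRegionClassifier()], [assignRegions()]
#' @export
setClass("RegionModel", representation(
  model = "ANY",
  kernel = "character",
  center = "numeric",
  scale = "numeric",
  healthyLabel = "character",
  p1Class = "character",
  classes = "character",
  cv = "data.frame",
  trainAccuracy = "numeric",
  seed = "numeric"
))

setMethod("show", "RegionModel", function(object) {
  cat("RegionModel (", object@kernel, " kernel): P1 = side of class '",
      object@p1Class, "'\n", sep = "")
  cat("  training accuracy:", format(object@trainAccuracy, digits = 4), "\n")
  if (nrow(object@cv))
    cat("  CV: ", paste(sprintf("%s=%.3f", names(object@cv), object@cv),
                        collapse = " "), "\n", sep = "")
})
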
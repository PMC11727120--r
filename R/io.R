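# Readers, writers and the end-to-end pipeline.  Trace tables travel as
# long-format CSV (region,well_id,channel,cycle,intensity) -- one row per
# observation -- which streams well at ~20k wells x 40 cycles x 3 channels.

#' @importFrom data.table fread fwrite as.data.table setorder dcast
NULL

#' Read a long-format trace table into a PlateRun
#'
#' Validates the header, rejects duplicate (region, well, channel, cycle)
#' rows and ragged cycle counts, sorts cycles, and assembles the traces x
#' cycles matrix.
#'
#' @param path CSV file with header
#'   `region,well_id,channel,cycle,intensity`.
#' @return a \linkS4class{PlateRun}.
#' @examples
#' f <- system.file("extdata", "toy_traces.csv", package = "digitalCTC")
#' readTraces(f)
#' @export
readTraces <- function(path) {
  dt <- fread(path, colClasses = list(character = c("region", "well_id",
                                                    "channel")))
  need <- c("region", "well_id", "channel", "cycle", "intensity")
  miss <- setdiff(need, names(dt))
  if (length(miss))
    stop("trace table is missing column(s): ", paste(miss, collapse = ", "))
  if (!is.numeric(dt$intensity) || any(!is.finite(dt$intensity)))
    stop("non-numeric or non-finite intensity values")
  if (!is.numeric(dt$cycle)) stop("non-numeric cycle values")
  dup <- duplicated(dt[, c("region", "well_id", "channel", "cycle")])
  if (any(dup)) {
    i <- which(dup)[1L]
    stop(sprintf(
      "duplicated trace row: region=%s well=%s channel=%s cycle=%s",
      dt$region[i], dt$well_id[i], dt$channel[i], dt$cycle[i]))
  }
  setorder(dt, region, channel, well_id, cycle)
  key <- paste(dt$region, dt$channel, dt$well_id, sep = "\r")
  counts <- table(key)
  if (length(unique(counts)) != 1L)
    stop("ragged trace table: traces have differing cycle counts")
  nC <- as.integer(counts[1L])
  first <- !duplicated(key)
  X <- matrix(dt$intensity, ncol = nC, byrow = TRUE)
  PlateRun(X, region = dt$region[first], well_id = dt$well_id[first],
           channel = dt$channel[first])
}

#' Write a PlateRun as a long-format trace CSV
#'
#' @param run a \linkS4class{PlateRun}.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeTraces <- function(run, path) {
  stopifnot(is(run, "PlateRun"))
  info <- traceInfo(run)
  X <- traceMatrix(run)
  nC <- ncol(X)
  dt <- data.table::data.table(
    region = rep(info$region, each = nC),
    well_id = rep(info$well_id, each = nC),
    channel = rep(info$channel, each = nC),
    cycle = rep(seq_len(nC), nrow(X)),
    intensity = as.vector(t(X)))
  fwrite(dt, path)
  invisible(path)
}

#' Default pipeline configuration
#'
#' @param seed master seed; stage seeds are derived from it
#'   deterministically.
#' @param plate a [plateSimParams()] list.
#' @param cohort a [cohortDesign()] list.
#' @param criteria a [callCriteria()] list.
#' @param reference scoring reference population ("all" or "healthy").
#' @param kernel region-classifier kernel.
#' @param ahp AHP comparison matrix or `NULL` for equal weights.
#' @return a `pipelineConfig` list.
#' @export
pipelineConfig <- function(seed = 1L,
                           plate = plateSimParams(),
                           cohort = cohortDesign(),
                           criteria = callCriteria(),
                           reference = "all",
                           kernel = "poly",
                           ahp = NULL) {
  structure(list(seed = as.integer(seed), plate = plate, cohort = cohort,
                 criteria = criteria, reference = reference,
                 kernel = kernel, ahp = ahp),
            class = "pipelineConfig")
}

.md5OfObject <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2L, compress = FALSE)
  unname(tools::md5sum(f))
}

#' Run the full analysis pipeline
#'
#' Executes simulate-plate, well calling, Poisson quantification,
#' simulate-cohort, scoring and 2D profiling in order, writing every stage
#' artifact to `outDir` as plain CSV/JSON, plus a run manifest with the
#' config hash and per-file checksums.  Identical config and seed produce
#' byte-identical stage outputs.  With `dryRun = TRUE` the stage plan is
#' returned and nothing is written.
#'
#' @param config a [pipelineConfig()].
#' @param outDir output directory (created if needed).
#' @param traces optional path to an existing trace CSV; when given, the
#'   plate-simulation stage is skipped and these traces are called instead.
#' @param dryRun if TRUE, return the stage plan without computing.
#' @return invisibly, a list with the manifest and the in-memory stage
#'   results.
#' @examples
#' cfg <- pipelineConfig(seed = 1, plate = plateSimParams(
#'   nWells = 100, targetCopies = 15, regions = "protein",
#'   channels = "FAM"),
#'   cohort = cohortDesign(nHD = 6, nEarly = 6, nAdvanced = 6))
#' res <- runPipeline(cfg, outDir = tempfile())
#' names(res$manifest$files)
#' @export
runPipeline <- function(config = pipelineConfig(), outDir,
                        traces = NULL, dryRun = FALSE) {
  stopifnot(inherits(config, "pipelineConfig"))
  stages <- c("simulate_plate", "call", "quantify", "simulate_cohort",
              "score", "profile", "report")
  if (!is.null(traces)) stages <- setdiff(stages, "simulate_plate")
  if (dryRun) {
    message("pipeline plan: ", paste(stages, collapse = " -> "))
    return(invisible(list(plan = stages)))
  }
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  outFile <- function(name) file.path(outDir, name)
  written <- character(0)
  emit <- function(df, name) {
    fwrite(as.data.table(df), outFile(name))
    written <<- c(written, name)
  }

  withStage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", stage,
                   conditionMessage(e)), call. = FALSE))
  }

  # -- plate ----------------------------------------------------------------
  run <- withStage("simulate_plate", {
    if (is.null(traces)) {
      r <- simulatePlate(config$plate, seed = seed)
      writeTraces(r, outFile("traces.csv"))
      written <- c(written, "traces.csv")
      tt <- truthTable(r)
      emit(tt[, c("region", "channel", "well_id", "molecules", "ct_true")],
           "truth.csv")
      r
    } else readTraces(traces)
  })

  calls <- withStage("call", callPlate(run, config$criteria))
  emit(wellCalls(calls), "calls.csv")
  emit(plateSummary(calls), "plate_summary.csv")

  quant <- withStage("quantify", quantifyPlate(calls))
  emit(quant, "quant.csv")

  # -- cohort ---------------------------------------------------------------
  ce <- withStage("simulate_cohort",
                  simulateCohort(config$cohort, seed = seed + 1L))
  cohortTab <- cbind(
    data.frame(sample_id = colnames(ce),
               cohort = cohortLabels(ce),
               timepoint = SummarizedExperiment::colData(ce)$timepoint,
               patient = SummarizedExperiment::colData(ce)$patient),
    as.data.frame(markerMatrix(ce)))
  emit(cohortTab, "cohort.csv")

  sr <- withStage("score", scoreCohort(ce, ahp = config$ahp,
                                       reference = config$reference))
  zTab <- as.data.frame(markerZ(sr))
  colnames(zTab) <- paste0("z_", colnames(zTab))
  emit(cbind(data.frame(sample_id = colnames(ce),
                        cohort = cohortLabels(ce)),
             zTab, composite = compositeScores(sr)), "scores.csv")
  jsonlite::write_json(
    list(weights = as.list(scoreWeights(sr)), cr = sr@cr,
         reference = sr@reference),
    outFile("weights.json"), auto_unbox = TRUE, digits = NA)
  written <- c(written, "weights.json")

  roc <- withStage("score", {
    isCase <- cohortLabels(ce) %in% c("early", "advanced")
    if (length(unique(isCase)) == 2L)
      rocAnalysis(compositeScores(sr), as.integer(isCase))
    else NULL
  })
  if (!is.null(roc)) emit(roc$curve, "roc.csv")

  # -- profile --------------------------------------------------------------
  prof <- withStage("profile", {
    cal <- calibrateCohort(ce)
    baseline <- is.na(cal$timepoint) | cal$timepoint != "post"
    lab <- ifelse(cal$cohort == "HD", "HD", "HCC")
    model <- fitRegionClassifier(cal[baseline, c("x", "y")], lab[baseline],
                                 kernel = config$kernel, seed = seed)
    regions <- assignRegions(model, cal[, c("x", "y")])
    props <- regionProportions(regions, cal$cohort)
    ev <- cohortEfficacyVectors(ce)
    list(cal = cal, model = model, regions = regions, props = props,
         ev = ev)
  })
  emit(prof$cal, "calibrated_points.csv")
  emit(data.frame(sample_id = prof$cal$sample_id,
                  marker = prof$cal$marker, region = prof$regions),
       "regions.csv")
  emit(prof$props, "region_proportions.csv")
  if (nrow(prof$ev)) emit(prof$ev, "efficacy_vectors.csv")
  jsonlite::write_json(
    c(list(kernel = prof$model@kernel,
           train_accuracy = prof$model@trainAccuracy),
      as.list(prof$model@cv)),
    outFile("classifier_metrics.json"), auto_unbox = TRUE, digits = NA)
  written <- c(written, "classifier_metrics.json")

  manifest <- list(
    tool = paste0("digitalCTC ",
                  as.character(utils::packageVersion("digitalCTC"))),
    seed = seed,
    config_hash = .md5OfObject(config),
    files = as.list(tools::md5sum(file.path(outDir, written))),
    timestamp = format(Sys.time(), tz = "UTC")
  )
  names(manifest$files) <- written
  jsonlite::write_json(manifest, outFile("manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  res <- list(manifest = manifest, run = run, calls = calls, quant = quant,
              cohort = ce, scores = sr, profile = prof)
  withStage("report", exportReport(res, outDir))
  invisible(res)
}

#' Export a machine-readable run report
#'
#' Writes `report.json`, a compact summary of every stage (positive-well
#' counts, copy estimates, score and ROC summaries, region proportions).
#' Regeneration from the same stage outputs is idempotent.
#'
#' @param results the list returned by [runPipeline()].
#' @param outDir output directory.
#' @return the report path, invisibly.
#' @export
exportReport <- function(results, outDir) {
  if (is.null(results$calls)) stop("missing upstream output: calls")
  s <- plateSummary(results$calls)
  ce <- results$cohort
  report <- list(
    plate = list(wells_analyzed = sum(s$N), wells_positive = sum(s$M),
                 cells = s),
    quant = results$quant,
    cohort = if (is.null(ce)) list(n_samples = 0,
                                   note = "zero samples: no cohort stage")
             else list(n_samples = ncol(ce),
                       cohorts = as.list(table(cohortLabels(ce)))),
    scores = if (!is.null(results$scores))
      list(weights = as.list(scoreWeights(results$scores)),
           composite_range = range(compositeScores(results$scores))),
    regions = if (!is.null(results$profile)) results$profile$props
  )
  path <- file.path(outDir, "report.json")
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
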
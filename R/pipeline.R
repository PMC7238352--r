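# End-to-end orchestration: segment -> extract -> normalize -> select ->
# train -> evaluate, as one reproducible run. Every stage is a pure function
# of (inputs, config, seeds); the resolved config is embedded in the report.

.FAMILY_IDS <- list(shape = 1:9, additional = 10:11, margin = 12:32,
                    density = 33:130)

#' Pipeline run configuration
#'
#' @param nCases phantom cohort size (balanced over the four categories).
#' @param seed master seed; all stage seeds derive from it.
#' @param radiusPx phantom base radius (also the approximate radius handed
#'   to candidate selection, mimicking the dataset annotation).
#' @param nThresholds region-growing threshold sweep size.
#' @param glcmLevels grey quantization for the texture family.
#' @param families feature families to extract (default all four).
#' @param lValues GA sweep subset sizes (default `c(1:6, 10, 16)`, a short
#'   schedule suited to cohort-scale runs).
#' @param populationBase,maxGenerations,stagnationX GA schedule overrides.
#' @param maxit,decay BPN fitting hyperparameters.
#' @param trainFraction train share of the stratified split (default 0.6).
#' @param outDir optional directory for JSON/CSV artifacts.
#' @return list of class `RunConfig`.
#' @export
cadConfig <- function(nCases = 120L, seed = 1L, radiusPx = 16,
                      nThresholds = 16L, glcmLevels = 32L,
                      families = names(.FAMILY_IDS),
                      lValues = c(1:6, 10L, 16L), populationBase = 3L,
                      maxGenerations = 12L, stagnationX = 5L,
                      maxit = 150L, decay = 1e-3, trainFraction = 0.6,
                      outDir = NULL) {
  families <- match.arg(families, names(.FAMILY_IDS), several.ok = TRUE)
  structure(as.list(environment()), class = "RunConfig")
}

#' Segment one ROI semi-automatically
#'
#' Histogram-equalizes the ROI, grows candidate masks over the threshold
#' sweep and picks the candidate whose equivalent radius best matches the
#' reported approximate lesion radius; holes are filled before the contour
#' is traced.
#'
#' @param roi an [ROIImage-class].
#' @param targetRadius approximate lesion radius in pixels.
#' @param nThresholds threshold sweep size.
#' @return list with `roi` (equalized), `mask`, `contour`.
#' @export
segmentROI <- function(roi, targetRadius, nThresholds = 16L) {
  eq <- equalizeHistogram(roi)
  cand <- suppressWarnings(generateCandidates(eq, nThresholds))
  mask <- fillMaskHoles(selectCandidate(cand, targetRadius))
  list(roi = eq, mask = mask, contour = extractContour(mask))
}

#' Run the full CAD pipeline on a synthetic phantom cohort
#'
#' Generates a balanced seeded phantom cohort, segments every ROI, extracts
#' the configured feature families, min-max normalizes on the training split
#' only, runs the GA feature-subset sweep with network validation accuracy
#' as fitness, trains the final network on the best subset and evaluates it
#' on the held-out 40%.
#'
#' @param config a [cadConfig()].
#' @return list of class `CADRun` with `config`, `table` (raw features),
#'   `split`, `sweep`, `bestSubset`, `model`, `metrics` and `log`.
#' @export
runAll <- function(config = cadConfig()) {
  stopifnot(inherits(config, "RunConfig"))
  log <- c(sprintf("cohort: %d phantoms, seed %d", config$nCases, config$seed))

  categories <- rep(.BIRADS_CLASSES, length.out = config$nCases)
  stage <- function(name, expr) tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))

  cases <- stage("synthesis+segmentation+extraction",
    lapply(seq_len(config$nCases), function(i) {
      ph <- makePhantom(phantomSpec(categories[i], radiusPx = config$radiusPx,
                                    seed = config$seed * 1000L + i))
      seg <- segmentROI(ph$roi, targetRadius = ph$radiusPx,
                        nThresholds = config$nThresholds)
      feats <- extractFeatures(seg$roi, seg$mask, ph$ageYears,
                               contour = seg$contour,
                               glcmCfg = glcmConfig(levels = config$glcmLevels))
      list(label = ph$category, features = feats)
    }))
  log <- c(log, sprintf("extracted %d features per case",
                        length(cases[[1]]$features)))

  keepIds <- sort(unlist(.FAMILY_IDS[config$families], use.names = FALSE))
  featureCols <- .featureIds(keepIds)
  mat <- t(vapply(cases, `[[`, numeric(130L), "features"))[, keepIds, drop = FALSE]
  colnames(mat) <- featureCols
  table <- data.frame(case_id = sprintf("case%04d", seq_len(config$nCases)),
                      label = vapply(cases, `[[`, character(1), "label"),
                      mat, stringsAsFactors = FALSE)

  split <- stage("split", stratifiedSplit(table, config$trainFraction,
                                          seed = config$seed))
  scaler <- stage("normalize", fitScaler(table[split$train, ]))
  norm <- applyScaler(scaler, table)
  trainTab <- norm[split$train, ]
  testTab <- norm[split$test, ]

  bpnCfg <- bpnConfig(maxit = config$maxit, decay = config$decay,
                      seed = config$seed)
  fitness <- function(ids) gaFitness(ids, trainTab, bpnCfg,
                                     featureCols = featureCols)
  sweep <- stage("select", gaSweep(fitness, nFeatures = length(featureCols),
                                   lValues = config$lValues[config$lValues <= length(featureCols)],
                                   populationBase = config$populationBase,
                                   maxGenerations = config$maxGenerations,
                                   stagnationX = config$stagnationX,
                                   seed = config$seed))
  bestIds <- sort(sweep$globalBest$genes)
  bestCols <- featureCols[bestIds]
  log <- c(log, sprintf("selected subset (L = %d): %s", length(bestIds),
                        paste(bestCols, collapse = " ")))

  model <- stage("train", trainBPN(as.matrix(trainTab[, bestCols, drop = FALSE]),
                                   trainTab$label, bpnCfg))
  pred <- stage("evaluate", predictBPN(model,
                                       as.matrix(testTab[, bestCols, drop = FALSE])))
  metrics <- metricsReport(confusionMatrix(testTab$label, pred))
  log <- c(log, sprintf("test accuracy %.1f%%", 100 * metrics$accuracy))

  run <- structure(list(config = config, table = table, split = split,
                        scaler = scaler, sweep = sweep, bestSubset = bestCols,
                        model = model, metrics = metrics, log = log),
                   class = "CADRun")
  if (!is.null(config$outDir)) writeRunArtifacts(run, config$outDir)
  run
}

#' Write the JSON/CSV artifacts of a pipeline run
#'
#' Emits `features.csv`, `sweep.json`, `metrics.json`, `confusion.csv` and
#' `run.log`; the metrics JSON embeds the resolved configuration and package
#' version for provenance.
#'
#' @param run a `CADRun`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
writeRunArtifacts <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeFeatureTable(run$table, file.path(dir, "features.csv"))
  jsonlite::write_json(
    list(perL = run$sweep$perL,
         genesPerL = run$sweep$genesPerL,
         globalBest = run$sweep$globalBest),
    file.path(dir, "sweep.json"), auto_unbox = TRUE, digits = NA)
  cfg <- run$config; cfg$outDir <- NULL
  jsonlite::write_json(
    list(config = unclass(cfg),
         package_version = as.character(utils::packageVersion("biradsCAD")),
         accuracy = run$metrics$accuracy,
         perClass = run$metrics$perClass,
         micro = as.list(run$metrics$micro),
         bestSubset = run$bestSubset),
    file.path(dir, "metrics.json"), auto_unbox = TRUE, digits = NA)
  writeConfusionCSV(run$metrics$confusion, file.path(dir, "confusion.csv"))
  writeLines(run$log, file.path(dir, "run.log"))
  invisible(dir)
}

#' @export
print.CADRun <- function(x, ...) {
  cat(sprintf("CAD pipeline run: %d cases, seed %d\n",
              x$config$nCases, x$config$seed))
  cat(sprintf("selected %d features; test accuracy %.1f%%\n",
              length(x$bestSubset), 100 * x$metrics$accuracy))
  invisible(x)
}
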
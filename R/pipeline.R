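#' Run the full analysis pipeline
#'
#' One-shot orchestration of every stage: simulate a synthetic cohort and
#' its drawings, write one stroke CSV per drawing, extract the feature
#' matrix, normalize it, run the association scan, select significant
#' features at the scan Bonferroni threshold, build composites, test them
#' against their neuropsychological tests, run the MCI logistic models for
#' both test scores and composites, and emit a group-comparison table, a
#' markdown + JSON report and a run manifest with content hashes of every
#' output. Deterministic under `(config, seed)`: rerunning with the same
#' configuration reproduces byte-identical result CSVs.
#'
#' @param config a [cohortConfig()], or a path to a YAML file of
#'   [cohortConfig()] arguments (plus optional `alpha`, `scanTests`
#'   override, `compositeScale`, `splitSample`, `minEvents`).
#' @param outDir output directory (created if absent).
#' @param seed optional integer overriding the config seed.
#' @param writeDrawings write per-drawing stroke CSVs under
#'   `drawings/` (default TRUE); when FALSE the drawings stay in memory
#'   and feature extraction is run on them directly.
#' @param alpha family-wise level for both Bonferroni families (default
#'   0.05).
#' @param compositeScale `"mean"` or `"sum"` (see [compositeScores()]).
#' @param splitSample additionally run the split-sample composite variant
#'   (default FALSE).
#' @param minEvents minimum MCI cases for the logistic stage; if unmet,
#'   the MCI stage is skipped with a note in the report rather than
#'   aborting the run.
#' @return (invisibly) list with every stage's in-memory result plus
#'   `manifest`.
#' @export
fullPipeline <- function(config, outDir, seed = NULL, writeDrawings = TRUE,
                         alpha = 0.05, compositeScale = "mean",
                         splitSample = FALSE, minEvents = 10) {
  if (is.character(config)) config <- .configFromYAML(config)
  stopifnot(inherits(config, "CohortConfig"))
  if (!is.null(seed)) config$seed <- as.integer(seed)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(0)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  ## simulate
  sim <- stage("simulate", simulateStudy(config))
  cohortPath <- file.path(outDir, "cohort.csv")
  write.csv(sim$cohort, cohortPath, row.names = FALSE, quote = FALSE)
  outputs <- c(outputs, cohortPath)
  if (writeDrawings) {
    ddir <- file.path(outDir, "drawings")
    dir.create(ddir, showWarnings = FALSE)
    for (d in sim$drawings) {
      p <- file.path(ddir, sprintf("%s_%s.csv", participantID(d),
                                   drawingCondition(d)))
      writeDrawing(d, p, dialect = "csv")
    }
  }

  ## extract
  cdTab <- sim$cohort
  rownames(cdTab) <- cdTab$participant_id
  fs <- stage("extract",
              buildFeatureMatrix(sim$drawings, colData = cdTab))
  featPath <- file.path(outDir, "features.csv")
  write.csv(data.frame(participant_id = colnames(fs),
                       t(rawFeatures(fs)), check.names = FALSE),
            featPath, row.names = FALSE, quote = FALSE)
  outputs <- c(outputs, featPath)

  ## normalize + associate
  fs <- stage("normalize", suppressWarnings(normalizeFeatures(fs)))
  scan <- stage("associate", suppressWarnings(scanAssociations(fs)))
  scanPath <- file.path(outDir, "associations.csv")
  write.csv(scan, scanPath, row.names = FALSE, quote = FALSE)
  outputs <- c(outputs, scanPath)

  ## composite
  nFeatures <- length(unique(scan$feature))
  sel <- stage("select", selectSignificant(scan, alpha = alpha))
  comp <- stage("composite",
                suppressMessages(compositeScores(sel, fs,
                                                 scale = compositeScale)))
  compTab <- stage("composite", if (length(comp)) {
    associateComposite(comp, fs)
  } else {
    data.frame()
  })
  compPath <- file.path(outDir, "composite_associations.csv")
  write.csv(compTab, compPath, row.names = FALSE, quote = FALSE)
  outputs <- c(outputs, compPath)
  if (length(comp)) {
    scoresPath <- file.path(outDir, "composite_scores.csv")
    scoresTab <- data.frame(participant_id = colnames(fs),
                            vapply(comp, function(cs) cs$scores[colnames(fs)],
                                   numeric(ncol(fs))),
                            check.names = FALSE)
    write.csv(scoresTab, scoresPath, row.names = FALSE, quote = FALSE)
    outputs <- c(outputs, scoresPath)
  }
  splitTab <- NULL
  if (splitSample) {
    splitTab <- stage("composite-split",
                      splitSampleComposite(fs, alpha = alpha,
                                           scale = compositeScale,
                                           seed = config$seed))
    splitPath <- file.path(outDir, "composite_associations_split.csv")
    write.csv(splitTab, splitPath, row.names = FALSE, quote = FALSE)
    outputs <- c(outputs, splitPath)
  }

  ## mci
  mciTab <- NULL
  mciNote <- NULL
  nEvents <- sum(sim$cohort$mci == 1L)
  if (nEvents >= minEvents) {
    preds <- c(
      setNames(lapply(intersect(npTestBattery()$key, colnames(sim$cohort)),
                      function(k) sim$cohort[[k]]),
               paste0("np:", intersect(npTestBattery()$key, colnames(sim$cohort)))),
      setNames(lapply(comp, function(cs) unname(cs$scores[colnames(fs)])),
               paste0("composite:", names(comp)))
    )
    mciTab <- stage("mci", associateMCI(preds, sim$cohort,
                                        minEvents = minEvents, alpha = alpha))
    mciPath <- file.path(outDir, "mci_associations.csv")
    write.csv(mciTab, mciPath, row.names = FALSE, quote = FALSE)
    outputs <- c(outputs, mciPath)
  } else {
    mciNote <- sprintf("MCI stage skipped: %d events < minimum %d",
                       nEvents, minEvents)
  }

  ## group comparison
  grp <- stage("group-compare", groupCompare(sim$cohort))
  grpPath <- file.path(outDir, "group_comparison.csv")
  write.csv(grp$continuous, grpPath, row.names = FALSE, quote = FALSE)
  outputs <- c(outputs, grpPath)

  ## report + manifest
  results <- list(config = config, scan = scan, selected = sel,
                  composites = comp, compositeTable = compTab,
                  splitTable = splitTab, mciTable = mciTab,
                  mciNote = mciNote, groupComparison = grp,
                  nFeatures = nFeatures, alpha = alpha)
  rep <- stage("report", .writeReport(results, outDir))
  outputs <- c(outputs, rep)
  manifest <- list(
    package_version = as.character(packageVersion("ClockInk")),
    seed = config$seed,
    n_participants = config$nParticipants,
    alpha = alpha,
    timestamp = format(Sys.time(), tz = "UTC"),
    outputs = lapply(setNames(nm = sub(paste0("^", outDir, "/?"), "",
                                       outputs)), function(rel) {
      list(md5 = unname(tools::md5sum(file.path(outDir, rel))))
    })
  )
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(results, list(cohort = sim$cohort, g = sim$g,
                            featureSet = fs, manifest = manifest)))
}

.configFromYAML <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  args <- yaml::read_yaml(path)
  known <- names(formals(cohortConfig))
  do.call(cohortConfig, args[intersect(names(args), known)])
}

# markdown + JSON summary of a pipeline run
.writeReport <- function(res, outDir) {
  scanThr <- bonferroniThreshold(res$alpha, res$nFeatures)
  reportThr <- bonferroniThreshold(res$alpha, nrow(npTestBattery()))
  mPerTest <- vapply(res$selected, nrow, integer(1))
  md <- c(
    "# Clock-drawing association pipeline report", "",
    sprintf("Cohort: n = %d, seed = %d.",
            res$config$nParticipants, res$config$seed),
    "",
    sprintf("Features scanned: %d. Feature-scan significance threshold: %.3g (= %.2g / %d).",
            res$nFeatures, scanThr, res$alpha, res$nFeatures),
    sprintf("Reporting threshold over the %d-test battery: %.3g (= %.2g / %d).",
            nrow(npTestBattery()), reportThr, res$alpha, nrow(npTestBattery())),
    "",
    "## Significant features per test", "",
    if (all(mPerTest == 0L)) {
      "No significant features for any test."
    } else {
      c(sprintf("- %s: m = %d", names(mPerTest), mPerTest),
        "",
        sprintf("Mean m across tests: %.2f", mean(mPerTest)))
    },
    "",
    "## Composite associations", "",
    if (is.null(res$compositeTable) || nrow(res$compositeTable) == 0L) {
      "No composites produced (no significant features)."
    } else {
      sprintf("- %s: m = %d, n = %d, beta = %.4g, SE = %.4g, Bonferroni p = %.3g",
              res$compositeTable$test, res$compositeTable$m,
              res$compositeTable$n_used, res$compositeTable$beta,
              res$compositeTable$se, res$compositeTable$p_bonferroni)
    },
    "",
    "## MCI associations", "",
    if (is.null(res$mciTable)) {
      res$mciNote %||% "MCI stage not run."
    } else {
      sprintf("- %s: coefficient = %.4g, SE = %.4g, p = %.3g%s",
              res$mciTable$predictor, res$mciTable$coefficient,
              res$mciTable$se, res$mciTable$p_value,
              ifelse(!is.na(res$mciTable$significant) & res$mciTable$significant,
                     " (significant)", ""))
    },
    ""
  )
  mdPath <- file.path(outDir, "report.md")
  writeLines(unlist(md), mdPath)
  js <- list(
    n_features = res$nFeatures,
    scan_threshold = scanThr,
    report_threshold = reportThr,
    m_per_test = as.list(mPerTest),
    mean_m = if (length(mPerTest)) mean(mPerTest) else 0,
    composite = res$compositeTable,
    mci = res$mciTable,
    mci_note = res$mciNote
  )
  jsPath <- file.path(outDir, "report.json")
  jsonlite::write_json(js, jsPath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  c(mdPath, jsPath)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Summarize a results directory
#'
#' Re-reads the CSV outputs of a [fullPipeline()] run and recomputes the
#' headline summary: the number of significant features per test (m), the
#' mean m across tests, and the two Bonferroni thresholds. Errors listing
#' the absent files when the directory is incomplete.
#'
#' @param resultsDir directory written by [fullPipeline()].
#' @param alpha family-wise level used in the run (default 0.05).
#' @return list with `m_per_test`, `mean_m`, `scan_threshold`,
#'   `report_threshold`, `composite`, `mci` (NULL when that stage was
#'   skipped).
#' @export
pipelineReport <- function(resultsDir, alpha = 0.05) {
  need <- c("associations.csv", "composite_associations.csv")
  absent <- need[!file.exists(file.path(resultsDir, need))]
  if (length(absent)) {
    stop("results directory incomplete; missing: ",
         paste(absent, collapse = ", "))
  }
  scan <- read.csv(file.path(resultsDir, "associations.csv"),
                   stringsAsFactors = FALSE)
  nFeatures <- length(unique(scan$feature))
  sel <- selectSignificant(scan, alpha = alpha)
  mPerTest <- vapply(sel, nrow, integer(1))
  compPath <- file.path(resultsDir, "composite_associations.csv")
  comp <- tryCatch(read.csv(compPath, stringsAsFactors = FALSE),
                   error = function(e) NULL)
  mciPath <- file.path(resultsDir, "mci_associations.csv")
  mci <- if (file.exists(mciPath)) {
    read.csv(mciPath, stringsAsFactors = FALSE)
  } else NULL
  list(m_per_test = mPerTest,
       mean_m = if (length(mPerTest)) mean(mPerTest) else 0,
       scan_threshold = bonferroniThreshold(alpha, nFeatures),
       report_threshold = bonferroniThreshold(alpha, nrow(npTestBattery())),
       composite = comp, mci = mci)
}
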
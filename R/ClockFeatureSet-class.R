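#' ClockFeatureSet: a participants-by-features container
#'
#' `ClockFeatureSet` extends [SummarizedExperiment::SummarizedExperiment]
#' with features as rows and participants as columns. The `"raw"` assay
#' holds extracted feature values (command and copy conditions as separate
#' rows, suffixed `_command` / `_copy`); [normalizeFeatures()] adds a
#' `"normalized"` assay holding the per-feature rank-based inverse normal
#' transform (the V matrix the composite scores are built from). `colData`
#' carries the cohort table: covariates (age, sex, education), the MCI
#' flag and neuropsychological test scores.
#'
#' @seealso [buildFeatureMatrix()], [normalizeFeatures()],
#'   [scanAssociations()]
#' @name ClockFeatureSet-class
#' @aliases ClockFeatureSet-class
#' @exportClass ClockFeatureSet
setClass("ClockFeatureSet", contains = "SummarizedExperiment")

.validClockFeatureSet <- function(object) {
  msgs <- character(0)
  if (!"raw" %in% assayNames(object)) {
    msgs <- c(msgs, "assay 'raw' is required")
  }
  if (is.null(rownames(object))) msgs <- c(msgs, "feature (row) names required")
  if (is.null(colnames(object))) msgs <- c(msgs, "participant (column) names required")
  if (length(msgs)) msgs else TRUE
}

setValidity("ClockFeatureSet", .validClockFeatureSet)

#' Construct a ClockFeatureSet
#'
#' @param raw features x participants numeric matrix with dimnames.
#' @param colData `DataFrame`/data.frame of per-participant data, rows
#'   aligned to `colnames(raw)`.
#' @param normalized optional matrix of the same shape holding normalized
#'   values.
#' @return a [ClockFeatureSet-class].
#' @export
ClockFeatureSet <- function(raw, colData = NULL, normalized = NULL) {
  raw <- as.matrix(raw)
  assays <- list(raw = raw)
  if (!is.null(normalized)) assays$normalized <- as.matrix(normalized)
  if (is.null(colData)) {
    colData <- S4Vectors::DataFrame(row.names = colnames(raw))
  }
  se <- SummarizedExperiment(assays = assays, colData = colData)
  new("ClockFeatureSet", se)
}

#' @describeIn ClockFeatureSet-class feature names (row names).
#' @param x a `ClockFeatureSet`.
#' @export
featureNames <- function(x) rownames(x)

#' @describeIn ClockFeatureSet-class participant identifiers (column names).
#' @export
participantIDs <- function(x) colnames(x)

#' @describeIn ClockFeatureSet-class raw features x participants matrix.
#' @export
rawFeatures <- function(x) assay(x, "raw")

#' @describeIn ClockFeatureSet-class normalized (rank-INT) matrix; errors if
#'   [normalizeFeatures()] has not been applied.
#' @export
normalizedFeatures <- function(x) {
  if (!"normalized" %in% assayNames(x)) {
    stop("no 'normalized' assay: run normalizeFeatures() first")
  }
  assay(x, "normalized")
}

#' Build a feature matrix from a set of drawings
#'
#' Extracts every registry feature from every drawing and assembles a
#' [ClockFeatureSet-class] with one row per (feature, condition) pair —
#' command and copy drawings yield separate columns suffixed `_command` and
#' `_copy`, treated as distinct features downstream — and one column per
#' participant. A feature undefined for a drawing propagates as `NA`; a
#' condition a participant lacks is `NA` across that condition's rows.
#'
#' @param drawings list of [ClockDrawing-class] objects, at most one per
#'   (participant, condition); duplicates are an error.
#' @param registry feature registry; default [defaultFeatureRegistry()].
#' @param colData optional per-participant table (row names = participant
#'   ids) carried into the object.
#' @return a [ClockFeatureSet-class] with the `"raw"` assay filled.
#' @export
buildFeatureMatrix <- function(drawings, registry = defaultFeatureRegistry(),
                               colData = NULL) {
  if (length(drawings) == 0L) stop("no drawings supplied")
  ids <- vapply(drawings, participantID, character(1))
  conds <- vapply(drawings, drawingCondition, character(1))
  key <- paste(ids, conds, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1L]
    stop("duplicate drawing for (participant, condition): ",
         gsub("\r", ", ", dup, fixed = TRUE))
  }
  pids <- unique(ids)
  usedConds <- intersect(.CLOCK_CONDITIONS, unique(conds))
  fnames <- names(registry)
  rows <- as.vector(outer(fnames, usedConds, paste, sep = "_"))
  raw <- matrix(NA_real_, nrow = length(rows), ncol = length(pids),
                dimnames = list(rows, pids))
  for (k in seq_along(drawings)) {
    v <- extractFeatures(drawings[[k]], registry)
    raw[paste(fnames, conds[k], sep = "_"), ids[k]] <- v
  }
  if (!is.null(colData)) {
    colData <- S4Vectors::DataFrame(colData)
    if (!is.null(rownames(colData))) {
      missing <- setdiff(pids, rownames(colData))
      if (length(missing)) {
        stop("colData lacks rows for participant(s): ",
             paste(head(missing, 5), collapse = ", "))
      }
      colData <- colData[pids, , drop = FALSE]
    } else if (nrow(colData) != length(pids)) {
      stop("colData must have one row per participant")
    }
  }
  ClockFeatureSet(raw, colData = colData)
}

#' Rank-based inverse normal normalization of all features
#'
#' Applies [rankInverseNormal()] to every feature row of the `"raw"` assay
#' and stores the result as the `"normalized"` assay. A feature that cannot
#' be transformed (constant across participants, or fewer than two
#' non-missing values) is set entirely to `NA` with a warning naming it —
#' never silently dropped.
#'
#' @param x a [ClockFeatureSet-class].
#' @return `x` with a `"normalized"` assay added.
#' @export
normalizeFeatures <- function(x) {
  stopifnot(is(x, "ClockFeatureSet"))
  raw <- assay(x, "raw")
  norm <- matrix(NA_real_, nrow = nrow(raw), ncol = ncol(raw),
                 dimnames = dimnames(raw))
  for (i in seq_len(nrow(raw))) {
    norm[i, ] <- tryCatch(rankInverseNormal(raw[i, ]), error = function(e) {
      warning("feature ", rownames(raw)[i], " not normalizable: ",
              conditionMessage(e), call. = FALSE)
      rep(NA_real_, ncol(raw))
    })
  }
  assays(x, withDimnames = FALSE)$normalized <- norm
  x
}

#' @rdname ClockFeatureSet-class
#' @param object a `ClockFeatureSet`.
#' @export
setMethod("show", "ClockFeatureSet", function(object) {
  cat("ClockFeatureSet:", nrow(object), "features x", ncol(object),
      "participants\n")
  cat("  assays:", paste(assayNames(object), collapse = ", "), "\n")
  cat("  colData:", paste(head(colnames(colData(object)), 8), collapse = ", "),
      if (ncol(colData(object)) > 8) "..." else "", "\n")
  invisible(NULL)
})
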
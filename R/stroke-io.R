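#' Nominal spatial resolution of the digital pen, in millimeters
#'
#' The capture hardware this package models reports pen position at a
#' nominal resolution of 0.002 inches; this constant converts that figure
#' to the package's millimeter coordinates (~0.0508 mm). Reference only —
#' no computation enforces it.
#' @export
PEN_RESOLUTION_MM <- 0.002 * 25.4

#' Read a clock drawing from a stroke file
#'
#' Two plain-text dialects are supported. The CSV dialect is one row per
#' sample with header
#' `participant_id,condition,stroke_id,component,t_ms,x_mm,y_mm`, samples
#' contiguous per stroke. The JSON dialect is one object with
#' `participant_id`, `condition` and `strokes: [{component, samples:
#' [[t, x, y], ...]}]`. Parsing is locale-independent (decimal point only).
#'
#' @param path path to an existing stroke file.
#' @param dialect `"csv"` or `"json"`; default guesses from the file
#'   extension.
#' @return a validated [ClockDrawing-class]; sample order and stroke
#'   grouping are preserved exactly.
#' @examples
#' # a bundled synthetic command-condition clock (20 Hz for compactness)
#' f <- system.file("extdata", "synthetic-clock-command.csv",
#'                  package = "ClockInk")
#' d <- readDrawing(f)
#' d
#' extractFeatures(d)[c("total_completion_time", "percent_think")]
#'
#' d2 <- ClockDrawing("p1", "command",
#'                    list(data.frame(t = c(0, 12.5, 25), x = 0:2, y = 0)),
#'                    "clockface")
#' f2 <- tempfile(fileext = ".csv")
#' writeDrawing(d2, f2)
#' identical(drawingToTable(readDrawing(f2)), drawingToTable(d2))
#' @export
readDrawing <- function(path, dialect = c("auto", "csv", "json")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("stroke file does not exist: ", path)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (dialect == "csv") .readDrawingCSV(path) else .readDrawingJSON(path)
}

.STROKE_CSV_COLS <- c("participant_id", "condition", "stroke_id",
                      "component", "t_ms", "x_mm", "y_mm")

.readDrawingCSV <- function(path) {
  if (file.size(path) == 0L) stop("empty stroke file: ", path)
  hdr <- names(read.csv(path, nrows = 0L))
  missing <- setdiff(.STROKE_CSV_COLS, hdr)
  if (length(missing)) {
    stop("malformed stroke CSV ", path, ": missing column(s) ",
         paste(missing, collapse = ", "))
  }
  tab <- tryCatch(
    read.csv(path, stringsAsFactors = FALSE, colClasses = c(
      participant_id = "character", condition = "character",
      stroke_id = "integer", component = "character",
      t_ms = "numeric", x_mm = "numeric", y_mm = "numeric")),
    error = function(e) stop("malformed stroke CSV ", path, ": ",
                             conditionMessage(e)))
  if (nrow(tab) == 0L) stop("empty stroke file (header only): ", path)
  bad <- which(!is.finite(tab$t_ms) | !is.finite(tab$x_mm) | !is.finite(tab$y_mm))
  if (length(bad)) {
    stop(sprintf("malformed stroke CSV %s: non-numeric t_ms/x_mm/y_mm at data line %d",
                 path, bad[1L]))
  }
  pid <- unique(tab$participant_id)
  cond <- unique(tab$condition)
  if (length(pid) != 1L || length(cond) != 1L) {
    stop("stroke CSV ", path, " must describe a single (participant, condition)")
  }
  # contiguity: stroke_id changes only at stroke boundaries
  runs <- rle(tab$stroke_id)
  if (anyDuplicated(runs$values)) {
    stop("malformed stroke CSV ", path,
         ": samples of stroke ", runs$values[anyDuplicated(runs$values)],
         " are not contiguous")
  }
  idx <- rep(seq_along(runs$values), runs$lengths)
  strokes <- lapply(split(seq_len(nrow(tab)), idx), function(i) {
    data.frame(t = tab$t_ms[i], x = tab$x_mm[i], y = tab$y_mm[i])
  })
  comps <- vapply(split(tab$component, idx), function(co) co[1L], character(1))
  ClockDrawing(pid, cond, strokes, comps)
}

.readDrawingJSON <- function(path) {
  if (file.size(path) == 0L) stop("empty stroke file: ", path)
  obj <- tryCatch(jsonlite::fromJSON(path, simplifyDataFrame = FALSE,
                                     simplifyMatrix = FALSE),
                  error = function(e) stop("malformed stroke JSON ", path, ": ",
                                           conditionMessage(e)))
  need <- c("participant_id", "condition", "strokes")
  missing <- setdiff(need, names(obj))
  if (length(missing)) {
    stop("malformed stroke JSON ", path, ": missing field(s) ",
         paste(missing, collapse = ", "))
  }
  if (length(obj$strokes) == 0L) stop("empty stroke file (no strokes): ", path)
  strokes <- lapply(seq_along(obj$strokes), function(i) {
    st <- obj$strokes[[i]]
    if (is.null(st$samples) || length(st$samples) == 0L) {
      stop("malformed stroke JSON ", path, ": stroke ", i, " has no samples")
    }
    m <- do.call(rbind, lapply(st$samples, function(s) {
      if (length(s) != 3L) {
        stop("malformed stroke JSON ", path, ": stroke ", i,
             " sample is not [t, x, y]")
      }
      as.numeric(s)
    }))
    data.frame(t = m[, 1L], x = m[, 2L], y = m[, 3L])
  })
  comps <- vapply(obj$strokes, function(st) {
    if (is.null(st$component)) "unlabeled" else as.character(st$component)
  }, character(1))
  ClockDrawing(obj$participant_id, obj$condition, strokes, comps)
}

#' Write a clock drawing to a stroke file
#'
#' Inverse of [readDrawing()]: `readDrawing(writeDrawing(d, f))` recovers
#' `d` exactly on the data model (identical samples, stroke grouping,
#' component labels, condition).
#'
#' @param drawing a valid [ClockDrawing-class].
#' @param path output file path.
#' @param dialect `"csv"` or `"json"`; default guesses from the extension.
#' @return `path`, invisibly.
#' @export
writeDrawing <- function(drawing, path, dialect = c("auto", "csv", "json")) {
  stopifnot(is(drawing, "ClockDrawing"))
  validObject(drawing)
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("unwritable path (directory does not exist): ", path)
  if (dialect == "csv") {
    write.csv(drawingToTable(drawing), path, row.names = FALSE, quote = FALSE)
  } else {
    obj <- list(
      participant_id = drawing@participantID,
      condition = drawing@condition,
      strokes = lapply(seq_along(drawing@strokes), function(i) {
        s <- drawing@strokes[[i]]
        list(component = drawing@components[i],
             samples = lapply(seq_len(nrow(s)),
                              function(k) c(s$t[k], s$x[k], s$y[k])))
      })
    )
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Check the sampling regularity of a drawing
#'
#' Advisory quality report on within-stroke inter-sample time gaps against a
#' nominal pen sampling rate (a digital pen nominally reports its position
#' 80 times per second, i.e. every 12.5 ms). Gaps between strokes are pen-up
#' think time, not sampling gaps, and are excluded.
#'
#' @param drawing a valid [ClockDrawing-class].
#' @param nominalHz nominal sampling rate in Hz (default 80).
#' @return list with `median_gap_ms` (median within-stroke gap),
#'   `outlier_fraction` (fraction of within-stroke gaps exceeding 3x the
#'   nominal gap), `n_gaps`, and `nominal_gap_ms`. Never mutates its input.
#' @export
validateSampling <- function(drawing, nominalHz = 80) {
  stopifnot(is(drawing, "ClockDrawing"))
  if (!is.numeric(nominalHz) || length(nominalHz) != 1L || nominalHz <= 0) {
    stop("nominalHz must be a positive number")
  }
  validObject(drawing)
  gaps <- unlist(lapply(drawing@strokes, function(s) diff(s$t)),
                 use.names = FALSE)
  nominal <- 1000 / nominalHz
  list(
    median_gap_ms = median(gaps),
    outlier_fraction = mean(gaps > 3 * nominal),
    n_gaps = length(gaps),
    nominal_gap_ms = nominal
  )
}
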
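#' @title ClockDrawing: a timestamped pen-stroke clock drawing
#'
#' @description
#' `ClockDrawing` holds one participant's clock drawing for one test
#' condition as an ordered set of pen-down strokes. Each stroke is a
#' data.frame with columns `t` (milliseconds since the first sample of the
#' drawing), `x` and `y` (millimeters, page coordinates, y increasing down
#' the page), plus a component label saying what the stroke belongs to
#' (clock face, number, hand, other, or unlabeled when no classification is
#' available).
#'
#' Validity rules: at least one stroke; every stroke has >= 2 samples with
#' strictly increasing non-negative times and finite coordinates; strokes
#' are ordered by their first sample time and their time intervals do not
#' overlap (a stroke may begin exactly when the previous one ends); the
#' first sample of the first stroke carries the minimum time of the
#' drawing.
#'
#' @slot participantID character(1), opaque participant identifier.
#' @slot condition character(1), `"command"` or `"copy"`.
#' @slot strokes a list of data.frames, one per stroke, each with numeric
#'   columns `t`, `x`, `y`.
#' @slot components character vector, one label per stroke, each one of
#'   `"clockface"`, `"number"`, `"hand"`, `"other"`, `"unlabeled"`.
#'
#' @seealso [readDrawing()], [writeDrawing()], [extractFeatures()],
#'   [generateDrawing()]
#' @name ClockDrawing-class
#' @aliases ClockDrawing-class
#' @exportClass ClockDrawing
setClass("ClockDrawing",
  representation(
    participantID = "character",
    condition = "character",
    strokes = "list",
    components = "character"
  )
)

.CLOCK_COMPONENTS <- c("clockface", "number", "hand", "other", "unlabeled")
.CLOCK_CONDITIONS <- c("command", "copy")

.validClockDrawing <- function(object) {
  msgs <- character(0)
  if (length(object@participantID) != 1L || is.na(object@participantID) ||
      !nzchar(object@participantID)) {
    msgs <- c(msgs, "participantID must be a single non-empty string")
  }
  if (length(object@condition) != 1L ||
      !object@condition %in% .CLOCK_CONDITIONS) {
    msgs <- c(msgs, sprintf("condition must be one of: %s",
                            paste(.CLOCK_CONDITIONS, collapse = ", ")))
  }
  ns <- length(object@strokes)
  if (ns < 1L) msgs <- c(msgs, "a drawing must contain at least one stroke")
  if (length(object@components) != ns) {
    msgs <- c(msgs, "components must have one label per stroke")
  } else if (!all(object@components %in% .CLOCK_COMPONENTS)) {
    msgs <- c(msgs, sprintf("component labels must be in: %s",
                            paste(.CLOCK_COMPONENTS, collapse = ", ")))
  }
  for (i in seq_len(ns)) {
    s <- object@strokes[[i]]
    if (!is.data.frame(s) || !all(c("t", "x", "y") %in% names(s))) {
      msgs <- c(msgs, sprintf("stroke %d lacks columns t, x, y", i))
      next
    }
    if (nrow(s) < 2L) {
      msgs <- c(msgs, sprintf("stroke %d has fewer than 2 samples", i))
      next
    }
    if (!all(is.finite(s$t)) || !all(is.finite(s$x)) || !all(is.finite(s$y))) {
      msgs <- c(msgs, sprintf("stroke %d has non-finite samples", i))
      next
    }
    if (any(s$t < 0)) {
      msgs <- c(msgs, sprintf("stroke %d has negative timestamps", i))
    }
    if (any(diff(s$t) <= 0)) {
      msgs <- c(msgs,
        sprintf("stroke %d: time must be strictly increasing within a stroke", i))
    }
  }
  if (length(msgs) == 0L && ns >= 1L) {
    starts <- vapply(object@strokes, function(s) s$t[1L], numeric(1))
    ends <- vapply(object@strokes, function(s) s$t[nrow(s)], numeric(1))
    if (is.unsorted(starts, strictly = FALSE)) {
      msgs <- c(msgs, "strokes must be ordered by first-sample time")
    }
    if (ns > 1L && any(starts[-1L] < ends[-ns])) {
      msgs <- c(msgs, "stroke time intervals must not overlap")
    }
    if (min(starts) != object@strokes[[1L]]$t[1L]) {
      msgs <- c(msgs, "the first sample of the first stroke must carry the minimum time")
    }
  }
  if (length(msgs)) msgs else TRUE
}

setValidity("ClockDrawing", .validClockDrawing)

#' Construct a ClockDrawing
#'
#' @param participantID single character identifier.
#' @param condition `"command"` or `"copy"`.
#' @param strokes list of data.frames with numeric columns `t` (ms), `x`,
#'   `y` (mm), one per pen-down stroke, time-ordered.
#' @param components character vector of per-stroke component labels
#'   (`"clockface"`, `"number"`, `"hand"`, `"other"`, `"unlabeled"`);
#'   defaults to `"unlabeled"` for every stroke.
#'
#' @return a validated [ClockDrawing-class] object.
#' @examples
#' s <- data.frame(t = c(0, 12.5, 25), x = c(0, 1, 2), y = c(0, 0, 0))
#' d <- ClockDrawing("p1", "command", list(s), "clockface")
#' nStrokes(d)
#' @export
ClockDrawing <- function(participantID, condition, strokes,
                         components = rep("unlabeled", length(strokes))) {
  strokes <- lapply(strokes, function(s) {
    s <- as.data.frame(s)[, c("t", "x", "y")]
    s$t <- as.numeric(s$t); s$x <- as.numeric(s$x); s$y <- as.numeric(s$y)
    rownames(s) <- NULL
    s
  })
  new("ClockDrawing", participantID = as.character(participantID),
      condition = as.character(condition), strokes = strokes,
      components = as.character(components))
}

#' @describeIn ClockDrawing-class participant identifier.
#' @param x,object a `ClockDrawing`.
#' @export
setGeneric("participantID", function(x) standardGeneric("participantID"))

#' @rdname ClockDrawing-class
#' @export
setMethod("participantID", "ClockDrawing", function(x) x@participantID)

#' @describeIn ClockDrawing-class test condition (`"command"`/`"copy"`).
#' @export
setGeneric("drawingCondition", function(x) standardGeneric("drawingCondition"))

#' @rdname ClockDrawing-class
#' @export
setMethod("drawingCondition", "ClockDrawing", function(x) x@condition)

#' @describeIn ClockDrawing-class list of per-stroke sample data.frames.
#' @export
setGeneric("strokes", function(x) standardGeneric("strokes"))

#' @rdname ClockDrawing-class
#' @export
setMethod("strokes", "ClockDrawing", function(x) x@strokes)

#' @describeIn ClockDrawing-class per-stroke component labels.
#' @export
setGeneric("strokeComponents", function(x) standardGeneric("strokeComponents"))

#' @rdname ClockDrawing-class
#' @export
setMethod("strokeComponents", "ClockDrawing", function(x) x@components)

#' @describeIn ClockDrawing-class number of strokes.
#' @export
setGeneric("nStrokes", function(x) standardGeneric("nStrokes"))

#' @rdname ClockDrawing-class
#' @export
setMethod("nStrokes", "ClockDrawing", function(x) length(x@strokes))

#' @rdname ClockDrawing-class
#' @export
setMethod("show", "ClockDrawing", function(object) {
  n <- vapply(object@strokes, nrow, integer(1))
  dur <- drawingDuration(object)
  cat("ClockDrawing for participant", sQuote(object@participantID),
      "(", object@condition, "condition )\n")
  cat("  strokes:", length(n), " samples:", sum(n),
      " duration:", format(dur), "ms\n")
  cat("  components:",
      paste(sprintf("%s=%d", names(table(object@components)),
                    as.integer(table(object@components))), collapse = " "),
      "\n")
  invisible(NULL)
})

#' Drawing duration in milliseconds
#'
#' Time span from the first sample of the first stroke to the last sample of
#' the last stroke.
#'
#' @param x a [ClockDrawing-class].
#' @return numeric(1), milliseconds.
#' @export
drawingDuration <- function(x) {
  stopifnot(is(x, "ClockDrawing"))
  last <- x@strokes[[length(x@strokes)]]
  last$t[nrow(last)] - x@strokes[[1L]]$t[1L]
}

#' Flatten a drawing to one sample table
#'
#' @param x a [ClockDrawing-class].
#' @return data.frame with columns `participant_id`, `condition`,
#'   `stroke_id`, `component`, `t_ms`, `x_mm`, `y_mm`, one row per sample,
#'   samples contiguous per stroke (the stroke CSV dialect).
#' @export
drawingToTable <- function(x) {
  stopifnot(is(x, "ClockDrawing"))
  n <- vapply(x@strokes, nrow, integer(1))
  all <- do.call(rbind, x@strokes)
  data.frame(
    participant_id = x@participantID,
    condition = x@condition,
    stroke_id = rep(seq_along(x@strokes), n),
    component = rep(x@components, n),
    t_ms = all$t, x_mm = all$x, y_mm = all$y,
    stringsAsFactors = FALSE
  )
}
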
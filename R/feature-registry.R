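# Graphomotor / temporal feature definitions.
#
# Each registry entry is a function(drawing) -> numeric(1), NA_real_ when the
# feature is undefined for that drawing (e.g. no hand strokes). Features span
# four families: drawing efficiency (time partition, latencies), simple motor
# operation (speed, ink length), information-processing speed (think/ink
# ratio), and spatial reasoning (clock-face geometry, number placement,
# hand angles).

.strokeStarts <- function(d) vapply(d@strokes, function(s) s$t[1L], numeric(1))
.strokeEnds <- function(d) vapply(d@strokes, function(s) s$t[nrow(s)], numeric(1))

.interStrokeGaps <- function(d) {
  if (nStrokes(d) < 2L) return(numeric(0))
  .strokeStarts(d)[-1L] - .strokeEnds(d)[-nStrokes(d)]
}

.polylineLength <- function(s) {
  if (nrow(s) < 2L) return(0)
  sum(sqrt(diff(s$x)^2 + diff(s$y)^2))
}

.inkTime <- function(d) {
  sum(.strokeEnds(d) - .strokeStarts(d))
}

.clockfaceStroke <- function(d) {
  i <- which(d@components == "clockface")
  if (length(i) == 0L) return(NULL)
  i[1L]
}

# fitted clock-face circle, or NULL when absent/degenerate
.clockfaceFit <- function(d) {
  i <- .clockfaceStroke(d)
  if (is.null(i)) return(NULL)
  s <- d@strokes[[i]]
  tryCatch(fitCircle(cbind(s$x, s$y)), error = function(e) NULL)
}

.boundingBoxCenter <- function(d) {
  all <- do.call(rbind, d@strokes)
  c(x = (min(all$x) + max(all$x)) / 2, y = (min(all$y) + max(all$y)) / 2)
}

# clock angle of a point: degrees clockwise from 12 o'clock, page y-down
.clockAngle <- function(dx, dy) {
  (atan2(dx, -dy) * 180 / pi) %% 360
}

.circDist <- function(a, b) {
  d <- abs(a - b) %% 360
  pmin(d, 360 - d)
}

# Target hand angles for the canonical "ten past eleven" command time:
# minute hand points at the 2 o'clock position (60 deg clockwise from 12),
# hour hand sits a sixth of the way from 11 toward 12 (335 deg).
.HAND_TARGETS_DEG <- c(minute = 60, hour = 335)

#' Default graphomotor feature registry
#'
#' Named list of feature functions, each mapping a [ClockDrawing-class] to a
#' single number (or `NA` when undefined for that drawing). The default set
#' covers completion-time partition (total, ink, think, percent-think),
#' stroke counts and latencies (including the pre-first-hand and
#' post-clock-face pauses), pen kinematics (ink length, mean and peak
#' speed), and clock-face / number / hand geometry from the least-squares
#' circle fit. The registry is an open extension point: add or replace
#' entries to extend the catalog.
#'
#' Units: times in milliseconds, lengths in millimeters, speeds in mm/s,
#' areas in mm^2, angles in degrees, percentages on 0-100.
#'
#' @return named list of functions `function(drawing) -> numeric(1)`.
#' @seealso [extractFeatures()], [buildFeatureMatrix()]
#' @export
defaultFeatureRegistry <- function() {
  list(
    total_completion_time = function(d) drawingDuration(d),
    ink_time = function(d) .inkTime(d),
    think_time = function(d) drawingDuration(d) - .inkTime(d),
    percent_think = function(d) {
      tot <- drawingDuration(d)
      if (tot <= 0) return(NA_real_)
      100 * (tot - .inkTime(d)) / tot
    },
    stroke_count = function(d) nStrokes(d),
    mean_stroke_duration = function(d) .inkTime(d) / nStrokes(d),
    total_ink_length = function(d) {
      sum(vapply(d@strokes, .polylineLength, numeric(1)))
    },
    mean_pen_speed = function(d) {
      ink <- .inkTime(d)
      if (ink <= 0) return(NA_real_)
      len <- sum(vapply(d@strokes, .polylineLength, numeric(1)))
      1000 * len / ink
    },
    peak_pen_speed = function(d) {
      v <- unlist(lapply(d@strokes, function(s) {
        if (nrow(s) < 2L) return(numeric(0))
        1000 * sqrt(diff(s$x)^2 + diff(s$y)^2) / diff(s$t)
      }), use.names = FALSE)
      if (length(v) == 0L) NA_real_ else max(v)
    },
    mean_inter_stroke_latency = function(d) {
      g <- .interStrokeGaps(d)
      if (length(g) == 0L) NA_real_ else mean(g)
    },
    max_inter_stroke_latency = function(d) {
      g <- .interStrokeGaps(d)
      if (length(g) == 0L) NA_real_ else max(g)
    },
    pre_first_hand_latency = function(d) {
      hands <- which(d@components == "hand")
      if (length(hands) == 0L) return(NA_real_)
      h <- hands[1L]
      prev <- which(d@components != "hand" & seq_len(nStrokes(d)) < h)
      if (length(prev) == 0L) return(NA_real_)
      .strokeStarts(d)[h] - .strokeEnds(d)[max(prev)]
    },
    post_clock_face_latency = function(d) {
      i <- .clockfaceStroke(d)
      if (is.null(i) || i >= nStrokes(d)) return(NA_real_)
      .strokeStarts(d)[i + 1L] - .strokeEnds(d)[i]
    },
    clock_face_area = function(d) {
      f <- .clockfaceFit(d)
      if (is.null(f)) NA_real_ else pi * f$radius^2
    },
    clock_face_circularity = function(d) {
      f <- .clockfaceFit(d)
      if (is.null(f)) NA_real_ else f$rms_residual / f$radius
    },
    clock_face_center_offset = function(d) {
      f <- .clockfaceFit(d)
      if (is.null(f)) return(NA_real_)
      bb <- .boundingBoxCenter(d)
      sqrt(sum((f$center - bb)^2))
    },
    number_count = function(d) sum(d@components == "number"),
    mean_number_radial_error = function(d) {
      f <- .clockfaceFit(d)
      nums <- which(d@components == "number")
      if (is.null(f) || length(nums) == 0L) return(NA_real_)
      err <- vapply(nums, function(i) {
        s <- d@strokes[[i]]
        cx <- mean(s$x); cy <- mean(s$y)
        abs(sqrt((cx - f$center[1L])^2 + (cy - f$center[2L])^2) - f$radius)
      }, numeric(1))
      mean(err)
    },
    hand_count = function(d) sum(d@components == "hand"),
    hand_angle_error = function(d) {
      hands <- which(d@components == "hand")
      if (length(hands) == 0L) return(NA_real_)
      f <- .clockfaceFit(d)
      ctr <- if (is.null(f)) .boundingBoxCenter(d) else f$center
      ang <- vapply(hands, function(i) {
        s <- d@strokes[[i]]
        dd <- sqrt((s$x - ctr[1L])^2 + (s$y - ctr[2L])^2)
        tip <- which.max(dd)
        .clockAngle(s$x[tip] - ctr[1L], s$y[tip] - ctr[2L])
      }, numeric(1))
      if (length(ang) >= 2L) {
        # assign the two most extreme hands to the two targets, minimising
        # the summed circular deviation over both assignments
        a <- ang[1:2]
        d1 <- .circDist(a[1L], .HAND_TARGETS_DEG["minute"]) +
              .circDist(a[2L], .HAND_TARGETS_DEG["hour"])
        d2 <- .circDist(a[1L], .HAND_TARGETS_DEG["hour"]) +
              .circDist(a[2L], .HAND_TARGETS_DEG["minute"])
        min(d1, d2) / 2
      } else {
        min(.circDist(ang, .HAND_TARGETS_DEG))
      }
    },
    drawing_bounding_box_area = function(d) {
      all <- do.call(rbind, d@strokes)
      (max(all$x) - min(all$x)) * (max(all$y) - min(all$y))
    }
  )
}

#' Extract registered features from one drawing
#'
#' Evaluates every registry feature on the drawing. A feature that is
#' undefined for a drawing (no hand strokes, degenerate clock face, ...)
#' is recorded as `NA`, never silently zero.
#'
#' @param drawing a valid [ClockDrawing-class].
#' @param registry named list of feature functions; default
#'   [defaultFeatureRegistry()].
#' @return named numeric vector, one entry per registry feature, in
#'   registry order.
#' @export
extractFeatures <- function(drawing, registry = defaultFeatureRegistry()) {
  stopifnot(is(drawing, "ClockDrawing"))
  if (length(registry) == 0L) stop("feature registry must be non-empty")
  if (is.null(names(registry)) || any(!nzchar(names(registry)))) {
    stop("feature registry entries must be named")
  }
  validObject(drawing)
  vapply(registry, function(f) {
    v <- f(drawing)
    if (length(v) != 1L || !is.numeric(v)) NA_real_ else as.numeric(v)
  }, numeric(1))
}
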
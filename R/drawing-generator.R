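# Parametric clock-drawing synthesis.
#
# A drawing is built stroke by stroke: the clock-face circle, twelve small
# two-segment number glyphs at canonical dial positions, then the two hands
# set to "ten past eleven". The latent cognition score g modulates the
# kinematics: lower g gives a smaller clock face, a slower pen, longer
# inter-stroke pauses (more think time) and more positional tremor. All
# randomness derives from one per-drawing seed.

# sample a polyline at constant pen speed; returns data.frame(t, x, y)
# starting at time t0, one sample per dt ms
.samplePath <- function(verts, speed, hz, t0) {
  dt <- 1000 / hz
  seg <- sqrt(diff(verts[, 1L])^2 + diff(verts[, 2L])^2)
  L <- sum(seg)
  stepLen <- speed * dt / 1000          # mm per sample
  nSteps <- max(1L, ceiling(L / stepLen))
  s <- seq(0, L, length.out = nSteps + 1L)
  cum <- c(0, cumsum(seg))
  x <- approx(cum, verts[, 1L], xout = s, ties = "ordered")$y
  y <- approx(cum, verts[, 2L], xout = s, ties = "ordered")$y
  data.frame(t = t0 + dt * seq(0, nSteps), x = x, y = y)
}

#' Generate one parametric clock drawing
#'
#' Emits a synthetic clock drawing whose kinematics depend on latent
#' cognition `g`: the clock-face radius is `baseRadius + radiusPerG * g`
#' (smaller at low cognition), pen speed is `baseSpeed * exp(speedPerG*g)`
#' (slower at low cognition), inter-stroke pauses are
#' `basePause * exp(-pausePerG * g)` (more think time at low cognition) and
#' positional tremor SD is `tremorBase * exp(-tremorPerG * g)`. On top of
#' these population links, each drawing carries idiosyncratic within-person
#' variability — log-normal multipliers on speed and pause
#' (`kinematicNoiseSD`) and a normal perturbation of the radius
#' (`radiusNoiseSD`) — so a single drawing is an imperfect measurement of
#' latent cognition, as single-task measures are. Strokes are
#' emitted in canonical order — clock face, numbers 12, 1, ..., 11, minute
#' hand, hour hand ("ten past eleven") — at the configured sampling rate,
#' each labeled with its ground-truth component. The copy condition uses a
#' `copySpeedup` factor on speed and pauses (copying is less demanding than
#' drawing to command). Deterministic given `(g, condition, config, seed)`.
#'
#' @param id participant identifier.
#' @param g latent cognition score (standard-normal scale).
#' @param condition `"command"` or `"copy"`.
#' @param config a [cohortConfig()] (its `drawing` block is used).
#' @param seed integer seed for this drawing's jitter.
#' @return a validated [ClockDrawing-class].
#' @examples
#' cfg <- cohortConfig(nParticipants = 10, seed = 1)
#' d <- generateDrawing("P0001", g = 0, "command", cfg, seed = 42)
#' d
#' @export
generateDrawing <- function(id, g, condition = c("command", "copy"),
                            config = cohortConfig(), seed = 1L) {
  condition <- match.arg(condition)
  stopifnot(inherits(config, "CohortConfig"))
  dw <- config$drawing
  set.seed(seed)
  # idiosyncratic within-person variability: a single drawing is a noisy
  # realization of the person's kinematics, so features correlate with
  # latent cognition imperfectly, as single-task measures do
  epsSpeed <- rnorm(1, 0, dw$kinematicNoiseSD)
  epsPause <- rnorm(1, 0, dw$kinematicNoiseSD)
  epsRadius <- rnorm(1, 0, dw$radiusNoiseSD)
  r <- dw$baseRadius + dw$radiusPerG * g + epsRadius
  if (!is.finite(r) || r < 2) r <- 2          # clamp to a drawable dial
  speed <- dw$baseSpeed * exp(dw$speedPerG * g + epsSpeed)
  pause <- dw$basePause * exp(-dw$pausePerG * g + epsPause)
  tremor <- dw$tremorBase * exp(-dw$tremorPerG * g)
  if (condition == "copy") {
    speed <- speed * dw$copySpeedup
    pause <- pause / dw$copySpeedup
  }
  if (speed <= 0) stop("non-positive pen speed")
  hz <- dw$samplingHz
  cx <- dw$center[1L]; cy <- dw$center[2L]

  strokes <- list(); comps <- character(0)
  t0 <- 0

  addStroke <- function(verts, comp) {
    s <- .samplePath(verts, speed, hz, t0)
    if (tremor > 0) {
      s$x <- s$x + rnorm(nrow(s), 0, tremor)
      s$y <- s$y + rnorm(nrow(s), 0, tremor)
    }
    strokes[[length(strokes) + 1L]] <<- s
    comps <<- c(comps, comp)
    t0 <<- s$t[nrow(s)] + pause
  }

  # clock face: full circle, start at 12, clockwise (page y-down)
  # path vertices well above the sample count so discretization error
  # stays far below the pen's spatial resolution
  nv <- max(72L, ceiling(2 * pi * r / speed * hz * 4))
  th <- seq(-pi / 2, 3 * pi / 2, length.out = nv + 1L)
  addStroke(cbind(cx + r * cos(th), cy + r * sin(th)), "clockface")

  # numbers 12, 1, ..., 11 at 0.8 r: short V-shaped two-segment glyphs
  glyph <- 0.12 * r
  for (k in c(12, 1:11)) {
    ang <- (k %% 12) * pi / 6 - pi / 2   # clock angle, y-down page coords
    px <- cx + 0.8 * r * cos(ang)
    py <- cy + 0.8 * r * sin(ang)
    verts <- rbind(c(px - glyph / 2, py + glyph / 2),
                   c(px, py - glyph / 2),
                   c(px + glyph / 2, py + glyph / 2))
    addStroke(verts, "number")
  }

  # hands for "ten past eleven": minute at the 2 o'clock position,
  # hour between 11 and 12; drawn center -> tip
  tip <- function(angDeg, len) {
    a <- angDeg * pi / 180
    c(cx + len * sin(a), cy - len * cos(a))   # 0 deg = up (12 o'clock)
  }
  addStroke(rbind(c(cx, cy), tip(.HAND_TARGETS_DEG[["minute"]], 0.75 * r)), "hand")
  addStroke(rbind(c(cx, cy), tip(.HAND_TARGETS_DEG[["hour"]], 0.50 * r)), "hand")

  ClockDrawing(id, condition, strokes, comps)
}

#' Simulate a full study: cohort plus drawings
#'
#' Convenience wrapper: generates the cohort via [generateCohort()] and one
#' drawing per participant per requested condition, with per-drawing seeds
#' derived deterministically from the master seed.
#'
#' @param config a [cohortConfig()].
#' @param conditions which conditions to draw (default both).
#' @return list with `cohort`, `g`, and `drawings` (list of
#'   [ClockDrawing-class]).
#' @export
simulateStudy <- function(config, conditions = c("command", "copy")) {
  stopifnot(inherits(config, "CohortConfig"))
  conditions <- match.arg(conditions, several.ok = TRUE)
  cc <- generateCohort(config)
  n <- config$nParticipants
  drawings <- vector("list", n * length(conditions))
  k <- 0L
  for (ci in seq_along(conditions)) {
    for (i in seq_len(n)) {
      k <- k + 1L
      drawings[[k]] <- generateDrawing(
        cc$cohort$participant_id[i], cc$g[i], conditions[ci], config,
        seed = .subSeed(config$seed, 1000L + i * 2L + ci))
    }
  }
  list(cohort = cc$cohort, g = cc$g, drawings = drawings)
}
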
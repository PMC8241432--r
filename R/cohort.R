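#' The 18-test neuropsychological battery
#'
#' Catalog of the standard multi-domain battery the association scan runs
#' against: Wechsler Memory Scale Logical Memory, Visual Reproduction and
#' Paired Associate Learning subtests (immediate, delayed, recognition),
#' WAIS Digit Span (forward, backward) and Similarities, Boston Naming Test
#' (30-item), Trail Making Tests A and B, Hooper Visual Organization Test,
#' and Verbal Fluency (letter and animal). Population means and SDs are
#' typical of a community-based cohort of dementia-free older adults and
#' parameterise the synthetic generator. The two Trail Making tests are
#' timed in seconds, so higher scores mean worse performance; all other
#' tests score higher = better.
#'
#' @return data.frame with columns `key` (column-safe name), `label`
#'   (display name), `mean`, `sd`, `timed` (TRUE when higher = worse),
#'   `integer_scale` (TRUE when scores are reported on an integer scale).
#' @export
npTestBattery <- function() {
  tab <- rbind(
    c("logical_memory_immediate_recall", "Logical Memory—Immediate Recall", 12, 3, 0, 1),
    c("logical_memory_delayed_recall",   "Logical Memory—Delayed Recall",   12, 4, 0, 1),
    c("logical_memory_recognition",      "Logical Memory—Recognition",      10, 1, 0, 1),
    c("visual_reproduction_immediate_recall", "Visual Reproduction—Immediate Recall", 8, 3, 0, 1),
    c("visual_reproduction_delayed_recall",   "Visual Reproduction—Delayed Recall",   8, 3, 0, 1),
    c("visual_reproduction_recognition",      "Visual Reproduction—Recognition",      3, 1, 0, 1),
    c("paired_associate_immediate_recall", "Paired Associate Learning—Immediate Recall", 15, 4, 0, 1),
    c("paired_associate_delayed_recall",   "Paired Associate Learning—Delayed Recall",    9, 1, 0, 1),
    c("paired_associate_recognition",      "Paired Associate Learning—Recognition",      10, 2, 0, 1),
    c("digit_span_forward",  "Digit Span—Forward",  7, 1, 0, 1),
    c("digit_span_backward", "Digit Span—Backward", 5, 1, 0, 1),
    c("similarities", "Similarities", 17, 3, 0, 1),
    c("boston_naming_30", "Boston Naming Test—30-item version", 26, 7, 0, 1),
    c("trail_making_a", "Trail Making Test A (seconds)", 32, 17, 1, 0),
    c("trail_making_b", "Trail Making Test B (seconds)", 88, 73, 1, 0),
    c("hooper_visual_organization", "Hooper Visual Organization Test", 25, 3, 0, 1),
    c("verbal_fluency", "Verbal Fluency", 41, 12, 0, 1),
    c("verbal_fluency_animal", "Verbal Fluency—Animal", 19, 6, 0, 1)
  )
  data.frame(key = tab[, 1L], label = tab[, 2L],
             mean = as.numeric(tab[, 3L]), sd = as.numeric(tab[, 4L]),
             timed = as.logical(as.integer(tab[, 5L])),
             integer_scale = as.logical(as.integer(tab[, 6L])),
             stringsAsFactors = FALSE)
}

.EDUCATION_LEVELS <- c("no_high_school", "high_school", "some_college",
                       "college_plus")

#' Synthetic cohort configuration
#'
#' Defines the study conditions the generator emulates: a community-based
#' cohort of dementia-free adults (age mean 62, SD 13; 51.6% women;
#' education mix 11.1/18.7/26.7/43.4% from no-high-school to college+;
#' MCI prevalence 36/2062) in which one standard-normal latent cognition
#' trait g drives both neuropsychological scores and drawing kinematics.
#' The latent trait is `g = -ageLoading * standardize(age) + e` with
#' `e ~ N(0, 1 - ageLoading^2)`, so older participants tend to score lower;
#' MCI labels are assigned to the lowest-g tail at the configured
#' prevalence, which reproduces the expected clinical picture (older, worse
#' scores) by construction.
#'
#' @param nParticipants cohort size.
#' @param seed integer master seed; every random draw derives from it.
#' @param ageMean,ageSD age distribution in years (truncated to
#'   `ageRange`).
#' @param ageRange length-2 admissible age range.
#' @param propFemale proportion of women.
#' @param educationProps length-4 proportions over the education levels
#'   (no high school, high school, some college, college and higher); must
#'   sum to 1.
#' @param mciPrevalence MCI prevalence in (0, 1).
#' @param ageLoading loading of standardized age on latent cognition, in
#'   [0, 1).
#' @param npLoadings named numeric vector of per-test loadings of g (keys
#'   from [npTestBattery()]); a single unnamed value is recycled. 0 gives a
#'   null battery.
#' @param npMissingness per-test missing-completely-at-random fraction.
#' @param drawing list of drawing-kinematics parameters, see
#'   [generateDrawing()]: `samplingHz`, `center`, `baseRadius`,
#'   `radiusPerG`, `baseSpeed`, `speedPerG`, `basePause`, `pausePerG`,
#'   `tremorBase`, `tremorPerG`, `copySpeedup`, `kinematicNoiseSD`,
#'   `radiusNoiseSD`.
#' @return validated list of class `CohortConfig`.
#' @export
cohortConfig <- function(nParticipants = 500,
                         seed = 1L,
                         ageMean = 62, ageSD = 13,
                         ageRange = c(30, 95),
                         propFemale = 0.516,
                         educationProps = c(0.111, 0.187, 0.267, 0.434),
                         mciPrevalence = 36 / 2062,
                         ageLoading = 0.5,
                         npLoadings = 0.5,
                         npMissingness = 0.01,
                         drawing = list()) {
  battery <- npTestBattery()
  if (length(npLoadings) == 1L && is.null(names(npLoadings))) {
    npLoadings <- setNames(rep(npLoadings, nrow(battery)), battery$key)
  }
  defaultsDrawing <- list(
    samplingHz = 80,
    center = c(100, 100),   # mm, page coordinates
    baseRadius = 30,        # mm at g = 0
    radiusPerG = 2,         # mm per unit g (smaller clock face at low g)
    baseSpeed = 40,         # mm/s pen speed at g = 0
    speedPerG = 0.15,       # speed = baseSpeed * exp(speedPerG * g)
    basePause = 600,        # ms inter-stroke pause at g = 0
    pausePerG = 0.3,        # pause = basePause * exp(-pausePerG * g)
    tremorBase = 0.25,      # mm positional jitter SD at g = 0
    tremorPerG = 0.2,       # tremor = tremorBase * exp(-tremorPerG * g)
    copySpeedup = 1.1,      # copy condition: faster pen, shorter pauses
    kinematicNoiseSD = 0.25, # idiosyncratic log-scale SD on speed and pause
    radiusNoiseSD = 1.5     # mm idiosyncratic SD on the clock-face radius
  )
  drawing <- utils::modifyList(defaultsDrawing, drawing)
  cfg <- list(nParticipants = as.integer(nParticipants), seed = as.integer(seed),
              ageMean = ageMean, ageSD = ageSD, ageRange = ageRange,
              propFemale = propFemale, educationProps = educationProps,
              mciPrevalence = mciPrevalence, ageLoading = ageLoading,
              npLoadings = npLoadings, npMissingness = npMissingness,
              drawing = drawing, battery = battery)
  bad <- character(0)
  if (cfg$nParticipants < 2L) bad <- c(bad, "nParticipants (< 2)")
  if (cfg$ageSD <= 0) bad <- c(bad, "ageSD (must be > 0)")
  if (cfg$propFemale < 0 || cfg$propFemale > 1) bad <- c(bad, "propFemale")
  # printed one-decimal percentages may sum to 99.9/100.1; renormalize
  if (length(cfg$educationProps) != 4L ||
      abs(sum(cfg$educationProps) - 1) > 0.02 || any(cfg$educationProps < 0)) {
    bad <- c(bad, "educationProps (4 non-negative values summing to 1)")
  } else {
    cfg$educationProps <- cfg$educationProps / sum(cfg$educationProps)
  }
  if (cfg$mciPrevalence <= 0 || cfg$mciPrevalence >= 1) {
    bad <- c(bad, "mciPrevalence (must be in (0,1))")
  }
  if (cfg$ageLoading < 0 || cfg$ageLoading >= 1) bad <- c(bad, "ageLoading")
  if (!all(battery$key %in% names(cfg$npLoadings))) {
    bad <- c(bad, "npLoadings (must cover every battery test)")
  }
  if (cfg$npMissingness < 0 || cfg$npMissingness >= 1) bad <- c(bad, "npMissingness")
  with(cfg$drawing, {
    if (baseRadius <= 0) bad <<- c(bad, "drawing$baseRadius (must be > 0)")
    if (baseSpeed <= 0) bad <<- c(bad, "drawing$baseSpeed (must be > 0)")
    if (samplingHz <= 0) bad <<- c(bad, "drawing$samplingHz (must be > 0)")
    if (basePause < 0) bad <<- c(bad, "drawing$basePause (must be >= 0)")
    if (tremorBase < 0) bad <<- c(bad, "drawing$tremorBase (must be >= 0)")
    if (kinematicNoiseSD < 0) bad <<- c(bad, "drawing$kinematicNoiseSD (must be >= 0)")
    if (radiusNoiseSD < 0) bad <<- c(bad, "drawing$radiusNoiseSD (must be >= 0)")
  })
  if (length(bad)) {
    stop("invalid cohort configuration: ", paste(bad, collapse = "; "))
  }
  structure(cfg, class = "CohortConfig")
}

#' @export
print.CohortConfig <- function(x, ...) {
  cat(sprintf("CohortConfig: n = %d, seed = %d, MCI prevalence = %.4f\n",
              x$nParticipants, x$seed, x$mciPrevalence))
  cat(sprintf("  age ~ N(%g, %g^2), %.1f%% women, age loading %.2f\n",
              x$ageMean, x$ageSD, 100 * x$propFemale, x$ageLoading))
  invisible(x)
}

# derived sub-seeds, kept below 2^31
.subSeed <- function(seed, offset) {
  as.integer((as.double(seed) * 7919 + offset * 104729) %% 2147483647)
}

#' Generate a synthetic cohort
#'
#' Draws covariates (age, sex, education), the latent cognition trait g,
#' MCI labels (lowest-g tail at the configured prevalence), and the
#' 18-test neuropsychological battery via [generateNPScores()]. Fully
#' reproducible given the config seed.
#'
#' @param config a [cohortConfig()] object.
#' @return list with `cohort` (data.frame: `participant_id`, `age`, `sex`,
#'   `education`, `mci`, then one column per battery test key) and `g`
#'   (named numeric vector of latent cognition scores).
#' @examples
#' cc <- generateCohort(cohortConfig(nParticipants = 100, seed = 7))
#' head(cc$cohort[, 1:6])
#' @export
generateCohort <- function(config) {
  stopifnot(inherits(config, "CohortConfig"))
  n <- config$nParticipants
  set.seed(.subSeed(config$seed, 1L))
  age <- rnorm(n, config$ageMean, config$ageSD)
  age <- pmin(pmax(age, config$ageRange[1L]), config$ageRange[2L])
  sex <- ifelse(runif(n) < config$propFemale, "female", "male")
  education <- sample(.EDUCATION_LEVELS, n, replace = TRUE,
                      prob = config$educationProps)
  a <- config$ageLoading
  e <- rnorm(n, 0, sqrt(1 - a^2))
  g <- -a * (age - config$ageMean) / config$ageSD + e
  nMCI <- max(1L, round(n * config$mciPrevalence))
  mci <- integer(n)
  mci[order(g)[seq_len(nMCI)]] <- 1L
  ids <- sprintf("P%04d", seq_len(n))
  cohort <- data.frame(participant_id = ids, age = age, sex = sex,
                       education = education, mci = mci,
                       stringsAsFactors = FALSE)
  np <- generateNPScores(g, config)
  cohort <- cbind(cohort, np)
  rownames(cohort) <- ids
  list(cohort = cohort, g = setNames(g, ids))
}

#' Generate neuropsychological scores from latent cognition
#'
#' Each test k is `mean_k + sd_k * z` with `z = load_k * g + e`,
#' `e ~ N(0, 1 - load_k^2)`, so the marginal SD matches the battery SD
#' when |load| <= 1. Timed tests (Trail Making) use a negative loading on
#' g, so lower cognition means longer times, and are kept as continuous
#' positive seconds; integer-scale tests are rounded and clipped to
#' [0, mean + 4 sd]. A missing-completely-at-random fraction is applied
#' per test.
#'
#' @param g numeric vector of latent cognition scores.
#' @param config a [cohortConfig()].
#' @return data.frame with one column per battery test key.
#' @export
generateNPScores <- function(g, config) {
  stopifnot(inherits(config, "CohortConfig"))
  battery <- config$battery
  n <- length(g)
  set.seed(.subSeed(config$seed, 2L))
  out <- vector("list", nrow(battery))
  names(out) <- battery$key
  for (i in seq_len(nrow(battery))) {
    key <- battery$key[i]
    load <- unname(config$npLoadings[key])
    if (is.na(load)) stop("unknown test name in npLoadings: ", key)
    sign <- if (battery$timed[i]) -1 else 1
    z <- sign * load * g + rnorm(n, 0, sqrt(max(0, 1 - load^2)))
    score <- battery$mean[i] + battery$sd[i] * z
    if (battery$timed[i]) {
      score <- pmax(score, 5)  # floor: no task completes in < 5 s
    } else if (battery$integer_scale[i]) {
      score <- round(pmin(pmax(score, 0), battery$mean[i] + 4 * battery$sd[i]))
    }
    if (config$npMissingness > 0) {
      score[runif(n) < config$npMissingness] <- NA_real_
    }
    out[[i]] <- score
  }
  as.data.frame(out)
}
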
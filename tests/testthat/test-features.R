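test_that("circle fit is exact on noiseless circles and circumcircles", {
  th <- seq(0, 2 * pi, length.out = 41)[-41]
  f <- fitCircle(cbind(10 + 30 * cos(th), 20 + 30 * sin(th)))
  expect_equal(unname(f$center), c(10, 20), tolerance = 1e-6)
  expect_equal(f$radius, 30, tolerance = 1e-6)
  expect_lt(f$rms_residual, 1e-8)

  # three-point case equals the perpendicular-bisector circumcircle
  f3 <- fitCircle(rbind(c(0, 0), c(2, 0), c(1, 1)))
  expect_equal(unname(f3$center), c(1, 0), tolerance = 1e-10)
  expect_equal(f3$radius, 1, tolerance = 1e-10)
  set.seed(8)
  for (i in 1:20) {
    pts <- matrix(rnorm(6, sd = 5), 3, 2)
    orc <- tryCatch(circumcircleOracle(pts[1, ], pts[2, ], pts[3, ]),
                    error = function(e) NULL)
    if (is.null(orc) || !all(is.finite(orc$center))) next
    fit <- fitCircle(pts)
    expect_equal(unname(fit$center), unname(orc$center), tolerance = 1e-8)
    expect_equal(fit$radius, orc$radius, tolerance = 1e-8)
  }
})

test_that("circle fit rejects degenerate geometry", {
  expect_error(fitCircle(rbind(c(0, 0), c(1, 1))), "at least 3")
  expect_error(fitCircle(cbind(1:10, 2 * (1:10) + 3)), "collinear")
})

test_that("think + ink partitions total completion time exactly", {
  cfg <- cohortConfig(nParticipants = 2, seed = 6)
  for (g in c(-2, 0, 2)) {
    d <- generateDrawing("p", g, "command", cfg, seed = 21)
    fv <- extractFeatures(d)
    expect_equal(fv[["think_time"]] + fv[["ink_time"]],
                 fv[["total_completion_time"]])
    expect_true(all(fv[c("total_completion_time", "ink_time", "think_time",
                         "mean_inter_stroke_latency")] >= 0))
    expect_gt(fv[["clock_face_area"]], 0)
  }
})

test_that("percent think is the pen-up share of total time", {
  # two strokes: 30 s of ink in a 60 s drawing
  s1 <- data.frame(t = seq(0, 15000, by = 100), x = seq(0, 150), y = 0)
  s2 <- data.frame(t = seq(45000, 60000, by = 100), x = seq(0, 150), y = 10)
  d <- ClockDrawing("p", "command", list(s1, s2), c("clockface", "other"))
  fv <- extractFeatures(d)
  expect_equal(fv[["total_completion_time"]], 60000)
  expect_equal(fv[["ink_time"]], 30000)
  expect_equal(fv[["percent_think"]], 50)
})

test_that("noiseless unit-kinematics drawings have zero think time and exact area", {
  cfg <- cohortConfig(nParticipants = 2, seed = 1, drawing = list(
    tremorBase = 0, basePause = 0, baseRadius = 25, radiusPerG = 0,
    kinematicNoiseSD = 0, radiusNoiseSD = 0))
  d <- generateDrawing("p", 0, "command", cfg, seed = 33)
  fv <- extractFeatures(d)
  expect_equal(fv[["think_time"]], 0)
  expect_equal(fv[["percent_think"]], 0)
  expect_equal(fv[["clock_face_area"]], pi * 625, tolerance = 0.01)
  expect_lt(fv[["clock_face_circularity"]], 1e-5)   # discretization floor
})

test_that("features are invariant to rigid translation of the drawing", {
  cfg <- cohortConfig(nParticipants = 2, seed = 2)
  d <- generateDrawing("p", -0.5, "command", cfg, seed = 13)
  shifted <- ClockDrawing(
    participantID(d), drawingCondition(d),
    lapply(strokes(d), function(s) { s$x <- s$x + 37; s$y <- s$y - 12; s }),
    strokeComponents(d))
  f1 <- extractFeatures(d)
  f2 <- extractFeatures(shifted)
  expect_equal(f1, f2, tolerance = 1e-9)
})

test_that("circularity residual shrinks as tremor vanishes", {
  mkCfg <- function(tr) cohortConfig(nParticipants = 2, seed = 1,
                                     drawing = list(tremorBase = tr,
                                                    tremorPerG = 0))
  noisy <- extractFeatures(generateDrawing("p", 0, "command", mkCfg(0.8), 55))
  quiet <- extractFeatures(generateDrawing("p", 0, "command", mkCfg(0.05), 55))
  expect_lt(quiet[["clock_face_circularity"]], noisy[["clock_face_circularity"]])
})

test_that("undefined features are recorded missing, never zero", {
  # a drawing with no hand strokes and no clock face
  d <- makeSimpleDrawing(nStrokes = 3)
  fv <- extractFeatures(d)
  expect_true(is.na(fv[["hand_angle_error"]]))
  expect_true(is.na(fv[["pre_first_hand_latency"]]))
  expect_true(is.na(fv[["clock_face_area"]]))
  expect_true(is.na(fv[["post_clock_face_latency"]]))
  expect_equal(fv[["hand_count"]], 0)       # counts are defined, and zero
  expect_equal(fv[["stroke_count"]], 3)
})

test_that("hand angle error is zero for canonical hands and positive otherwise", {
  cfg <- cohortConfig(nParticipants = 2, seed = 1,
                      drawing = list(tremorBase = 0))
  d <- generateDrawing("p", 0, "command", cfg, seed = 3)
  fv <- extractFeatures(d)
  expect_lt(fv[["hand_angle_error"]], 1)    # generator draws the target time
  expect_equal(fv[["hand_count"]], 2)
  expect_equal(fv[["number_count"]], 12)
})

test_that("feature matrices align participants, preserve registry order, and propagate NA", {
  cfg <- cohortConfig(nParticipants = 3, seed = 10)
  dA <- generateDrawing("A", 0.5, "command", cfg, seed = 1)
  dB <- generateDrawing("B", -0.5, "command", cfg, seed = 2)
  dC <- makeSimpleDrawing("C")                 # no hands
  fs <- buildFeatureMatrix(list(dA, dB, dC))
  expect_s4_class(fs, "ClockFeatureSet")
  expect_equal(ncol(fs), 3L)
  expect_equal(featureNames(fs),
               paste0(names(defaultFeatureRegistry()), "_command"))
  raw <- rawFeatures(fs)
  expect_true(is.na(raw["hand_angle_error_command", "C"]))
  expect_false(anyNA(raw["hand_angle_error_command", c("A", "B")]))

  expect_error(buildFeatureMatrix(list(dA, dA)), "duplicate")
  # command and copy become separate feature columns
  dAc <- generateDrawing("A", 0.5, "copy", cfg, seed = 1)
  fs2 <- buildFeatureMatrix(list(dA, dAc))
  expect_equal(nrow(fs2), 2L * length(defaultFeatureRegistry()))
  expect_true(all(grepl("_(command|copy)$", featureNames(fs2))))
})

test_that("normalization gives each feature row the rank-INT property", {
  cfg <- cohortConfig(nParticipants = 20, seed = 12)
  sim <- simulateStudy(cfg, conditions = "command")
  fs <- buildFeatureMatrix(sim$drawings)
  fs <- suppressWarnings(normalizeFeatures(fs))
  V <- normalizedFeatures(fs)
  raw <- rawFeatures(fs)
  for (i in seq_len(nrow(V))) {
    v <- V[i, ]
    if (all(is.na(v))) next                      # constant feature, warned
    ok <- !is.na(v)
    expect_equal(unname(v[ok]),
                 unname(rankInverseNormal(raw[i, ])[ok]), tolerance = 1e-12)
  }
  # constant features (the count features have no variance in clean
  # drawings) are warned about, one warning each
  w <- capture_warnings(normalizeFeatures(fs))
  expect_true(any(grepl("not normalizable", w)))
})
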
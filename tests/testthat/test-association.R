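test_that("a planted linear feature is found with the generating slope", {
  fs <- plantedFeatureSet(n = 200, p = 10, slope = 3, seed = 11)
  scan <- scanAssociations(fs, tests = "score")
  hit <- scan[scan$feature == "f1", ]
  expect_lt(hit$p_value, 1e-50)
  expect_equal(hit$beta, 3, tolerance = 0.05)
  sel <- selectSignificant(scan)
  expect_equal(sel$score$feature, "f1")
  expect_equal(attr(sel, "threshold"), 0.05 / 10)
})

test_that("scan results are invariant to feature order and complete-case per pair", {
  fs <- plantedFeatureSet(n = 120, p = 6, seed = 21)
  scan1 <- scanAssociations(fs, tests = "score")
  fsRev <- fs[rev(seq_len(nrow(fs))), ]
  scan2 <- scanAssociations(fsRev, tests = "score")
  m1 <- scan1[order(scan1$feature), c("feature", "beta", "se", "p_value")]
  m2 <- scan2[order(scan2$feature), c("feature", "beta", "se", "p_value")]
  rownames(m1) <- rownames(m2) <- NULL
  expect_equal(m1, m2, tolerance = 1e-12)

  # a missing feature value drops only that pair's rows
  raw <- rawFeatures(fs)
  raw["f2", 1:10] <- NA
  cd <- SummarizedExperiment::colData(fs)
  fs2 <- normalizeFeatures(ClockFeatureSet(raw, colData = cd))
  scan3 <- scanAssociations(fs2, tests = "score")
  expect_equal(scan3$n_used[scan3$feature == "f2"], 110L)
  expect_equal(scan3$n_used[scan3$feature == "f1"], 120L)
})

test_that("selection uses the feature-family Bonferroni threshold", {
  scan <- data.frame(feature = paste0("f", 1:105),
                     test = "t1",
                     beta = 1,
                     p_value = rep(1, 105))
  sel <- selectSignificant(scan)
  expect_equal(nrow(sel$t1), 0L)
  expect_equal(attr(sel, "threshold"), 0.05 / 105)
  scan$p_value[7] <- 4e-4                       # below 4.76e-4
  scan$p_value[8] <- 5e-4                       # above it
  sel2 <- selectSignificant(scan)
  expect_equal(sel2$t1$feature, "f7")
})

test_that("composite scores implement the weighted-mean formula", {
  V <- rbind(f1 = c(0.5, -1, 2), f2 = c(1, 1, -1))
  colnames(V) <- c("a", "b", "c")
  fs <- ClockFeatureSet(V, normalized = V)

  # m = 1, beta = 1: composite is the feature itself
  sel1 <- list(t = data.frame(feature = "f1", beta = 1))
  cs1 <- compositeScores(sel1, fs)
  expect_equal(unname(cs1$t$scores), c(0.5, -1, 2))

  # m = 2, beta = (1, -1), identical rows: cancellation to 0
  Vc <- rbind(f1 = c(1, 2, 3), f2 = c(1, 2, 3))
  colnames(Vc) <- c("a", "b", "c")
  fsc <- ClockFeatureSet(Vc, normalized = Vc)
  sel2 <- list(t = data.frame(feature = c("f1", "f2"), beta = c(1, -1)))
  cs2 <- compositeScores(sel2, fsc)
  expect_equal(unname(cs2$t$scores), c(0, 0, 0))

  # hand-computed 3-participant, m = 2 example
  sel3 <- list(t = data.frame(feature = c("f1", "f2"), beta = c(0.4, -1.2)))
  cs3 <- compositeScores(sel3, fs)
  expected <- (0.4 * V["f1", ] + (-1.2) * V["f2", ]) / 2
  expect_equal(cs3$t$scores, expected, tolerance = 1e-12)
  csSum <- compositeScores(sel3, fs, scale = "sum")
  expect_equal(csSum$t$scores, expected * 2, tolerance = 1e-12)

  # missing V propagates by default; renormalize averages the rest
  Vna <- V; Vna["f2", "b"] <- NA
  fsn <- ClockFeatureSet(Vna, normalized = Vna)
  csNA <- compositeScores(sel3, fsn)
  expect_true(is.na(csNA$t$scores[["b"]]))
  csRe <- compositeScores(sel3, fsn, renormalize = TRUE)
  expect_equal(csRe$t$scores[["b"]], 0.4 * V["f1", "b"], tolerance = 1e-12)

  # m = 0 produces no composite, with a message
  expect_message(compositeScores(list(t = data.frame(feature = character(0),
                                                     beta = numeric(0))), fs),
                 "not produced")
})

test_that("composite inference is invariant to the 1/m scaling", {
  set.seed(31)
  n <- 150; p <- 8
  raw <- matrix(rnorm(p * n), nrow = p,
                dimnames = list(paste0("f", 1:p), sprintf("P%03d", 1:n)))
  cd <- data.frame(age = rnorm(n, 62, 13),
                   sex = sample(c("female", "male"), n, TRUE),
                   row.names = colnames(raw))
  fs <- normalizeFeatures(ClockFeatureSet(raw, colData = cd))
  V <- normalizedFeatures(fs)
  SummarizedExperiment::colData(fs)$score <-
    as.numeric(colSums(0.6 * V[1:3, ]) + rnorm(n, 0, 0.8))
  scan <- scanAssociations(fs, tests = "score")
  sel <- selectSignificant(scan)
  expect_gt(nrow(sel$score), 1)
  tabMean <- associateComposite(compositeScores(sel, fs, scale = "mean"), fs)
  tabSum <- associateComposite(compositeScores(sel, fs, scale = "sum"), fs)
  expect_equal(tabMean$p_value, tabSum$p_value, tolerance = 1e-10)
  # the sum composite is m x larger, so its coefficient is m x smaller
  expect_equal(tabMean$beta, tabSum$beta * tabSum$m, tolerance = 1e-10)
  expect_true(all(c("m", "n_used") %in% colnames(tabMean)))
  expect_false(anyNA(tabMean$m) || anyNA(tabMean$n_used))
})

test_that("composite features are exactly the selected ones", {
  fs <- plantedFeatureSet(n = 150, p = 8, slope = 1.5, seed = 41, noiseSD = 1)
  scan <- scanAssociations(fs, tests = "score")
  sel <- selectSignificant(scan, alpha = 0.3)
  comp <- compositeScores(sel, fs)
  for (test in names(comp)) {
    expect_setequal(comp[[test]]$features$feature, sel[[test]]$feature)
    expect_equal(comp[[test]]$m, nrow(sel[[test]]))
  }
})

test_that("a multi-feature composite outperforms its median constituent", {
  set.seed(61)
  n <- 300; p <- 8
  raw <- matrix(rnorm(p * n), nrow = p,
                dimnames = list(paste0("f", 1:p), sprintf("P%03d", 1:n)))
  cd <- data.frame(age = rnorm(n, 62, 13),
                   sex = sample(c("female", "male"), n, TRUE),
                   row.names = colnames(raw))
  fs <- normalizeFeatures(ClockFeatureSet(raw, colData = cd))
  V <- normalizedFeatures(fs)
  # several weak contributors: each feature alone is mildly associated
  y <- colSums(0.25 * V[1:4, ]) + rnorm(n, 0, 1)
  SummarizedExperiment::colData(fs)$score <- as.numeric(y)
  scan <- scanAssociations(fs, tests = "score")
  sel <- selectSignificant(scan, alpha = 0.5)
  comp <- compositeScores(sel, fs)
  tab <- associateComposite(comp, fs)
  constituents <- scan[scan$feature %in% sel$score$feature, "p_value"]
  expect_lte(tab$p_value, median(constituents))
})

test_that("MCI models use education-adjusted logistic regression", {
  cfg <- cohortConfig(nParticipants = 1200, seed = 13, mciPrevalence = 0.05,
                      npMissingness = 0)
  cc <- generateCohort(cfg)
  preds <- list(similarities = cc$cohort$similarities,
                trail_making_b = cc$cohort$trail_making_b)
  tab <- associateMCI(preds, cc$cohort)
  expect_equal(attr(tab, "threshold"), 0.05 / 18)
  expect_true(all(tab$converged))
  # direction: higher-is-better predictor protective (negative), timed
  # predictor deleterious (positive), mirroring the clinical expectation
  expect_lt(tab$coefficient[tab$predictor == "similarities"], 0)
  expect_gt(tab$coefficient[tab$predictor == "trail_making_b"], 0)
  expect_true(all(tab$n_events == sum(cc$cohort$mci)))

  expect_error(associateMCI(preds, transform(cc$cohort, mci = 0)),
               "both MCI classes")
  small <- cc$cohort[c(which(cc$cohort$mci == 1)[1:3],
                       which(cc$cohort$mci == 0)[1:50]), ]
  expect_error(associateMCI(preds["similarities"], small), "at least 10")
})

test_that("separated MCI predictors are flagged, not tabulated", {
  cfg <- cohortConfig(nParticipants = 600, seed = 17, mciPrevalence = 0.04,
                      npMissingness = 0)
  cc <- generateCohort(cfg)
  # a predictor that perfectly separates MCI from the rest
  sepPred <- ifelse(cc$cohort$mci == 1, 10, -10)
  tab <- associateMCI(list(sep = sepPred), cc$cohort)
  expect_false(tab$converged[tab$predictor == "sep"])
  expect_true(is.na(tab$coefficient[tab$predictor == "sep"]))
  expect_true(is.na(tab$significant[tab$predictor == "sep"]))
})

test_that("group comparison reproduces printed-count arithmetic", {
  # identical groups: rank-sum finds nothing
  grp <- data.frame(mci = rep(c(0, 1), each = 20),
                    age = rep(1:20, 2),
                    sex = rep(c("female", "male"), 20),
                    education = "high_school")
  out <- groupCompare(grp, continuous = "age", categorical = "sex")
  expect_gt(out$continuous$p_value, 0.95)

  # a cohort with 1065/997 women/men overall and 21/15 among MCI:
  # percentages and the 2x2 chi-square come out as printed counts imply
  sex <- c(rep("female", 1065), rep("male", 997))
  mci <- c(rep(1, 21), rep(0, 1044), rep(1, 15), rep(0, 982))
  tab <- groupCompare(data.frame(mci = mci, sex = sex, age = 1,
                                 education = "high_school"),
                      continuous = character(0), categorical = "sex")
  women <- tab$categorical[tab$categorical$level == "female", ]
  expect_equal(round(women$pct_all, 1), 51.6)
  expect_equal(round(women$pct_mci, 1), 58.3)
  # a sex imbalance this small is nowhere near significant
  expect_gt(women$p_value, 0.3)
  expect_lt(women$p_value, 0.7)
  expect_error(groupCompare(data.frame(mci = rep(0, 5), age = 1:5)),
               "non-empty")
})

test_that("same-sample composite reuse is anti-conservative; split-sample is not", {
  set.seed(91)
  nrep <- 150; n <- 120; p <- 10
  pSame <- pSplit <- rep(NA_real_, nrep)
  for (r in seq_len(nrep)) {
    raw <- matrix(rnorm(p * n), nrow = p,
                  dimnames = list(paste0("f", 1:p), sprintf("P%03d", 1:n)))
    cd <- data.frame(age = rnorm(n, 62, 13),
                     sex = sample(c("female", "male"), n, TRUE),
                     row.names = colnames(raw))
    cd$score <- rnorm(n)                        # pure null
    fs <- normalizeFeatures(ClockFeatureSet(raw, colData = cd))
    scan <- scanAssociations(fs, tests = "score")
    # near-1 threshold: keep (almost) every feature in the composite
    sel <- selectSignificant(scan, alpha = 0.999, nTests = 1)
    tabSame <- associateComposite(compositeScores(sel, fs), fs)
    pSame[r] <- tabSame$p_value
    tabSplit <- splitSampleComposite(fs, tests = "score", alpha = 0.999,
                                     nTests = 1, seed = r)
    if (nrow(tabSplit)) pSplit[r] <- tabSplit$p_value
  }
  rateSame <- mean(pSame < 0.05, na.rm = TRUE)
  rateSplit <- mean(pSplit < 0.05, na.rm = TRUE)
  # weights fitted and tested on the same nulls inflate rejections several
  # fold; held-out weights stay near the nominal level
  expect_gt(rateSame, 0.15)
  expect_lt(rateSplit, 0.13)
  expect_gt(rateSame, rateSplit)
})
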
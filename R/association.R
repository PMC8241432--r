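#' Mass-univariate association scan of features against the battery
#'
#' For every (feature, test) pair, fits one linear model
#' `test score ~ intercept + V_j + age + sex` on the complete-case rows for
#' that pair (so the n varies by pair, as it does when tests have
#' missingness). `V_j` is the rank-inverse-normal-transformed feature, so
#' the effect size is per 1 normalized-SD of the feature. Sex is coded
#' female = 1, male = 0. A feature with zero variance after complete-case
#' restriction for a pair is excluded with a warning, never silently
#' dropped.
#'
#' @param x a normalized [ClockFeatureSet-class] (run
#'   [normalizeFeatures()] first) whose `colData` holds `age`, `sex` and
#'   the test score columns.
#' @param tests character vector of test score column names in
#'   `colData(x)`; defaults to the battery keys present.
#' @param covariates covariate column names; default `c("age", "sex")`.
#' @return data.frame of class `AssociationScan` with columns `feature`,
#'   `test`, `beta`, `se`, `p_value`, `n_used`, one row per scanned pair,
#'   ordered by test then feature.
#' @export
scanAssociations <- function(x, tests = NULL, covariates = c("age", "sex")) {
  stopifnot(is(x, "ClockFeatureSet"))
  V <- normalizedFeatures(x)
  cd <- as.data.frame(colData(x))
  if (is.null(tests)) {
    tests <- intersect(npTestBattery()$key, colnames(cd))
  }
  if (length(tests) == 0L) stop("no test score columns found in colData")
  missing <- setdiff(c(tests, covariates), colnames(cd))
  if (length(missing)) {
    stop("colData lacks column(s): ", paste(missing, collapse = ", "))
  }
  covMat <- .covariateMatrix(cd, covariates)
  out <- vector("list", length(tests) * nrow(V))
  k <- 0L
  for (test in tests) {
    yAll <- as.numeric(cd[[test]])
    for (j in seq_len(nrow(V))) {
      k <- k + 1L
      feat <- rownames(V)[j]
      vj <- V[j, ]
      ok <- !is.na(yAll) & !is.na(vj) & complete.cases(covMat)
      row <- data.frame(feature = feat, test = test, beta = NA_real_,
                        se = NA_real_, p_value = NA_real_,
                        n_used = as.integer(sum(ok)),
                        stringsAsFactors = FALSE)
      if (sum(ok) >= ncol(covMat) + 4L) {
        if (var(vj[ok]) == 0 || !is.finite(var(vj[ok]))) {
          warning("feature ", feat, " has zero variance for test ", test,
                  " after complete-case restriction; excluded", call. = FALSE)
        } else {
          X <- cbind(intercept = 1, V = vj, covMat)
          fit <- fitLinearModel(yAll, X)
          row$beta <- fit$coefficients[["V"]]
          row$se <- fit$se[["V"]]
          row$p_value <- fit$p_value[["V"]]
          row$n_used <- fit$n_used
        }
      }
      out[[k]] <- row
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("AssociationScan", "data.frame")
  res
}

# covariate design columns: continuous age, sex indicator (female = 1),
# education dummies with no_high_school as the reference level
.covariateMatrix <- function(cd, covariates) {
  cols <- list()
  for (cv in covariates) {
    if (cv == "sex") {
      cols$sex_female <- as.numeric(cd$sex == "female")
    } else if (cv == "education") {
      edu <- factor(cd$education, levels = .EDUCATION_LEVELS)
      for (lev in .EDUCATION_LEVELS[-1L]) {
        cols[[paste0("edu_", lev)]] <- as.numeric(edu == lev)  # NA stays NA
      }
    } else {
      cols[[cv]] <- as.numeric(cd[[cv]])
    }
  }
  do.call(cbind, cols)
}

#' Select Bonferroni-significant features per test
#'
#' Feature j is selected for test k iff `p_jk < alpha / nTests`, with
#' `nTests` defaulting to the number of distinct features scanned (the
#' correction is per test across the feature family, not features x
#' tests).
#'
#' @param results an `AssociationScan` from [scanAssociations()].
#' @param alpha family-wise level, default 0.05.
#' @param nTests number of tests in the Bonferroni family; default the
#'   number of distinct features in `results`.
#' @return named list (one entry per test) of data.frames with columns
#'   `feature`, `beta` (the selected features and their effect-size
#'   weights); attribute `threshold` records the cutoff used.
#' @export
selectSignificant <- function(results, alpha = 0.05, nTests = NULL) {
  stopifnot(is.data.frame(results),
            all(c("feature", "test", "beta", "p_value") %in% colnames(results)))
  if (is.null(nTests)) nTests <- length(unique(results$feature))
  thr <- bonferroniThreshold(alpha, nTests)
  out <- lapply(split(results, results$test), function(rt) {
    sel <- rt[!is.na(rt$p_value) & rt$p_value < thr, c("feature", "beta")]
    rownames(sel) <- NULL
    sel
  })
  attr(out, "threshold") <- thr
  attr(out, "n_tests") <- nTests
  out
}

#' Per-test weighted composite scores from significant features
#'
#' For each test with m >= 1 selected features, the composite for
#' participant i is the effect-size-weighted combination of that
#' participant's normalized features,
#' `score_i = (1/m) * sum_j beta_j * V_ij` (`scale = "mean"`, the default)
#' or the unscaled sum (`scale = "sum"`). The two choices differ only by
#' the constant 1/m, so downstream regression p-values are identical.
#' By default a participant missing any contributing `V_ij` gets a missing
#' score; `renormalize = TRUE` instead averages over the available
#' features.
#'
#' @param selected output of [selectSignificant()].
#' @param x the normalized [ClockFeatureSet-class] the scan ran on.
#' @param scale `"mean"` (divide by m) or `"sum"`.
#' @param renormalize average over available features instead of
#'   propagating missingness (default FALSE).
#' @return list of class `CompositeScoreSet`: one entry per test with a
#'   composite (`m`, `features` data.frame of features and weights,
#'   `scores` named numeric per participant). Tests with m = 0 are
#'   omitted with a message.
#' @export
compositeScores <- function(selected, x, scale = c("mean", "sum"),
                            renormalize = FALSE) {
  scale <- match.arg(scale)
  stopifnot(is(x, "ClockFeatureSet"))
  V <- normalizedFeatures(x)
  out <- list()
  for (test in names(selected)) {
    sel <- selected[[test]]
    m <- nrow(sel)
    if (m == 0L) {
      message("no significant features for test ", test, "; composite not produced")
      next
    }
    W <- V[sel$feature, , drop = FALSE] * sel$beta
    if (renormalize) {
      scores <- colMeans(W, na.rm = TRUE)
      scores[colSums(!is.na(W)) == 0L] <- NA_real_
      if (scale == "sum") scores <- scores * m
    } else {
      scores <- if (scale == "mean") colMeans(W) else colSums(W)
    }
    out[[test]] <- list(test = test, m = m, features = sel,
                        scores = scores)
  }
  class(out) <- "CompositeScoreSet"
  out
}

#' @export
print.CompositeScoreSet <- function(x, ...) {
  cat("CompositeScoreSet:", length(x), "tests with composites\n")
  for (cs in x) {
    cat(sprintf("  %-45s m = %3d, non-missing scores = %d\n",
                cs$test, cs$m, sum(!is.na(cs$scores))))
  }
  invisible(x)
}

#' Association between composite scores and their neuropsychological tests
#'
#' For each composite, fits `test score ~ intercept + composite + age +
#' sex` on complete cases and reports the composite coefficient with a
#' Bonferroni-corrected p-value (multiplied by the number of battery
#' tests, capped at 1 with a flag).
#'
#' @param composites a `CompositeScoreSet` from [compositeScores()].
#' @param x the [ClockFeatureSet-class] carrying `colData` with the test
#'   scores and covariates.
#' @param covariates covariate columns; default `c("age", "sex")`.
#' @param nReported number of tests in the reporting Bonferroni family;
#'   default 18 (the battery size).
#' @return data.frame with columns `test`, `m`, `n_used`, `beta`, `se`,
#'   `p_value`, `p_bonferroni`, `p_capped` — the composite-vs-test
#'   summary table.
#' @export
associateComposite <- function(composites, x, covariates = c("age", "sex"),
                               nReported = nrow(npTestBattery())) {
  stopifnot(inherits(composites, "CompositeScoreSet"), is(x, "ClockFeatureSet"))
  cd <- as.data.frame(colData(x))
  covMat <- .covariateMatrix(cd, covariates)
  rows <- lapply(composites, function(cs) {
    y <- as.numeric(cd[[cs$test]])
    X <- cbind(intercept = 1, composite = cs$scores[colnames(x)], covMat)
    fit <- fitLinearModel(y, X)
    p <- fit$p_value[["composite"]]
    pb <- p * nReported
    data.frame(test = cs$test, m = cs$m, n_used = fit$n_used,
               beta = fit$coefficients[["composite"]],
               se = fit$se[["composite"]], p_value = p,
               p_bonferroni = min(pb, 1), p_capped = !is.na(pb) && pb > 1,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Covariate-adjusted logistic association with MCI
#'
#' Fits `logit P(MCI) ~ intercept + predictor + age + sex + education`
#' (education dummy-coded against a no-high-school reference) for each
#' supplied predictor — a neuropsychological test score or a composite
#' score — and tabulates the predictor coefficient with Wald inference.
#' Significance for an 18-test battery is at `0.05 / 18`. Separated or
#' non-converged fits are flagged and their rows marked non-tabulated;
#' the function refuses to run with fewer MCI events than `minEvents`
#' (unstable Wald inference).
#'
#' @param predictors named list of numeric vectors (aligned to the cohort
#'   rows) or a named numeric matrix/data.frame of predictor columns.
#' @param cohort data.frame with `age`, `sex`, `education`, `mci`.
#' @param minEvents minimum number of MCI cases required (default 10).
#' @param alpha,nTests reporting Bonferroni family (default 0.05 over 18).
#' @return data.frame with `predictor`, `coefficient`, `se`, `p_value`,
#'   `n_used`, `n_events`, `converged`, `significant` (at the Bonferroni
#'   threshold, NA when not converged); attribute `threshold`.
#' @export
associateMCI <- function(predictors, cohort, minEvents = 10,
                         alpha = 0.05, nTests = nrow(npTestBattery())) {
  if (is.matrix(predictors) || is.data.frame(predictors)) {
    predictors <- as.list(as.data.frame(predictors))
  }
  stopifnot(is.list(predictors), !is.null(names(predictors)),
            all(c("age", "sex", "education", "mci") %in% colnames(cohort)))
  y <- as.integer(cohort$mci)
  nEvents <- sum(y == 1L, na.rm = TRUE)
  if (length(unique(y[!is.na(y)])) < 2L) {
    stop("both MCI classes must be present")
  }
  if (nEvents < minEvents) {
    stop(sprintf(paste0("only %d MCI cases; at least %d required for stable ",
                        "Wald inference. Increase the cohort size or prevalence, ",
                        "or lower minEvents deliberately."), nEvents, minEvents))
  }
  covMat <- .covariateMatrix(as.data.frame(cohort),
                             c("age", "sex", "education"))
  thr <- bonferroniThreshold(alpha, nTests)
  rows <- lapply(names(predictors), function(nm) {
    pv <- as.numeric(predictors[[nm]])
    fit <- tryCatch(
      fitLogisticModel(y, cbind(intercept = 1, predictor = pv, covMat)),
      error = function(e) NULL)
    if (is.null(fit)) {
      return(data.frame(predictor = nm, coefficient = NA_real_, se = NA_real_,
                        p_value = NA_real_, n_used = NA_integer_,
                        n_events = NA_integer_, converged = FALSE,
                        significant = NA, stringsAsFactors = FALSE))
    }
    conv <- fit$converged
    data.frame(predictor = nm,
               coefficient = if (conv) fit$coefficients[["predictor"]] else NA_real_,
               se = if (conv) fit$se[["predictor"]] else NA_real_,
               p_value = if (conv) fit$p_value[["predictor"]] else NA_real_,
               n_used = fit$n_used, n_events = fit$n_events,
               converged = conv,
               significant = if (conv) fit$p_value[["predictor"]] < thr else NA,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  attr(res, "threshold") <- thr
  res
}

#' Group comparison table by MCI status
#'
#' Descriptive characteristics split by MCI status: mean (SD) and a
#' tie-corrected Wilcoxon rank-sum p-value for continuous variables; n (%)
#' and a Pearson chi-square p-value (no continuity correction) for
#' dichotomous and categorical variables.
#'
#' @param cohort data.frame with `age`, `sex`, `education`, `mci` and test
#'   score columns.
#' @param continuous continuous variable names; default age plus every
#'   battery column present.
#' @param categorical categorical variable names; default sex and
#'   education.
#' @return list with `continuous` (variable, means/SDs per group, p) and
#'   `categorical` (variable, level, counts and percentages per group, p).
#' @export
groupCompare <- function(cohort,
                         continuous = NULL, categorical = c("sex", "education")) {
  stopifnot("mci" %in% colnames(cohort))
  grp <- as.integer(cohort$mci)
  if (!any(grp == 1L, na.rm = TRUE) || !any(grp == 0L, na.rm = TRUE)) {
    stop("both MCI groups must be non-empty")
  }
  if (is.null(continuous)) {
    continuous <- intersect(c("age", npTestBattery()$key), colnames(cohort))
  }
  contRows <- lapply(continuous, function(v) {
    val <- as.numeric(cohort[[v]])
    p <- suppressWarnings(
      wilcox.test(val[grp == 1L], val[grp == 0L], exact = FALSE)$p.value)
    data.frame(variable = v,
               mean_all = mean(val, na.rm = TRUE), sd_all = sd(val, na.rm = TRUE),
               mean_mci = mean(val[grp == 1L], na.rm = TRUE),
               sd_mci = sd(val[grp == 1L], na.rm = TRUE),
               mean_normal = mean(val[grp == 0L], na.rm = TRUE),
               sd_normal = sd(val[grp == 0L], na.rm = TRUE),
               p_value = p, stringsAsFactors = FALSE)
  })
  catRows <- lapply(categorical, function(v) {
    f <- factor(cohort[[v]])
    tab <- table(f, grp)
    p <- suppressWarnings(chisq.test(tab, correct = FALSE)$p.value)
    do.call(rbind, lapply(levels(f), function(lev) {
      data.frame(variable = v, level = lev,
                 n_all = sum(f == lev, na.rm = TRUE),
                 pct_all = 100 * sum(f == lev, na.rm = TRUE) / sum(!is.na(f)),
                 n_mci = sum(f == lev & grp == 1L, na.rm = TRUE),
                 pct_mci = 100 * sum(f == lev & grp == 1L, na.rm = TRUE) /
                   sum(grp == 1L & !is.na(f)),
                 n_normal = sum(f == lev & grp == 0L, na.rm = TRUE),
                 pct_normal = 100 * sum(f == lev & grp == 0L, na.rm = TRUE) /
                   sum(grp == 0L & !is.na(f)),
                 p_value = p, stringsAsFactors = FALSE)
    }))
  })
  list(continuous = do.call(rbind, contRows),
       categorical = do.call(rbind, catRows))
}

#' Split-sample composite association
#'
#' Selecting features and testing the composite on the same sample reuses
#' the data twice and is anti-conservative under the null. This variant
#' splits participants in half (deterministically given `seed`): features
#' are scanned and selected on the first half, and the composite built
#' from those weights is associated with the test on the held-out half,
#' giving well-calibrated null inference.
#'
#' @param x a normalized [ClockFeatureSet-class] with cohort `colData`.
#' @param tests test columns to analyse; default all battery columns
#'   present.
#' @param alpha,nTests selection Bonferroni family, as in
#'   [selectSignificant()].
#' @param scale composite scaling, as in [compositeScores()].
#' @param seed integer seed for the participant split.
#' @return data.frame in the shape of [associateComposite()], computed on
#'   the held-out half.
#' @export
splitSampleComposite <- function(x, tests = NULL, alpha = 0.05,
                                 nTests = NULL, scale = "mean", seed = 1L) {
  stopifnot(is(x, "ClockFeatureSet"))
  n <- ncol(x)
  set.seed(seed)
  half <- sample(n, floor(n / 2))
  xa <- x[, half]
  xb <- x[, -half]
  # re-normalize each half on its own sample (rank-INT is sample-relative)
  xa <- normalizeFeatures(.stripNormalized(xa))
  xb <- normalizeFeatures(.stripNormalized(xb))
  scan <- suppressWarnings(scanAssociations(xa, tests = tests))
  sel <- selectSignificant(scan, alpha = alpha, nTests = nTests)
  comp <- compositeScores(sel, xb, scale = scale)
  if (length(comp) == 0L) {
    return(data.frame(test = character(0), m = integer(0), n_used = integer(0),
                      beta = numeric(0), se = numeric(0), p_value = numeric(0),
                      p_bonferroni = numeric(0), p_capped = logical(0)))
  }
  associateComposite(comp, xb)
}

.stripNormalized <- function(x) {
  a <- assays(x)
  assays(x) <- a[names(a) != "normalized"]
  x
}
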
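#' Rank-based inverse normal transformation (Blom)
#'
#' Maps each non-missing value with rank r (average ranks for ties) among n
#' non-missing values to `qnorm((r - 3/8) / (n + 1/4))`. The Blom offset
#' c = 3/8 is the prevailing choice in epidemiology. The transform removes
#' distributional skewness while preserving order: it is monotone in its
#' input and missing values stay missing.
#'
#' @param values numeric vector, possibly with `NA`.
#' @return numeric vector of the same length; `NA` where the input is `NA`.
#' @examples
#' rankInverseNormal(c(1, 10, 100))   # middle value maps to 0 exactly
#' @export
rankInverseNormal <- function(values) {
  if (!is.numeric(values)) stop("values must be numeric")
  ok <- !is.na(values)
  n <- sum(ok)
  if (n == 0L) stop("rank inverse normal transform undefined: all values missing")
  if (n < 2L) stop("rank inverse normal transform needs >= 2 non-missing values")
  v <- values[ok]
  if (max(v) == min(v)) {
    stop("rank inverse normal transform undefined for a constant vector")
  }
  r <- rank(v, ties.method = "average")
  out <- rep(NA_real_, length(values))
  out[ok] <- qnorm((r - 3 / 8) / (n + 1 / 4))
  out
}

#' Bonferroni-corrected significance threshold
#'
#' Family-wise error control at level `alpha` over `nTests` hypotheses:
#' each test is declared significant when its p-value falls below
#' `alpha / nTests`. With alpha = 0.05 this gives 4.76e-4 for a
#' 105-feature scan and 2.78e-3 for an 18-test battery.
#'
#' @param alpha family-wise error level, in (0, 1).
#' @param nTests number of hypotheses, a positive integer.
#' @return `alpha / nTests`, exactly.
#' @export
bonferroniThreshold <- function(alpha, nTests) {
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha <= 0 || alpha >= 1) {
    stop("alpha must be a single number in (0, 1)")
  }
  if (!is.numeric(nTests) || length(nTests) != 1L || is.na(nTests) ||
      nTests < 1 || nTests != round(nTests)) {
    stop("nTests must be a positive integer")
  }
  alpha / nTests
}

#' Covariate-adjusted ordinary least squares with per-coefficient inference
#'
#' Fits `y ~ X` by OLS on the complete-case rows (rows with no missing value
#' in `y` or any column of `X`), with standard errors from
#' `sigma^2 (X'X)^{-1}` and two-sided p-values from the t distribution on
#' n - p residual degrees of freedom. `X` must already contain the intercept
#' column. Exact fits (zero residual variance) report SE 0 with
#' `exact_fit = TRUE` and `NA` p-values rather than NaNs.
#'
#' @param y numeric response vector.
#' @param X numeric design matrix with named columns, including the
#'   intercept; `nrow(X) == length(y)`.
#' @return list of class `LinearFit`: `coefficients`, `se`, `p_value`
#'   (named vectors), `n_used`, `df_residual`, `sigma`, `exact_fit`.
#' @export
fitLinearModel <- function(y, X) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (nrow(X) != length(y)) stop("y and X must have matching rows")
  ok <- !is.na(y) & complete.cases(X)
  n <- sum(ok)
  p <- ncol(X)
  if (n < p + 2L) {
    stop(sprintf("insufficient complete-case rows: %d available, need >= %d",
                 n, p + 2L))
  }
  Xc <- X[ok, , drop = FALSE]
  yc <- y[ok]
  qrX <- qr(Xc)
  if (qrX$rank < p) {
    dropped <- colnames(Xc)[qrX$pivot[(qrX$rank + 1L):p]]
    stop("rank-deficient design: collinear column(s) ",
         paste(dropped, collapse = ", "))
  }
  fit <- lm(yc ~ Xc - 1)
  est <- setNames(as.numeric(coef(fit)), colnames(Xc))
  res <- yc - as.numeric(Xc %*% est)
  df <- n - p
  rss <- sum(res^2)
  # exact fit: residual SS indistinguishable from 0 at the response scale
  exact <- rss <= 1e-12 * max(1, sum(yc^2))
  sigma2 <- if (exact) 0 else rss / df
  xtxinv <- chol2inv(qr.R(qrX))[order(qrX$pivot), order(qrX$pivot), drop = FALSE]
  se <- setNames(sqrt(pmax(sigma2 * diag(xtxinv), 0)), colnames(Xc))
  pv <- if (exact) {
    setNames(rep(NA_real_, p), colnames(Xc))
  } else {
    setNames(2 * pt(abs(est / se), df = df, lower.tail = FALSE), colnames(Xc))
  }
  structure(list(coefficients = est, se = se, p_value = pv,
                 n_used = n, df_residual = df,
                 sigma = sqrt(sigma2), exact_fit = exact),
            class = "LinearFit")
}

#' @export
print.LinearFit <- function(x, ...) {
  cat(sprintf("LinearFit: n = %d, residual df = %d%s\n", x$n_used,
              x$df_residual, if (x$exact_fit) " (exact fit)" else ""))
  print(data.frame(estimate = x$coefficients, se = x$se, p = x$p_value))
  invisible(x)
}

#' Logistic regression with Wald inference and separation detection
#'
#' Fits `logit P(y = 1) = X b` by maximum likelihood (iteratively
#' reweighted least squares) on the complete-case rows. Wald standard
#' errors come from the inverse observed information. Complete or
#' quasi-complete separation — diverging coefficients with fitted
#' probabilities collapsing to 0/1 — is detected and flagged; a separated
#' or non-converged fit is reported with `converged = FALSE` and downstream
#' tabulation refuses it.
#'
#' @param y 0/1 response vector (both classes must be present after
#'   complete-case restriction).
#' @param X numeric design matrix with named columns, including the
#'   intercept.
#' @return list of class `LogisticFit`: `coefficients`, `se`, `p_value`
#'   (Wald, two-sided), `n_used`, `n_events`, `converged`, `separation`.
#' @export
fitLogisticModel <- function(y, X) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (nrow(X) != length(y)) stop("y and X must have matching rows")
  ok <- !is.na(y) & complete.cases(X)
  yc <- as.numeric(y[ok])
  if (!all(yc %in% c(0, 1))) stop("y must be coded 0/1")
  if (length(unique(yc)) < 2L) {
    stop("one-class response: both outcome classes must be present")
  }
  Xc <- X[ok, , drop = FALSE]
  qrX <- qr(Xc)
  if (qrX$rank < ncol(Xc)) {
    dropped <- colnames(Xc)[qrX$pivot[(qrX$rank + 1L):ncol(Xc)]]
    stop("rank-deficient design: collinear column(s) ",
         paste(dropped, collapse = ", "))
  }
  sepWarn <- FALSE
  fit <- withCallingHandlers(
    glm(yc ~ Xc - 1, family = binomial(), control = list(maxit = 50, epsilon = 1e-10)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        sepWarn <<- TRUE
        invokeRestart("muffleWarning")
      }
      if (grepl("algorithm did not converge", conditionMessage(w))) {
        invokeRestart("muffleWarning")   # reported via the converged flag
      }
    })
  est <- setNames(as.numeric(coef(fit)), colnames(Xc))
  vc <- vcov(fit)
  se <- setNames(sqrt(diag(vc)), colnames(Xc))
  mu <- fit$fitted.values
  # separation heuristics: (a) the model classifies every observation
  # essentially perfectly (zero residual deviance), the signature of
  # complete separation whatever the predictor's scale; (b) boundary
  # fitted probabilities together with a diverging slope — judged on the
  # per-SD scale so rare outcomes with strongly negative intercepts are
  # not mistaken for separation
  sdx <- apply(Xc, 2L, sd)
  scaled <- abs(est[sdx > 0]) * sdx[sdx > 0]
  separation <- all(abs(yc - mu) < 1e-3) ||
    (sepWarn && any(mu < 1e-8 | mu > 1 - 1e-8) &&
       length(scaled) > 0 && max(scaled) > 15)
  converged <- isTRUE(fit$converged) && !separation
  pv <- setNames(2 * pnorm(abs(est / se), lower.tail = FALSE), colnames(Xc))
  structure(list(coefficients = est, se = se, p_value = pv,
                 n_used = length(yc), n_events = sum(yc),
                 converged = converged, separation = separation),
            class = "LogisticFit")
}

#' @export
print.LogisticFit <- function(x, ...) {
  cat(sprintf("LogisticFit: n = %d (%d events), converged = %s%s\n",
              x$n_used, x$n_events, x$converged,
              if (x$separation) ", SEPARATION DETECTED" else ""))
  print(data.frame(estimate = x$coefficients, se = x$se, p = x$p_value))
  invisible(x)
}
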
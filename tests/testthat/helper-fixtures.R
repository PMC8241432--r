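# Shared fixtures and independent oracles for the test suite.

# minimal hand-built drawing: nStrokes strokes on an 80 Hz grid
makeSimpleDrawing <- function(id = "p1", condition = "command",
                              nStrokes = 2, gap = 100) {
  t0 <- 0
  strokes <- list()
  for (i in seq_len(nStrokes)) {
    strokes[[i]] <- data.frame(t = t0 + c(0, 12.5, 25),
                               x = c(0, 1, 2) + i, y = c(0, 1, 0))
    t0 <- t0 + 25 + gap
  }
  ClockDrawing(id, condition,
               strokes, rep("other", nStrokes))
}

# closed-form OLS via explicit normal equations (independent of lm)
olsOracle <- function(y, X) {
  XtX <- t(X) %*% X
  b <- solve(XtX, t(X) %*% y)
  res <- y - X %*% b
  n <- nrow(X); p <- ncol(X)
  s2 <- sum(res^2) / (n - p)
  se <- sqrt(diag(s2 * solve(XtX)))
  pv <- 2 * pt(abs(b / se), df = n - p, lower.tail = FALSE)
  list(coef = drop(b), se = se, p = drop(pv))
}

# brute-force Newton optimizer of the exact Bernoulli log-likelihood,
# independent of glm/IRLS
logisticOracle <- function(y, X, maxit = 200, tol = 1e-12) {
  b <- rep(0, ncol(X))
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% b)
    mu <- 1 / (1 + exp(-eta))
    grad <- drop(t(X) %*% (y - mu))
    W <- mu * (1 - mu)
    H <- t(X) %*% (X * W)
    step <- solve(H, grad)
    # step halving on the exact log-likelihood
    ll <- function(bb) {
      e <- drop(X %*% bb)
      sum(y * e - log1p(exp(e)))
    }
    lam <- 1
    while (ll(b + lam * step) < ll(b) && lam > 1e-8) lam <- lam / 2
    bNew <- b + lam * step
    if (max(abs(bNew - b)) < tol) { b <- bNew; break }
    b <- bNew
  }
  list(coef = b, se = sqrt(diag(solve(H))),
       loglik = sum(y * drop(X %*% b) - log1p(exp(drop(X %*% b)))))
}

logisticLogLik <- function(y, X, b) {
  eta <- drop(X %*% b)
  sum(y * eta - log1p(exp(eta)))
}

# circumcircle of three points, solved from perpendicular-bisector
# equations (independent of fitCircle)
circumcircleOracle <- function(p1, p2, p3) {
  A <- rbind(2 * (p2 - p1), 2 * (p3 - p1))
  rhs <- c(sum(p2^2) - sum(p1^2), sum(p3^2) - sum(p1^2))
  ctr <- solve(A, rhs)
  list(center = ctr, radius = sqrt(sum((p1 - ctr)^2)))
}

# small feature set with a planted linear relationship between one feature
# and one test score; returns a normalized ClockFeatureSet
plantedFeatureSet <- function(n = 200, p = 10, slope = 3, seed = 11,
                              noiseSD = 0.1) {
  set.seed(seed)
  raw <- matrix(rnorm(p * n), nrow = p,
                dimnames = list(paste0("f", seq_len(p)),
                                sprintf("P%03d", seq_len(n))))
  age <- rnorm(n, 62, 13)
  sex <- sample(c("female", "male"), n, replace = TRUE)
  fs <- ClockFeatureSet(raw, colData = data.frame(
    age = age, sex = sex, row.names = colnames(raw)))
  fs <- normalizeFeatures(fs)
  V <- normalizedFeatures(fs)
  y <- slope * V["f1", ] + 0.02 * age + rnorm(n, 0, noiseSD)
  SummarizedExperiment::colData(fs)$score <- as.numeric(y)
  fs
}
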
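#' Algebraic least-squares circle fit
#'
#' Kasa's linearized fit: minimise the algebraic residual of
#' `x^2 + y^2 = a x + b y + c` over (a, b, c) by ordinary least squares,
#' giving center (a/2, b/2) and radius `sqrt(c + cx^2 + cy^2)`. With exactly
#' three non-collinear points this is the circumcircle. Used for clock-face
#' geometry (area, circularity, radial placement of numbers).
#'
#' @param points two-column numeric matrix or data.frame of (x, y)
#'   positions; at least 3 non-collinear points.
#' @return list of class `CircleFit` with `center` (length-2 numeric),
#'   `radius`, `rms_residual` (root-mean-square radial deviation of the
#'   points from the fitted circle) and `n`.
#' @examples
#' th <- seq(0, 2 * pi, length.out = 40)
#' fitCircle(cbind(10 + 30 * cos(th), 20 + 30 * sin(th)))
#' @export
fitCircle <- function(points) {
  pts <- as.matrix(points)
  if (ncol(pts) < 2L) stop("points must have two columns (x, y)")
  pts <- pts[complete.cases(pts[, 1:2, drop = FALSE]), 1:2, drop = FALSE]
  if (nrow(pts) < 3L) {
    stop("degenerate geometry: circle fit needs at least 3 points")
  }
  x <- pts[, 1L]; y <- pts[, 2L]
  A <- cbind(x, y, 1)
  b <- x^2 + y^2
  qrA <- qr(A)
  if (qrA$rank < 3L) {
    stop("degenerate geometry: points are collinear (or coincident)")
  }
  sol <- qr.coef(qrA, b)
  cx <- sol[1L] / 2
  cy <- sol[2L] / 2
  r2 <- sol[3L] + cx^2 + cy^2
  if (!is.finite(r2) || r2 <= 0) {
    stop("degenerate geometry: non-positive fitted radius")
  }
  r <- sqrt(r2)
  d <- sqrt((x - cx)^2 + (y - cy)^2)
  structure(list(center = c(x = unname(cx), y = unname(cy)),
                 radius = unname(r),
                 rms_residual = sqrt(mean((d - r)^2)),
                 n = nrow(pts)),
            class = "CircleFit")
}

#' @export
print.CircleFit <- function(x, ...) {
  cat(sprintf("CircleFit: center (%.4g, %.4g), radius %.4g, rms residual %.4g (n = %d)\n",
              x$center[1L], x$center[2L], x$radius, x$rms_residual, x$n))
  invisible(x)
}
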
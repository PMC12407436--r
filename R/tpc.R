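## Quadratic thermal-performance curves.
##
## Performance (a composite development score, or any per-larva measure) is
## modeled as y = a t^2 + b t + c by ordinary least squares on individual
## observations. The thermal optimum is the temperature maximizing the
## fitted curve *within the tested range*: an interior vertex when the fit
## is concave, otherwise the better endpoint. Clamping keeps the statistic
## defined on every bootstrap resample, including non-concave ones.

# OLS for y ~ 1 + t + t^2 from raw sums; returns c(c, b, a).
# Shared by fit_quadratic() and the bootstrap loop so both use the same
# estimator. Solves the 3x3 normal equations (well-conditioned at these
# temperature magnitudes).
.quad_ols <- function(t, y) {
  n <- length(t)
  s1 <- sum(t); s2 <- sum(t * t); s3 <- sum(t^3); s4 <- sum(t^4)
  XtX <- matrix(c(n, s1, s2,
                  s1, s2, s3,
                  s2, s3, s4), 3L, 3L)
  Xty <- c(sum(y), sum(t * y), sum(t * t * y))
  solve(XtX, Xty)
}

#' Fit a quadratic thermal-performance curve
#'
#' @param temperature Temperatures (degrees C), one per observation.
#' @param value Performance values (composite scores or raw measurements).
#' @return Object of class `"quadratic_tpc"` with coefficients `a`, `b`,
#'   `c` of `y = a t^2 + b t + c`, the tested range `t_min`/`t_max`, the
#'   clamped optimum `t_opt`, `n_obs`, and a `concave` flag (`a < 0`).
#' @examples
#' t <- rep(c(10, 12, 14, 16, 18), each = 3)
#' fit <- fit_quadratic(t, -(t - 15)^2)
#' fit$t_opt  # 15
#' @export
fit_quadratic <- function(temperature, value) {
  ok <- !is.na(temperature) & !is.na(value)
  t <- temperature[ok]; y <- value[ok]
  if (length(unique(t)) < 3L)
    stop("quadratic unidentifiable: need >= 3 distinct temperatures",
         call. = FALSE)
  beta <- .quad_ols(t, y)
  t_min <- min(t); t_max <- max(t)
  a <- beta[3L]; b <- beta[2L]
  structure(list(a = a, b = b, c = beta[1L],
                 t_min = t_min, t_max = t_max,
                 t_opt = peak(a, b, t_min, t_max),
                 n_obs = length(y), concave = a < 0),
            class = "quadratic_tpc")
}

#' Thermal optimum of a fitted quadratic, clamped to the tested range
#'
#' For a concave fit whose vertex `-b/(2a)` lies inside `[t_min, t_max]`,
#' the vertex is the optimum. Otherwise (vertex outside the range, or a
#' convex/linear fit) the optimum is whichever tested extreme gives the
#' larger fitted value, so the estimate always lies within the experimental
#' conditions. A fit with `a = 0` and `b = 0` is flat; it is flagged with a
#' warning and `t_max` is returned.
#'
#' @param a,b Quadratic and linear coefficients of `y = a t^2 + b t + c`.
#' @param t_min,t_max Tested temperature range (degrees C), `t_min < t_max`.
#' @return The optimum temperature in `[t_min, t_max]`.
#' @export
peak <- function(a, b, t_min, t_max) {
  stopifnot(t_min < t_max)
  if (a == 0 && b == 0) {
    warning("flat fit (a = 0, b = 0): optimum undefined, returning t_max")
    return(t_max)
  }
  if (a < 0) {
    v <- -b / (2 * a)
    if (v >= t_min && v <= t_max) return(v)
  }
  # endpoint argmax; the intercept cancels
  y_lo <- a * t_min^2 + b * t_min
  y_hi <- a * t_max^2 + b * t_max
  if (y_lo > y_hi) t_min else t_max
}

#' @export
print.quadratic_tpc <- function(x, ...) {
  cat(sprintf("Quadratic TPC: y = %.4g t^2 + %.4g t + %.4g\n", x$a, x$b, x$c))
  cat(sprintf("  n = %d, tested range [%.1f, %.1f] degC, %s\n",
              x$n_obs, x$t_min, x$t_max,
              if (x$concave) "concave" else "non-concave"))
  cat(sprintf("  thermal optimum t_opt = %.2f degC\n", x$t_opt))
  invisible(x)
}

#' Predict from a fitted quadratic TPC
#'
#' @param object A `"quadratic_tpc"`.
#' @param temperature Temperatures at which to evaluate the fitted curve.
#' @param ... Unused.
#' @return Fitted values.
#' @export
predict.quadratic_tpc <- function(object, temperature, ...) {
  object$a * temperature^2 + object$b * temperature + object$c
}
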
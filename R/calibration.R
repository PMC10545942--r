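#' Fit the illuminance-to-irradiance calibration curve
#'
#' Least-squares quadratic `y = a x^2 + b x + c` relating an on-board
#' photometric sensor reading (illuminance, lux) to the radiometric power
#' density measured on the arena (irradiance, uW/mm^2). Once fitted, the
#' curve converts routine sensor readings into approximate irradiance via
#' [apply_calibration()].
#'
#' @param x Sensor readings (>= 3 distinct values).
#' @param y Reference measurements, same length.
#' @return A `quadratic_fit` object with fields `a`, `b`, `c`, `r_squared`
#'   (`1 - SS_res/SS_tot`; defined as 1 when `SS_tot = 0`), and `n`.
#' @examples
#' fit <- fit_quadratic(0:10, (0:10)^2)
#' glance(fit)
#' @export
fit_quadratic <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  if (length(unique(x)) < 3) abort("Need at least 3 distinct x values.")
  fit <- stats::lm.fit(cbind(1, x, x^2), y)
  cf <- unname(fit$coefficients)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  structure(list(a = cf[3], b = cf[2], c = cf[1], r_squared = r2,
                 n = length(x)),
            class = "quadratic_fit")
}

#' @export
print.quadratic_fit <- function(x, ...) {
  cat(sprintf("<quadratic_fit: y = %.6g x^2 + %.6g x + %.6g, R^2 = %.4f, n = %d>\n",
              x$a, x$b, x$c, x$r_squared, x$n))
  invisible(x)
}

#' Apply a fitted calibration curve
#'
#' Evaluates `a x^2 + b x + c`, clipped below at 0 (irradiance cannot be
#' negative).
#'
#' @param fit A [fit_quadratic()] result.
#' @param x Sensor readings.
#' @return Calibrated values (same units as the fit's `y`).
#' @export
apply_calibration <- function(fit, x) {
  if (!inherits(fit, "quadratic_fit")) abort("`fit` must be a quadratic_fit.")
  pmax(0, fit$a * x^2 + fit$b * x + fit$c)
}
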
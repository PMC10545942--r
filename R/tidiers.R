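#' Broom-style tidiers for fitted objects
#'
#' `tidy()` returns one row per term or component; `glance()` returns a
#' one-row model summary.
#'
#' @param x A `quadratic_fit`, `drift_model` or `paired_wilcoxon` object.
#' @param ... Unused.
#' @return A tibble.
#' @name tidiers
NULL

#' @rdname tidiers
#' @exportS3Method generics::tidy
tidy.quadratic_fit <- function(x, ...) {
  tibble(term = c("x^2", "x", "(Intercept)"),
         estimate = c(x$a, x$b, x$c))
}

#' @rdname tidiers
#' @exportS3Method generics::glance
glance.quadratic_fit <- function(x, ...) {
  tibble(r.squared = x$r_squared, nobs = x$n)
}

#' @rdname tidiers
#' @exportS3Method generics::tidy
tidy.drift_model <- function(x, ...) {
  tibble(term = c("offset", "slope"), estimate = c(x$offset, x$slope))
}

#' @rdname tidiers
#' @exportS3Method generics::glance
glance.drift_model <- function(x, ...) {
  tibble(offset = x$offset, slope = x$slope,
         drift_s_per_hour = (x$slope - 1) * 3600)
}

#' @rdname tidiers
#' @exportS3Method generics::glance
glance.paired_wilcoxon <- function(x, ...) {
  tibble(statistic = x$statistic, p.value = x$p_value, n_pairs = x$n_pairs,
         n_used = x$n_used, method = x$method)
}

#' @export
print.drift_model <- function(x, ...) {
  cat(sprintf("<drift_model: device = %.8g * host + %.6g (%+.4g s/hour)>\n",
              x$slope, x$offset, (x$slope - 1) * 3600))
  invisible(x)
}
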
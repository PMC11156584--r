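# Shared container for nonlinear least-squares fits.
#
# `estimates`, `std_error` are named numeric vectors (same names);
# `ci` is a 2-column matrix (conf.low, conf.high) with those rownames;
# `fitted_fn` maps a time/distance vector to the fitted mean curve.
new_transport_fit <- function(subclass, estimates, std_error, rss, n,
                              converged, data, fitted_fn, extra = list()) {
  se <- std_error[names(estimates)]
  half <- qnorm(0.975) * se
  ci <- cbind(conf.low = estimates - half, conf.high = estimates + half)
  structure(
    c(list(estimates = estimates, std_error = se, ci = ci, rss = rss,
           n = n, converged = converged, data = data,
           fitted_fn = fitted_fn), extra),
    class = c(subclass, "transport_fit")
  )
}

# internal: linearised standard errors from an nls-like fit; zero-residual
# (noiseless round-trip) fits get zero SEs rather than an error.
nls_std_error <- function(fit, par_names, n) {
  se <- setNames(rep(0, length(par_names)), par_names)
  out <- tryCatch(sqrt(diag(vcov(fit))), error = function(e) NULL,
                  warning = function(w) NULL)
  if (!is.null(out) && all(is.finite(out[par_names]))) {
    se[par_names] <- out[par_names]
  }
  se
}

#' @export
print.transport_fit <- function(x, ...) {
  cat("<", class(x)[1], ">  n = ", x$n, ", rss = ",
      format(x$rss, digits = 4), ", converged: ", x$converged, "\n",
      sep = "")
  print(tidy(x), ...)
  invisible(x)
}

#' Tidy a transport model fit
#'
#' @param x A fit returned by [fit_frap()], [fit_clearance()],
#'   [fit_gaussian_profile()] or [calibrate_intensity()].
#' @param ... Unused.
#' @return A tibble with one row per parameter: `term`, `estimate`,
#'   `std.error`, `conf.low`, `conf.high` (95% linearised intervals).
#' @method tidy transport_fit
#' @export
tidy.transport_fit <- function(x, ...) {
  tibble(
    term = names(x$estimates),
    estimate = unname(x$estimates),
    std.error = unname(x$std_error),
    conf.low = unname(x$ci[, "conf.low"]),
    conf.high = unname(x$ci[, "conf.high"])
  )
}

#' Glance at a transport model fit
#'
#' @inheritParams tidy.transport_fit
#' @return A one-row tibble with `rss`, `n`, `converged`.
#' @method glance transport_fit
#' @export
glance.transport_fit <- function(x, ...) {
  tibble(rss = x$rss, n = x$n, converged = x$converged)
}

#' Plot a transport model fit over its data
#'
#' @param object A `transport_fit`.
#' @param ... Unused.
#' @return A ggplot object: observed points and the fitted curve.
#' @method autoplot transport_fit
#' @export
autoplot.transport_fit <- function(object, ...) {
  d <- object$data
  xvar <- names(d)[1]
  yvar <- names(d)[2]
  grid <- seq(min(d[[xvar]]), max(d[[xvar]]), length.out = 400)
  curve <- tibble(!!xvar := grid, !!yvar := object$fitted_fn(grid))
  ggplot2::ggplot(d, ggplot2::aes(.data[[xvar]], .data[[yvar]])) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_line(data = curve, colour = "firebrick", linewidth = 0.8) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang :=
NULL
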
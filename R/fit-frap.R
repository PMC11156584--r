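#' Fit the photobleaching-recovery model to estimate a diffusion coefficient
#'
#' Least-squares fit of the hemisphere-moles recovery model
#' ([recovery_intensity()]) to a fluorescence trace. The bleached-volume
#' width `sigma` and detection radius `radius` are fixed inputs (the
#' recovery time course is sensitive to `sigma` but insensitive to
#' `radius`); the diffusion coefficient is estimated by bounded nonlinear
#' least squares (Levenberg-Marquardt) from five log-spaced starting
#' values, keeping the lowest residual sum of squares.
#'
#' If `bleach_event = c(t0, duration)` is supplied, `data` is a full trace:
#' the equilibrium intensity is estimated as the mean of the final
#' 5 minutes before `t0`, and the recovery segment after `t0 + duration`
#' is fitted with time re-zeroed to the end of the bleach. Otherwise
#' `data` must already be the recovery segment with `time_s` starting at
#' the end of the bleach. `i0` defaults to the first post-bleach sample.
#' With `free_intensities = TRUE` both intensities are refined jointly
#' with the diffusion coefficient.
#'
#' @param data Data frame with columns `time_s` and `intensity_au`,
#'   baseline-corrected (see [baseline_correct()]).
#' @param sigma Bleached-volume Gaussian width (\eqn{\mu m}), > 0.
#' @param radius Detection hemisphere radius (\eqn{\mu m}); defaults to
#'   `sigma`.
#' @param bleach_event Optional `c(t0, duration)` (s) locating the bleach
#'   within a full trace.
#' @param i0,i_inf Optional post-bleach and equilibrium intensities (a.u.);
#'   estimated from the trace when `NULL`.
#' @param free_intensities Refine `i0` and `i_inf` jointly with `d`?
#' @param d_starts Starting values for the diffusion coefficient
#'   (\eqn{\mu m^2\,s^{-1}}).
#'
#' @return A `frap_fit` (see [tidy.transport_fit()]); the diffusion
#'   coefficient is term `d_um2_s`.
#' @export
#' @examples
#' tr <- sim_frap_trace(d = 136, sigma = 150, noise_cv = 0, drift_rate = 0,
#'                      bleach_times = 0, duration = 3600)
#' fit <- fit_frap(tr, sigma = 150, bleach_event = c(0, 30))
#' tidy(fit)
fit_frap <- function(data, sigma, radius = sigma, bleach_event = NULL,
                     i0 = NULL, i_inf = NULL, free_intensities = FALSE,
                     d_starts = 10^seq(0, 3, length.out = 5)) {
  stopifnot(is.data.frame(data),
            all(c("time_s", "intensity_au") %in% names(data)))
  check_num(sigma, "sigma", positive = TRUE, scalar = TRUE)
  check_num(radius, "radius", positive = TRUE, scalar = TRUE)

  if (!is.null(bleach_event)) {
    t0 <- bleach_event[1]
    dur <- if (length(bleach_event) > 1) bleach_event[2] else 30
    pre <- data$time_s < t0 & data$time_s >= t0 - 300
    if (is.null(i_inf) && any(pre)) i_inf <- mean(data$intensity_au[pre])
    data <- data[data$time_s >= t0 + dur, , drop = FALSE]
    data$time_s <- data$time_s - (t0 + dur)
  }
  tt <- data$time_s
  yy <- data$intensity_au
  if (length(tt) < 10) abort("too few recovery samples to fit")
  if (is.null(i0)) i0 <- yy[which.min(tt)]
  if (is.null(i_inf)) i_inf <- max(mean(tail(yy[order(tt)], 60)), i0 + 1e-9)

  m_ratio <- function(t, d) {
    hemisphere_moles(t, d, sigma, radius) / hemisphere_moles(0, d, sigma, radius)
  }
  lower_d <- 1e-3
  upper_d <- 1e5

  best <- NULL
  for (d0 in d_starts) {
    fit <- tryCatch({
      if (free_intensities) {
        minpack.lm::nlsLM(
          yy ~ b - (b - a) * m_ratio(tt, d),
          start = list(d = d0, a = i0, b = i_inf),
          lower = c(lower_d, -Inf, -Inf), upper = c(upper_d, Inf, Inf),
          control = minpack.lm::nls.lm.control(maxiter = 300))
      } else {
        minpack.lm::nlsLM(
          yy ~ i_inf - (i_inf - i0) * m_ratio(tt, d),
          start = list(d = d0),
          lower = lower_d, upper = upper_d,
          control = minpack.lm::nls.lm.control(maxiter = 300))
      }
    }, error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::resid(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) abort("FRAP fit failed to converge from any start")

  cf <- coef(best$fit)
  d_hat <- unname(cf[["d"]])
  if (free_intensities) {
    i0 <- unname(cf[["a"]])
    i_inf <- unname(cf[["b"]])
  }
  at_bounds <- d_hat <= lower_d * (1 + 1e-6) || d_hat >= upper_d * (1 - 1e-6)

  par_names <- if (free_intensities) c("d", "a", "b") else "d"
  se <- nls_std_error(best$fit, par_names, length(tt))
  est <- c(d_um2_s = d_hat, i0_au = i0, i_inf_au = i_inf)
  ses <- c(d_um2_s = unname(se[["d"]]),
           i0_au = if (free_intensities) unname(se[["a"]]) else 0,
           i_inf_au = if (free_intensities) unname(se[["b"]]) else 0)

  new_transport_fit(
    "frap_fit", est, ses, best$rss, length(tt),
    converged = !at_bounds,
    data = tibble(time_s = tt, intensity_au = yy),
    fitted_fn = function(t) i_inf - (i_inf - i0) * m_ratio(t, d_hat),
    extra = list(sigma_um = sigma, radius_um = radius)
  )
}
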
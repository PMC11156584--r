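#' Fit a Gaussian to a histology intensity-versus-distance profile
#'
#' Coronal-slice fluorescence averaged along the anterior-posterior axis
#' spreads as a Gaussian when transport is diffusive. The profile is fitted
#' by least squares to a Gaussian with free amplitude, centre, width and
#' constant baseline; the width is reported as a standard deviation
#' (\eqn{\mu m}).
#'
#' @param data Data frame with columns `ap_distance_um` (signed distance
#'   from the injection site) and `mean_intensity_au`; at least 8 points
#'   spanning both sides of the expected centre.
#'
#' @return A `profile_fit` with terms `amplitude_au`, `center_um`,
#'   `width_um` (SD) and `baseline_au`.
#' @export
#' @examples
#' pr <- sim_histology_profile(noise_cv = 0, seed = 1)
#' tidy(fit_gaussian_profile(pr))
fit_gaussian_profile <- function(data) {
  stopifnot(is.data.frame(data),
            all(c("ap_distance_um", "mean_intensity_au") %in% names(data)))
  xx <- data$ap_distance_um
  yy <- data$mean_intensity_au
  if (length(xx) < 8) abort("need at least 8 distance points")
  if (is.unsorted(xx)) abort("`ap_distance_um` must be sorted")

  b0 <- min(yy)
  a0 <- max(yy) - b0
  x00 <- xx[which.max(yy)]
  w0 <- max(diff(range(xx)) / 6, 1)
  model <- function(p) p[4] + p[1] * exp(-(xx - p[2])^2 / (2 * p[3]^2))
  jac <- function(p) {
    e <- exp(-(xx - p[2])^2 / (2 * p[3]^2))
    cbind(e,
          p[1] * (xx - p[2]) / p[3]^2 * e,
          p[1] * (xx - p[2])^2 / p[3]^3 * e,
          1)
  }
  # nls.lm with an analytic jacobian: finite differencing degenerates when
  # the centre sits near 0 (relative step underflow)
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = c(a0, x00, w0, b0),
      fn = function(p) yy - model(p),
      jac = function(p) -jac(p),
      lower = c(0, min(xx) - diff(range(xx)), 1e-6, -Inf),
      upper = c(Inf, max(xx) + diff(range(xx)), Inf, Inf),
      control = minpack.lm::nls.lm.control(maxiter = 400)),
    error = function(e) abort(paste0("Gaussian profile fit failed: ",
                                     conditionMessage(e)))
  )
  if (!fit$info %in% 1:4) {
    abort(paste0("Gaussian profile fit did not converge: ", fit$message))
  }
  cf <- fit$par
  rss <- sum(fit$fvec^2)
  # linearised SEs from the analytic jacobian at the solution
  se <- rep(0, 4)
  if (rss > 0 && length(xx) > 4) {
    sig2 <- rss / (length(xx) - 4)
    jt <- jac(cf)
    cv <- tryCatch(solve(crossprod(jt)) * sig2, error = function(e) NULL)
    if (!is.null(cv)) se <- sqrt(pmax(diag(cv), 0))
  }
  est <- c(amplitude_au = cf[1], center_um = cf[2],
           width_um = abs(cf[3]), baseline_au = cf[4])
  ses <- setNames(se, names(est))
  new_transport_fit(
    "profile_fit", est, ses, rss, length(xx),
    converged = TRUE,
    data = tibble(ap_distance_um = xx, mean_intensity_au = yy),
    fitted_fn = function(x) {
      cf[4] + cf[1] * exp(-(x - cf[2])^2 / (2 * cf[3]^2))
    }
  )
}

#' Linear intensity-to-concentration calibration
#'
#' Fluorescent intensity is linear in dye concentration over the working
#' range; `calibrate_intensity()` fits the ordinary least-squares line
#' intensity = slope * concentration + intercept, and
#' [apply_calibration()] inverts it to convert recorded intensities to
#' concentrations.
#'
#' @param data Data frame with columns `concentration` and `intensity_au`;
#'   at least 3 points.
#'
#' @return A `calibration_fit` with terms `slope` (a.u. per concentration
#'   unit, must be positive) and `intercept_au`; the fit carries
#'   `r_squared`.
#' @export
#' @examples
#' cal <- calibrate_intensity(data.frame(concentration = 0:5,
#'                                       intensity_au = 2 * (0:5) + 1))
#' tidy(cal)
calibrate_intensity <- function(data) {
  stopifnot(is.data.frame(data),
            all(c("concentration", "intensity_au") %in% names(data)))
  if (nrow(data) < 3) abort("need at least 3 calibration points")
  fit <- lm(intensity_au ~ concentration, data = data)
  cf <- coef(fit)
  slope <- unname(cf[["concentration"]])
  if (!is.finite(slope) || slope <= 0) {
    abort("invalid calibration: fitted slope is not positive")
  }
  se <- sqrt(diag(suppressWarnings(vcov(fit))))
  r2 <- suppressWarnings(summary(fit))$r.squared
  est <- c(slope = slope, intercept_au = unname(cf[["(Intercept)"]]))
  ses <- c(slope = unname(se[["concentration"]]),
           intercept_au = unname(se[["(Intercept)"]]))
  new_transport_fit(
    "calibration_fit", est, ses, sum(stats::resid(fit)^2), nrow(data),
    converged = TRUE,
    data = as_tibble(data[c("concentration", "intensity_au")]),
    fitted_fn = function(x) cf[["(Intercept)"]] + slope * x,
    extra = list(r_squared = r2)
  )
}

#' Convert a trace from intensity to concentration
#'
#' @param data Data frame with an `intensity_au` column.
#' @param calibration A [calibrate_intensity()] fit.
#' @return `data` as a tibble with an added `concentration` column.
#' @export
#' @rdname calibrate_intensity
apply_calibration <- function(data, calibration) {
  stopifnot(inherits(calibration, "calibration_fit"),
            "intensity_au" %in% names(data))
  est <- calibration$estimates
  out <- as_tibble(data)
  out$concentration <- (out$intensity_au - est[["intercept_au"]]) / est[["slope"]]
  out
}
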
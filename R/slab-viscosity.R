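#' Concentration in a slab draining across one face
#'
#' Reference ("direct") diffusimetry: a gel sheet of thickness `thickness`
#' holds a uniform concentration `c0` at `t = 0`, is sealed at `x = 0` and
#' loses solute across the open face `x = thickness`. The concentration at
#' depth `x` follows the cosine series
#' \deqn{C(x,t) = \frac{4C_0}{\pi}\sum_{n=0}^{\infty}
#'   \frac{(-1)^n}{2n+1}
#'   \exp\!\left(-\frac{D(2n+1)^2\pi^2 t}{4L^2}\right)
#'   \cos\frac{(2n+1)\pi x}{2L}.}
#' For \eqn{x \lesssim 0.2L} the time course is nearly independent of `x`,
#' so a fiber placed against the sealed face measures `d` knowing only `L`.
#' The series is truncated when the next term falls below
#' \eqn{10^{-12} c_0} or after `n_terms` terms, whichever comes first.
#'
#' @param t Time (s), >= 0. Vectorised.
#' @param d Diffusion coefficient (\eqn{\mu m^2\,s^{-1}}), > 0.
#' @param thickness Slab thickness L (\eqn{\mu m}), > 0.
#' @param x Measurement depth from the sealed face (\eqn{\mu m}), in
#'   `[0, thickness]`.
#' @param c0 Initial uniform concentration (arbitrary units).
#' @param n_terms Maximum number of series terms.
#'
#' @return Concentration in the units of `c0`.
#' @export
#' @examples
#' slab_concentration(t = 0.1, d = 1, thickness = 1) # Dt/L^2 = 0.1
slab_concentration <- function(t, d, thickness, x = 0, c0 = 1,
                               n_terms = 200) {
  check_num(t, "t", non_negative = TRUE)
  check_num(d, "d", positive = TRUE, scalar = TRUE)
  check_num(thickness, "thickness", positive = TRUE, scalar = TRUE)
  check_num(x, "x", non_negative = TRUE, scalar = TRUE)
  if (x > thickness) abort("`x` must lie within the slab (0 <= x <= L).")
  vapply(t, function(ti) {
    total <- 0
    for (n in 0:(n_terms - 1)) {
      m <- 2 * n + 1
      term <- 4 * c0 / pi * (-1)^n / m *
        exp(-d * m^2 * pi^2 * ti / (4 * thickness^2)) *
        cos(m * pi * x / (2 * thickness))
      total <- total + term
      if (abs(term) < 1e-12 * c0) break
    }
    total
  }, numeric(1))
}

# Dynamic viscosity of pure water (mPa s) at standard handbook temperatures.
# Anchors used by the temperature correction: 1.0016 at 20 C, 0.6913 at 37 C.
.water_viscosity_table <- data.frame(
  temp_c = c(0, 5, 10, 15, 20, 25, 30, 35, 37, 40, 45, 50,
             55, 60, 65, 70, 75, 80, 85, 90, 95, 100),
  eta_mpas = c(1.7911, 1.5182, 1.3059, 1.1375, 1.0016, 0.8900,
               0.7972, 0.7190, 0.6913, 0.6527, 0.5958, 0.5465,
               0.5036, 0.4660, 0.4329, 0.4035, 0.3774, 0.3540,
               0.3330, 0.3142, 0.2971, 0.2818)
)

#' Dynamic viscosity of pure water
#'
#' Linear interpolation in a hard-coded handbook table (0-100 degrees C).
#'
#' @param temp_c Temperature (degrees C), within 0-100. Vectorised.
#' @return Viscosity (mPa s).
#' @export
#' @examples
#' water_viscosity(c(20, 37))
water_viscosity <- function(temp_c) {
  check_num(temp_c, "temp_c")
  if (any(temp_c < 0 | temp_c > 100)) {
    abort("`temp_c` must be within the table range 0-100 degrees C.")
  }
  stats::approx(.water_viscosity_table$temp_c,
                .water_viscosity_table$eta_mpas, xout = temp_c)$y
}

#' Stokes-Einstein temperature correction of a diffusion coefficient
#'
#' The Stokes-Einstein relation \eqn{D \propto T/\eta(T)} converts a
#' free-solution diffusion coefficient measured at one temperature to
#' another:
#' \deqn{D(T_2) = D(T_1)\,\frac{T_2}{T_1}\,\frac{\eta(T_1)}{\eta(T_2)},}
#' with absolute temperatures and water viscosities from
#' [water_viscosity()]. Typical use is correcting bench-top gel
#' measurements at 20 degrees C to body temperature (37 degrees C) before
#' computing a tortuosity.
#'
#' @param d Diffusion coefficient (\eqn{\mu m^2\,s^{-1}}), > 0. Vectorised.
#' @param t_from,t_to Measurement and target temperatures (degrees C),
#'   within 0-100.
#'
#' @return Corrected diffusion coefficient (\eqn{\mu m^2\,s^{-1}}).
#' @export
#' @examples
#' stokes_einstein_correct(136, t_from = 20, t_to = 37)
stokes_einstein_correct <- function(d, t_from, t_to) {
  check_num(d, "d", positive = TRUE)
  check_num(t_from, "t_from", scalar = TRUE)
  check_num(t_to, "t_to", scalar = TRUE)
  d * ((t_to + 273.15) / (t_from + 273.15)) *
    (water_viscosity(t_from) / water_viscosity(t_to))
}
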
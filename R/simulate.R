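#' Simulate a photobleaching-recovery photometry trace
#'
#' Forward-simulates the in vivo recording protocol: a fluorescence
#' baseline at equilibrium intensity, one or more 30-s bleach events each
#' followed by a recovery that is exactly the analytic model
#' ([recovery_intensity()]), a slow multiplicative baseline decline
#' (default 6% per hour, matching the post-peak dye washout), and
#' multiplicative Gaussian measurement noise with a fixed coefficient of
#' variation (default 1%, a lock-in photometry scale where noise tracks
#' signal). All randomness flows from `seed`; the noiseless mean shares
#' the exact code path with the fitter's model, so round-trip tests probe
#' the fitter and not a reimplementation.
#'
#' @param d True diffusion coefficient (\eqn{\mu m^2\,s^{-1}}); default the
#'   agarose-gel example value 136.
#' @param sigma Bleached-volume width (\eqn{\mu m}), default 150.
#' @param radius Detection radius (\eqn{\mu m}), default `sigma`.
#' @param bleach_times Start times of bleach events (s); events must be
#'   separated by at least the recovery horizon.
#' @param bleach_duration Bleach length (s), default 30.
#' @param duration Total trace length (s); default covers the last bleach
#'   plus one hour.
#' @param fs Sampling rate (Hz), default 1.
#' @param i0,i_inf Post-bleach and equilibrium intensities (a.u.).
#' @param drift_rate Fractional baseline loss per hour (default 0.06).
#' @param noise_cv Multiplicative noise coefficient of variation
#'   (default 0.01).
#' @param seed Integer seed; `NULL` leaves the RNG alone.
#'
#' @return A tibble with `time_s` and `intensity_au`.
#' @export
#' @examples
#' tr <- sim_frap_trace(seed = 1)
sim_frap_trace <- function(d = 136, sigma = 150, radius = sigma,
                           bleach_times = 0, bleach_duration = 30,
                           duration = if (length(bleach_times)) {
                             max(bleach_times) + bleach_duration + 3600
                           } else 3600,
                           fs = 1, i0 = 0.2, i_inf = 1,
                           drift_rate = 0.06, noise_cv = 0.01, seed = NULL) {
  check_num(d, "d", positive = TRUE, scalar = TRUE)
  check_num(drift_rate, "drift_rate", non_negative = TRUE, scalar = TRUE)
  check_num(noise_cv, "noise_cv", non_negative = TRUE, scalar = TRUE)
  bleach_times <- sort(bleach_times)
  if (length(bleach_times) > 1 && any(diff(bleach_times) < 3600)) {
    abort("bleach events must be separated by at least the 1-h recovery horizon")
  }
  tt <- seq(0, duration, by = 1 / fs)
  y <- rep(i_inf, length(tt))
  for (tb in bleach_times) {
    during <- tt >= tb & tt < tb + bleach_duration
    # linear ramp down while the shutter is open
    y[during] <- i_inf + (i0 - i_inf) * (tt[during] - tb) / bleach_duration
    after <- tt >= tb + bleach_duration
    y[after] <- recovery_intensity(tt[after] - (tb + bleach_duration),
                                   d, sigma, i0, i_inf, radius)
  }
  if (drift_rate > 0) y <- y * (1 - drift_rate)^(tt / 3600)
  if (noise_cv > 0) {
    y <- with_seed(seed, y * (1 + rnorm(length(y), sd = noise_cv)))
  }
  tibble(time_s = tt, intensity_au = y)
}

#' Simulate a dye-arrival (clearance) photometry trace
#'
#' Forward-simulates the cortical fluorescence after a bolus injection at
#' distance `distance`: the noiseless mean is exactly
#' [clearance_concentration()] on the sampling grid, and multiplicative
#' Gaussian noise with coefficient of variation `noise_cv` (default 2%) is
#' added. Defaults describe the saline (undisturbed-clearance) condition:
#' effective diffusion coefficient 230.7 \eqn{\mu m^2\,s^{-1}} (the
#' free-solution value 452.2 at 37 degrees C divided by a tortuosity of
#' 1.4 squared), source width 250 \eqn{\mu m}, fiber-cannula distance
#' 3335 \eqn{\mu m}, and a clearance half-time of 2600 s, which puts about
#' 75% clearance at the concentration peak. Sampling is 0.2 Hz over 8 h.
#'
#' @param d True diffusion coefficient (\eqn{\mu m^2\,s^{-1}}).
#' @param tau True clearance half-time (s); `Inf` simulates a gel (no
#'   clearance).
#' @param sigma Initial source width (\eqn{\mu m}).
#' @param distance Source-detector distance (\eqn{\mu m}).
#' @param duration Trace length (s), default 8 h.
#' @param fs Sampling rate (Hz), default 0.2.
#' @param c_peak Source peak concentration (arbitrary units).
#' @param noise_cv Multiplicative noise CV, default 0.02.
#' @param seed Integer seed; `NULL` leaves the RNG alone.
#'
#' @return A tibble with `time_s` and `intensity_au`.
#' @export
#' @examples
#' tr <- sim_clearance_trace(seed = 1)
sim_clearance_trace <- function(d = 230.7, tau = 2600, sigma = 250,
                                distance = 3335, duration = 8 * 3600,
                                fs = 0.2, c_peak = 1, noise_cv = 0.02,
                                seed = NULL) {
  check_num(noise_cv, "noise_cv", non_negative = TRUE, scalar = TRUE)
  tt <- seq(0, duration, by = 1 / fs)
  y <- clearance_concentration(distance, tt, d, sigma, tau, c_peak)
  if (noise_cv > 0) {
    y <- with_seed(seed, y * (1 + rnorm(length(y), sd = noise_cv)))
  }
  tibble(time_s = tt, intensity_au = y)
}

#' Simulate a histology intensity-versus-distance profile
#'
#' Samples the cleared Gaussian-source model along the anterior-posterior
#' axis at the time of death `t_kill`, on a grid with one point per group
#' of four 60-\eqn{\mu m} slices (240 \eqn{\mu m}), adds a constant tissue
#' autofluorescence baseline and multiplicative Gaussian noise. The planted
#' Gaussian has standard deviation \eqn{\sqrt{\sigma^2 + 2 D t}}.
#'
#' @inheritParams sim_clearance_trace
#' @param t_kill Time of death after injection (s); the study used 3 h and
#'   5 h.
#' @param spacing Distance between profile points (\eqn{\mu m}),
#'   default 240.
#' @param extent Half-width of the sampled axis (\eqn{\mu m}),
#'   default 5000.
#' @param baseline Constant tissue-autofluorescence background, as a
#'   fraction of the profile's peak intensity (default 0.1).
#' @param noise_cv Multiplicative noise CV, default 0.05.
#'
#' @return A tibble with `ap_distance_um` and `mean_intensity_au`.
#' @export
#' @examples
#' pr <- sim_histology_profile(t_kill = 3 * 3600, seed = 1)
sim_histology_profile <- function(d = 230.7, tau = 2600, t_kill = 3 * 3600,
                                  sigma = 250, spacing = 240, extent = 5000,
                                  c_peak = 1, baseline = 0.1,
                                  noise_cv = 0.05, seed = NULL) {
  check_num(t_kill, "t_kill", non_negative = TRUE, scalar = TRUE)
  xx <- seq(-extent, extent, by = spacing)
  y <- clearance_concentration(abs(xx), t_kill, d, sigma, tau, c_peak)
  y <- y + baseline * max(y)
  if (noise_cv > 0) {
    y <- with_seed(seed, y * (1 + rnorm(length(y), sd = noise_cv)))
  }
  tibble(ap_distance_um = xx, mean_intensity_au = y)
}

# per-state means of log10(delta power), log10(theta power), log10(EMG RMS);
# separations of >= 3 within-state SDs (0.15 log10 units) on the
# discriminating axes
.sleep_state_means <- rbind(
  wake = c(delta = 1.0, theta = 1.2, emg = 1.5),
  nrem = c(delta = 1.8, theta = 1.4, emg = 0.6),
  rem  = c(delta = 0.9, theta = 1.6, emg = 0.2)
)

#' Simulate per-bin vigilance-state features
#'
#' Generates the 5-s-bin feature stream the sleep scorer consumes: for each
#' bin, log10 delta power, log10 theta power and log10 EMG RMS are drawn
#' from a state-conditional multivariate normal (independent components,
#' common SD `log_sd`), exponentiated, and the theta/delta ratio computed
#' from the drawn powers. State means are fixed package conventions chosen
#' so adjacent states are separated by at least `separation = 3` SDs on
#' their discriminating features (slow-wave power for NREM, muscle tone for
#' Wake, theta dominance for REM); lowering `separation` shrinks the means
#' toward their grand mean to make the problem harder. If `states` is not
#' supplied, a bout-structured sequence is drawn from a simple Markov chain
#' (mean bout lengths of a few minutes, wake-dominant occupancy).
#'
#' @param n_bins Number of 5-s bins (ignored when `states` is given).
#' @param states Optional character vector of `"wake"/"nrem"/"rem"` labels.
#' @param bin_size Bin length (s), default 5.
#' @param separation Between-state separation in within-state SD units,
#'   default 3.
#' @param log_sd Within-state SD of the log10 features, default 0.15.
#' @param seed Integer seed.
#'
#' @return A tibble with `bin_start_s`, `delta_power`, `theta_power`,
#'   `theta_delta_ratio`, `emg_rms` and the true `state`.
#' @export
#' @examples
#' ff <- sim_sleep_features(n_bins = 200, seed = 1)
#' table(ff$state)
sim_sleep_features <- function(n_bins = 720, states = NULL, bin_size = 5,
                               separation = 3, log_sd = 0.15, seed = NULL) {
  check_num(separation, "separation", non_negative = TRUE, scalar = TRUE)
  check_num(log_sd, "log_sd", non_negative = TRUE, scalar = TRUE)
  with_seed(seed, {
    if (is.null(states)) {
      trans <- rbind(wake = c(0.98, 0.02, 0.00),
                     nrem = c(0.02, 0.965, 0.015),
                     rem  = c(0.05, 0.01, 0.94))
      colnames(trans) <- rownames(trans)
      states <- character(n_bins)
      states[1] <- "wake"
      for (i in seq_len(n_bins - 1)) {
        states[i + 1] <- sample(colnames(trans), 1,
                                prob = trans[states[i], ])
      }
    }
    states <- tolower(states)
    if (!all(states %in% rownames(.sleep_state_means))) {
      abort("states must be in {wake, nrem, rem}")
    }
    mu <- .sleep_state_means
    grand <- colMeans(mu)
    mu <- sweep(sweep(mu, 2, grand) * (separation / 3), 2, grand, `+`)
    n <- length(states)
    logf <- mu[states, , drop = FALSE] +
      matrix(rnorm(3 * n, sd = log_sd), n, 3)
    tibble(
      bin_start_s = (seq_len(n) - 1) * bin_size,
      delta_power = 10^logf[, "delta"],
      theta_power = 10^logf[, "theta"],
      theta_delta_ratio = 10^(logf[, "theta"] - logf[, "delta"]),
      emg_rms = 10^logf[, "emg"],
      state = states
    )
  })
}

#' Simulate toy raw EEG/EMG signals for a state sequence
#'
#' A deliberately simple waveform generator used to exercise the filtering
#' and band-power path of [compute_sleep_features()]: per 5-s bin the EEG
#' is a state-characteristic sinusoid (2.5 Hz in NREM, 7 Hz in REM, a
#' low-amplitude 8 Hz rhythm awake) plus white noise, and the EMG is white
#' noise with state-dependent amplitude. It makes no claim to spectral
#' realism beyond placing power in the right bands.
#'
#' @param states Character vector of per-bin states
#'   (`"wake"/"nrem"/"rem"`).
#' @param fs Sampling rate (Hz), default 200.
#' @param bin_size Bin length (s), default 5.
#' @param seed Integer seed.
#'
#' @return A tibble with `time_s`, `eeg` and `emg`.
#' @export
#' @examples
#' sig <- sim_sleep_signals(rep(c("wake", "nrem"), each = 12), seed = 1)
sim_sleep_signals <- function(states, fs = 200, bin_size = 5, seed = NULL) {
  states <- tolower(states)
  if (!all(states %in% c("wake", "nrem", "rem"))) {
    abort("states must be in {wake, nrem, rem}")
  }
  spb <- round(fs * bin_size)
  n <- length(states) * spb
  tt <- (seq_len(n) - 1) / fs
  freq <- c(wake = 8, nrem = 2.5, rem = 7)[states]
  amp <- c(wake = 0.5, nrem = 2.0, rem = 1.0)[states]
  emg_amp <- c(wake = 2.0, nrem = 0.5, rem = 0.15)[states]
  with_seed(seed, {
    eeg <- rep(amp, each = spb) * sin(2 * pi * rep(freq, each = spb) * tt) +
      rnorm(n, sd = 0.2)
    emg <- rep(emg_amp, each = spb) * rnorm(n)
    tibble(time_s = tt, eeg = eeg, emg = emg)
  })
}
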
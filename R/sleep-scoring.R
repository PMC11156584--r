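# internal: Welch band power of one segment of signal.
# 2-s Hann windows with 50% overlap inside each bin; returns a function of
# frequency band (integrated one-sided PSD, signal-units^2).
welch_psd <- function(x, fs, seg_s = 2) {
  nseg <- round(seg_s * fs)
  step <- nseg %/% 2
  starts <- seq(1, length(x) - nseg + 1, by = step)
  w <- 0.5 * (1 - cos(2 * pi * seq_len(nseg) / (nseg + 1))) # Hann
  scale <- fs * sum(w^2)
  acc <- 0
  for (s in starts) {
    seg <- x[s:(s + nseg - 1)] * w
    p <- abs(stats::fft(seg))^2 / scale
    acc <- acc + p
  }
  psd <- acc / length(starts)
  freq <- (seq_along(psd) - 1) * fs / nseg
  half <- seq_len(nseg %/% 2 + 1)
  psd <- psd[half]
  psd[-c(1, length(psd))] <- 2 * psd[-c(1, length(psd))] # one-sided
  list(freq = freq[half], psd = psd, df = fs / nseg)
}

band_power <- function(spec, band) {
  sel <- spec$freq >= band[1] & spec$freq <= band[2]
  sum(spec$psd[sel]) * spec$df
}

#' EEG/EMG features for sleep scoring
#'
#' Computes, per `bin_size`-second bin, the features used to classify
#' vigilance states: EEG power in the delta (1-4 Hz) and theta (5-10 Hz)
#' bands, their ratio, and the EMG root-mean-square. The EEG is first
#' high-pass filtered at 0.5 Hz and the EMG band-pass filtered 1-50 Hz
#' (zero-phase Butterworth); band powers come from a Welch periodogram
#' (2-s Hann segments, 50% overlap within each bin).
#'
#' A 0.5-4 Hz delta variant (used when correlating clearance with
#' slow-wave activity) is available via `delta_band = c(0.5, 4)`.
#'
#' @param eeg,emg Numeric signal vectors sampled at `fs`.
#' @param fs Sampling rate (Hz); must exceed 100 so the 50-Hz EMG band
#'   edge is below Nyquist.
#' @param bin_size Bin length (s), default 5.
#' @param delta_band,theta_band Frequency bands (Hz).
#'
#' @return A tibble with `bin_start_s`, `delta_power`, `theta_power`,
#'   `theta_delta_ratio`, `emg_rms`.
#' @export
#' @examples
#' sig <- sim_sleep_signals(rep("nrem", 12), seed = 1)
#' compute_sleep_features(sig$eeg, sig$emg, fs = 200)
compute_sleep_features <- function(eeg, emg, fs, bin_size = 5,
                                   delta_band = c(1, 4),
                                   theta_band = c(5, 10)) {
  check_num(fs, "fs", positive = TRUE, scalar = TRUE)
  if (fs <= 100) abort("`fs` must exceed 100 Hz for the 50-Hz EMG band edge")
  stopifnot(length(eeg) == length(emg))
  spb <- round(fs * bin_size)
  if (length(eeg) < spb) abort("signal shorter than one bin")

  hp <- signal::butter(2, 0.5 / (fs / 2), type = "high")
  bp <- signal::butter(4, c(1, 50) / (fs / 2), type = "pass")
  eeg_f <- signal::filtfilt(hp, eeg)
  emg_f <- signal::filtfilt(bp, emg)

  n_bins <- length(eeg) %/% spb
  out <- purrr::map_dfr(seq_len(n_bins), function(i) {
    idx <- ((i - 1) * spb + 1):(i * spb)
    spec <- welch_psd(eeg_f[idx], fs)
    dp <- band_power(spec, delta_band)
    tp <- band_power(spec, theta_band)
    tibble(
      bin_start_s = (i - 1) * bin_size,
      delta_power = dp,
      theta_power = tp,
      theta_delta_ratio = if (dp > 0) tp / dp else NA_real_,
      emg_rms = sqrt(mean(emg_f[idx]^2))
    )
  })
  out
}

#' Score vigilance states with a Gaussian mixture model
#'
#' Fits a 3-component full-covariance Gaussian mixture to the standardised
#' log features and maps components to states by a fixed rule: the
#' component with the highest mean EMG RMS is Wake; of the remaining two,
#' the one with the higher mean theta/delta ratio is REM and the other
#' NREM. Because the log theta/delta ratio is an exact linear combination
#' of the log band powers (which would make a full covariance singular),
#' the mixture is fitted on the three independent features (log delta
#' power, log theta power, log EMG RMS); the ratio enters through the
#' component-mapping rule, using posterior-weighted component means of
#' the log ratio. Bins are classified independently (no temporal
#' smoothing), so permuting bin order permutes labels identically. If the
#' fit degenerates it is retried with a regularising conjugate prior and
#' a warning.
#'
#' @param features A data frame with columns `delta_power`, `theta_power`,
#'   `theta_delta_ratio`, `emg_rms` (see [compute_sleep_features()] or
#'   [sim_sleep_features()]); at least 50 bins.
#' @param seed Integer seed (model fitting is deterministic; the seed
#'   guards any internal initialisation).
#'
#' @return A tibble (`bin_start_s` preserved if present) with `state` and
#'   per-bin posterior probabilities `p_wake`, `p_nrem`, `p_rem`.
#' @export
#' @examples
#' ff <- sim_sleep_features(n_bins = 300, seed = 2)
#' hyp <- score_sleep(ff, seed = 1)
#' confusion_metrics(hyp$state, ff$state)
score_sleep <- function(features, seed = 1) {
  cols <- c("delta_power", "theta_power", "theta_delta_ratio", "emg_rms")
  stopifnot(is.data.frame(features), all(cols %in% names(features)))
  if (nrow(features) < 50) abort("need at least 50 bins to fit the mixture")
  fit_cols <- c("delta_power", "theta_power", "emg_rms")
  x <- log(as.matrix(features[fit_cols]))
  log_ratio <- log(features$theta_delta_ratio)
  if (any(!is.finite(x)) || any(!is.finite(log_ratio))) {
    abort("features must be positive and finite")
  }
  z <- scale(x)

  fit <- with_seed(seed, {
    m <- tryCatch(
      mclust::Mclust(z, G = 3, modelNames = "VVV", verbose = FALSE),
      error = function(e) NULL)
    if (is.null(m)) {
      warn("mixture fit degenerate; refitting with a regularising prior")
      m <- mclust::Mclust(z, G = 3, modelNames = "VVV", verbose = FALSE,
                          prior = mclust::priorControl())
    }
    m
  })
  if (is.null(fit)) abort("Gaussian mixture fit failed")

  mu <- fit$parameters$mean # features x components (standardised scale)
  emg_row <- which(fit_cols == "emg_rms")
  # posterior-weighted component means of the log theta/delta ratio
  ratio_mu <- drop(crossprod(fit$z, log_ratio)) / colSums(fit$z)
  comp_state <- rep(NA_character_, 3)
  wake_c <- which.max(mu[emg_row, ])
  comp_state[wake_c] <- "wake"
  rest <- setdiff(1:3, wake_c)
  rem_c <- rest[which.max(ratio_mu[rest])]
  comp_state[rem_c] <- "rem"
  comp_state[setdiff(rest, rem_c)] <- "nrem"

  post <- fit$z
  out <- tibble(
    state = comp_state[fit$classification],
    p_wake = post[, wake_c],
    p_nrem = post[, setdiff(rest, rem_c)],
    p_rem = post[, rem_c]
  )
  if ("bin_start_s" %in% names(features)) {
    out <- dplyr::bind_cols(tibble(bin_start_s = features$bin_start_s), out)
  }
  out
}

#' Per-state sensitivity and specificity of a hypnogram
#'
#' One-versus-rest agreement between predicted and reference per-bin
#' labels.
#'
#' @param pred,truth Character vectors of states (or data frames with a
#'   `state` column), equal length.
#' @return A tibble with `state`, `sensitivity`, `specificity`, `n_true`.
#' @export
#' @examples
#' confusion_metrics(c("wake", "wake", "nrem"), c("wake", "nrem", "nrem"))
confusion_metrics <- function(pred, truth) {
  if (is.data.frame(pred)) pred <- pred$state
  if (is.data.frame(truth)) truth <- truth$state
  pred <- tolower(pred)
  truth <- tolower(truth)
  if (length(pred) != length(truth)) abort("pred and truth lengths differ")
  purrr::map_dfr(sort(unique(truth)), function(s) {
    tp <- sum(pred == s & truth == s)
    fn <- sum(pred != s & truth == s)
    tn <- sum(pred != s & truth != s)
    fp <- sum(pred == s & truth != s)
    tibble(state = s,
           sensitivity = tp / (tp + fn),
           specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
           n_true = tp + fn)
  })
}

#' Fraction of time in each vigilance state
#'
#' @param hypnogram A data frame with `bin_start_s` and `state`, or a
#'   character vector of states.
#' @param window Optional `c(start, end)` (s) restricting the summary.
#' @param bin_size Bin length (s), used when `hypnogram` is a bare vector.
#' @return A tibble with `state` and `fraction` (fractions sum to 1).
#' @export
#' @examples
#' state_fractions(c("wake", "wake", "nrem", "rem"))
state_fractions <- function(hypnogram, window = NULL, bin_size = 5) {
  if (is.data.frame(hypnogram)) {
    states <- hypnogram$state
    starts <- hypnogram$bin_start_s
  } else {
    states <- hypnogram
    starts <- (seq_along(states) - 1) * bin_size
  }
  if (!is.null(window)) {
    keep <- starts >= window[1] & starts < window[2]
    if (!any(keep)) abort("window contains no bins")
    states <- states[keep]
  }
  tb <- table(factor(tolower(states), levels = c("wake", "nrem", "rem")))
  tibble(state = names(tb), fraction = as.numeric(tb) / length(states))
}
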
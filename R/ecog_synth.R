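# Synthetic sensorimotor epochs: 1/f background, movement-locked beta
# modulation, injectable stimulation effects and DBS on/offset edge
# artifacts at known times.

# 1/f ("pink") background noise, one column per trial, unit SD.
pink_noise <- function(n, n_trials) {
  W <- matrix(stats::rnorm(n * n_trials), n, n_trials)
  FW <- stats::mvfft(W)
  k <- seq_len(n) - 1L
  f_bin <- pmin(k, n - k)            # symmetric frequency index
  scale <- ifelse(f_bin == 0, 0, 1 / sqrt(f_bin))
  X <- Re(stats::mvfft(FW * scale, inverse = TRUE)) / n
  sds <- apply(X, 2, stats::sd)
  sweep(X, 2, sds, "/")
}

# Boxcar over [win[1], win[2]] with raised-linear ramps of `ramp` seconds.
window_taper <- function(times, win, ramp = 0.02) {
  up <- pmin(pmax((times - win[1]) / ramp, 0), 1)
  down <- pmin(pmax((win[2] - times) / ramp, 0), 1)
  pmin(up, down)
}

# One-sided exponentially decaying transient starting at t0.
artifact_pulse <- function(times, t0, amplitude, tau = 0.004) {
  dt <- times - t0
  out <- numeric(length(times))
  idx <- dt >= 0 & dt <= 10 * tau
  out[idx] <- amplitude * exp(-dt[idx] / tau)
  out
}

#' Generate synthetic sensorimotor epochs
#'
#' Produces 2-s epochs centred on a nominal peak-speed time: a 1/f
#' background plus a beta-band oscillation whose amplitude shows
#' peri-movement desynchronisation and a post-movement rebound. A fraction
#' of trials is flagged as stimulated; their beta amplitude is additionally
#' scaled by `1 + peri_effect` within the peri-stimulation window and by
#' `1 + post_effect` within the post-stimulation window, and high-amplitude
#' edge transients are added at the stimulation on/offset times. The
#' injected effect sizes are returned as ground truth.
#'
#' @param n_trials Number of trials (at least 2).
#' @param spec An [epoch_spec()].
#' @param seed Optional integer seed.
#' @param peri_effect,post_effect Fractional beta-amplitude change injected
#'   in stimulated trials within the respective analysis window (0 = none).
#' @param stim_fraction Fraction of trials flagged stimulated.
#' @param beta_freq Carrier frequency of the beta oscillation (Hz).
#' @param beta_amplitude Beta amplitude in background-SD units.
#' @param artifact_amplitude Peak amplitude of the edge transients.
#' @param stim_onset Stimulation onset time within the epoch (seconds after
#'   peak speed).
#' @param burst_duration Burst length (seconds).
#' @return A list of class `kinestim_ecog_sim`: `epochs` (trials x time),
#'   `times`, `meta` (trial, stimulated, peak_speed, stim_onset,
#'   stim_offset), `spec` and `truth` (the injected effects).
#' @export
generate_synthetic_ecog <- function(n_trials, spec = epoch_spec(),
                                    seed = NULL,
                                    peri_effect = 0, post_effect = 0,
                                    stim_fraction = 0.5,
                                    beta_freq = 27, beta_amplitude = 1,
                                    artifact_amplitude = 20,
                                    stim_onset = 0.066,
                                    burst_duration = 0.300) {
  if (!is.numeric(n_trials) || length(n_trials) != 1L || n_trials < 2) {
    abort_invalid("`n_trials` must be at least 2")
  }
  if (spec$sample_rate <= 0) abort_invalid("`spec` has a non-positive sample rate")
  n_trials <- as.integer(n_trials)
  with_seed(seed, {
    fs <- spec$sample_rate
    times <- seq(spec$window[1], spec$window[2], by = 1 / fs)
    nt <- length(times)
    X <- t(pink_noise(nt, n_trials))
    # movement-locked modulation common to all trials: desynchronisation
    # around the peak, rebound afterwards
    env0 <- 1 - 0.4 * exp(-times^2 / (2 * 0.25^2)) +
      0.3 * exp(-(times - 0.7)^2 / (2 * 0.15^2))
    stim <- rep(FALSE, n_trials)
    stim[sample.int(n_trials, round(stim_fraction * n_trials))] <- TRUE
    onset <- ifelse(stim, stim_onset, NA_real_)
    offset <- onset + burst_duration
    peri_taper <- window_taper(times, spec$stim_window)
    post_taper <- window_taper(times, spec$post_window)
    for (tr in seq_len(n_trials)) {
      env <- env0
      if (stim[tr]) {
        env <- env * (1 + peri_effect * peri_taper) *
          (1 + post_effect * post_taper)
      }
      phase <- stats::runif(1L, 0, 2 * pi)
      X[tr, ] <- X[tr, ] + beta_amplitude * env *
        sin(2 * pi * beta_freq * times + phase)
      if (stim[tr]) {
        X[tr, ] <- X[tr, ] +
          artifact_pulse(times, onset[tr], artifact_amplitude) +
          artifact_pulse(times, offset[tr], -artifact_amplitude)
      }
    }
    meta <- data.frame(
      trial = seq_len(n_trials), stimulated = stim,
      peak_speed = stats::rlnorm(n_trials, log(1500), 0.1),
      stim_onset = onset, stim_offset = offset)
    structure(
      list(epochs = X, times = times, meta = meta, spec = spec,
           truth = list(peri_effect = peri_effect, post_effect = post_effect)),
      class = "kinestim_ecog_sim")
  })
}
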
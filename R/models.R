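#' Reaching-task screen geometry
#'
#' Describes the tablet task layout: a 1920x1080 screen with target
#' rectangles alternating between the left and right edge at one of four
#' vertical positions, and a fixed inter-movement interval during which the
#' cursor rests on the reached target.
#'
#' @param screen_w,screen_h Screen size in pixels.
#' @param target_x_left,target_x_right Horizontal centres of the left and
#'   right target columns (pixels).
#' @param target_ys Vertical target positions (pixels).
#' @param rect_size Target rectangle edge length (pixels).
#' @param inter_movement_interval Rest period between movements (seconds).
#' @return An object of class `task_geometry`.
#' @export
task_geometry <- function(screen_w = 1920, screen_h = 1080,
                          target_x_left = 100, target_x_right = 1820,
                          target_ys = c(390, 465, 615, 690),
                          rect_size = 175,
                          inter_movement_interval = 0.350) {
  check_positive_scalar(screen_w, "screen_w")
  check_positive_scalar(screen_h, "screen_h")
  check_positive_scalar(rect_size, "rect_size")
  if (target_x_left >= target_x_right) {
    abort_invalid("`target_x_left` must be smaller than `target_x_right`")
  }
  if (any(target_ys < 0 | target_ys > screen_h)) {
    abort_invalid("all `target_ys` must lie within [0, screen_h]")
  }
  if (inter_movement_interval < 0) {
    abort_invalid("`inter_movement_interval` must be non-negative")
  }
  structure(
    list(screen_w = screen_w, screen_h = screen_h,
         target_x_left = target_x_left, target_x_right = target_x_right,
         target_ys = target_ys, rect_size = rect_size,
         inter_movement_interval = inter_movement_interval),
    class = "task_geometry"
  )
}

#' Kinematics model for synthetic reaches
#'
#' Parameters of the synthetic movement generator: minimum-jerk speed
#' profiles whose peak speeds follow a geometric bradykinetic decrement with
#' multiplicative lognormal trial-to-trial noise, plus an injectable
#' reinforcement effect of stimulation on the next same-direction movement.
#'
#' @param sample_rate Cursor sampling rate in Hz.
#' @param duration_mean,duration_sd Movement duration distribution (seconds).
#' @param peak_speed_start Expected peak speed of the first movement of a
#'   block (pixels/s).
#' @param decrement_rate Per-movement geometric decay of the expected peak
#'   speed (fraction per movement; 0.002 = 0.2%).
#' @param noise_cv Coefficient of variation of the multiplicative lognormal
#'   peak-speed noise.
#' @param reinforcement_delta Fractional change applied to the target peak
#'   speed of the next same-direction movement after a stimulated movement;
#'   the sign of the applied effect follows the sign of the stimulated
#'   movement's deviation from the decrement trend.
#' @param position_noise_sd Additive Gaussian position noise per sample
#'   (pixels).
#' @param sampling_jitter Uniform jitter of the sampling interval as a
#'   fraction of the nominal interval (0 disables jitter).
#' @return An object of class `kinematics_model`.
#' @export
kinematics_model <- function(sample_rate = 62,
                             duration_mean = 0.812, duration_sd = 0.115,
                             peak_speed_start = 1800,
                             decrement_rate = 0.002,
                             noise_cv = 0.10,
                             reinforcement_delta = 0,
                             position_noise_sd = 2,
                             sampling_jitter = 0) {
  check_positive_scalar(sample_rate, "sample_rate")
  check_positive_scalar(duration_mean, "duration_mean")
  check_positive_scalar(peak_speed_start, "peak_speed_start")
  if (duration_sd < 0) abort_invalid("`duration_sd` must be non-negative")
  if (noise_cv < 0) abort_invalid("`noise_cv` must be non-negative")
  if (decrement_rate < 0 || decrement_rate >= 1) {
    abort_invalid("`decrement_rate` must lie in [0, 1)")
  }
  if (abs(reinforcement_delta) >= 1) {
    abort_invalid("`reinforcement_delta` must satisfy |delta| < 1")
  }
  if (position_noise_sd < 0) abort_invalid("`position_noise_sd` must be non-negative")
  if (sampling_jitter < 0 || sampling_jitter >= 1) {
    abort_invalid("`sampling_jitter` must lie in [0, 1)")
  }
  structure(
    list(sample_rate = sample_rate,
         duration_mean = duration_mean, duration_sd = duration_sd,
         peak_speed_start = peak_speed_start,
         decrement_rate = decrement_rate,
         noise_cv = noise_cv,
         reinforcement_delta = reinforcement_delta,
         position_noise_sd = position_noise_sd,
         sampling_jitter = sampling_jitter),
    class = "kinematics_model"
  )
}

#' Stimulation protocol
#'
#' Block structure and burst parameters of the speed-selective stimulation
#' session: four 96-movement blocks, speed-selective 300-ms bursts in blocks
#' 1 and 3, recovery (no stimulation) in blocks 2 and 4. Frequency, pulse
#' width and amplitude are metadata only; no electrical model is implied.
#'
#' @param condition_order Target conditions of the stimulation blocks, in
#'   block order (recycled over `stim_blocks`).
#' @param burst_duration Burst length in seconds.
#' @param stim_frequency Stimulation frequency in Hz (metadata).
#' @param pulse_width_us Pulse width in microseconds (metadata).
#' @param amplitude_ma Stimulation amplitude in mA (metadata).
#' @param block_length Movements per block.
#' @param n_blocks Number of blocks.
#' @param stim_blocks Indices of the stimulation blocks.
#' @return An object of class `stim_protocol`.
#' @export
stim_protocol <- function(condition_order = c("fast", "slow"),
                          burst_duration = 0.300,
                          stim_frequency = 130,
                          pulse_width_us = 60,
                          amplitude_ma = 2.4,
                          block_length = 96,
                          n_blocks = 4,
                          stim_blocks = c(1, 3)) {
  check_positive_scalar(burst_duration, "burst_duration")
  if (block_length < 3) abort_invalid("`block_length` must be at least 3")
  if (n_blocks < 1) abort_invalid("`n_blocks` must be at least 1")
  if (!all(stim_blocks %in% seq_len(n_blocks))) {
    abort_invalid("`stim_blocks` must be a subset of the blocks")
  }
  if (!all(condition_order %in% c("fast", "slow"))) {
    abort_invalid("`condition_order` entries must be 'fast' or 'slow'")
  }
  structure(
    list(condition_order = condition_order,
         burst_duration = burst_duration,
         stim_frequency = stim_frequency,
         pulse_width_us = pulse_width_us,
         amplitude_ma = amplitude_ma,
         block_length = block_length,
         n_blocks = n_blocks,
         stim_blocks = stim_blocks),
    class = "stim_protocol"
  )
}

#' Offline speed thresholds
#'
#' Constants of the offline behavioural pipeline. The defaults are the
#' standard values for this task: the movement threshold is 3 SD above the
#' pooled rest-period speed, the outlier threshold is 3 SD above the pooled
#' average movement speed. Both can be recomputed from a cohort with
#' [compute_rest_threshold()].
#'
#' @param movement_threshold Speed above which samples count as movement
#'   (pixels/s).
#' @param outlier_threshold Average movement speeds above this value are
#'   treated as missing (pixels/s).
#' @param rest_window Length of the rest segment used when recomputing the
#'   movement threshold (seconds).
#' @param sd_multiplier SD multiplier of the threshold definitions.
#' @return An object of class `speed_thresholds`.
#' @export
speed_thresholds <- function(movement_threshold = 800.77,
                             outlier_threshold = 2413.35,
                             rest_window = 0.300,
                             sd_multiplier = 3) {
  check_positive_scalar(movement_threshold, "movement_threshold")
  check_positive_scalar(outlier_threshold, "outlier_threshold")
  check_positive_scalar(rest_window, "rest_window")
  check_positive_scalar(sd_multiplier, "sd_multiplier")
  if (movement_threshold >= outlier_threshold) {
    abort_invalid("`movement_threshold` must be below `outlier_threshold`")
  }
  structure(
    list(movement_threshold = movement_threshold,
         outlier_threshold = outlier_threshold,
         rest_window = rest_window,
         sd_multiplier = sd_multiplier),
    class = "speed_thresholds"
  )
}

#' Epoching and spectral-analysis specification
#'
#' Parameters of the event-related spectral pipeline: 2-s epochs centred on
#' the peak-speed time, Morlet wavelets with four cycles, z-score baseline
#' -400 to -100 ms, the 20-35 Hz beta band, the peri-stimulation
#' (0.13-0.3 s) and post-stimulation (0.41-1.0 s) analysis windows, the
#' 65-ms half-width of the stimulation edge-artifact mask, and the 15%
#' masked-epoch fraction above which a time point is dropped from cluster
#' analysis.
#'
#' @param sample_rate Sampling rate of the synthetic neural signal (Hz).
#' @param window Epoch limits around the peak-speed time (seconds).
#' @param baseline Baseline window for z-scoring (seconds).
#' @param beta_band Beta frequency band (Hz).
#' @param stim_window,post_window Analysis windows (seconds).
#' @param artifact_halfwidth Half-width of the artifact mask around each
#'   stimulation edge (seconds).
#' @param nan_epoch_fraction Masked-epoch fraction at or above which a time
#'   point is excluded from cluster analysis (below it, masked entries are
#'   replaced by the cross-epoch median).
#' @param n_cycles Morlet wavelet cycles.
#' @param freqs Frequency grid of the time-frequency transform (Hz).
#' @return An object of class `epoch_spec`.
#' @export
epoch_spec <- function(sample_rate = 1000,
                       window = c(-1.0, 1.0),
                       baseline = c(-0.400, -0.100),
                       beta_band = c(20, 35),
                       stim_window = c(0.13, 0.30),
                       post_window = c(0.41, 1.00),
                       artifact_halfwidth = 0.065,
                       nan_epoch_fraction = 0.15,
                       n_cycles = 4,
                       freqs = 5:45) {
  check_positive_scalar(sample_rate, "sample_rate")
  check_positive_scalar(n_cycles, "n_cycles")
  if (baseline[2] > 0 || baseline[1] >= baseline[2]) {
    abort_invalid("`baseline` must be an increasing interval preceding 0")
  }
  if (stim_window[2] > post_window[1]) {
    abort_invalid("`stim_window` must precede `post_window`")
  }
  if (nan_epoch_fraction <= 0 || nan_epoch_fraction >= 1) {
    abort_invalid("`nan_epoch_fraction` must lie in (0, 1)")
  }
  if (any(freqs <= 0 | freqs >= sample_rate / 2)) {
    abort_invalid("`freqs` must lie strictly between 0 and the Nyquist frequency")
  }
  structure(
    list(sample_rate = sample_rate, window = window, baseline = baseline,
         beta_band = beta_band, stim_window = stim_window,
         post_window = post_window, artifact_halfwidth = artifact_halfwidth,
         nan_epoch_fraction = nan_epoch_fraction, n_cycles = n_cycles,
         freqs = freqs),
    class = "epoch_spec"
  )
}
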
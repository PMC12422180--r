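# Emulation of the real-time speed-selective stimulation controller.

#' Streaming speed estimate from a cursor trace
#'
#' Computes the instantaneous speed (Euclidean step length divided by the
#' elapsed time between consecutive samples) and the causal trailing mean
#' over the most recent six instantaneous values, averaging over however
#' many samples exist at the stream head.
#'
#' @param trace A cursor trace data frame with columns `time_s`, `x_px`,
#'   `y_px` and optionally `trial_index`.
#' @param smooth_n Number of samples of the trailing mean.
#' @return A data frame with one row per instantaneous value (aligned to the
#'   second sample of each step): `time_s`, `instantaneous`, `speed` (the
#'   smoothed series) and, when present in the input, `trial_index`.
#' @export
compute_online_speed <- function(trace, smooth_n = 6) {
  if (nrow(trace) < 2L) abort_invalid("`trace` needs at least 2 samples")
  dtv <- diff(trace$time_s)
  if (any(dtv <= 0)) {
    abort_invalid("`trace` timestamps must be strictly increasing")
  }
  inst <- sqrt(diff(trace$x_px)^2 + diff(trace$y_px)^2) / dtv
  cs <- cumsum(inst)
  k <- seq_along(inst)
  sm <- cs / k
  full <- k > smooth_n
  sm[full] <- (cs[full] - cs[k[full] - smooth_n]) / smooth_n
  out <- data.frame(time_s = trace$time_s[-1L], instantaneous = inst,
                    speed = sm)
  if ("trial_index" %in% names(trace)) {
    out$trial_index <- trace$trial_index[-1L]
  }
  out
}

#' Online peak detection by three decreasing speed values
#'
#' Streaming rule of the real-time controller: the peak of the ongoing
#' movement is declared at the first sample completing a strictly decreasing
#' run of three consecutive speed values lying entirely after the running
#' maximum; the online peak speed is the maximum of all samples seen so far.
#' Ties interrupt the decreasing run. Fires at most once; a movement may end
#' without a detection.
#'
#' @param speed Smoothed speed samples of one movement, in stream order.
#' @return `NULL` if no detection, else a list with `index` (the detecting
#'   sample), `peak_index` and `peak` (the online peak speed).
#' @export
detect_peak_three_decreasing <- function(speed) {
  n <- length(speed)
  if (n < 4L) return(NULL)
  pk <- 1L
  for (i in 2:n) {
    if (speed[i] > speed[pk]) pk <- i
    if (i >= 3L && (i - 2L) > pk &&
        speed[i - 2L] > speed[i - 1L] && speed[i - 1L] > speed[i]) {
      return(list(index = i, peak_index = pk, peak = speed[pk]))
    }
  }
  NULL
}

#' Calibrate the peak-time readout threshold
#'
#' For the timer-based detector variant: returns the q-th percentile (linear
#' interpolation between order statistics) of peak latencies measured during
#' familiarization; downstream, the online peak is read out once the elapsed
#' time since movement initiation reaches this threshold.
#'
#' @param latencies Peak latencies (seconds) of the familiarization trials.
#' @param q Percentile in (0, 100); default 80.
#' @return The latency threshold in seconds.
#' @export
calibrate_peak_time_percentile <- function(latencies, q = 80) {
  latencies <- latencies[!is.na(latencies)]
  if (length(latencies) == 0L) {
    abort_invalid("`latencies` must contain at least 2 values")
  }
  if (length(latencies) < 2L) {
    abort_invalid("`latencies` must contain at least 2 values")
  }
  if (q <= 0 || q >= 100) abort_invalid("`q` must lie strictly in (0, 100)")
  if (length(latencies) < 32L) {
    warning(sprintf(
      "peak-time percentile calibrated on %d latencies (the standard protocol uses 32 familiarization trials)",
      length(latencies)), call. = FALSE)
  }
  unname(stats::quantile(latencies, q / 100, type = 7))
}

#' Two-back fast/slow classification
#'
#' A movement is `fast` if its peak speed strictly exceeds both of the
#' previous two peak speeds, `slow` if it falls strictly below both, and
#' `intermediate` otherwise (ties included). With fewer than two preceding
#' movements in scope the movement is `unclassified`.
#'
#' @param peak Peak speed of the ongoing movement (pixels/s).
#' @param prev1,prev2 Peak speeds of the previous two movements; `NA` when
#'   missing.
#' @return A list with `label` and `reference_peaks`.
#' @export
classify_speed <- function(peak, prev1, prev2) {
  if (is.na(prev1) || is.na(prev2)) {
    return(list(label = "unclassified", reference_peaks = c(prev1, prev2)))
  }
  if (!all(is.finite(c(peak, prev1, prev2))) || any(c(peak, prev1, prev2) <= 0)) {
    abort_invalid("peak speeds must be finite and positive")
  }
  label <- if (peak > max(prev1, prev2)) "fast"
           else if (peak < min(prev1, prev2)) "slow" else "intermediate"
  list(label = label, reference_peaks = c(prev1, prev2))
}

#' Run the closed-loop controller over a session trace
#'
#' Emulates the real-time pipeline movement by movement: six-sample smoothed
#' speed, arming of the peak detector once the smoothed speed exceeds the
#' movement threshold, online peak detection (three-decreasing rule or
#' percentile-timer), two-back classification against the previous two
#' online peaks (reset at each block boundary), and scheduling of one
#' stimulation burst at detection time whenever the label matches the
#' block's target condition in a stimulation block. If a movement ends
#' without a detection its online peak is read out at movement end (maximum
#' smoothed speed) for classification bookkeeping, but no burst is emitted.
#'
#' @param trace Cursor trace with `time_s`, `x_px`, `y_px`, `trial_index`.
#' @param protocol A [stim_protocol()].
#' @param detector `"three_decreasing"` or `"percentile_time"`.
#' @param arm_threshold Smoothed speed (pixels/s) that arms the detector;
#'   defaults to the standard movement threshold.
#' @param peak_time_threshold Latency threshold in seconds (required for the
#'   `"percentile_time"` detector; see [calibrate_peak_time_percentile()]).
#' @return A list of class `kinestim_session`: `movements` (one row per
#'   movement with online peak, detection time, label, stimulated flag) and
#'   `stim_events` (block, movement, start time, duration).
#' @export
run_closed_loop_session <- function(trace, protocol = stim_protocol(),
                                    detector = c("three_decreasing",
                                                 "percentile_time"),
                                    arm_threshold = 800.77,
                                    peak_time_threshold = NULL) {
  detector <- match.arg(detector)
  if (detector == "percentile_time" && is.null(peak_time_threshold)) {
    abort_invalid("`peak_time_threshold` is required for the percentile_time detector")
  }
  n_needed <- protocol$n_blocks * protocol$block_length
  if (max(trace$trial_index) < n_needed) {
    abort_invalid(sprintf(
      "trace covers %d movements but the protocol requires %d",
      max(trace$trial_index), n_needed))
  }
  sp <- compute_online_speed(trace)
  idx_by_trial <- split(seq_len(nrow(sp)), sp$trial_index)
  x_by_trial <- split(trace$x_px, trace$trial_index)
  cond <- condition_of_blocks(protocol)

  rows <- vector("list", n_needed)
  events <- list()
  prev1 <- prev2 <- NA_real_
  for (i in seq_len(n_needed)) {
    b <- ((i - 1L) %/% protocol$block_length) + 1L
    k <- i - (b - 1L) * protocol$block_length
    if (k == 1L) prev1 <- prev2 <- NA_real_
    ii <- idx_by_trial[[as.character(i)]]
    v <- sp$speed[ii]
    tt <- sp$time_s[ii]
    arm <- which(v > arm_threshold)[1L]
    detected <- FALSE
    detection_time <- NA_real_
    online_peak <- max(v)
    if (!is.na(arm)) {
      if (detector == "three_decreasing") {
        d <- detect_peak_three_decreasing(v[arm:length(v)])
        if (!is.null(d)) {
          detected <- TRUE
          detection_time <- tt[arm + d$index - 1L]
          online_peak <- d$peak
        }
      } else {
        j <- which(tt - tt[arm] >= peak_time_threshold)[1L]
        if (!is.na(j)) {
          detected <- TRUE
          detection_time <- tt[j]
          online_peak <- max(v[arm:j])
        }
      }
    }
    label <- if (is.na(prev1) || is.na(prev2)) "unclassified"
             else if (online_peak > max(prev1, prev2)) "fast"
             else if (online_peak < min(prev1, prev2)) "slow"
             else "intermediate"
    stim <- detected && as.character(b) %in% names(cond) &&
      label == cond[[as.character(b)]]
    if (stim) {
      events[[length(events) + 1L]] <- data.frame(
        block = b, movement = i, start_time = detection_time,
        duration = protocol$burst_duration)
    }
    xs <- x_by_trial[[as.character(i)]]
    rows[[i]] <- data.frame(
      movement = i, block = b, index_in_block = k,
      direction = if (xs[length(xs)] >= xs[1L]) "left_to_right" else "right_to_left",
      online_peak = online_peak, detected = detected,
      detection_time = detection_time, label = label, stimulated = stim)
    prev2 <- prev1
    prev1 <- online_peak
  }
  stim_events <- if (length(events)) do.call(rbind, events) else
    data.frame(block = integer(0), movement = integer(0),
               start_time = numeric(0), duration = numeric(0))
  structure(
    list(movements = do.call(rbind, rows), stim_events = stim_events,
         protocol = protocol, detector = detector,
         arm_threshold = arm_threshold),
    class = "kinestim_session"
  )
}

#' Audit the controller against ground truth
#'
#' Compares the online labels with labels recomputed offline from the true
#' peak speeds (same two-back rule, same per-block reset) and summarises the
#' controller's behaviour.
#'
#' @param session A `kinestim_session` from [run_closed_loop_session()].
#' @param truth The ground-truth table of the generating `kinestim_sim`.
#' @return A list with `accuracy` (agreement on classified movements),
#'   `coverage` (stimulated fraction per block), `mean_latency_s` (detection
#'   time minus true peak time), `total_stim_time_s` and the per-movement
#'   comparison table.
#' @export
evaluate_controller <- function(session, truth) {
  mv <- session$movements
  if (nrow(mv) > nrow(truth) ||
      !all(mv$movement == truth$movement[seq_len(nrow(mv))])) {
    abort_invalid("session and ground truth are misaligned")
  }
  truth <- truth[seq_len(nrow(mv)), , drop = FALSE]
  offline <- unlist(lapply(split(truth$true_peak_speed, mv$block),
                           two_back_labels), use.names = FALSE)
  classified <- mv$label != "unclassified"
  accuracy <- mean(mv$label[classified] == offline[classified])
  coverage <- tapply(mv$stimulated, mv$block, mean)
  lat <- mv$detection_time - truth$true_peak_time
  list(
    accuracy = accuracy,
    coverage = coverage,
    mean_latency_s = mean(lat[mv$detected], na.rm = TRUE),
    total_stim_time_s = sum(session$stim_events$duration),
    n_stim = nrow(session$stim_events),
    comparison = data.frame(movement = mv$movement, block = mv$block,
                            online = mv$label, offline = offline,
                            stimulated = mv$stimulated)
  )
}

#' Expected active stimulation time per block
#'
#' Burst duration times block length times the stimulated fraction of
#' movements, averaged over the supplied per-condition fractions.
#'
#' @param protocol A [stim_protocol()].
#' @param stim_fractions Stimulated fractions of movements, one per
#'   condition.
#' @return Expected stimulation time per stimulation block, in seconds.
#' @export
stim_time_budget <- function(protocol = stim_protocol(),
                             stim_fractions) {
  if (length(stim_fractions) == 0L || any(stim_fractions < 0 | stim_fractions > 1)) {
    abort_invalid("`stim_fractions` must be proportions in [0, 1]")
  }
  protocol$burst_duration * protocol$block_length * mean(stim_fractions)
}
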
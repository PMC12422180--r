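# Offline behavioural pipeline: movement bounds, average speed, block-level
# speed-change normalisation and the direction-resolved post-stimulation
# speed shift.

#' Rest-based movement threshold
#'
#' The movement threshold is defined as `mean + sd_multiplier * SD` of the
#' speed during the intertrial rest periods, pooled over trials (and, in a
#' cohort, over subjects).
#'
#' @param rest_speeds Pooled rest-period speed samples (pixels/s), e.g. from
#'   [extract_rest_speeds()].
#' @param sd_multiplier SD multiplier (default 3).
#' @return The threshold in pixels/s.
#' @export
compute_rest_threshold <- function(rest_speeds, sd_multiplier = 3) {
  rest_speeds <- rest_speeds[is.finite(rest_speeds)]
  if (length(rest_speeds) == 0L) {
    abort_invalid("no rest-period speed samples supplied")
  }
  mean(rest_speeds) + sd_multiplier * stats::sd(rest_speeds)
}

#' Extract rest-period speeds from a trace
#'
#' Instantaneous speeds during the last `rest_window` seconds before each
#' movement onset, for pooling into [compute_rest_threshold()].
#'
#' @param trace A cursor trace.
#' @param onsets Movement onset times in seconds (e.g. `truth$onset_s`).
#' @param rest_window Rest window length in seconds.
#' @return A numeric vector of pooled rest speeds.
#' @export
extract_rest_speeds <- function(trace, onsets, rest_window = 0.300) {
  sp <- compute_online_speed(trace)
  keep <- rep(FALSE, nrow(sp))
  for (t0 in onsets) {
    keep <- keep | (sp$time_s >= t0 - rest_window & sp$time_s < t0)
  }
  sp$instantaneous[keep]
}

#' Movement onset and offset around the peak
#'
#' Centred on the peak sample, onset and offset are the first and last
#' samples of the contiguous above-threshold run containing the peak
#' (scanning outward from the peak, the last samples still above threshold
#' before the first sub-threshold sample on each side). Samples outside that
#' run -- e.g. secondary sub-movements -- are excluded.
#'
#' @param speed Speed series of one trial (pixels/s).
#' @param peak_index Index of the peak-speed sample.
#' @param threshold Movement threshold in pixels/s.
#' @return A named integer vector `c(onset, offset)`.
#' @export
detect_movement_bounds <- function(speed, peak_index, threshold) {
  if (peak_index < 1L || peak_index > length(speed)) {
    abort_invalid("`peak_index` out of range")
  }
  if (speed[peak_index] <= threshold) {
    stop(errorCondition("peak speed does not exceed the movement threshold",
                        class = c("kinestim_no_movement", "kinestim_error")))
  }
  above <- speed > threshold
  onset <- peak_index
  while (onset > 1L && above[onset - 1L]) onset <- onset - 1L
  offset <- peak_index
  while (offset < length(speed) && above[offset + 1L]) offset <- offset + 1L
  c(onset = onset, offset = offset)
}

#' Per-movement average speeds from a trace
#'
#' For every trial: the six-sample smoothed speed within the trial (the same
#' readout the online algorithm classifies on), the peak sample, movement
#' bounds via [detect_movement_bounds()], and the average speed between
#' onset and offset (the main behavioural outcome). Movements whose peak
#' never exceeds the movement threshold yield `NA`.
#'
#' @param trace A cursor trace with `trial_index`.
#' @param thresholds A [speed_thresholds()].
#' @return A data frame with one row per movement: `movement`, `direction`,
#'   `peak_speed` (offline peak of the smoothed series), `avg_speed`,
#'   `onset_s`, `offset_s`.
#' @export
movement_average_speeds <- function(trace, thresholds = speed_thresholds()) {
  trials <- split(seq_len(nrow(trace)), trace$trial_index)
  out <- lapply(names(trials), function(tr) {
    ii <- trials[[tr]]
    seg <- trace[ii, , drop = FALSE]
    if (nrow(seg) < 2L) {
      return(data.frame(movement = as.integer(tr), direction = NA_character_,
                        peak_speed = NA_real_, avg_speed = NA_real_,
                        onset_s = NA_real_, offset_s = NA_real_))
    }
    sp <- compute_online_speed(seg)
    pk <- which.max(sp$speed)
    direction <- if (seg$x_px[nrow(seg)] >= seg$x_px[1L]) "left_to_right"
                 else "right_to_left"
    if (sp$speed[pk] <= thresholds$movement_threshold) {
      return(data.frame(movement = as.integer(tr), direction = direction,
                        peak_speed = sp$speed[pk], avg_speed = NA_real_,
                        onset_s = NA_real_, offset_s = NA_real_))
    }
    b <- detect_movement_bounds(sp$speed, pk, thresholds$movement_threshold)
    data.frame(movement = as.integer(tr), direction = direction,
               peak_speed = sp$speed[pk],
               avg_speed = mean(sp$speed[b["onset"]:b["offset"]]),
               onset_s = sp$time_s[b["onset"]], offset_s = sp$time_s[b["offset"]])
  })
  out <- do.call(rbind, out)
  out[order(out$movement), , drop = FALSE]
}

#' Block-level percent speed change
#'
#' Average speeds above the outlier threshold become missing; speeds are
#' normalised to the mean of the block's first five movements (or to an
#' external baseline, e.g. the preceding stimulation block's for a recovery
#' block) by subtracting and dividing, yielding percent change from block
#' start. The first five trials are excluded from the returned series.
#'
#' @param avg_speeds Average movement speeds of one block (pixels/s).
#' @param thresholds A [speed_thresholds()].
#' @param baseline_value Optional external baseline (pixels/s); if `NULL`
#'   the block's own first-five mean is used.
#' @return A list with `percent_change` (trials 6..n, `NA` for outliers),
#'   `trials`, `baseline`, `block_mean` (missing-value aware) and
#'   `n_outliers`.
#' @export
block_speed_change <- function(avg_speeds, thresholds = speed_thresholds(),
                               baseline_value = NULL) {
  n <- length(avg_speeds)
  if (n < 6L) abort_invalid("a block needs at least 6 movements")
  v <- avg_speeds
  out <- !is.na(v) & v > thresholds$outlier_threshold
  v[out] <- NA_real_
  b <- if (!is.null(baseline_value)) baseline_value else
    mean(v[1:5], na.rm = TRUE)
  if (!is.finite(b) || b == 0) {
    abort_invalid("block baseline is undefined (zero or all-missing first five)")
  }
  change <- 100 * (v - b) / b
  list(percent_change = change[6:n], trials = 6:n, baseline = b,
       block_mean = mean(change[6:n], na.rm = TRUE),
       n_outliers = sum(out))
}

#' Session-level speed-change summary
#'
#' Applies [block_speed_change()] to every block of a session. A recovery
#' block (a non-stimulation block immediately following a stimulation
#' block) is normalised to the first-five baseline of that preceding
#' stimulation block; all other blocks use their own baseline.
#'
#' @param movements Data frame with columns `block` and `avg_speed` (one row
#'   per movement, in order).
#' @param protocol A [stim_protocol()] or `NULL` (every block then uses its
#'   own baseline, as for healthy controls).
#' @param thresholds A [speed_thresholds()].
#' @return A list with `per_trial` (block, trial, percent_change) and
#'   `block_means` (block, block_mean, baseline, n_outliers).
#' @export
session_speed_change <- function(movements, protocol = NULL,
                                 thresholds = speed_thresholds()) {
  blocks <- sort(unique(movements$block))
  stim_blocks <- if (is.null(protocol)) integer(0) else protocol$stim_blocks
  baselines <- list()
  per_trial <- list()
  block_means <- list()
  for (b in blocks) {
    v <- movements$avg_speed[movements$block == b]
    ext <- NULL
    if (!(b %in% stim_blocks) && (b - 1L) %in% stim_blocks &&
        !is.null(baselines[[as.character(b - 1L)]])) {
      ext <- baselines[[as.character(b - 1L)]]
    }
    res <- block_speed_change(v, thresholds, baseline_value = ext)
    baselines[[as.character(b)]] <- res$baseline
    per_trial[[as.character(b)]] <- data.frame(
      block = b, trial = res$trials, percent_change = res$percent_change)
    block_means[[as.character(b)]] <- data.frame(
      block = b, block_mean = res$block_mean, baseline = res$baseline,
      n_outliers = res$n_outliers)
  }
  list(per_trial = do.call(rbind, per_trial),
       block_means = do.call(rbind, block_means))
}

#' Direction-resolved post-stimulation speed shift
#'
#' For every stimulated movement k the percent change of the two following
#' movements relative to the stimulated one is computed:
#' `100 * (v[k+j] - v[k]) / v[k]` for followers j = 1 (opposite direction,
#' since targets alternate) and j = 2 (same direction). The identical
#' quantity is computed for not-stimulated reference movements of the same
#' speed class, identified post hoc in the paired recovery block with the
#' same two-back rule on offline peak speeds. The shift is the stimulated
#' mean change minus the reference mean change, per condition and follower
#' position. Followers crossing a block boundary are dropped; cells without
#' reference movements are reported as `NA`, not zero.
#'
#' @param movements Data frame with one row per movement in session order:
#'   `block`, `direction`, `stimulated`, `peak_speed`, `avg_speed`.
#' @param protocol A [stim_protocol()]; stimulation block b is paired with
#'   recovery block b + 1.
#' @param thresholds A [speed_thresholds()] (outlier rule applied to the
#'   average speeds before computing changes).
#' @return A data frame of class `kinestim_shift` with one row per condition
#'   and relative direction: `condition`, `relative_direction`, `shift`,
#'   `mean_change_stim`, `mean_change_ref`, `n_stim`, `n_ref`.
#' @export
poststim_speed_shift <- function(movements, protocol = stim_protocol(),
                                 thresholds = speed_thresholds()) {
  v <- movements$avg_speed
  v[!is.na(v) & v > thresholds$outlier_threshold] <- NA_real_
  cond <- condition_of_blocks(protocol)

  follower_changes <- function(rows_in_block, anchors) {
    # returns matrix with columns ch1 (k+1) and ch2 (k+2), NA when missing
    sapply(c(1L, 2L), function(j) {
      vapply(anchors, function(k) {
        kj <- k + j
        if (kj > length(rows_in_block)) return(NA_real_)
        vk <- v[rows_in_block[k]]
        vj <- v[rows_in_block[kj]]
        if (is.na(vk) || is.na(vj) || vk == 0) return(NA_real_)
        100 * (vj - vk) / vk
      }, numeric(1))
    })
  }

  out <- list()
  for (b in protocol$stim_blocks) {
    c_b <- cond[[as.character(b)]]
    r <- b + 1L
    rows_stim <- which(movements$block == b)
    rows_rec <- which(movements$block == r)
    anchors_stim <- which(movements$stimulated[rows_stim])
    ch_stim <- if (length(anchors_stim))
      follower_changes(rows_stim, anchors_stim) else
      matrix(numeric(0), ncol = 2)
    if (length(rows_rec)) {
      rec_labels <- two_back_labels(movements$peak_speed[rows_rec])
      anchors_rec <- which(rec_labels == c_b)
      ch_rec <- if (length(anchors_rec))
        follower_changes(rows_rec, anchors_rec) else
        matrix(numeric(0), ncol = 2)
    } else {
      ch_rec <- matrix(numeric(0), ncol = 2)
    }
    for (j in c(1L, 2L)) {
      ms <- if (nrow(ch_stim)) mean(ch_stim[, j], na.rm = TRUE) else NA_real_
      mr <- if (nrow(ch_rec)) mean(ch_rec[, j], na.rm = TRUE) else NA_real_
      out[[length(out) + 1L]] <- data.frame(
        condition = c_b,
        relative_direction = if (j == 1L) "opposite" else "same",
        shift = if (is.na(ms) || is.na(mr)) NA_real_ else ms - mr,
        mean_change_stim = ms, mean_change_ref = mr,
        n_stim = if (nrow(ch_stim)) sum(!is.na(ch_stim[, j])) else 0L,
        n_ref = if (nrow(ch_rec)) sum(!is.na(ch_rec[, j])) else 0L)
    }
  }
  res <- do.call(rbind, out)
  class(res) <- c("kinestim_shift", class(res))
  res
}

#' Assemble the per-movement behavioural table of a session
#'
#' Joins the controller output with the offline kinematic measures of the
#' trace into the table consumed by [session_speed_change()] and
#' [poststim_speed_shift()].
#'
#' @param session A `kinestim_session` from [run_closed_loop_session()].
#' @param trace The cursor trace the session was run on.
#' @param thresholds A [speed_thresholds()].
#' @return A data frame with `movement`, `block`, `index_in_block`,
#'   `direction`, `label`, `stimulated`, `online_peak`, `peak_speed`
#'   (offline), `avg_speed`, `onset_s`, `offset_s`.
#' @export
session_movements <- function(session, trace,
                              thresholds = speed_thresholds()) {
  beh <- movement_average_speeds(trace, thresholds)
  mv <- session$movements
  beh <- beh[match(mv$movement, beh$movement), , drop = FALSE]
  data.frame(mv[, c("movement", "block", "index_in_block", "direction",
                    "label", "stimulated", "online_peak")],
             peak_speed = beh$peak_speed, avg_speed = beh$avg_speed,
             onset_s = beh$onset_s, offset_s = beh$offset_s)
}
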
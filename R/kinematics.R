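# Synthetic cursor kinematics: minimum-jerk reaches with a bradykinetic
# decrement, lognormal peak-speed noise and an injectable reinforcement
# effect of stimulation on the next same-direction movement.

# Sample times in [from, until) at nominal spacing dt, optionally with
# uniform interval jitter. Returns the times plus the first sample time of
# the following segment as attribute "next_time".
sample_times <- function(from, until, dt, jitter = 0) {
  if (jitter <= 0) {
    n <- max(0L, floor((until - from - 1e-12) / dt) + 1L)
    ts <- from + dt * (seq_len(n) - 1L)
    attr(ts, "next_time") <- from + dt * n
    return(ts)
  }
  ts <- numeric(0)
  t <- from
  while (t < until - 1e-12) {
    ts <- c(ts, t)
    t <- t + dt * (1 + stats::runif(1L, -jitter, jitter))
  }
  attr(ts, "next_time") <- t
  ts
}

#' Generate synthetic cursor kinematics for a target sequence
#'
#' Simulates one session of reaching movements. Each movement follows a
#' minimum-jerk speed profile (speed proportional to `tau^2 (1-tau)^2` on the
#' normalised movement span) aimed at its target; the true peak speed of the
#' i-th movement of a block is `peak_speed_start * (1 - decrement_rate)^(i-1)`
#' times multiplicative lognormal noise. When a stimulation protocol is
#' supplied, the generator runs an idealised two-back classifier on the true
#' peak speeds, flags stimulated movements, and multiplies the target peak
#' speed of the next same-direction movement (two movements ahead, as targets
#' alternate) by `1 + reinforcement_delta * sign(v_k - trend_k)`.
#'
#' Movements are separated by rest segments of the geometry's inter-movement
#' interval during which the cursor holds its position; each trial consists
#' of its preceding rest segment plus the movement. Additive Gaussian
#' position noise is applied to the emitted samples only, so the ground
#' truth refers to the noiseless profile.
#'
#' @param targets A target sequence from [generate_target_sequence()].
#' @param model A [kinematics_model()].
#' @param protocol A [stim_protocol()] or `NULL` (no stimulation).
#' @param seed Optional integer seed.
#' @return A list of class `kinestim_sim` with elements `trace` (data frame
#'   `time_s`, `x_px`, `y_px`, `trial_index`) and `truth` (one row per
#'   movement: true peak speed/time, onset/offset, direction, decrement
#'   trend, noise and reinforcement bookkeeping, stimulated flag).
#' @export
generate_kinematics <- function(targets, model = kinematics_model(),
                                protocol = NULL, seed = NULL) {
  if (is.null(targets) || nrow(targets) == 0L) {
    abort_invalid("`targets` must contain at least one movement")
  }
  geometry <- attr(targets, "geometry")
  if (is.null(geometry)) geometry <- task_geometry()
  n <- nrow(targets)
  if (n > 1L && any(sign(diff(targets$x - (geometry$target_x_left +
                                           geometry$target_x_right) / 2)) == 0)) {
    abort_invalid("`targets` must alternate between the two screen sides")
  }

  with_seed(seed, {
    dt <- 1 / model$sample_rate
    imi <- geometry$inter_movement_interval
    block <- if ("block" %in% names(targets)) targets$block else rep(1L, n)
    idx_in_block <- stats::ave(seq_len(n), block, FUN = seq_along)
    trend <- model$peak_speed_start *
      (1 - model$decrement_rate)^(idx_in_block - 1)
    durations <- pmax(stats::rnorm(n, model$duration_mean, model$duration_sd), 0.2)
    noise <- rlnorm_cv(n, model$noise_cv)
    reinf <- rep(1, n)
    injected_sign <- rep(0, n)
    stimulated <- logical(n)
    cond <- condition_of_blocks(protocol)

    v <- numeric(n)
    prev1 <- prev2 <- NA_real_
    cur_block <- -1L
    for (i in seq_len(n)) {
      if (block[i] != cur_block) {
        prev1 <- prev2 <- NA_real_
        cur_block <- block[i]
      }
      v[i] <- trend[i] * noise[i] * reinf[i]
      if (!is.null(protocol) && as.character(block[i]) %in% names(cond) &&
          !is.na(prev1) && !is.na(prev2)) {
        lab <- if (v[i] > max(prev1, prev2)) "fast"
               else if (v[i] < min(prev1, prev2)) "slow" else "intermediate"
        if (lab == cond[[as.character(block[i])]]) {
          stimulated[i] <- TRUE
          j <- i + 2L
          if (j <= n && block[j] == block[i]) {
            s <- sign(v[i] - trend[i])
            reinf[j] <- reinf[j] * (1 + model$reinforcement_delta * s)
            injected_sign[j] <- s
          }
        }
      }
      prev2 <- prev1
      prev1 <- v[i]
    }

    pos <- c(targets$start_x[1L], targets$start_y[1L])
    t_s <- 0
    t_move_end <- 0
    traces <- vector("list", n)
    onset <- offset <- peak_time <- amplitude <- numeric(n)
    for (i in seq_len(n)) {
      t0 <- t_move_end + imi
      t1 <- t0 + durations[i]
      D <- v[i] * durations[i] * 16 / 30  # min-jerk: peak speed = 1.875 D / T
      tgt <- c(targets$x[i], targets$y[i])
      dvec <- tgt - pos
      u <- dvec / sqrt(sum(dvec^2))
      times_i <- sample_times(t_s, t1, dt, model$sampling_jitter)
      t_s <- attr(times_i, "next_time")
      tau <- pmin(pmax((times_i - t0) / durations[i], 0), 1)
      s <- D * (10 * tau^3 - 15 * tau^4 + 6 * tau^5)
      traces[[i]] <- data.frame(
        time_s = as.numeric(times_i),
        x_px = pos[1L] + u[1L] * s,
        y_px = pos[2L] + u[2L] * s,
        trial_index = i
      )
      onset[i] <- t0
      offset[i] <- t1
      peak_time[i] <- t0 + durations[i] / 2
      amplitude[i] <- D
      pos <- pos + u * D
      t_move_end <- t1
    }
    trace <- do.call(rbind, traces)
    rownames(trace) <- NULL
    if (model$position_noise_sd > 0) {
      trace$x_px <- trace$x_px + stats::rnorm(nrow(trace), 0, model$position_noise_sd)
      trace$y_px <- trace$y_px + stats::rnorm(nrow(trace), 0, model$position_noise_sd)
    }
    truth <- data.frame(
      movement = seq_len(n),
      block = block,
      index_in_block = idx_in_block,
      direction = targets$direction,
      target_x = targets$x, target_y = targets$y,
      duration_s = durations,
      onset_s = onset, offset_s = offset,
      true_peak_time = peak_time,
      true_peak_speed = v,
      trend = trend,
      noise_factor = noise,
      reinforcement_factor = reinf,
      injected_sign = injected_sign,
      amplitude_px = amplitude,
      stimulated = stimulated
    )
    structure(
      list(trace = trace, truth = truth),
      class = "kinestim_sim",
      model = model, protocol = protocol, geometry = geometry, seed = seed
    )
  })
}

#' Simulate a complete session
#'
#' Convenience wrapper chaining [generate_target_sequence()] and
#' [generate_kinematics()] for a full session laid out by a protocol.
#'
#' @param seed Integer seed.
#' @param model A [kinematics_model()].
#' @param protocol A [stim_protocol()] or `NULL`.
#' @param geometry A [task_geometry()].
#' @param n_movements Number of movements; defaults to the protocol's
#'   `n_blocks * block_length` (or one 96-movement block without protocol).
#' @return A `kinestim_sim` (see [generate_kinematics()]).
#' @export
simulate_session <- function(seed = NULL, model = kinematics_model(),
                             protocol = stim_protocol(),
                             geometry = task_geometry(),
                             n_movements = NULL) {
  block_length <- if (is.null(protocol)) 96L else protocol$block_length
  if (is.null(n_movements)) {
    n_movements <- if (is.null(protocol)) 96L else
      protocol$n_blocks * protocol$block_length
  }
  targets <- generate_target_sequence(n_movements, geometry, seed = seed,
                                      block_length = block_length)
  generate_kinematics(targets, model, protocol, seed = if (is.null(seed))
    NULL else seed + 1L)
}

#' Generate a null cohort for type-I error assessment
#'
#' Produces per-subject pairs of condition summaries (block-mean percent
#' speed change) drawn from identical generating distributions: both
#' "conditions" use the same kinematics model with the reinforcement effect
#' forced to zero, so any paired test applied to the cohort operates under
#' an exact null.
#'
#' @param n_subjects Number of subjects (at least 2).
#' @param model A [kinematics_model()]; a nonzero `reinforcement_delta` is
#'   forced to 0 with a warning.
#' @param seed Optional integer seed.
#' @param block_length Movements per simulated block.
#' @param thresholds A [speed_thresholds()] used for the block normalisation.
#' @return A data frame of class `kinestim_null_cohort` with columns
#'   `subject`, `cond_a`, `cond_b`.
#' @export
generate_null_cohort <- function(n_subjects, model = kinematics_model(),
                                 seed = NULL, block_length = 96,
                                 thresholds = speed_thresholds()) {
  if (!is.numeric(n_subjects) || length(n_subjects) != 1L || n_subjects < 2) {
    abort_invalid("`n_subjects` must be at least 2")
  }
  n_subjects <- as.integer(n_subjects)
  if (model$reinforcement_delta != 0) {
    warning("`reinforcement_delta` forced to 0 for the null cohort",
            call. = FALSE)
    model$reinforcement_delta <- 0
  }
  with_seed(seed, {
    m <- as.integer(block_length)
    trend <- model$peak_speed_start * (1 - model$decrement_rate)^(0:(m - 1L))
    f <- matrix(rlnorm_cv(m * 2L * n_subjects, model$noise_cv), nrow = m)
    speeds <- trend * f
    summ <- vapply(seq_len(ncol(speeds)), function(j) {
      block_speed_change(speeds[, j], thresholds)$block_mean
    }, numeric(1))
    out <- data.frame(
      subject = seq_len(n_subjects),
      cond_a = summ[seq(1L, by = 2L, length.out = n_subjects)],
      cond_b = summ[seq(2L, by = 2L, length.out = n_subjects)]
    )
    class(out) <- c("kinestim_null_cohort", class(out))
    out
  })
}

#' Noiseless trimmed average speed of a minimum-jerk movement
#'
#' The average speed the offline pipeline would measure for a noiseless
#' minimum-jerk movement with peak speed `v`: the profile is sampled at the
#' cursor rate, smoothed with the trailing six-sample mean, trimmed at the
#' movement threshold, and averaged -- the same operator the analysis
#' applies to recorded traces. Averaged over sampling phases so the map is
#' smooth in `v`. Set `sample_rate = NULL` for the continuum profile
#' without smoothing.
#'
#' @param v Peak speeds (pixels/s).
#' @param duration Movement durations (seconds), recycled against `v`.
#' @param threshold Movement threshold (pixels/s).
#' @param sample_rate Cursor sampling rate (Hz), or `NULL` for the
#'   continuum limit.
#' @param smooth_n Trailing-mean window of the speed readout.
#' @param n_phases Sampling phases averaged over.
#' @return Average speeds; `NA` where the peak does not exceed the
#'   threshold.
#' @export
minjerk_trimmed_average <- function(v, duration = 0.812, threshold = 800.77,
                                    sample_rate = 62, smooth_n = 6,
                                    n_phases = 8) {
  duration <- rep_len(duration, length(v))
  if (is.null(sample_rate)) {
    tau <- seq(0, 1, length.out = 4001)
    g <- 16 * tau^2 * (1 - tau)^2
    return(vapply(v, function(vi) {
      if (is.na(vi) || vi <= threshold) return(NA_real_)
      sel <- vi * g > threshold
      vi * mean(g[sel])
    }, numeric(1)))
  }
  dt <- 1 / sample_rate
  one <- function(vi, Ti) {
    if (is.na(vi) || is.na(Ti)) return(NA_real_)
    vals <- vapply(seq_len(n_phases), function(ph) {
      tt <- seq(-smooth_n * dt + (ph - 1) * dt / n_phases, Ti, by = dt)
      tau <- pmin(pmax(tt / Ti, 0), 1)
      s <- vi * 16 * tau^2 * (1 - tau)^2
      cs <- cumsum(s)
      k <- seq_along(s)
      sm <- cs / k
      full <- k > smooth_n
      sm[full] <- (cs[full] - cs[k[full] - smooth_n]) / smooth_n
      sel <- sm > threshold
      if (!any(sel)) return(NA_real_)
      mean(sm[sel])
    }, numeric(1))
    if (all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE)
  }
  vapply(seq_along(v), function(i) one(v[i], duration[i]), numeric(1))
}

#' Realized injected effect on the post-stimulation change statistic
#'
#' Computes, from generator ground truth, the causal effect of the injected
#' reinforcement on the follower-change statistic that
#' [poststim_speed_shift()] estimates: for every stimulated movement the
#' percent change of its followers on the noiseless measured-average-speed
#' scale ([minjerk_trimmed_average()]) is compared between the realized
#' world and the counterfactual world with all reinforcement factors
#' removed. Chain effects (a stimulated anchor that itself carries an
#' earlier injection) are therefore part of the target, which is what makes
#' this the correct recovery benchmark.
#'
#' @param truth Ground-truth table of a `kinestim_sim`; its `stimulated`
#'   column defines the anchor set (replace it with the controller's flags
#'   to benchmark the analyzed sample).
#' @param protocol The [stim_protocol()] used for the simulation.
#' @param thresholds A [speed_thresholds()] (movement threshold of the
#'   average-speed map).
#' @param sample_rate Cursor sampling rate of the measurement operator.
#' @return A data frame with `condition`, `relative_direction`, `target`
#'   (percent points) and `n` anchors.
#' @export
injected_change_targets <- function(truth, protocol = stim_protocol(),
                                    thresholds = speed_thresholds(),
                                    sample_rate = 62) {
  cond <- condition_of_blocks(protocol)
  a_obs <- minjerk_trimmed_average(truth$true_peak_speed, truth$duration_s,
                                   thresholds$movement_threshold,
                                   sample_rate = sample_rate)
  a_cf <- minjerk_trimmed_average(
    truth$true_peak_speed / truth$reinforcement_factor, truth$duration_s,
    thresholds$movement_threshold, sample_rate = sample_rate)
  out <- list()
  for (b in protocol$stim_blocks) {
    rows <- which(truth$block == b)
    anchors <- which(truth$stimulated[rows])
    for (j in c(1L, 2L)) {
      dd <- vapply(anchors, function(k) {
        if (k + j > length(rows)) return(NA_real_)
        ko <- rows[k]; fo <- rows[k + j]
        if (any(is.na(c(a_obs[ko], a_obs[fo], a_cf[ko], a_cf[fo])))) {
          return(NA_real_)
        }
        100 * (a_obs[fo] - a_obs[ko]) / a_obs[ko] -
          100 * (a_cf[fo] - a_cf[ko]) / a_cf[ko]
      }, numeric(1))
      out[[length(out) + 1L]] <- data.frame(
        condition = cond[[as.character(b)]],
        relative_direction = if (j == 1L) "opposite" else "same",
        target = mean(dd, na.rm = TRUE),
        n = sum(!is.na(dd)))
    }
  }
  do.call(rbind, out)
}
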
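# Artifact-aware event-related spectral analysis: referencing, epoching,
# Morlet time-frequency transform, baseline z-scoring, speed-matched trial
# sampling, artifact masking and beta-window statistics.

#' Common average reference
#'
#' Subtracts the mean of the included channels from each included channel;
#' excluded channels (e.g. contacts with poor signal quality) are dropped
#' from both the average and the output.
#'
#' @param channels A channels-by-time numeric matrix.
#' @param exclude Indices of channels to exclude.
#' @return The referenced channels-by-time matrix (included channels only).
#' @export
common_average_reference <- function(channels, exclude = integer(0)) {
  included <- setdiff(seq_len(nrow(channels)), exclude)
  if (length(included) < 2L) {
    abort_invalid("common average reference needs at least 2 included channels")
  }
  x <- channels[included, , drop = FALSE]
  sweep(x, 2, colMeans(x), "-")
}

#' Epoch a continuous signal around events
#'
#' Cuts fixed-length windows around event times; events whose window falls
#' outside the recording are dropped with a message.
#'
#' @param signal Continuous signal (numeric vector), first sample at time 0.
#' @param event_times Event times in seconds.
#' @param spec An [epoch_spec()] (window and sample rate).
#' @return A list with `epochs` (events x time), `times` (the epoch time
#'   axis) and `dropped` (number of discarded events).
#' @export
epoch_around_events <- function(signal, event_times, spec = epoch_spec()) {
  fs <- spec$sample_rate
  off <- seq(round(spec$window[1] * fs), round(spec$window[2] * fs))
  centers <- round(event_times * fs) + 1L
  ok <- centers + off[1L] >= 1L & centers + off[length(off)] <= length(signal)
  if (!any(ok)) abort_invalid("no event window fits inside the recording")
  dropped <- sum(!ok)
  if (dropped > 0L) {
    message(sprintf("dropped %d event(s) too close to the recording edge", dropped))
  }
  epochs <- t(vapply(centers[ok], function(cc) signal[cc + off],
                     numeric(length(off))))
  list(epochs = epochs, times = off / fs, dropped = dropped)
}

new_epochs_tfr <- function(power, mask, freqs, times, meta = NULL,
                           normalized = FALSE) {
  structure(
    list(power = power, mask = mask, freqs = freqs, times = times,
         meta = meta, normalized = normalized),
    class = "kinestim_tfr")
}

#' Morlet wavelet time-frequency transform
#'
#' Power is the squared magnitude of the convolution with complex Morlet
#' wavelets of `n_cycles` cycles per frequency (unit-energy normalisation).
#' Edge samples whose wavelet support (3.5 temporal SDs) extends beyond the
#' epoch are masked.
#'
#' @param epochs A trials-by-time matrix.
#' @param spec An [epoch_spec()] (sample rate, default frequency grid and
#'   cycle count).
#' @param freqs Frequencies in Hz; must lie strictly below Nyquist.
#' @param n_cycles Wavelet cycles.
#' @param meta Optional per-trial metadata carried on the result.
#' @return A `kinestim_tfr`: `power` (trials x freqs x time), `mask`
#'   (logical, `TRUE` where power is undefined), `freqs`, `times`.
#' @export
morlet_tfr <- function(epochs, spec = epoch_spec(), freqs = spec$freqs,
                       n_cycles = spec$n_cycles, meta = NULL) {
  fs <- spec$sample_rate
  if (any(freqs <= 0 | freqs >= fs / 2)) {
    abort_invalid("`freqs` must lie strictly between 0 and the Nyquist frequency")
  }
  if (is.vector(epochs)) epochs <- matrix(epochs, nrow = 1L)
  n_tr <- nrow(epochs)
  nt <- ncol(epochs)
  times <- seq(spec$window[1], by = 1 / fs, length.out = nt)

  sig_t <- n_cycles / (2 * pi * freqs)
  halves <- ceiling(3.5 * sig_t * fs)
  L <- stats::nextn(nt + 2L * max(halves) + 1L, 2)
  E <- matrix(0, L, n_tr)
  E[seq_len(nt), ] <- t(epochs)
  FE <- stats::mvfft(E)

  power <- array(NA_real_, dim = c(n_tr, length(freqs), nt))
  mask <- array(FALSE, dim = c(n_tr, length(freqs), nt))
  for (fi in seq_along(freqs)) {
    half <- halves[fi]
    tt <- (-half:half) / fs
    w <- exp(2i * pi * freqs[fi] * tt) * exp(-tt^2 / (2 * sig_t[fi]^2))
    w <- w / sqrt(sum(Mod(w)^2))
    wf <- stats::fft(c(w, rep(0, L - length(w))))
    conv <- stats::mvfft(FE * wf, inverse = TRUE) / L
    # wavelet centre sits at index half+1, so sample j aligns with conv row j+half
    sl <- conv[seq_len(nt) + half, , drop = FALSE]
    power[, fi, ] <- t(Mod(sl)^2)
    edge <- seq_len(nt) <= half | seq_len(nt) > nt - half
    mask[, fi, edge] <- TRUE
  }
  power[mask] <- NA_real_
  new_epochs_tfr(power, mask, freqs, times, meta = meta)
}

#' Baseline z-score normalisation
#'
#' Normalises each trial and frequency to z-scores with respect to the
#' baseline window preceding the peak speed. Trial-frequency rows with a
#' degenerate baseline (zero SD or fewer than two unmasked samples) are
#' masked entirely.
#'
#' @param tfr A `kinestim_tfr`.
#' @param baseline Baseline window in seconds, default `c(-0.4, -0.1)`.
#' @return The normalised `kinestim_tfr`.
#' @export
baseline_zscore <- function(tfr, baseline = c(-0.400, -0.100)) {
  d <- dim(tfr$power)
  bl <- which(tfr$times >= baseline[1] & tfr$times <= baseline[2])
  if (length(bl) < 2L) abort_invalid("baseline window contains fewer than 2 samples")
  P <- tfr$power
  dim(P) <- c(d[1] * d[2], d[3])
  B <- P[, bl, drop = FALSE]
  nb <- rowSums(!is.na(B))
  m <- rowMeans(B, na.rm = TRUE)
  s2 <- rowMeans(B^2, na.rm = TRUE) - m^2
  s <- sqrt(pmax(s2, 0) * nb / pmax(nb - 1, 1))
  bad <- nb < 2L | !is.finite(s) | s == 0
  Z <- (P - m) / s
  Z[bad, ] <- NA_real_
  dim(Z) <- d
  mask <- tfr$mask
  if (any(bad)) {
    bad_tr <- ((which(bad) - 1L) %% d[1]) + 1L
    bad_f <- ((which(bad) - 1L) %/% d[1]) + 1L
    for (k in seq_along(bad_tr)) {
      mask[bad_tr[k], bad_f[k], ] <- TRUE
    }
  }
  mask <- mask | is.na(Z)
  new_epochs_tfr(Z, mask, tfr$freqs, tfr$times, meta = tfr$meta,
                 normalized = TRUE)
}

#' Speed-matched sample of not-stimulated trials
#'
#' Selects a subset of the not-stimulated pool with the same size as the
#' stimulated sample by greedy nearest-neighbour matching on peak speed
#' without replacement, processing stimulated trials in descending speed
#' order (ties resolved to the lowest pool index). The match is accepted
#' when an independent permutation test on peak speed is non-significant;
#' otherwise matching is retried with randomised neighbour choice up to a
#' retry cap.
#'
#' @param stim_speeds Peak speeds of the stimulated trials.
#' @param pool_speeds Peak speeds of the not-stimulated pool.
#' @param seed Optional integer seed.
#' @param alpha Acceptance level of the balance check.
#' @param n_perm Permutations of the balance check.
#' @param max_retries Retry cap.
#' @return A list with `indices` (into the pool), `p_value` and `retries`.
#' @export
match_speed_sample <- function(stim_speeds, pool_speeds, seed = NULL,
                               alpha = 0.05, n_perm = 2000, max_retries = 20) {
  ns <- length(stim_speeds)
  if (length(pool_speeds) < ns) {
    abort_invalid("not-stimulated pool is smaller than the stimulated sample")
  }
  with_seed(seed, {
    for (r in 0:max_retries) {
      avail <- rep(TRUE, length(pool_speeds))
      sel <- integer(ns)
      for (k in order(stim_speeds, decreasing = TRUE)) {
        dists <- abs(pool_speeds - stim_speeds[k])
        dists[!avail] <- Inf
        j <- if (r == 0L) {
          which.min(dists)
        } else {
          cand <- order(dists)[seq_len(min(r + 1L, sum(avail)))]
          if (length(cand) == 1L) cand else sample(cand, 1L)
        }
        sel[k] <- j
        avail[j] <- FALSE
      }
      pt <- independent_permutation_test(stim_speeds, pool_speeds[sel],
                                         n_perm = n_perm)
      if (pt$p_value > alpha) {
        return(list(indices = sel, p_value = pt$p_value, retries = r))
      }
    }
    stop(errorCondition(
      sprintf("speed matching failed after %d retries (last p = %.3g)",
              max_retries, pt$p_value),
      class = c("kinestim_matching_failed", "kinestim_error")))
  })
}

#' Mask stimulation edge artifacts
#'
#' For every stimulated trial, samples within `artifact_halfwidth` seconds
#' of the stimulation onset or offset are masked across all frequencies.
#' Edges falling outside the epoch are ignored with a warning.
#'
#' @param tfr A `kinestim_tfr`.
#' @param onsets,offsets Per-trial stimulation on/offset times in seconds
#'   (`NA` for not-stimulated trials).
#' @param spec An [epoch_spec()] (artifact half-width).
#' @return The masked `kinestim_tfr`.
#' @export
mask_stim_artifacts <- function(tfr, onsets, offsets, spec = epoch_spec()) {
  d <- dim(tfr$power)
  if (length(onsets) != d[1] || length(offsets) != d[1]) {
    abort_invalid("one on/offset time per trial is required")
  }
  hw <- spec$artifact_halfwidth
  t_max <- max(tfr$times)
  for (tr in seq_len(d[1])) {
    for (edge in c(onsets[tr], offsets[tr])) {
      if (is.na(edge)) next
      if (edge > t_max) {
        warning(sprintf("stimulation edge at %.3f s is outside the epoch; ignored",
                        edge), call. = FALSE)
        next
      }
      # small tolerance keeps boundary samples inside despite float grids
      idx <- which(abs(tfr$times - edge) <= hw + 1e-9)
      if (length(idx)) {
        tfr$mask[tr, , idx] <- TRUE
        tfr$power[tr, , idx] <- NA_real_
      }
    }
  }
  tfr
}

#' Beta-band time course with the masked-epoch rule applied
#'
#' Reduces a normalised, artifact-masked TFR to a trials-by-time matrix of
#' mean beta power and applies the masked-epoch rule: at every time point
#' the masked-trial fraction is computed; below `nan_epoch_fraction`,
#' masked entries are replaced by the cross-trial median; at or above it
#' the time point is excluded from cluster analysis.
#'
#' @param tfr A normalised `kinestim_tfr`.
#' @param spec An [epoch_spec()] (beta band and masked-epoch fraction).
#' @return A list with `beta` (raw trial x time means, `NA` where masked),
#'   `filled` (median-replaced matrix restricted to included time points),
#'   `included` and `excluded` (integer time indices) and `masked_fraction`.
#' @export
cluster_ready_beta <- function(tfr, spec = epoch_spec()) {
  band <- which(tfr$freqs >= spec$beta_band[1] & tfr$freqs <= spec$beta_band[2])
  if (!length(band)) abort_invalid("no frequencies in the beta band")
  d <- dim(tfr$power)
  B <- apply(tfr$power[, band, , drop = FALSE], c(1, 3), function(x) {
    if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
  })
  frac <- colMeans(is.na(B))
  included <- which(frac < spec$nan_epoch_fraction)
  excluded <- which(frac >= spec$nan_epoch_fraction)
  filled <- B[, included, drop = FALSE]
  for (j in seq_along(included)) {
    nas <- is.na(filled[, j])
    if (any(nas)) {
      filled[nas, j] <- stats::median(filled[!nas, j])
    }
  }
  list(beta = B, filled = filled, included = included, excluded = excluded,
       masked_fraction = frac)
}

#' Interpolate masked samples for visualization
#'
#' Linear interpolation across masked spans, per trial and frequency. The
#' result is intended for plotting only; no statistic in this package is
#' ever computed on interpolated values.
#'
#' @param tfr A `kinestim_tfr`.
#' @return The power array with masked samples linearly interpolated.
#' @export
interpolate_masked <- function(tfr) {
  d <- dim(tfr$power)
  out <- tfr$power
  for (tr in seq_len(d[1])) {
    for (fi in seq_len(d[2])) {
      y <- out[tr, fi, ]
      ok <- !is.na(y)
      if (any(!ok) && sum(ok) >= 2L) {
        out[tr, fi, ] <- stats::approx(which(ok), y[ok], xout = seq_len(d[3]),
                                       rule = 2)$y
      }
    }
  }
  out
}

#' Beta-power window statistics and cluster test
#'
#' Per trial, the missing-value-aware mean of normalised power over the
#' beta band within the peri-stimulation and post-stimulation windows;
#' group differences (stimulated vs not-stimulated) are tested with
#' independent permutation tests per window, and over the full time axis
#' with the cluster permutation test on the median-filled beta time course
#' (excluded time points removed; clusters cannot bridge them).
#'
#' @param tfr A normalised, artifact-masked `kinestim_tfr`.
#' @param stimulated Logical vector, one entry per trial.
#' @param spec An [epoch_spec()].
#' @param n_perm Permutations of the window tests.
#' @param n_perm_cluster Permutations of the cluster test.
#' @param alpha Alpha level of the cluster-forming threshold.
#' @param seed Optional integer seed.
#' @return A list with `window_means` (trial, stimulated, peri, post),
#'   `tests` (`peri`, `post`: `kinestim_perm`), `cluster`
#'   (`kinestim_clusters`) and `excluded_times`.
#' @export
beta_window_stats <- function(tfr, stimulated, spec = epoch_spec(),
                              n_perm = 10000, n_perm_cluster = 1000,
                              alpha = 0.05, seed = NULL) {
  if (!isTRUE(tfr$normalized)) {
    abort_invalid("`tfr` must be baseline-normalised first")
  }
  d <- dim(tfr$power)
  if (length(stimulated) != d[1]) {
    abort_invalid("`stimulated` must have one entry per trial")
  }
  band <- which(tfr$freqs >= spec$beta_band[1] & tfr$freqs <= spec$beta_band[2])
  win_mean <- function(win) {
    idx <- which(tfr$times >= win[1] & tfr$times <= win[2])
    apply(tfr$power[, band, idx, drop = FALSE], 1, function(x) {
      if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
    })
  }
  peri <- win_mean(spec$stim_window)
  post <- win_mean(spec$post_window)
  tests <- list(
    peri = independent_permutation_test(peri[stimulated], peri[!stimulated],
                                        n_perm = n_perm, seed = seed),
    post = independent_permutation_test(post[stimulated], post[!stimulated],
                                        n_perm = n_perm,
                                        seed = if (is.null(seed)) NULL else seed + 1L))
  cr <- cluster_ready_beta(tfr, spec)
  cluster <- cluster_permutation_test(
    cr$filled[stimulated, , drop = FALSE],
    cr$filled[!stimulated, , drop = FALSE],
    n_perm = n_perm_cluster, alpha = alpha,
    seed = if (is.null(seed)) NULL else seed + 2L,
    time_index = cr$included)
  list(window_means = data.frame(trial = seq_len(d[1]),
                                 stimulated = stimulated,
                                 peri = peri, post = post),
       tests = tests, cluster = cluster, excluded_times = cr$excluded)
}
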
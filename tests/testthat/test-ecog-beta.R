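spec_fast <- epoch_spec(freqs = c(10, seq(20, 35, by = 3), 45))

test_that("common average referencing removes the channel mean", {
  x <- matrix(c(1, 1, 1, 3, 3, 3), nrow = 2, byrow = TRUE)
  ref <- common_average_reference(x)
  expect_equal(ref, matrix(c(-1, -1, -1, 1, 1, 1), nrow = 2, byrow = TRUE))
  # two identical channels -> both referenced to zero
  y <- matrix(rnorm(10), nrow = 1)[c(1, 1), ]
  expect_true(all(common_average_reference(y) == 0))
  # referenced included channels sum to zero at every sample
  z <- matrix(rnorm(6 * 50), 6)
  ref <- common_average_reference(z, exclude = 6)
  expect_equal(nrow(ref), 5)
  expect_equal(colSums(ref), rep(0, 50), tolerance = 1e-12)
  expect_error(common_average_reference(z, exclude = 1:5),
               class = "kinestim_invalid_argument")
})

test_that("epoching cuts symmetric windows and drops edge events", {
  spec <- epoch_spec(sample_rate = 100)
  signal <- seq_len(1001)  # 10 s at 100 Hz
  ep <- suppressMessages(
    epoch_around_events(signal, c(5, 0.5, 9.9), spec))
  expect_equal(ep$dropped, 2)
  expect_equal(dim(ep$epochs), c(1, 2 * 100 + 1))
  # event at t = 5 s spans samples of 4..6 s
  expect_equal(ep$epochs[1, 1], signal[401])
  expect_equal(ep$epochs[1, 201], signal[601])
  expect_equal(range(ep$times), c(-1, 1))
  expect_error(epoch_around_events(signal, 0.2, spec),
               class = "kinestim_invalid_argument")
})

test_that("Morlet power is frequency selective and scales quadratically", {
  tt <- seq(-1, 1, by = 1 / 1000)
  spec <- epoch_spec()
  ep <- matrix(sin(2 * pi * 25 * tt), nrow = 1)
  tfr <- morlet_tfr(ep, spec, freqs = c(10, 25, 60))
  ic <- which.min(abs(tfr$times))
  expect_gt(tfr$power[1, 2, ic] / max(tfr$power[1, c(1, 3), ic]), 10)
  # 25 Hz lies inside the beta band of the analysis
  tfr_b <- morlet_tfr(ep, spec, freqs = spec$freqs)
  band <- tfr_b$freqs >= 20 & tfr_b$freqs <= 35
  expect_gt(mean(tfr_b$power[1, band, ic]),
            mean(tfr_b$power[1, !band, ic]) * 5)
  # quadratic amplitude scaling, zero in -> zero out
  tfr2 <- morlet_tfr(2 * ep, spec, freqs = 25)
  expect_equal(tfr2$power[1, 1, ic] / tfr$power[1, 2, ic], 4, tolerance = 1e-9)
  tfr0 <- morlet_tfr(matrix(0, 2, length(tt)), spec, freqs = c(20, 30))
  expect_equal(max(tfr0$power, na.rm = TRUE), 0)
  # wavelet-support edges are masked
  expect_true(all(tfr$mask[, , 1]))
  expect_false(any(tfr$mask[, , ic]))
  expect_error(morlet_tfr(ep, spec, freqs = 600),
               class = "kinestim_invalid_argument")
})

test_that("baseline z-scoring normalises each trial-frequency row", {
  times <- seq(-1, 1, by = 0.01)
  set.seed(21)
  p <- array(rnorm(2 * 2 * length(times), mean = 10, sd = 2),
             dim = c(2, 2, length(times)))
  # trial 1, freq 1: add a +2 SD step after the movement
  tfr <- toy_tfr(p, times)
  z <- baseline_zscore(tfr, c(-0.4, -0.1))
  bl <- times >= -0.4 & times <= -0.1
  for (tr in 1:2) for (fi in 1:2) {
    expect_equal(mean(z$power[tr, fi, bl]), 0, tolerance = 1e-10)
    expect_equal(sd(z$power[tr, fi, bl]), 1, tolerance = 1e-10)
  }
  # a +2 baseline-SD injected step reads out as approximately +2
  win <- times >= 0.2 & times <= 0.6
  p2 <- p
  m <- mean(p[1, 1, bl]); s <- sd(p[1, 1, bl])
  p2[1, 1, win] <- m + 2 * s
  z2 <- baseline_zscore(toy_tfr(p2, times), c(-0.4, -0.1))
  expect_equal(mean(z2$power[1, 1, win]), 2, tolerance = 1e-6)
  # constant-power rows have zero baseline SD and are masked
  p3 <- p
  p3[2, 2, ] <- 7
  z3 <- baseline_zscore(toy_tfr(p3, times), c(-0.4, -0.1))
  expect_true(all(z3$mask[2, 2, ]))
  expect_false(any(z3$mask[1, 1, ]))
})

test_that("speed matching follows the greedy nearest-neighbour rule", {
  m <- match_speed_sample(c(10, 20), c(9, 11, 19, 30), n_perm = 500)
  expect_equal(sort(c(9, 11, 19, 30)[m$indices]), c(9, 19))
  expect_equal(m$retries, 0)
  set.seed(31)
  stim <- rlnorm(30, log(1500), 0.1)
  pool <- rlnorm(90, log(1500), 0.1)
  m2 <- match_speed_sample(stim, pool, seed = 1)
  expect_gt(m2$p_value, 0.05)
  expect_false(any(duplicated(m2$indices)))
  expect_error(match_speed_sample(stim, pool[1:10]),
               class = "kinestim_invalid_argument")
  # an impossible pool exhausts the retry cap
  expect_error(match_speed_sample(seq(1, 2, length.out = 10), 50 + 1:20,
                                  max_retries = 2, n_perm = 500, seed = 2),
               class = "kinestim_matching_failed")
})

test_that("artifact masking covers 65 ms around each stimulation edge", {
  times <- seq(-1, 1, by = 0.001)
  p <- array(1, dim = c(2, 3, length(times)))
  tfr <- toy_tfr(p, times)
  m <- mask_stim_artifacts(tfr, onsets = c(0.10, NA), offsets = c(0.40, NA),
                           spec = epoch_spec())
  masked_t <- times[apply(m$mask[1, , ], 2, any)]
  expect_equal(range(masked_t[masked_t < 0.3]), c(0.035, 0.165))
  expect_equal(range(masked_t[masked_t > 0.3]), c(0.335, 0.465))
  # not-stimulated trial untouched
  expect_false(any(m$mask[2, , ]))
  expect_warning(mask_stim_artifacts(tfr, onsets = c(2, NA),
                                     offsets = c(NA, NA)),
                 "outside the epoch")
})

test_that("the masked-epoch rule median-replaces below 15% and excludes above", {
  times <- seq(-0.5, 0.5, by = 0.01)
  n_tr <- 100
  set.seed(41)
  p <- array(rnorm(n_tr * 2 * length(times)), dim = c(n_tr, 2, length(times)))
  # time 50: mask 14 of 100 trials; time 60: mask 16 of 100
  p[1:14, , 50] <- NA
  p[1:16, , 60] <- NA
  tfr <- toy_tfr(p, times, freqs = c(25, 30), normalized = TRUE)
  cr <- cluster_ready_beta(tfr, epoch_spec())
  expect_true(50 %in% cr$included)
  expect_false(60 %in% cr$included)
  expect_true(60 %in% cr$excluded)
  col50 <- cr$filled[, which(cr$included == 50)]
  expect_false(any(is.na(col50)))
  raw50 <- cr$beta[!is.na(cr$beta[, 50]), 50]
  expect_equal(unique(col50[1:14]), median(raw50))
})

test_that("interpolation is produced for visualization but never enters statistics", {
  spec <- spec_fast
  eco <- generate_synthetic_ecog(40, spec, seed = 51, peri_effect = -0.5,
                                 post_effect = 0.5)
  tfr <- morlet_tfr(eco$epochs, spec)
  tfr <- baseline_zscore(tfr, spec$baseline)
  tfr <- mask_stim_artifacts(tfr, eco$meta$stim_onset, eco$meta$stim_offset,
                             spec)
  interp <- interpolate_masked(tfr)
  tr1 <- which(eco$meta$stimulated)[1]
  art <- which(abs(tfr$times - eco$meta$stim_onset[tr1]) <= 0.065)
  expect_false(any(is.na(interp[tr1, , art])))
  # the masked TFR handed to the statistics still carries its NAs there
  expect_true(all(is.na(tfr$power[tr1, , art])))
  bw <- beta_window_stats(tfr, eco$meta$stimulated, spec, n_perm = 2000,
                          n_perm_cluster = 200, seed = 1)
  # cluster input excludes every time point the 15% rule removed
  expect_length(intersect(bw$cluster$time_index, bw$excluded_times), 0)
})

test_that("injected beta effects are detected with the correct signs", {
  spec <- spec_fast
  eco <- generate_synthetic_ecog(118, spec, seed = 61, peri_effect = -0.4,
                                 post_effect = 0.3)
  tfr <- morlet_tfr(eco$epochs, spec, meta = eco$meta)
  tfr <- baseline_zscore(tfr, spec$baseline)
  tfr <- mask_stim_artifacts(tfr, eco$meta$stim_onset, eco$meta$stim_offset,
                             spec)
  bw <- beta_window_stats(tfr, eco$meta$stimulated, spec, n_perm = 5000,
                          n_perm_cluster = 500, seed = 2)
  expect_lt(bw$tests$peri$statistic, 0)
  expect_lt(bw$tests$peri$p_value, 0.05)
  expect_gt(bw$tests$post$statistic, 0)
  expect_lt(bw$tests$post$p_value, 0.05)
  sig <- bw$cluster$clusters[bw$cluster$clusters$p_value < 0.05, ]
  expect_gte(nrow(sig), 1)
  # significant clusters overlap the injected windows
  idx_time <- function(w) which(tfr$times >= w[1] & tfr$times <= w[2])
  covered <- unlist(Map(seq, sig$start_index, sig$end_index))
  expect_gt(length(intersect(covered, idx_time(spec$stim_window))), 0)
  expect_gt(length(intersect(covered, idx_time(spec$post_window))), 0)
})

test_that("identical groups give null window statistics", {
  spec <- spec_fast
  eco <- generate_synthetic_ecog(40, spec, seed = 71)
  tfr <- baseline_zscore(morlet_tfr(eco$epochs, spec), spec$baseline)
  # random grouping unrelated to any signal difference
  grp <- rep(c(TRUE, FALSE), 20)
  bw <- beta_window_stats(tfr, grp, spec, n_perm = 2000,
                          n_perm_cluster = 200, seed = 3)
  expect_gt(bw$tests$peri$p_value, 0.05)
  expect_gt(bw$tests$post$p_value, 0.05)
})
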
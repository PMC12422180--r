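test_that("the rest-based movement threshold is mean + 3 SD of pooled rest speeds", {
  expect_equal(compute_rest_threshold(rep(150, 50)), 150)  # zero SD
  set.seed(1)
  x <- rnorm(2e5, 200, 200)
  expect_lt(abs(compute_rest_threshold(x) - 800), 10)
  expect_error(compute_rest_threshold(numeric(0)),
               class = "kinestim_invalid_argument")
  # the default constant stands in when no cohort is supplied
  expect_equal(speed_thresholds()$movement_threshold, 800.77)
  expect_equal(speed_thresholds()$outlier_threshold, 2413.35)
})

test_that("rest speeds are extracted from the pre-movement window", {
  sim <- simulate_session(seed = 31, protocol = NULL, n_movements = 96)
  rest <- extract_rest_speeds(sim$trace, sim$truth$onset_s)
  expect_gt(length(rest), 500)
  # rest speeds (position noise only) sit far below movement speeds
  expect_lt(mean(rest), 500)
  thr <- compute_rest_threshold(rest)
  expect_lt(thr, min(sim$truth$true_peak_speed))
})

test_that("movement bounds follow the contiguous above-threshold run", {
  b <- detect_movement_bounds(c(0, 900, 1500, 900, 0), 3, 800.77)
  expect_equal(unname(b), c(2, 4))
  # entire trial above threshold -> bounds at the edges
  b <- detect_movement_bounds(c(900, 1200, 1100), 2, 800.77)
  expect_equal(unname(b), c(1, 3))
  # secondary sub-movement outside the peak's run is excluded
  b <- detect_movement_bounds(c(0, 900, 100, 1500, 900, 0), 4, 800.77)
  expect_equal(unname(b), c(4, 5))
  expect_error(detect_movement_bounds(c(0, 500, 0), 2, 800.77),
               class = "kinestim_no_movement")
})

test_that("block speed change normalises to the first-five mean", {
  expect_equal(block_speed_change(rep(1200, 20))$percent_change, rep(0, 15))
  ch <- block_speed_change(c(rep(1000, 5), 900, 1100))
  expect_equal(ch$percent_change, c(-10, 10))
  expect_equal(ch$baseline, 1000)
  # outliers become missing and never contribute to the mean
  ch <- block_speed_change(c(rep(1000, 5), 2500, 900))
  expect_true(is.na(ch$percent_change[1]))
  expect_equal(ch$block_mean, -10)
  expect_equal(ch$n_outliers, 1)
  # external baseline (recovery-block normalisation)
  ch <- block_speed_change(c(rep(800, 5), 900), baseline_value = 1000)
  expect_equal(ch$percent_change, -10)
  expect_error(block_speed_change(rep(1000, 5)),
               class = "kinestim_invalid_argument")
  expect_error(block_speed_change(c(rep(NA_real_, 5), 900, 1000)),
               class = "kinestim_invalid_argument")
  # normalising an already-normalised constant-baseline series is idempotent
  v <- c(rep(1000, 5), seq(950, 1050, length.out = 10))
  ch1 <- block_speed_change(v)
  v2 <- 1000 * (1 + c(rep(0, 5), ch1$percent_change) / 100)
  expect_equal(block_speed_change(v2)$percent_change, ch1$percent_change)
})

test_that("recovery blocks are normalised to the preceding stimulation block", {
  mv <- data.frame(block = rep(1:2, each = 10),
                   avg_speed = c(rep(1000, 10), rep(900, 10)))
  res <- session_speed_change(mv, stim_protocol(n_blocks = 2, stim_blocks = 1))
  expect_equal(res$block_means$baseline, c(1000, 1000))
  expect_equal(res$block_means$block_mean, c(0, -10))
  # without protocol every block uses its own baseline
  res0 <- session_speed_change(mv, NULL)
  expect_equal(res0$block_means$block_mean, c(0, 0))
})

test_that("follower changes show regression to the mean that the matched subtraction cancels", {
  set.seed(3)
  shifts <- do.call(rbind, lapply(1:10, function(s) {
    p <- subject_pipeline(seed = 400 + s, delta = 0, fast_first = s %% 2 == 0)
    poststim_speed_shift(p$movements, p$protocol)
  }))
  # raw follower change is negative after fast and positive after slow anchors
  expect_lt(mean(shifts$mean_change_stim[shifts$condition == "fast"]), -3)
  expect_gt(mean(shifts$mean_change_stim[shifts$condition == "slow"]), 3)
  # the matched estimator is centred on zero under the null (3 SE tolerance)
  for (cell in split(shifts$shift, paste(shifts$condition,
                                         shifts$relative_direction))) {
    expect_lt(abs(mean(cell)), 3 * sd(cell) / sqrt(length(cell)) + 0.2)
  }
})

test_that("injected reinforcement is recovered with the expected sign structure", {
  set.seed(4)
  res <- do.call(rbind, lapply(1:8, function(s) {
    p <- subject_pipeline(seed = 700 + s, delta = 0.05, fast_first = s %% 2 == 0)
    sh <- poststim_speed_shift(p$movements, p$protocol)
    tg <- injected_change_targets(p$sim$truth, p$protocol)
    merge(sh, tg, by = c("condition", "relative_direction"))
  }))
  m <- aggregate(cbind(shift, target) ~ condition + relative_direction, res, mean)
  same_fast <- m[m$condition == "fast" & m$relative_direction == "same", ]
  same_slow <- m[m$condition == "slow" & m$relative_direction == "same", ]
  expect_gt(same_fast$shift, 0)
  expect_lt(same_slow$shift, 0)
  expect_gt(same_fast$target, 1)
  expect_lt(same_slow$target, -1)
  # the direct injection acts on same-direction followers only
  opp <- m[m$relative_direction == "opposite", ]
  expect_true(all(abs(opp$target) < abs(m$target[m$relative_direction == "same"])))
})

test_that("shift cells without reference movements are undefined, not zero", {
  mv <- data.frame(block = rep(1:2, each = 10),
                   direction = rep(c("left_to_right", "right_to_left"), 10),
                   stimulated = c(rep(c(FALSE, FALSE, TRUE, FALSE, FALSE), 2),
                                  rep(FALSE, 10)),
                   peak_speed = c(seq(2000, 1100, length.out = 10),
                                  seq(1000, 1900, length.out = 10)),
                   avg_speed = c(seq(2000, 1100, length.out = 10),
                                 seq(1000, 1900, length.out = 10)))
  # recovery block is strictly increasing -> it contains no "slow" movements
  sh <- poststim_speed_shift(mv, stim_protocol(n_blocks = 2, stim_blocks = 1,
                                               condition_order = "slow",
                                               block_length = 10))
  expect_true(all(is.na(sh$shift)))
  expect_true(all(sh$n_ref == 0))
})
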
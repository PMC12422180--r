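test_that("online speed is the trailing six-sample mean of instantaneous speeds", {
  # constant position -> zero speed
  tr <- data.frame(time_s = (0:20) / 62, x_px = 500, y_px = 500)
  expect_true(all(compute_online_speed(tr)$speed == 0))
  # 10 px per sample at exactly 62 Hz -> 620 px/s once 6 samples accumulated
  tr <- data.frame(time_s = (0:19) / 62, x_px = 10 * (0:19), y_px = 0)
  sp <- compute_online_speed(tr)
  expect_equal(sp$speed[6:19], rep(620, 14))
  expect_equal(sp$instantaneous, rep(620, 19))
  # diagonal step (3, 4) px in 1/62 s -> Euclidean 5 px * 62 Hz = 310 px/s
  tr <- data.frame(time_s = c(0, 1 / 62), x_px = c(0, 3), y_px = c(0, 4))
  expect_equal(compute_online_speed(tr)$instantaneous, 310)
  # stream head averages over however many samples exist
  tr <- data.frame(time_s = (0:3) / 62, x_px = c(0, 62, 62, 62), y_px = 0)
  sp <- compute_online_speed(tr)
  expect_equal(sp$speed, c(3844, 1922, 3844 / 3))
  # duplicate timestamps rejected
  tr <- data.frame(time_s = c(0, 0.1, 0.1), x_px = 1:3, y_px = 0)
  expect_error(compute_online_speed(tr), class = "kinestim_invalid_argument")
})

test_that("three-decreasing peak detection matches its worked examples", {
  d <- detect_peak_three_decreasing(c(1, 3, 5, 4, 3, 2))
  expect_equal(d$index, 6)
  expect_equal(d$peak, 5)
  # monotonically increasing -> no detection
  expect_null(detect_peak_three_decreasing(1:10))
  # plateau interrupts the decreasing run; detection shifts to the 7th sample
  d <- detect_peak_three_decreasing(c(1, 3, 5, 4, 4, 3, 2, 1))
  expect_equal(d$index, 7)
  expect_equal(d$peak, 5)
  expect_null(detect_peak_three_decreasing(c(5, 4)))
})

test_that("peak-time percentile calibration uses linear interpolation", {
  lat <- seq(0.1, 3.2, by = 0.1)
  expect_equal(calibrate_peak_time_percentile(lat, 80), 2.58)
  expect_equal(calibrate_peak_time_percentile(rep(0.7, 32), 37), 0.7)
  expect_warning(v <- calibrate_peak_time_percentile(lat[1:31], 80),
                 "32 familiarization")
  expect_equal(v, unname(quantile(lat[1:31], 0.8)))
  expect_error(calibrate_peak_time_percentile(numeric(0)),
               class = "kinestim_invalid_argument")
  expect_error(suppressWarnings(calibrate_peak_time_percentile(lat, 100)),
               class = "kinestim_invalid_argument")
})

test_that("two-back classification applies strict inequalities", {
  expect_equal(classify_speed(5, 3, 4)$label, "fast")
  expect_equal(classify_speed(2, 3, 4)$label, "slow")
  expect_equal(classify_speed(3.5, 3, 4)$label, "intermediate")
  expect_equal(classify_speed(4, 4, 3)$label, "intermediate")  # tie
  expect_equal(classify_speed(5, NA, 4)$label, "unclassified")
})

test_that("iid peak speeds are classified fast/slow one third of the time", {
  set.seed(42)
  v <- iid_peaks(20000)
  lab <- kinestim:::two_back_labels(v)
  expect_lt(abs(mean(lab == "fast") - 1 / 3), 0.012)
  expect_lt(abs(mean(lab == "slow") - 1 / 3), 0.012)
})

test_that("a decreasing trend biases classification toward slow", {
  set.seed(43)
  v <- iid_peaks(96 * 200, decrement = 0)
  vt <- v * rep(0.998^(0:95), 200)
  lab <- unlist(lapply(split(vt, rep(seq_len(200), each = 96)),
                       kinestim:::two_back_labels), use.names = FALSE)
  expect_lt(mean(lab == "fast"), 1 / 3)
  expect_gt(mean(lab == "slow"), 1 / 3)
})

test_that("the controller emits bursts only in stimulation blocks", {
  p <- subject_pipeline(seed = 21)
  ev <- p$session$stim_events
  mv <- p$session$movements
  expect_true(all(ev$block %in% c(1, 3)))
  expect_true(all(ev$duration == 0.3))
  expect_false(any(duplicated(ev$movement)))
  expect_true(all(mv$label[mv$index_in_block <= 2] == "unclassified"))
  expect_false(any(mv$stimulated[mv$index_in_block <= 2]))
  expect_false(any(mv$stimulated[mv$block %in% c(2, 4)]))
  # stimulated movements carry the block's target condition
  expect_true(all(mv$label[mv$stimulated & mv$block == 1] == "fast"))
  expect_true(all(mv$label[mv$stimulated & mv$block == 3] == "slow"))
  # empty stim_blocks -> no events
  p0 <- stim_protocol(stim_blocks = integer(0))
  s0 <- run_closed_loop_session(p$sim$trace, p0)
  expect_equal(nrow(s0$stim_events), 0)
  # too-short trace rejected
  short <- p$sim$trace[p$sim$trace$trial_index <= 100, ]
  expect_error(run_closed_loop_session(short),
               class = "kinestim_invalid_argument")
})

test_that("detection latency respects the three-sample confirmation delay", {
  # on clean data the confirming run cannot complete earlier than three
  # sampling intervals after the peak
  sim <- simulate_session(seed = 22, model = noiseless_model())
  ses <- run_closed_loop_session(sim$trace)
  lat <- ses$movements$detection_time - sim$truth$true_peak_time
  lat <- lat[ses$movements$detected]
  expect_gt(min(lat, na.rm = TRUE), 3 / 62 - 1e-9)
})

test_that("on noiseless sessions the controller equals the offline oracle", {
  proto <- stim_protocol(condition_order = c("slow", "slow"))
  sim <- simulate_session(seed = 23, model = noiseless_model(), protocol = proto)
  ses <- run_closed_loop_session(sim$trace, proto)
  aud <- evaluate_controller(ses, sim$truth)
  expect_equal(aud$accuracy, 1)
  expect_identical(ses$movements$stimulated, sim$truth$stimulated)
  expect_equal(aud$total_stim_time_s, 0.3 * nrow(ses$stim_events))
})

test_that("the percentile-time detector reads the peak at the calibrated latency", {
  proto <- stim_protocol()
  sim <- simulate_session(seed = 24, model = noiseless_model(), protocol = proto)
  ses <- run_closed_loop_session(sim$trace, proto,
                                 detector = "percentile_time",
                                 peak_time_threshold = 0.45)
  expect_true(all(ses$movements$detected))
  aud <- evaluate_controller(ses, sim$truth)
  expect_equal(aud$accuracy, 1)
  expect_error(run_closed_loop_session(sim$trace, proto,
                                       detector = "percentile_time"),
               class = "kinestim_invalid_argument")
})

test_that("controller audit arithmetic is exact", {
  ses <- list(movements = data.frame(movement = 1:3, block = 1,
                                     label = c("unclassified", "unclassified", "fast"),
                                     stimulated = c(FALSE, FALSE, TRUE),
                                     detected = c(TRUE, TRUE, TRUE),
                                     detection_time = c(0.5, 1.5, 2.5)),
              stim_events = data.frame(block = rep(1, 28), movement = 1:28,
                                       start_time = 1:28,
                                       duration = rep(0.3, 28)))
  truth <- data.frame(movement = 1:3, true_peak_speed = c(1, 2, 3),
                      true_peak_time = c(0.4, 1.4, 2.4))
  aud <- evaluate_controller(ses, truth)
  expect_equal(aud$total_stim_time_s, 8.4)  # 28 bursts x 0.3 s
  expect_equal(aud$accuracy, 1)             # (3,2,1)-> fast matches oracle
  expect_error(evaluate_controller(ses, truth[1:2, ]),
               class = "kinestim_invalid_argument")
})
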
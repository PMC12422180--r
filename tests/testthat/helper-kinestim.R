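# Shared fixtures for the test suite; everything is generated in code.

# Noise-free kinematics: constant durations so the smoothed online readout
# preserves the peak-speed ordering exactly (see the methods vignette on
# degenerate ties).
noiseless_model <- function(decrement = 0.002) {
  kinematics_model(noise_cv = 0, position_noise_sd = 0, duration_sd = 0,
                   decrement_rate = decrement)
}

# One iid lognormal peak-speed block with optional geometric decrement.
iid_peaks <- function(n, cv = 0.10, decrement = 0) {
  sig <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, -sig^2 / 2, sig)) * (1 - decrement)^(seq_len(n) - 1)
}

# Simulate one subject through generator + controller + offline pipeline.
subject_pipeline <- function(seed, delta = 0, fast_first = TRUE) {
  proto <- stim_protocol(condition_order = if (fast_first) c("fast", "slow")
                         else c("slow", "fast"))
  sim <- simulate_session(seed = seed,
                          model = kinematics_model(reinforcement_delta = delta),
                          protocol = proto)
  session <- run_closed_loop_session(sim$trace, proto)
  movements <- session_movements(session, sim$trace)
  list(sim = sim, protocol = proto, session = session, movements = movements)
}

# Minimal hand-built TFR object for unit tests of the normalisation and
# masking rules (trials x freqs x time).
toy_tfr <- function(power, times, freqs = seq_len(dim(power)[2]),
                    normalized = FALSE) {
  kinestim:::new_epochs_tfr(power, is.na(power), freqs, times,
                            normalized = normalized)
}

bootstrap_ci <- function(x, n_boot = 2000, level = 0.95) {
  x <- x[!is.na(x)]
  means <- vapply(seq_len(n_boot), function(i) {
    mean(sample(x, replace = TRUE))
  }, numeric(1))
  stats::quantile(means, c((1 - level) / 2, 1 - (1 - level) / 2),
                  names = FALSE)
}
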
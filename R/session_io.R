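# Session persistence (TSV tables) and summary reporting.

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

protocol_to_kv <- function(protocol) {
  data.frame(
    key = c("condition_order", "burst_duration", "stim_frequency",
            "pulse_width_us", "amplitude_ma", "block_length", "n_blocks",
            "stim_blocks"),
    value = c(paste(protocol$condition_order, collapse = ","),
              protocol$burst_duration, protocol$stim_frequency,
              protocol$pulse_width_us, protocol$amplitude_ma,
              protocol$block_length, protocol$n_blocks,
              paste(protocol$stim_blocks, collapse = ",")))
}

kv_to_protocol <- function(kv) {
  g <- function(k) kv$value[match(k, kv$key)]
  stim_protocol(
    condition_order = strsplit(g("condition_order"), ",")[[1]],
    burst_duration = as.numeric(g("burst_duration")),
    stim_frequency = as.numeric(g("stim_frequency")),
    pulse_width_us = as.numeric(g("pulse_width_us")),
    amplitude_ma = as.numeric(g("amplitude_ma")),
    block_length = as.integer(g("block_length")),
    n_blocks = as.integer(g("n_blocks")),
    stim_blocks = as.integer(strsplit(g("stim_blocks"), ",")[[1]]))
}

validate_session <- function(session) {
  ev <- session$stim_events
  if (nrow(ev)) {
    if (!all(ev$block %in% session$protocol$stim_blocks)) {
      abort_invalid("stimulation events found outside the stimulation blocks")
    }
    if (any(abs(ev$duration - session$protocol$burst_duration) > 1e-9)) {
      abort_invalid("stimulation event durations do not match the protocol")
    }
    if (anyDuplicated(ev$movement)) {
      abort_invalid("more than one stimulation event for a movement")
    }
  }
  invisible(session)
}

#' Write a session to disk
#'
#' Writes the movement table, stimulation events and protocol snapshot (and
#' optionally the cursor trace and ground truth) as TSV tables; the session
#' is validated first (events confined to stimulation blocks, burst
#' durations matching the protocol, at most one event per movement).
#'
#' @param session A `kinestim_session`.
#' @param path Output directory (created if missing).
#' @param trace Optional cursor trace to persist alongside.
#' @param truth Optional ground-truth table; when absent, the config records
#'   `has_truth = FALSE`.
#' @param seed Optional seed recorded in the config snapshot.
#' @return The path, invisibly.
#' @export
write_session <- function(session, path, trace = NULL, truth = NULL,
                          seed = NULL) {
  validate_session(session)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  write_tsv(session$movements, file.path(path, "movements.tsv"))
  write_tsv(session$stim_events, file.path(path, "stim_events.tsv"))
  kv <- protocol_to_kv(session$protocol)
  kv <- rbind(kv,
              data.frame(key = c("detector", "arm_threshold", "seed",
                                 "has_truth"),
                         value = c(session$detector, session$arm_threshold,
                                   if (is.null(seed)) "NA" else seed,
                                   !is.null(truth))))
  write_tsv(kv, file.path(path, "config.tsv"))
  if (!is.null(trace)) write_tsv(trace, file.path(path, "trace.tsv"))
  if (!is.null(truth)) write_tsv(truth, file.path(path, "truth.tsv"))
  invisible(path)
}

#' Read a session from disk
#'
#' Reads a directory written by [write_session()] (or schema-conformant
#' tables), rebuilds the protocol and validates the result. Extra columns in
#' the tables are preserved; a trace with non-monotonic timestamps is
#' rejected with the offending row.
#'
#' @param path Directory containing the session tables.
#' @return A `kinestim_session`, with `trace` and `truth` attached when
#'   present.
#' @export
read_session <- function(path) {
  req <- c("movements.tsv", "stim_events.tsv", "config.tsv")
  missing <- req[!file.exists(file.path(path, req))]
  if (length(missing)) {
    abort_invalid(paste("missing session files:", paste(missing, collapse = ", ")))
  }
  movements <- read_tsv(file.path(path, "movements.tsv"))
  needed <- c("movement", "block", "label", "stimulated", "online_peak")
  absent <- setdiff(needed, names(movements))
  if (length(absent)) {
    abort_invalid(paste("movements.tsv lacks column(s):",
                        paste(absent, collapse = ", ")))
  }
  kv <- read_tsv(file.path(path, "config.tsv"))
  session <- structure(
    list(movements = movements,
         stim_events = read_tsv(file.path(path, "stim_events.tsv")),
         protocol = kv_to_protocol(kv),
         detector = kv$value[match("detector", kv$key)],
         arm_threshold = as.numeric(kv$value[match("arm_threshold", kv$key)])),
    class = "kinestim_session")
  validate_session(session)
  trace_path <- file.path(path, "trace.tsv")
  if (file.exists(trace_path)) {
    trace <- read_tsv(trace_path)
    bad <- which(diff(trace$time_s) <= 0)
    if (length(bad)) {
      abort_invalid(sprintf(
        "trace.tsv: non-monotonic timestamp at row %d", bad[1] + 1L))
    }
    session$trace <- trace
  }
  truth_path <- file.path(path, "truth.tsv")
  if (file.exists(truth_path)) session$truth <- read_tsv(truth_path)
  session
}

#' Summary report of a pipeline run
#'
#' Assembles the standard summary figures: per-trial block speed-change
#' curves, post-stimulation shift bars per condition and relative
#' direction, and (when spectral results are supplied) the group-difference
#' beta time course. Missing inputs are listed and a partial report is
#' produced.
#'
#' @param speed_change Result of [session_speed_change()], or `NULL`.
#' @param shift Result of [poststim_speed_shift()], or `NULL`.
#' @param beta Result of [beta_window_stats()], or `NULL`.
#' @param out_dir Optional directory; tabular sections are written there as
#'   TSV.
#' @return A list with `plots` (named ggplot objects), `tables` and
#'   `missing` (names of absent inputs).
#' @export
report_pipeline <- function(speed_change = NULL, shift = NULL, beta = NULL,
                            out_dir = NULL) {
  plots <- list()
  tables <- list()
  missing <- character(0)

  if (!is.null(speed_change)) {
    pt <- speed_change$per_trial
    plots$speed_change <- ggplot2::ggplot(
      pt, ggplot2::aes(x = .data$trial, y = .data$percent_change)) +
      ggplot2::geom_line(na.rm = TRUE, colour = "grey40") +
      ggplot2::geom_smooth(method = "loess", formula = y ~ x, se = FALSE,
                           na.rm = TRUE, colour = "firebrick") +
      ggplot2::facet_wrap(~block, labeller = ggplot2::label_both) +
      ggplot2::labs(x = "movement within block",
                    y = "speed change from block start (%)") +
      ggplot2::theme_minimal()
    tables$block_means <- speed_change$block_means
  } else {
    missing <- c(missing, "speed_change")
  }

  if (!is.null(shift)) {
    plots$shift <- ggplot2::ggplot(
      shift, ggplot2::aes(x = .data$condition, y = .data$shift,
                          fill = .data$relative_direction)) +
      ggplot2::geom_col(position = "dodge", na.rm = TRUE) +
      ggplot2::geom_hline(yintercept = 0) +
      ggplot2::labs(y = "post-stimulation speed shift (% points)",
                    fill = "follower direction") +
      ggplot2::theme_minimal()
    tables$shift <- as.data.frame(shift)
  } else {
    missing <- c(missing, "shift")
  }

  if (!is.null(beta)) {
    wm <- beta$window_means
    long <- rbind(
      data.frame(window = "peri", stimulated = wm$stimulated, z = wm$peri),
      data.frame(window = "post", stimulated = wm$stimulated, z = wm$post))
    plots$beta <- ggplot2::ggplot(
      long, ggplot2::aes(x = .data$window, y = .data$z,
                         fill = .data$stimulated)) +
      ggplot2::geom_boxplot(na.rm = TRUE) +
      ggplot2::labs(y = "beta power (baseline z)") +
      ggplot2::theme_minimal()
    tables$beta_windows <- wm
  } else {
    missing <- c(missing, "beta")
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(tables)) {
      write_tsv(tables[[nm]], file.path(out_dir, paste0(nm, ".tsv")))
    }
  }
  list(plots = plots, tables = tables, missing = missing)
}

#' Run the full desk-scale pipeline
#'
#' Chains target generation, kinematics simulation, the closed-loop
#' controller, the offline behavioural analysis and (optionally) the
#' synthetic spectral analysis into one reproducible run.
#'
#' @param seed Integer seed driving every stage.
#' @param model A [kinematics_model()].
#' @param protocol A [stim_protocol()].
#' @param geometry A [task_geometry()].
#' @param thresholds A [speed_thresholds()].
#' @param with_ecog Also run the synthetic spectral pipeline.
#' @param n_ecog_trials Trials per group of the synthetic spectral run.
#' @return A list with `sim`, `session`, `movements`, `speed_change`,
#'   `shift`, `audit` and (optionally) `beta`.
#' @export
run_pipeline <- function(seed = 1, model = kinematics_model(),
                         protocol = stim_protocol(),
                         geometry = task_geometry(),
                         thresholds = speed_thresholds(),
                         with_ecog = FALSE, n_ecog_trials = 118) {
  sim <- simulate_session(seed, model, protocol, geometry)
  session <- run_closed_loop_session(sim$trace, protocol,
                                     arm_threshold = thresholds$movement_threshold)
  movements <- session_movements(session, sim$trace, thresholds)
  out <- list(
    sim = sim, session = session, movements = movements,
    speed_change = session_speed_change(movements, protocol, thresholds),
    shift = poststim_speed_shift(movements, protocol, thresholds),
    audit = evaluate_controller(session, sim$truth))
  if (with_ecog) {
    spec <- epoch_spec()
    eco <- generate_synthetic_ecog(n_ecog_trials, spec, seed = seed + 1000L,
                                   peri_effect = -0.4, post_effect = 0.3)
    tfr <- morlet_tfr(eco$epochs, spec, meta = eco$meta)
    tfr <- baseline_zscore(tfr, spec$baseline)
    tfr <- mask_stim_artifacts(tfr, eco$meta$stim_onset,
                               eco$meta$stim_offset, spec)
    out$beta <- beta_window_stats(tfr, eco$meta$stimulated, spec,
                                  n_perm = 5000, seed = seed + 2000L)
  }
  out
}
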
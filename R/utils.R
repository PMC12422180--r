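# Internal helpers shared across modules.

abort_invalid <- function(msg, class = "kinestim_invalid_argument") {
  stop(errorCondition(msg, class = c(class, "kinestim_error")))
}

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. seed = NULL means "use the current stream".
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(code)
  }
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  code
}

check_positive_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    abort_invalid(sprintf("`%s` must be a single positive number", name))
  }
  invisible(x)
}

# Multiplicative lognormal noise with unit mean and coefficient of variation cv.
rlnorm_cv <- function(n, cv) {
  if (cv <= 0) {
    return(rep(1, n))
  }
  sig <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, mean = -sig^2 / 2, sd = sig))
}

# Vectorised strict two-back labelling of a peak-speed sequence (one block).
# First two entries are "unclassified"; ties yield "intermediate".
two_back_labels <- function(peaks) {
  n <- length(peaks)
  lab <- rep("unclassified", n)
  if (n >= 3L) {
    i <- 3:n
    p <- peaks[i]
    hi <- pmax(peaks[i - 1L], peaks[i - 2L])
    lo <- pmin(peaks[i - 1L], peaks[i - 2L])
    lab[i] <- ifelse(p > hi, "fast", ifelse(p < lo, "slow", "intermediate"))
  }
  lab
}

# Percentile rank within a sample, in percent (mean 50 for any sample).
percentile_rank <- function(x) {
  100 * (rank(x, ties.method = "average") - 0.5) / length(x)
}

# Map stimulation blocks to their target condition ("fast"/"slow").
condition_of_blocks <- function(protocol) {
  if (is.null(protocol) || length(protocol$stim_blocks) == 0L) {
    return(character(0))
  }
  conds <- rep_len(protocol$condition_order, length(protocol$stim_blocks))
  stats::setNames(conds, as.character(protocol$stim_blocks))
}
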
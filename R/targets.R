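# Pseudorandomised target sequences for the alternating reaching task.

# Random Eulerian circuit on the bipartite multigraph whose nodes are the
# 2*n_y target positions (left/right x 4 y-positions) and whose edges are the
# trajectory classes, each with multiplicity `reps`. Every circuit visits each
# class exactly `reps` times while alternating sides, which is what balances
# the 32 trajectory classes within a 96-movement block (3 repeats each).
eulerian_block <- function(n_y, reps, start_node) {
  n_nodes <- 2L * n_y
  cnt <- matrix(0L, n_nodes, n_nodes)
  cnt[seq_len(n_y), n_y + seq_len(n_y)] <- reps
  cnt[n_y + seq_len(n_y), seq_len(n_y)] <- reps
  stack <- start_node
  circuit <- integer(0)
  while (length(stack)) {
    v <- stack[length(stack)]
    nb <- which(cnt[v, ] > 0L)
    if (length(nb)) {
      u <- if (length(nb) == 1L) nb else sample(nb, 1L)
      cnt[v, u] <- cnt[v, u] - 1L
      stack <- c(stack, u)
    } else {
      circuit <- c(circuit, v)
      stack <- stack[-length(stack)]
    }
  }
  rev(circuit)
}

#' Generate a pseudorandomised target sequence
#'
#' Produces the sequence of target positions for the alternating reaching
#' task. Targets strictly alternate between the left and right screen edge;
#' within every block each trajectory class (start-y x end-y x direction; 32
#' classes for four y-positions) occurs an equal number of times, realised as
#' a seeded random Eulerian circuit over the class multigraph.
#'
#' @param n_movements Number of movements to generate.
#' @param geometry A [task_geometry()].
#' @param seed Optional integer seed; identical seeds give identical
#'   sequences.
#' @param block_length Movements per block; must be a multiple of the number
#'   of trajectory classes.
#' @return A data frame with one row per movement: `movement`, `block`,
#'   `start_x`, `start_y`, `x`, `y` (the target) and `direction`
#'   (`"left_to_right"` or `"right_to_left"`), with the geometry attached as
#'   attribute `"geometry"`.
#' @export
generate_target_sequence <- function(n_movements, geometry = task_geometry(),
                                     seed = NULL, block_length = 96) {
  if (!is.numeric(n_movements) || length(n_movements) != 1L || n_movements < 1) {
    abort_invalid("`n_movements` must be a positive count")
  }
  n_movements <- as.integer(n_movements)
  n_y <- length(geometry$target_ys)
  n_class <- 2L * n_y^2
  if (block_length %% n_class != 0) {
    abort_invalid(sprintf(
      "`block_length` (%d) must be a multiple of the %d trajectory classes",
      block_length, n_class))
  }
  reps <- block_length %/% n_class
  n_blocks <- ceiling(n_movements / block_length)

  with_seed(seed, {
    node_seqs <- vector("list", n_blocks)
    start_node <- sample(2L * n_y, 1L)
    for (b in seq_len(n_blocks)) {
      node_seqs[[b]] <- eulerian_block(n_y, reps, start_node)
      # a circuit returns to its start, so side alternation carries across blocks
      start_node <- node_seqs[[b]][length(node_seqs[[b]])]
    }
    node_xy <- function(node) {
      left <- node <= n_y
      y_idx <- ((node - 1L) %% n_y) + 1L
      list(x = ifelse(left, geometry$target_x_left, geometry$target_x_right),
           y = geometry$target_ys[y_idx])
    }
    out <- do.call(rbind, lapply(seq_len(n_blocks), function(b) {
      nodes <- node_seqs[[b]]
      from <- node_xy(nodes[-length(nodes)])
      to <- node_xy(nodes[-1L])
      data.frame(
        movement = (b - 1L) * block_length + seq_len(block_length),
        block = b,
        start_x = from$x, start_y = from$y,
        x = to$x, y = to$y,
        direction = ifelse(to$x > from$x, "left_to_right", "right_to_left")
      )
    }))
    out <- out[seq_len(n_movements), , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "geometry") <- geometry
    out
  })
}
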
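# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the chain is simulated event-by-event, Gaussian
# masses are summed from the closed form, and the summary statistics are
# re-derived term by term.

# Event-driven (Gillespie) simulation of the two-state chain, sampled at
# frame times. Exponential waiting times in each state; state 1 = unwound.
gillespie_states <- function(p_unwound, exchange_rate, n_frames,
                             frame_interval) {
  k_open <- p_unwound * exchange_rate   # rewound -> unwound
  k_close <- (1 - p_unwound) * exchange_rate
  t_end <- n_frames * frame_interval
  state <- as.integer(runif(1) < p_unwound)
  times <- 0
  states <- state
  t <- 0
  repeat {
    rate <- if (state == 1L) k_close else k_open
    if (rate <= 0) break
    t <- t + rexp(1, rate)
    if (t >= t_end) break
    state <- 1L - state
    times <- c(times, t)
    states <- c(states, state)
  }
  # state at each frame time (left-continuous sampling at frame starts)
  frame_times <- (seq_len(n_frames) - 1) * frame_interval
  idx <- findInterval(frame_times, times)
  states[idx]
}

# Pixel-integrated 2-D Gaussian mass over a window of whole pixels, from
# the closed form (product of normal CDF differences per axis).
gauss_window_mass <- function(row, col, sigma, rows, cols) {
  wr <- pnorm(rows + 0.5, row, sigma) - pnorm(rows - 0.5, row, sigma)
  wc <- pnorm(cols + 0.5, col, sigma) - pnorm(cols - 0.5, col, sigma)
  sum(outer(wr, wc))
}

# Paint one pixel-integrated Gaussian of integrated amplitude `amp` onto an
# image matrix (used to build hand-made detection fixtures).
paint_spot <- function(img, row, col, sigma, amp) {
  rows <- max(1, floor(row - 6)):min(nrow(img), ceiling(row + 6))
  cols <- max(1, floor(col - 6)):min(ncol(img), ceiling(col + 6))
  wr <- pnorm(rows + 0.5, row, sigma) - pnorm(rows - 0.5, row, sigma)
  wc <- pnorm(cols + 0.5, col, sigma) - pnorm(cols - 0.5, col, sigma)
  img[rows, cols] <- img[rows, cols] + amp * outer(wr, wc)
  img
}

# Shared quick constructors.
quiet_photophysics <- function(...) {
  args <- utils::modifyList(list(donor_only_fraction = 0, noise_sd = 0,
                                 background = 0), list(...))
  do.call(photophysics_params, args)
}

fit_quiet <- function(traces, ...) {
  suppressWarnings(fit_unwinding(traces, min_molecules = 0, ...))
}

# Greedy matching of detected spots to true positions within a radius;
# returns recall/precision bookkeeping.
match_spots <- function(spots, true_rows, true_cols, radius = 2) {
  if (nrow(spots) == 0)
    return(list(recall = 0, precision = NA_real_, matched_true = integer(0)))
  d2 <- outer(spots$row, true_rows, "-")^2 + outer(spots$col, true_cols, "-")^2
  matched_true <- which(apply(d2, 2, min) < radius^2)
  tp <- sum(apply(d2, 1, min) < radius^2)
  list(recall = length(matched_true) / length(true_rows),
       precision = tp / nrow(spots),
       matched_true = matched_true)
}
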
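#' Simulate rewound/unwound state trajectories
#'
#' Samples the two-state continuous-time Markov chain at the frame times
#' using its exact discrete-time propagator: with total exchange rate
#' `k = k_open + k_close` and equilibrium occupancy `p = k_open / k`, the
#' probability of being unwound one frame after being rewound is
#' `p * (1 - exp(-k * dt))`, and after being unwound it is
#' `p + (1 - p) * exp(-k * dt)`. The initial state is an equilibrium draw.
#' No time discretisation error is incurred, which an event-driven
#' (Gillespie) simulation of the same chain confirms.
#'
#' @param kinetics A [kinetic_params()] object.
#' @param n_frames Number of frames (>= 1).
#' @param frame_interval Frame time in seconds.
#' @param n_molecules Number of independent trajectories.
#' @param seed Optional integer seed; when given the result is reproducible.
#' @return Integer matrix (`n_molecules` x `n_frames`); 1 = unwound,
#'   0 = rewound.
#' @examples
#' simulate_states(kinetic_params(k_open = 0, k_close = 1), 5, seed = 1) # all rewound
#' @export
simulate_states <- function(kinetics, n_frames, frame_interval = 0.1,
                            n_molecules = 1, seed = NULL) {
  stopifnot(inherits(kinetics, "kinetic_params"))
  if (n_frames < 1) stop("n_frames must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n_molecules)
  tt <- as.integer(n_frames)
  p <- kinetics$p_unwound
  k <- kinetics$k_open + kinetics$k_close
  decay <- exp(-k * frame_interval)           # 1 when both rates are 0 (frozen)
  p_u_from_r <- p * (1 - decay)
  p_u_from_u <- p + (1 - p) * decay
  s <- matrix(0L, n, tt)
  s[, 1L] <- as.integer(stats::runif(n) < p)
  if (tt > 1L) {
    u <- matrix(stats::runif(n * (tt - 1L)), n, tt - 1L)
    for (t in 2:tt) {
      prev <- s[, t - 1L]
      s[, t] <- as.integer(u[, t - 1L] < ifelse(prev == 1L, p_u_from_u, p_u_from_r))
    }
  }
  s
}

#' Simulate a set of per-molecule donor/acceptor intensity traces
#'
#' Generates a population of immobilised molecules under one experimental
#' condition, together with full ground truth. Each molecule is assigned a
#' donor-only flag, a state trajectory from [simulate_states()], independent
#' geometric bleach frames for acceptor and donor, and per-frame channel
#' intensities `I_A = E * total_intensity + background` and
#' `I_D = (1 - E) * total_intensity + background` plus per-channel Gaussian
#' noise. Donor-only molecules (and molecules past their acceptor bleach
#' frame) emit all signal in the donor channel; past the donor bleach frame
#' both channels emit background only.
#'
#' @param cond A [condition()] object.
#' @param n_molecules Number of molecules (>= 1).
#' @param n_frames Frames per trace.
#' @param frame_interval Frame time in seconds.
#' @param seed Optional integer seed; identical seeds and parameters give
#'   bit-identical output.
#' @return A list of class `sim_traces` with elements `traces` (a
#'   [trace_set()]) and `truth` (a `ground_truth` object, see
#'   [ground_truth()]).
#' @export
simulate_traces <- function(cond, n_molecules, n_frames = 10,
                            frame_interval = 0.1, seed = NULL) {
  stopifnot(inherits(cond, "fret_condition"))
  if (n_molecules < 1) stop("n_molecules must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n_molecules)
  tt <- as.integer(n_frames)
  ph <- cond$photophysics

  donor_only <- stats::runif(n) < ph$donor_only_fraction
  states <- simulate_states(cond$kinetics, tt, frame_interval, n)
  bleach_a <- bleach_frames(n, tt, ph$bleach_rate)
  bleach_d <- bleach_frames(n, tt, ph$bleach_rate)

  frame_idx <- matrix(rep(seq_len(tt), each = n), n, tt)
  acceptor_on <- !donor_only & (frame_idx < bleach_a)
  donor_on <- frame_idx < bleach_d

  e_state <- ifelse(states == 1L, ph$e_unwound, ph$e_rewound)
  e_true <- ifelse(acceptor_on, e_state, 0)
  e_true[!donor_on] <- NA_real_

  emitting <- donor_on
  i_a <- ifelse(emitting, ifelse(acceptor_on, e_state, 0) * ph$total_intensity, 0)
  i_d <- ifelse(emitting, (1 - ifelse(acceptor_on, e_state, 0)) * ph$total_intensity, 0)
  i_a <- i_a + ph$background
  i_d <- i_d + ph$background
  if (ph$noise_sd > 0) {
    i_d <- i_d + matrix(stats::rnorm(n * tt, sd = ph$noise_sd), n, tt)
    i_a <- i_a + matrix(stats::rnorm(n * tt, sd = ph$noise_sd), n, tt)
  }

  mol <- data.frame(molecule_id = seq_len(n),
                    donor_only = donor_only,
                    bleach_frame_acceptor = ifelse(bleach_a > tt, NA_integer_, bleach_a),
                    bleach_frame_donor = ifelse(bleach_d > tt, NA_integer_, bleach_d))
  traces <- trace_set(i_d, i_a, frame_interval,
                      provenance = sprintf("simulate_traces('%s')", cond$label))
  truth <- ground_truth(mol, states, e_true, condition = cond)
  structure(list(traces = traces, truth = truth), class = "sim_traces")
}

# First frame (1-based) at which a dye has bleached; tt + 1 means "never
# within the trace". rate is per-frame single-step probability.
bleach_frames <- function(n, tt, rate) {
  if (rate <= 0) return(rep(tt + 1L, n))
  # geometric: number of surviving frames before the bleach event
  pmin(stats::rgeom(n, rate) + 1L, tt + 1L)
}

#' Per-molecule donor/acceptor intensity traces
#'
#' Container for background-corrected per-molecule, per-frame donor (`I_D`)
#' and acceptor (`I_A`) intensities. Values are counts/frame and may be
#' slightly negative after background subtraction.
#'
#' @param i_d,i_a Numeric matrices (molecules x frames) of donor and
#'   acceptor intensities.
#' @param frame_interval Frame time in seconds.
#' @param molecule_id Optional molecule identifiers (default row index).
#' @param provenance Character note on where the traces came from.
#' @return An object of class `trace_set`.
#' @export
trace_set <- function(i_d, i_a, frame_interval = 0.1,
                      molecule_id = NULL, provenance = "") {
  i_d <- as.matrix(i_d); i_a <- as.matrix(i_a)
  if (!identical(dim(i_d), dim(i_a)))
    stop("I_D and I_A must have identical dimensions")
  if (any(!is.finite(i_d)) || any(!is.finite(i_a)))
    stop("trace intensities must be finite")
  if (is.null(molecule_id)) molecule_id <- seq_len(nrow(i_d))
  if (length(molecule_id) != nrow(i_d))
    stop("molecule_id length must match the number of molecules")
  structure(list(i_d = unname(i_d), i_a = unname(i_a),
                 frame_interval = frame_interval,
                 molecule_id = molecule_id, provenance = provenance),
            class = "trace_set")
}

#' Ground truth for a synthetic data set
#'
#' Book-keeping container that makes parameter-recovery tests possible: per
#' molecule the donor-only flag, bleach frames and (for movies) the true
#' positions in both channel halves, plus the full state trajectory and the
#' true per-frame FRET efficiency (0 for donor-only/acceptor-bleached
#' frames, `NA` after donor bleaching).
#'
#' @param molecules Data frame with one row per molecule.
#' @param states Integer matrix (molecules x frames); 1 = unwound.
#' @param e_true Numeric matrix of true per-frame FRET efficiencies.
#' @param condition The generating [condition()], kept for reference.
#' @return An object of class `ground_truth`.
#' @export
ground_truth <- function(molecules, states, e_true, condition = NULL) {
  stopifnot(is.data.frame(molecules), nrow(molecules) == nrow(states),
            identical(dim(states), dim(e_true)))
  structure(list(molecules = molecules, states = states, e_true = e_true,
                 condition = condition),
            class = "ground_truth")
}

#' Number of molecules in a trace set
#' @param x A `trace_set`.
#' @return Integer count.
#' @export
n_molecules <- function(x) {
  stopifnot(inherits(x, "trace_set"))
  nrow(x$i_d)
}

#' @export
print.trace_set <- function(x, ...) {
  cat(sprintf("trace_set: %d molecules x %d frames (%.3g s/frame)%s\n",
              nrow(x$i_d), ncol(x$i_d), x$frame_interval,
              if (nzchar(x$provenance)) paste0(" [", x$provenance, "]") else ""))
  invisible(x)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("ground_truth: %d molecules, %d frames; %d donor-only\n",
              nrow(x$molecules), ncol(x$states), sum(x$molecules$donor_only)))
  invisible(x)
}

#' @export
print.sim_traces <- function(x, ...) {
  print(x$traces); print(x$truth)
  invisible(x)
}
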
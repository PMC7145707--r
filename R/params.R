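#' Two-state kinetic parameters for the rewound/unwound equilibrium
#'
#' Cas9-RNA induced DNA unwinding is modelled as a reversible two-state
#' system: a high-FRET rewound state (duplex reformed, E ~ 0.75) and a
#' low-FRET unwound state (R-loop open, E ~ 0.3). The chain is
#' parameterised either by the equilibrium occupancy of the unwound state
#' (`p_unwound`, the simulated analogue of the unwound fraction) or by the
#' microscopic rates `k_open` (rewound to unwound) and `k_close` (unwound
#' to rewound).
#'
#' The published histograms constrain only the equilibrium populations, not
#' the exchange rates; when only `p_unwound` is given the rates default to a
#' total exchange rate `exchange_rate` that is slow relative to the frame
#' time, so the first few frames of a trace sample a quasi-static state.
#' This default is a placeholder, not a measured quantity.
#'
#' @param p_unwound Equilibrium occupancy of the unwound state, in `[0, 1]`.
#'   May be omitted when both rates are given.
#' @param k_open Rate (per second, >= 0) of the rewound -> unwound transition.
#' @param k_close Rate (per second, >= 0) of the unwound -> rewound transition.
#' @param exchange_rate Total exchange rate `k_open + k_close` (per second)
#'   used to derive rates when only `p_unwound` is supplied. Default 0.5/s,
#'   i.e. mean dwell times of seconds, long compared to 35-100 ms frames.
#' @return An object of class `kinetic_params`: a list with fields
#'   `p_unwound`, `k_open`, `k_close`.
#' @examples
#' kinetic_params(p_unwound = 0.6)
#' kinetic_params(k_open = 2, k_close = 2) # p_unwound = 0.5
#' @export
kinetic_params <- function(p_unwound = NULL, k_open = NULL, k_close = NULL,
                           exchange_rate = 0.5) {
  has_rates <- !is.null(k_open) && !is.null(k_close)
  if (!has_rates && is.null(p_unwound))
    stop("supply either p_unwound or both k_open and k_close")
  if (has_rates) {
    for (nm in c("k_open", "k_close")) {
      v <- get(nm)
      if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
        stop(sprintf("%s must be a single finite non-negative rate", nm))
    }
    k_tot <- k_open + k_close
    p_eq <- if (k_tot > 0) k_open / k_tot else NA_real_
    if (!is.null(p_unwound)) {
      if (is.na(p_eq)) {
        p_eq <- p_unwound  # both rates zero: frozen chain, occupancy sets the initial draw
      } else if (abs(p_unwound - p_eq) > 1e-12) {
        stop(sprintf(
          "inconsistent parameters: p_unwound = %.15g but k_open/(k_open+k_close) = %.15g",
          p_unwound, p_eq))
      }
    }
    if (is.na(p_eq))
      stop("with k_open = k_close = 0, p_unwound must be supplied")
    p_unwound <- p_eq
  } else {
    if (!is.numeric(p_unwound) || length(p_unwound) != 1L || !is.finite(p_unwound))
      stop("p_unwound must be a single finite probability")
    if (p_unwound < 0 || p_unwound > 1)
      stop("p_unwound must lie in [0, 1]")
    if (!is.numeric(exchange_rate) || length(exchange_rate) != 1L ||
        !is.finite(exchange_rate) || exchange_rate < 0)
      stop("exchange_rate must be a single finite non-negative rate")
    k_open <- p_unwound * exchange_rate
    k_close <- (1 - p_unwound) * exchange_rate
  }
  if (p_unwound < 0 || p_unwound > 1)
    stop("p_unwound must lie in [0, 1]")
  structure(list(p_unwound = p_unwound, k_open = k_open, k_close = k_close),
            class = "kinetic_params")
}

#' Photophysical parameters of the simulated dye pair
#'
#' Describes the state-dependent FRET efficiencies and the intensity model
#' of a simulated molecule. Before noise, a molecule in state `s` with
#' efficiency `E_s` emits `I_A = E_s * total_intensity + background` in the
#' acceptor channel and `I_D = (1 - E_s) * total_intensity + background` in
#' the donor channel, so total emission is roughly constant across states.
#' Per-channel additive Gaussian noise of standard deviation `noise_sd` is
#' then added (EMCCD excess noise at these count levels is approximately
#' Gaussian, and a single SD keeps the FRET-broadening interpretable).
#'
#' A fraction `donor_only_fraction` of molecules carries an inactive or
#' missing acceptor: they emit all signal in the donor channel and appear
#' at E = 0. `bleach_rate` is a per-frame single-step photobleaching
#' probability, applied independently to each dye; after acceptor bleaching
#' the molecule becomes donor-only, after donor bleaching both channels
#' emit background only.
#'
#' @param e_rewound FRET efficiency of the high-FRET rewound state, in (0, 1].
#' @param e_unwound FRET efficiency of the low-FRET unwound state, in [0, 1);
#'   must be below `e_rewound`.
#' @param total_intensity Mean total emission, counts/frame (> 0).
#' @param noise_sd Per-channel additive Gaussian noise SD, counts/frame (>= 0).
#'   The default 25 counts at `total_intensity = 500` gives a per-frame FRET
#'   efficiency SD of about 0.04 in either state.
#' @param background Per-channel additive background, counts/frame (>= 0).
#'   Extracted traces are background-corrected, so the default is 0.
#' @param donor_only_fraction Probability that a molecule is donor-only.
#' @param bleach_rate Per-frame, per-dye bleaching probability in [0, 1).
#' @return An object of class `photophysics_params`.
#' @export
photophysics_params <- function(e_rewound = 0.75, e_unwound = 0.30,
                                total_intensity = 500, noise_sd = 25,
                                background = 0, donor_only_fraction = 0.1,
                                bleach_rate = 0) {
  num1 <- function(v, nm) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop(sprintf("%s must be a single finite number", nm))
    v
  }
  e_rewound <- num1(e_rewound, "e_rewound")
  e_unwound <- num1(e_unwound, "e_unwound")
  if (e_rewound <= 0 || e_rewound > 1) stop("e_rewound must lie in (0, 1]")
  if (e_unwound < 0 || e_unwound >= 1) stop("e_unwound must lie in [0, 1)")
  if (e_unwound >= e_rewound) stop("e_unwound must be smaller than e_rewound")
  if (num1(total_intensity, "total_intensity") <= 0)
    stop("total_intensity must be positive")
  if (num1(noise_sd, "noise_sd") < 0) stop("noise_sd must be non-negative")
  if (num1(background, "background") < 0) stop("background must be non-negative")
  if (num1(donor_only_fraction, "donor_only_fraction") < 0 ||
      donor_only_fraction >= 1)
    stop("donor_only_fraction must lie in [0, 1)")
  if (num1(bleach_rate, "bleach_rate") < 0 || bleach_rate >= 1)
    stop("bleach_rate must lie in [0, 1)")
  structure(list(e_rewound = e_rewound, e_unwound = e_unwound,
                 total_intensity = total_intensity, noise_sd = noise_sd,
                 background = background,
                 donor_only_fraction = donor_only_fraction,
                 bleach_rate = bleach_rate),
            class = "photophysics_params")
}

#' Experimental condition: Cas9 variant x gRNA design x PAM-distal mismatches
#'
#' Bundles the simulation parameters of one experimental condition. `n_pd`
#' is the number of PAM-distal base-pair mismatches between the gRNA spacer
#' and the protospacer (0 = cognate DNA), the mismatch axis along which the
#' unwound fraction is profiled.
#'
#' @param label Condition label, typically the Cas9 variant name.
#' @param n_pd Number of PAM-distal mismatches, an integer in 0..4.
#' @param kinetics A [kinetic_params()] object.
#' @param photophysics A [photophysics_params()] object.
#' @param grna gRNA design label; one of `"X20"`, `"gX20"`, `"ggX20"`
#'   (canonical and 5'-guanine-extended, full 20-nt hybridising region) or
#'   `"X18"`, `"gX18"`, `"X17"` (5'-truncated). Truncated designs cannot be
#'   assigned a specificity score.
#' @return An object of class `fret_condition`.
#' @export
condition <- function(label, n_pd = 0L, kinetics = kinetic_params(0.5),
                      photophysics = photophysics_params(), grna = "X20") {
  if (!is.character(label) || length(label) != 1L || !nzchar(label))
    stop("label must be a non-empty string")
  if (length(n_pd) != 1L || is.na(n_pd) || n_pd != as.integer(n_pd) ||
      !(as.integer(n_pd) %in% 0:4))
    stop("n_pd must be an integer in {0, 1, 2, 3, 4}")
  stopifnot(inherits(kinetics, "kinetic_params"),
            inherits(photophysics, "photophysics_params"))
  grna <- match.arg(grna, grna_designs())
  structure(list(label = label, n_pd = as.integer(n_pd), kinetics = kinetics,
                 photophysics = photophysics, grna = grna),
            class = "fret_condition")
}

#' gRNA design vocabulary
#'
#' @return Character vector of recognised gRNA design labels.
#' @export
grna_designs <- function() c("X20", "gX20", "ggX20", "X18", "gX18", "X17")

#' gRNA designs whose specificity S is undefined
#'
#' Truncated gRNAs cannot base-pair with the full 20 nucleotides of the
#' protospacer, so unwinding promiscuity and specificity, defined against
#' PAM-distal mismatches of a 20-nt spacer, cannot be determined for them.
#'
#' @return Character vector of truncated design labels.
#' @export
truncated_designs <- function() c("X18", "gX18", "X17")

#' Build a panel of conditions from an occupancy-vs-mismatch profile
#'
#' Convenience constructor for a mismatch series: one condition per `n_pd`
#' value, sharing photophysics, with kinetics set to the stated equilibrium
#' occupancies of the unwound state.
#'
#' @param profile Named numeric vector mapping `n_pd` (names `"0"`..`"4"`) to
#'   the unwound-state equilibrium occupancy in `[0, 1]`.
#' @param photophysics Shared [photophysics_params()].
#' @param label Condition label applied to every member.
#' @param grna gRNA design label applied to every member.
#' @param exchange_rate Passed to [kinetic_params()].
#' @return A list of [condition()] objects, one per profile entry.
#' @examples
#' condition_panel(c(`0` = 0.9, `1` = 0.3, `2` = 0.1, `3` = 0.05), label = "WT")
#' @export
condition_panel <- function(profile, photophysics = photophysics_params(),
                            label = "condition", grna = "X20",
                            exchange_rate = 0.5) {
  if (length(profile) == 0L) return(list())
  if (is.null(names(profile)) || any(!nzchar(names(profile))))
    stop("profile must be a named vector with n_pd values as names")
  npd <- suppressWarnings(as.integer(names(profile)))
  if (anyNA(npd) || !all(npd %in% 0:4))
    stop("profile names must be n_pd values in {0, 1, 2, 3, 4}")
  if (any(!is.finite(profile)) || any(profile < 0 | profile > 1))
    stop("occupancies must lie in [0, 1]")
  lapply(seq_along(profile), function(i) {
    condition(label = label, n_pd = npd[i],
              kinetics = kinetic_params(p_unwound = unname(profile[i]),
                                        exchange_rate = exchange_rate),
              photophysics = photophysics, grna = grna)
  })
}

#' Movie geometry and camera parameters
#'
#' Describes the rendered dual-channel recording: both emission paths are
#' projected side by side onto one EMCCD frame, donor on the left half
#' (columns `1..width/2`) and acceptor on the right half. Coordinates are
#' 1-based pixel centres. The acceptor-half position of a molecule maps to
#' its donor-half position by the pure translation `channel_offset`.
#'
#' @param n_frames Number of frames (>= 1).
#' @param frame_interval Frame time in seconds; the recordings emulated here
#'   used 0.100 or 0.035 s.
#' @param height,width Frame size in pixels; `width` must be even.
#' @param psf_sigma Gaussian point-spread-function SD in pixels (> 0).
#' @param n_molecules Number of molecules to plant.
#' @param channel_offset Numeric `c(dx, dy)`: donor-half column = acceptor
#'   column + `dx`, donor-half row = acceptor row + `dy` (sub-pixel allowed).
#' @param camera_baseline Constant per-pixel camera pedestal, counts.
#' @param camera_read_sd Per-pixel Gaussian read-noise SD, counts.
#' @param min_separation Minimum allowed distance between planted spots in
#'   pixels; default `6 * psf_sigma`, below which aperture photometry of
#'   neighbouring spots overlaps.
#' @return An object of class `movie_params`.
#' @export
movie_params <- function(n_frames = 15, frame_interval = 0.1, height = 360,
                         width = 720, psf_sigma = 1.1, n_molecules = 100,
                         channel_offset = c(0, 0), camera_baseline = 100,
                         camera_read_sd = 3,
                         min_separation = 6 * psf_sigma) {
  if (n_frames < 1) stop("n_frames must be >= 1")
  if (!frame_interval > 0) stop("frame_interval must be positive")
  if (width %% 2 != 0) stop("width must be even (two channel halves)")
  if (height < 16 || width < 32) stop("frame too small")
  if (!psf_sigma > 0) stop("psf_sigma must be positive")
  if (n_molecules < 0) stop("n_molecules must be non-negative")
  if (length(channel_offset) != 2L || any(!is.finite(channel_offset)))
    stop("channel_offset must be finite c(dx, dy)")
  if (camera_baseline < 0 || camera_read_sd < 0)
    stop("camera parameters must be non-negative")
  if (!min_separation > 0) stop("min_separation must be positive")
  structure(list(n_frames = as.integer(n_frames),
                 frame_interval = frame_interval,
                 height = as.integer(height), width = as.integer(width),
                 psf_sigma = psf_sigma, n_molecules = as.integer(n_molecules),
                 channel_offset = as.numeric(channel_offset),
                 camera_baseline = camera_baseline,
                 camera_read_sd = camera_read_sd,
                 min_separation = min_separation),
            class = "movie_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat(sprintf("Two-state kinetics: p_unwound = %.4g (k_open = %.4g/s, k_close = %.4g/s)\n",
              x$p_unwound, x$k_open, x$k_close))
  invisible(x)
}

#' @export
print.fret_condition <- function(x, ...) {
  cat(sprintf("Condition '%s' (%s, n_PD = %d): p_unwound = %.4g, E = %.2f/%.2f\n",
              x$label, x$grna, x$n_pd, x$kinetics$p_unwound,
              x$photophysics$e_unwound, x$photophysics$e_rewound))
  invisible(x)
}
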
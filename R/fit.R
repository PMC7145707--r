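#' Fit the two-state unwinding model to a set of smFRET traces
#'
#' The central estimator of the package. DNA unwinding by Cas9-RNA is a
#' reversible two-state equilibrium between a high-FRET rewound state and a
#' low-FRET unwound state; its occupancy is estimated from the E histogram
#' by threshold classification. The fit pools the first `k` valid E values
#' of every molecule ([pool_first_k()]), classifies them into donor-only /
#' low / high populations ([classify_populations()]) and estimates the
#' unwound fraction
#' \deqn{\hat f_{unwound} = n_{low} / (n_{low} + n_{high}),}
#' excluding the donor-only population from the denominator by default
#' (donor-only molecules carry no unwinding information;
#' `include_donor_only = TRUE` adds them to the denominator for
#' comparison). Uncertainty is a nonparametric bootstrap over molecules
#' (not frames, which are correlated within a molecule), resampling
#' per-molecule class counts with replacement.
#'
#' @param traces A [trace_set()], a `fret_series`, or a `fret_sample`.
#' @param thresholds A [fret_thresholds()] object.
#' @param k Leading valid frames pooled per molecule (default 5).
#' @param n_boot Bootstrap replicates for the SD (default 1000; 0 disables).
#' @param seed Optional integer seed for the bootstrap.
#' @param include_donor_only Include the donor-only count in the
#'   denominator of the unwound fraction (default `FALSE`).
#' @param floor,total_intensity Passed to [fret_efficiency()] when `traces`
#'   is a `trace_set`.
#' @param min_molecules Passed to [pool_first_k()].
#' @param label Optional condition label.
#' @return An object of class `unwind_fit` with components `f_unwound`,
#'   `sd`, `counts` (a `population_counts`), `n_molecules`, `k`,
#'   `thresholds`, `mean_e_low`, `mean_e_high`, `boot` (bootstrap
#'   replicates), `sample` (the pooled `fret_sample`), `label`, `call`.
#'   Methods: [print()], [summary()], [coef()], [confint()], [plot()],
#'   [simulate()].
#' @examples
#' cond <- condition("demo", kinetics = kinetic_params(0.4),
#'                   photophysics = photophysics_params(donor_only_fraction = 0))
#' sim <- simulate_traces(cond, 300, n_frames = 6, seed = 1)
#' fit <- fit_unwinding(sim$traces, n_boot = 100, seed = 1,
#'                      min_molecules = 0, label = "demo")
#' coef(fit)
#' @export
fit_unwinding <- function(traces, thresholds = fret_thresholds(), k = 5,
                          n_boot = 1000, seed = NULL,
                          include_donor_only = FALSE, floor = NULL,
                          total_intensity = NULL, min_molecules = 2000,
                          label = NULL) {
  cl <- match.call()
  sample <- if (inherits(traces, "fret_sample")) {
    traces
  } else {
    fs <- if (inherits(traces, "trace_set"))
      fret_efficiency(traces, floor = floor, total_intensity = total_intensity)
    else traces
    stopifnot(inherits(fs, "fret_series"))
    pool_first_k(fs, k = k, min_molecules = min_molecules, label = label)
  }
  if (sample$n_molecules < 2)
    stop("at least 2 molecules are required")
  if (is.null(label)) label <- sample$label

  cls <- classify_e(sample$e, thresholds)
  counts <- structure(list(n_donor_only = sum(cls == 0L),
                           n_low = sum(cls == 1L),
                           n_high = sum(cls == 2L),
                           thresholds = thresholds),
                      class = "population_counts")
  f_est <- f_from_counts(counts$n_donor_only, counts$n_low, counts$n_high,
                         include_donor_only)
  if (!is.finite(f_est))
    stop("no FRET-active molecules: low and high populations are both empty")

  # per-molecule class counts drive the molecule-level bootstrap
  n <- sample$n_molecules
  per_mol <- matrix(0L, n, 3L)
  for (j in 0:2)
    per_mol[, j + 1L] <- tabulate(sample$molecule[cls == j], nbins = n)

  boot <- numeric(0)
  sd_f <- NA_real_
  if (n_boot > 0) {
    if (!is.null(seed)) set.seed(seed)
    boot <- numeric(n_boot)
    for (b in seq_len(n_boot)) {
      idx <- sample.int(n, n, replace = TRUE)
      cs <- colSums(per_mol[idx, , drop = FALSE])
      boot[b] <- f_from_counts(cs[1], cs[2], cs[3], include_donor_only)
    }
    sd_f <- stats::sd(boot[is.finite(boot)])
  }

  low <- cls == 1L
  high <- cls == 2L
  structure(list(f_unwound = f_est, sd = sd_f, counts = counts,
                 n_molecules = n, k = sample$k, thresholds = thresholds,
                 include_donor_only = include_donor_only,
                 mean_e_low = if (any(low)) mean(sample$e[low]) else NA_real_,
                 mean_e_high = if (any(high)) mean(sample$e[high]) else NA_real_,
                 boot = boot, sample = sample, label = label, call = cl),
            class = "unwind_fit")
}

# 0 = donor-only, 1 = low, 2 = high
classify_e <- function(e, thresholds) {
  out <- rep(1L, length(e))
  out[e <= thresholds$donor_only_max] <- 0L
  out[e >= thresholds$low_high_boundary] <- 2L
  out
}

f_from_counts <- function(n_donor, n_low, n_high, include_donor_only) {
  den <- n_low + n_high + if (include_donor_only) n_donor else 0L
  if (den == 0) return(NA_real_)
  n_low / den
}

#' @export
print.unwind_fit <- function(x, ...) {
  cat(sprintf("Two-state unwinding fit%s\n",
              if (!is.null(x$label)) paste0(": ", x$label) else ""))
  cat(sprintf("  f_unwound = %.4f (bootstrap SD %s), %d molecules, first %d frames\n",
              x$f_unwound,
              if (is.finite(x$sd)) sprintf("%.4f", x$sd) else "not computed",
              x$n_molecules, x$k))
  invisible(x)
}

#' @export
coef.unwind_fit <- function(object, ...) {
  c(f_unwound = object$f_unwound)
}

#' @export
confint.unwind_fit <- function(object, parm = "f_unwound", level = 0.95, ...) {
  if (!length(object$boot))
    stop("no bootstrap replicates stored; refit with n_boot > 0")
  a <- (1 - level) / 2
  q <- stats::quantile(object$boot[is.finite(object$boot)], c(a, 1 - a),
                       names = FALSE)
  out <- matrix(q, 1, 2,
                dimnames = list("f_unwound",
                                sprintf("%.1f %%", 100 * c(a, 1 - a))))
  out
}

#' @export
summary.unwind_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.unwind_fit")
}

#' @export
print.summary.unwind_fit <- function(x, ...) {
  f <- x$fit
  print(f)
  tot <- f$counts$n_donor_only + f$counts$n_low + f$counts$n_high
  cat(sprintf("  pooled E values: %d (donor-only %d, low %d, high %d)\n",
              tot, f$counts$n_donor_only, f$counts$n_low, f$counts$n_high))
  cat(sprintf("  thresholds: donor-only <= %.2f, low/high boundary %.2f%s\n",
              f$thresholds$donor_only_max, f$thresholds$low_high_boundary,
              if (f$include_donor_only) " (donor-only in denominator)" else ""))
  cat(sprintf("  mean E: low %.3f, high %.3f\n", f$mean_e_low, f$mean_e_high))
  if (length(f$boot)) {
    ci <- confint(f)
    cat(sprintf("  95%% bootstrap CI: [%.4f, %.4f] (%d replicates)\n",
                ci[1], ci[2], length(f$boot)))
  }
  invisible(x)
}

#' Plot the FRET-efficiency histogram behind an unwinding fit
#'
#' Draws the binned E histogram of the pooled sample with the
#' classification thresholds and the fitted unwound fraction annotated.
#'
#' @param x An `unwind_fit`.
#' @param bin_width,range Passed to [fret_histogram()].
#' @param ... Further arguments passed to [graphics::barplot()].
#' @return The histogram data frame, invisibly.
#' @export
plot.unwind_fit <- function(x, bin_width = 0.02, range = c(-0.1, 1.1), ...) {
  h <- fret_histogram(x$sample, bin_width = bin_width, range = range)
  mid <- (h$bin_lo + h$bin_hi) / 2
  graphics::barplot(h$density, names.arg = NULL, space = 0, border = NA,
                    col = "grey40",
                    xlab = "FRET efficiency E", ylab = "density",
                    main = sprintf("%s: f_unwound = %.3f",
                                   if (!is.null(x$label)) x$label else "unwind_fit",
                                   x$f_unwound), ...)
  usr_x <- function(e) (e - range[1]) / bin_width
  graphics::abline(v = usr_x(x$thresholds$donor_only_max), lty = 2, col = "red")
  graphics::abline(v = usr_x(x$thresholds$low_high_boundary), lty = 2, col = "blue")
  graphics::axis(1, at = usr_x(seq(0, 1, 0.25)), labels = seq(0, 1, 0.25))
  invisible(h)
}

#' Simulate new trace sets from a fitted unwinding model
#'
#' Generates synthetic trace sets whose unwound-state occupancy equals the
#' fitted `f_unwound` and whose state FRET efficiencies default to the
#' fitted population means, enabling parametric-bootstrap style checks.
#'
#' @param object An `unwind_fit`.
#' @param nsim Number of trace sets.
#' @param seed Optional integer seed.
#' @param n_molecules,n_frames Size of each simulated set (defaults: as
#'   fitted; `n_frames = k`).
#' @param photophysics Optional [photophysics_params()] overriding the
#'   defaults derived from the fit.
#' @param ... Unused.
#' @return A list of `nsim` objects of class `sim_traces`.
#' @export
simulate.unwind_fit <- function(object, nsim = 1, seed = NULL,
                                n_molecules = object$n_molecules,
                                n_frames = object$k,
                                photophysics = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(photophysics)) {
    e_lo <- if (is.finite(object$mean_e_low)) object$mean_e_low else 0.3
    e_hi <- if (is.finite(object$mean_e_high)) object$mean_e_high else 0.75
    photophysics <- photophysics_params(e_rewound = min(e_hi, 1),
                                        e_unwound = max(e_lo, 0),
                                        donor_only_fraction = 0)
  }
  cond <- condition(label = if (!is.null(object$label)) object$label else "simulated",
                    kinetics = kinetic_params(object$f_unwound),
                    photophysics = photophysics)
  lapply(seq_len(nsim), function(i)
    simulate_traces(cond, n_molecules, n_frames))
}
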
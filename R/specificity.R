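#' Unwound-fraction profile across PAM-distal mismatches
#'
#' Collects the estimated unwound fraction for one Cas9 variant x gRNA
#' combination across DNA targets with `n_pd` = 0..4 PAM-distal mismatches
#' (0 = cognate DNA). Specificity requires `n_pd` 0 through 3; `n_pd = 4`
#' may be present but never enters the score.
#'
#' @param fits Either a list of [fit_unwinding()] objects (one per `n_pd`,
#'   matched by position to `n_pd`), or a data frame with columns `n_pd`,
#'   `f_unwound` and optionally `sd`.
#' @param n_pd Integer vector of mismatch counts when `fits` is a list of
#'   fits (default `0:(length(fits) - 1)`).
#' @param label Condition label (Cas9 variant).
#' @param grna gRNA design, one of [grna_designs()].
#' @return An object of class `mismatch_profile`: a data frame with
#'   columns `n_pd`, `f_unwound`, `sd` and attributes `label`, `grna`.
#' @export
mismatch_profile <- function(fits, n_pd = NULL, label = "condition",
                             grna = "X20") {
  grna <- match.arg(grna, grna_designs())
  if (is.data.frame(fits)) {
    if (!all(c("n_pd", "f_unwound") %in% names(fits)))
      stop("data frame must have columns n_pd and f_unwound")
    df <- data.frame(n_pd = as.integer(fits$n_pd),
                     f_unwound = fits$f_unwound,
                     sd = if ("sd" %in% names(fits)) fits$sd else NA_real_)
  } else {
    stopifnot(is.list(fits), all(vapply(fits, inherits, TRUE, "unwind_fit")))
    if (is.null(n_pd)) n_pd <- seq_along(fits) - 1L
    if (length(n_pd) != length(fits)) stop("n_pd must match fits in length")
    df <- data.frame(n_pd = as.integer(n_pd),
                     f_unwound = vapply(fits, function(f) f$f_unwound, 0),
                     sd = vapply(fits, function(f) f$sd, 0))
  }
  if (anyNA(df$n_pd) || !all(df$n_pd %in% 0:4))
    stop("n_pd must lie in {0, 1, 2, 3, 4}")
  if (anyDuplicated(df$n_pd)) stop("duplicate n_pd entries")
  if (any(!is.finite(df$f_unwound)) ||
      any(df$f_unwound < 0 | df$f_unwound > 1))
    stop("f_unwound values must lie in [0, 1]")
  df <- df[order(df$n_pd), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, label = label, grna = grna,
            class = c("mismatch_profile", "data.frame"))
}

profile_value <- function(profile, n, what = "f_unwound") {
  i <- match(n, profile$n_pd)
  if (is.na(i))
    stop(sprintf("profile '%s' is missing n_pd = %d", attr(profile, "label"), n))
  profile[[what]][i]
}

#' Unwinding promiscuity
#'
#' Promiscuity is the mismatch-weighted aggregate of off-target unwinding:
#' \deqn{P = \sum_{n_{PD} = 1}^{3} n_{PD} \, f_{unwound}(n_{PD}),}
#' so unwinding a target with more PAM-distal mismatches incurs a larger
#' penalty. Its SD combines the per-condition SDs in quadrature with the
#' same weights (the three conditions are independent experiments).
#'
#' @param profile A [mismatch_profile()] containing `n_pd` 1, 2 and 3.
#' @return List with `value` and `sd`.
#' @examples
#' p <- mismatch_profile(data.frame(n_pd = 0:3,
#'                                  f_unwound = c(0.9, 0.3, 0.1, 0.05)))
#' promiscuity(p)$value # 0.3 + 0.2 + 0.15 = 0.65
#' @export
promiscuity <- function(profile) {
  stopifnot(inherits(profile, "mismatch_profile"))
  f <- vapply(1:3, profile_value, 0, profile = profile)
  s <- vapply(1:3, profile_value, 0, profile = profile, what = "sd")
  list(value = sum((1:3) * f),
       sd = if (all(is.finite(s))) sqrt(sum(((1:3) * s)^2)) else NA_real_)
}

#' Unwinding specificity S
#'
#' The headline comparison statistic: the ratio of on-target unwinding
#' activity to unwinding promiscuity,
#' \deqn{S = f_{unwound}(0) \Big/ \sum_{n_{PD}=1}^{3} n_{PD}\,
#'   f_{unwound}(n_{PD}).}
#' An ideal enzyme/guide combination unwinds cognate DNA fully and
#' mismatched DNA not at all, giving large S. The SD of S is first-order
#' (delta-method) propagation of the ratio; a molecule-level bootstrap
#' alternative is available via `sd_method = "bootstrap"` when the profile
#' rows carry bootstrap replicates (profiles built from [fit_unwinding()]
#' objects via [specificity_score()]'s `fits` argument).
#'
#' @param profile A [mismatch_profile()] containing `n_pd` 0, 1, 2 and 3.
#' @param sd_method `"delta"` (default) or `"bootstrap"`.
#' @param fits Optional list of the `unwind_fit` objects behind the
#'   profile (required for `sd_method = "bootstrap"`), ordered to match
#'   `profile$n_pd`.
#' @return An object of class `specificity_result`: list with `label`,
#'   `grna`, `on_target`, `on_target_sd`, `promiscuity`, `promiscuity_sd`,
#'   `S`, `sd_S`. For a perfectly specific enzyme (`promiscuity = 0`) S is
#'   undefined and an error is raised; report `on_target` and
#'   `promiscuity` alone in that case.
#' @examples
#' p <- mismatch_profile(data.frame(n_pd = 0:3,
#'                                  f_unwound = c(0.9, 0.3, 0.1, 0.05)))
#' specificity_score(p)$S # 0.9 / 0.65
#' @export
specificity_score <- function(profile, sd_method = c("delta", "bootstrap"),
                              fits = NULL) {
  stopifnot(inherits(profile, "mismatch_profile"))
  sd_method <- match.arg(sd_method)
  f0 <- profile_value(profile, 0)
  s0 <- profile_value(profile, 0, "sd")
  pr <- promiscuity(profile)
  if (pr$value == 0)
    stop("S undefined: zero promiscuity (perfectly specific; report on_target and promiscuity alone)")
  S <- f0 / pr$value
  sd_S <- if (sd_method == "delta") {
    if (is.finite(s0) && is.finite(pr$sd) && f0 > 0)
      abs(S) * sqrt((s0 / f0)^2 + (pr$sd / pr$value)^2)
    else if (is.finite(s0) && is.finite(pr$sd) && f0 == 0)
      s0 / pr$value  # ratio SD degenerates to numerator SD scaled
    else NA_real_
  } else {
    if (is.null(fits)) stop("sd_method = 'bootstrap' requires the fits")
    stopifnot(all(vapply(fits, inherits, TRUE, "unwind_fit")))
    nb <- min(vapply(fits, function(f) length(f$boot), 0L))
    if (nb == 0) stop("fits carry no bootstrap replicates")
    idx <- match(c(0, 1, 2, 3), profile$n_pd)
    b <- vapply(fits[idx], function(f) f$boot[seq_len(nb)], numeric(nb))
    stats::sd(b[, 1] / (b[, 2] + 2 * b[, 3] + 3 * b[, 4]), na.rm = TRUE)
  }
  structure(list(label = attr(profile, "label"), grna = attr(profile, "grna"),
                 on_target = f0, on_target_sd = s0,
                 promiscuity = pr$value, promiscuity_sd = pr$sd,
                 S = S, sd_S = sd_S),
            class = "specificity_result")
}

#' @export
print.specificity_result <- function(x, ...) {
  cat(sprintf("Specificity of '%s' (%s):\n", x$label, x$grna))
  cat(sprintf("  on-target activity %.3f +- %.3f, promiscuity %.3f +- %.3f\n",
              x$on_target, x$on_target_sd, x$promiscuity, x$promiscuity_sd))
  cat(sprintf("  S = %.3f +- %.3f\n", x$S, x$sd_S))
  invisible(x)
}

#' Cross-condition specificity comparison table
#'
#' Assembles one row per Cas9 variant x gRNA combination with on-target
#' activity, promiscuity and S, sorted by S (descending, the most specific
#' combination first). Conditions using truncated gRNAs (X18, gX18, X17)
#' cannot base-pair with the full protospacer, so promiscuity and S cannot
#' be determined for them: their rows report on-target activity with `NA`
#' in the S columns and sort last.
#'
#' @param profiles A list of [mismatch_profile()] objects with distinct
#'   labels (label x gRNA must be unique).
#' @return A data frame with columns `label`, `grna`, `on_target`,
#'   `on_target_sd`, `promiscuity`, `promiscuity_sd`, `S`, `sd_S`.
#' @export
compare_conditions <- function(profiles) {
  if (inherits(profiles, "mismatch_profile")) profiles <- list(profiles)
  if (length(profiles) < 1) stop("need at least one profile")
  stopifnot(all(vapply(profiles, inherits, TRUE, "mismatch_profile")))
  key <- vapply(profiles, function(p)
    paste(attr(p, "label"), attr(p, "grna"), sep = " / "), "")
  if (anyDuplicated(key))
    stop(sprintf("duplicate condition labels: %s", key[duplicated(key)][1]))
  rows <- lapply(profiles, function(p) {
    lab <- attr(p, "label"); g <- attr(p, "grna")
    f0 <- profile_value(p, 0); s0 <- profile_value(p, 0, "sd")
    if (g %in% truncated_designs()) {
      data.frame(label = lab, grna = g, on_target = f0, on_target_sd = s0,
                 promiscuity = NA_real_, promiscuity_sd = NA_real_,
                 S = NA_real_, sd_S = NA_real_)
    } else {
      sc <- specificity_score(p)
      data.frame(label = lab, grna = g, on_target = f0, on_target_sd = s0,
                 promiscuity = sc$promiscuity, promiscuity_sd = sc$promiscuity_sd,
                 S = sc$S, sd_S = sc$sd_S)
    }
  })
  out <- do.call(rbind, rows)
  out <- out[order(-ifelse(is.na(out$S), -Inf, out$S), out$label), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Scatter of on-target activity versus promiscuity
#'
#' The plane in which enzyme/guide combinations are compared: the ideal
#' corner is high on-target activity (top) and low promiscuity (left).
#'
#' @param comparison A comparison table from [compare_conditions()].
#' @param ... Further arguments to [graphics::plot()].
#' @return The comparison table, invisibly.
#' @export
plot_activity_promiscuity <- function(comparison, ...) {
  ok <- is.finite(comparison$promiscuity)
  d <- comparison[ok, , drop = FALSE]
  graphics::plot(d$promiscuity, d$on_target,
                 xlab = "unwinding promiscuity",
                 ylab = "on-target unwinding activity",
                 pch = 19, xlim = c(0, max(d$promiscuity) * 1.15),
                 ylim = c(0, 1), ...)
  if (all(is.finite(d$promiscuity_sd)))
    graphics::arrows(d$promiscuity - d$promiscuity_sd, d$on_target,
                     d$promiscuity + d$promiscuity_sd, d$on_target,
                     angle = 90, code = 3, length = 0.03)
  if (all(is.finite(d$on_target_sd)))
    graphics::arrows(d$promiscuity, d$on_target - d$on_target_sd,
                     d$promiscuity, d$on_target + d$on_target_sd,
                     angle = 90, code = 3, length = 0.03)
  graphics::text(d$promiscuity, d$on_target,
                 labels = paste(d$label, d$grna, sep = "/"),
                 pos = 3, cex = 0.8)
  invisible(comparison)
}
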
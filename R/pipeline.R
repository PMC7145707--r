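#' Pipeline configuration
#'
#' Builds a validated, fully-defaulted configuration for [run_pipeline()].
#' Every parameter has a default; unknown keys (top-level or inside any
#' block) are rejected before any stage runs, and a configuration
#' round-trips through [write_config()]/[read_config()] unchanged.
#'
#' @param seed Global integer seed.
#' @param mode `"traces"` (simulate intensity traces directly) or
#'   `"movie"` (render dual-channel movies and recover traces by detection
#'   and photometry).
#' @param stages Character subset of
#'   `c("simulate", "extract", "analyze", "score")` to execute, in order.
#' @param conditions List of condition entries, each a list with keys
#'   `label`, `grna`, `n_pd`, `p_unwound`.
#' @param n_molecules,n_frames,frame_interval Simulation size per
#'   condition.
#' @param exchange_rate Total two-state exchange rate (per second) used to
#'   derive kinetic rates from occupancies.
#' @param photophysics Named list overriding [photophysics_params()]
#'   defaults.
#' @param movie Named list overriding movie defaults (`height`, `width`,
#'   `psf_sigma`, `channel_offset`, `camera_baseline`, `camera_read_sd`).
#' @param detection Named list: `threshold_k`, `n_avg`.
#' @param photometry Named list: `aperture_radius`, `annulus`.
#' @param analysis Named list: `k`, `donor_only_max`, `low_high_boundary`,
#'   `n_boot`, `include_donor_only`, `min_molecules`.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            mode = c("traces", "movie"),
                            stages = c("simulate", "extract", "analyze", "score"),
                            conditions = list(),
                            n_molecules = 2000L,
                            n_frames = 10L,
                            frame_interval = 0.1,
                            exchange_rate = 0.5,
                            photophysics = list(),
                            movie = list(),
                            detection = list(),
                            photometry = list(),
                            analysis = list()) {
  mode <- match.arg(mode)
  stages <- match.arg(stages, several.ok = TRUE)
  merge_block <- function(given, defaults, name) {
    if (length(given) && (is.null(names(given)) || any(!nzchar(names(given)))))
      stop(sprintf("%s block must be a named list", name))
    unknown <- setdiff(names(given), names(defaults))
    if (length(unknown))
      stop(sprintf("unknown key '%s' in %s block", unknown[1], name))
    utils::modifyList(defaults, given)
  }
  photophysics <- merge_block(photophysics, list(
    e_rewound = 0.75, e_unwound = 0.30, total_intensity = 500,
    noise_sd = 25, background = 0, donor_only_fraction = 0.1,
    bleach_rate = 0), "photophysics")
  movie <- merge_block(movie, list(
    height = 360L, width = 720L, psf_sigma = 1.1,
    channel_offset = c(0, 0), camera_baseline = 100, camera_read_sd = 3),
    "movie")
  movie$height <- as.integer(movie$height)
  movie$width <- as.integer(movie$width)
  movie$channel_offset <- as.numeric(movie$channel_offset)
  detection <- merge_block(detection, list(threshold_k = 6, n_avg = 20L),
                           "detection")
  detection$n_avg <- as.integer(detection$n_avg)
  photometry <- merge_block(photometry, list(aperture_radius = 3.5,
                                             annulus = c(5, 8)), "photometry")
  photometry$annulus <- as.numeric(photometry$annulus)
  analysis <- merge_block(analysis, list(
    k = 5L, donor_only_max = 0.2, low_high_boundary = 0.65,
    n_boot = 1000L, include_donor_only = FALSE, min_molecules = 2000L),
    "analysis")
  analysis$k <- as.integer(analysis$k)
  analysis$n_boot <- as.integer(analysis$n_boot)
  analysis$min_molecules <- as.integer(analysis$min_molecules)
  conditions <- lapply(conditions, function(cc) {
    cc <- merge_block(cc, list(label = "condition", grna = "X20",
                               n_pd = 0L, p_unwound = 0.5), "conditions")
    cc$n_pd <- as.integer(cc$n_pd)
    cc$p_unwound <- as.numeric(cc$p_unwound)
    cc
  })
  structure(list(seed = as.integer(seed), mode = mode, stages = stages,
                 conditions = conditions,
                 n_molecules = as.integer(n_molecules),
                 n_frames = as.integer(n_frames),
                 frame_interval = as.numeric(frame_interval),
                 exchange_rate = as.numeric(exchange_rate),
                 photophysics = photophysics, movie = movie,
                 detection = detection, photometry = photometry,
                 analysis = analysis),
            class = "pipeline_config")
}

#' Read or write a pipeline configuration as YAML
#'
#' @param config A [pipeline_config()].
#' @param path YAML file path.
#' @return `read_config()` returns a validated `pipeline_config`;
#'   `write_config()` returns `path` invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.list(raw)) stop("config file must contain a mapping")
  do.call(pipeline_config, raw)
}

#' Run the simulate / extract / analyze / score pipeline
#'
#' Executes the configured stages in order, writing every intermediate
#' artifact (traces, ground truth, movies and spot tables in movie mode,
#' per-condition histograms, the estimates table and the specificity
#' comparison table) plus a machine-readable run manifest to `out_dir`.
#' A re-run with the same configuration and seed produces byte-identical
#' artifacts. Any stage error aborts with the stage name and the offending
#' condition label.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @param seed Optional seed overriding `config$seed`.
#' @return Invisibly, a list with `estimates` (data frame), `comparison`
#'   (data frame or `NULL`), `fits` (list of `unwind_fit`), `manifest`.
#' @export
run_pipeline <- function(config, out_dir, seed = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(seed)) config$seed <- as.integer(seed)
  if (length(config$conditions) == 0)
    stop("stage simulate: no conditions configured")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  log_lines <- character(0)
  say <- function(fmt, ...) {
    log_lines <<- c(log_lines, sprintf(fmt, ...))
  }
  say("unwindFRET pipeline: mode=%s seed=%d stages=%s",
      config$mode, config$seed, paste(config$stages, collapse = ","))

  ph <- do.call(photophysics_params, config$photophysics)
  conds <- lapply(config$conditions, function(cc)
    condition(cc$label, cc$n_pd,
              kinetic_params(cc$p_unwound, exchange_rate = config$exchange_rate),
              ph, grna = cc$grna))
  stems <- vapply(config$conditions, function(cc)
    sprintf("%s_%s_npd%d", gsub("[^A-Za-z0-9]+", "-", cc$label), cc$grna,
            cc$n_pd), "")
  if (anyDuplicated(stems)) stop("conditions must be unique (label x grna x n_pd)")

  stage <- function(name, label, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage %s [%s]: %s", name, label, conditionMessage(e)),
           call. = FALSE))
  }

  trace_sets <- vector("list", length(conds))
  truths <- vector("list", length(conds))
  counts <- data.frame(condition = stems, simulated = NA_integer_,
                       detected = NA_integer_, analyzed = NA_integer_)

  if ("simulate" %in% config$stages) {
    for (i in seq_along(conds)) {
      cond_seed <- config$seed + 1009L * i
      if (config$mode == "traces") {
        sim <- stage("simulate", stems[i],
                     simulate_traces(conds[[i]], config$n_molecules,
                                     config$n_frames, config$frame_interval,
                                     seed = cond_seed))
        trace_sets[[i]] <- sim$traces
        truths[[i]] <- sim$truth
        write_traces(sim$traces, file.path(out_dir, paste0(stems[i], "_traces.tsv")))
      } else {
        mp <- movie_params(n_frames = config$n_frames,
                           frame_interval = config$frame_interval,
                           height = config$movie$height,
                           width = config$movie$width,
                           psf_sigma = config$movie$psf_sigma,
                           n_molecules = config$n_molecules,
                           channel_offset = config$movie$channel_offset,
                           camera_baseline = config$movie$camera_baseline,
                           camera_read_sd = config$movie$camera_read_sd)
        sim <- stage("simulate", stems[i], render_movie(mp, conds[[i]], seed = cond_seed))
        truths[[i]] <- sim$truth
        write_movie(sim$movie, file.path(out_dir, paste0(stems[i], "_movie.tif")))
        trace_sets[[i]] <- sim$movie  # handed to the extract stage
      }
      write_ground_truth(truths[[i]], file.path(out_dir, paste0(stems[i], "_truth")))
      counts$simulated[i] <- config$n_molecules
      say("simulate [%s]: %d molecules, %d frames", stems[i],
          config$n_molecules, config$n_frames)
    }
  }

  if (config$mode == "movie" && "extract" %in% config$stages) {
    for (i in seq_along(conds)) {
      movie <- trace_sets[[i]]
      if (!inherits(movie, "fret_movie")) {
        path <- file.path(out_dir, paste0(stems[i], "_movie.tif"))
        movie <- stage("extract", stems[i], read_movie(path, config$frame_interval))
      }
      halves <- split_channels(movie)
      spots <- stage("extract", stems[i],
                     detect_spots(halves$acceptor,
                                  psf_sigma = config$movie$psf_sigma,
                                  threshold_k = config$detection$threshold_k,
                                  n_avg = config$detection$n_avg))
      spots <- map_to_donor(spots, config$movie$channel_offset,
                            c(dim(halves$donor)[1], dim(halves$donor)[2]))
      write_spots(spots, file.path(out_dir, paste0(stems[i], "_spots.tsv")))
      tr <- stage("extract", stems[i],
                  extract_traces(halves$donor, halves$acceptor, spots,
                                 config$frame_interval,
                                 config$photometry$aperture_radius,
                                 config$photometry$annulus))
      trace_sets[[i]] <- tr
      write_traces(tr, file.path(out_dir, paste0(stems[i], "_traces.tsv")))
      counts$detected[i] <- n_molecules(tr)
      say("extract [%s]: %d spots -> %d traces (%d excluded)", stems[i],
          nrow(spots), n_molecules(tr), nrow(attr(tr, "excluded")))
    }
  }

  fits <- NULL
  estimates <- NULL
  if ("analyze" %in% config$stages) {
    fits <- vector("list", length(conds))
    for (i in seq_along(conds)) {
      tr <- trace_sets[[i]]
      if (is.null(tr) || !inherits(tr, "trace_set")) {
        path <- file.path(out_dir, paste0(stems[i], "_traces.tsv"))
        tr <- stage("analyze", stems[i], read_traces(path, config$frame_interval))
      }
      thr <- fret_thresholds(config$analysis$donor_only_max,
                             config$analysis$low_high_boundary)
      fits[[i]] <- stage("analyze", stems[i],
        fit_unwinding(tr, thresholds = thr, k = config$analysis$k,
                      n_boot = config$analysis$n_boot,
                      seed = config$seed + 2003L * i,
                      include_donor_only = config$analysis$include_donor_only,
                      total_intensity = config$photophysics$total_intensity,
                      min_molecules = config$analysis$min_molecules,
                      label = conds[[i]]$label))
      sample <- fits[[i]]$sample
      hist <- fret_histogram(sample)
      write_tsv(hist, file.path(out_dir, paste0(stems[i], "_histogram.tsv")))
      counts$analyzed[i] <- fits[[i]]$n_molecules
      say("analyze [%s]: f_unwound = %.4f +- %.4f (%d molecules)", stems[i],
          fits[[i]]$f_unwound, fits[[i]]$sd, fits[[i]]$n_molecules)
    }
    estimates <- write_estimates(fits,
                                 vapply(config$conditions, `[[`, 0L, "n_pd"),
                                 file.path(out_dir, "estimates.tsv"),
                                 grna = vapply(config$conditions, `[[`, "", "grna"))
  }

  comparison <- NULL
  if ("score" %in% config$stages) {
    if (is.null(estimates)) {
      path <- file.path(out_dir, "estimates.tsv")
      estimates <- stage("score", "estimates", read_estimates(path))
    }
    groups <- split(estimates, paste(estimates$label, estimates$grna, sep = " / "))
    profiles <- lapply(groups, function(g)
      mismatch_profile(g, label = g$label[1], grna = g$grna[1]))
    scorable <- vapply(profiles, function(p)
      all(0:3 %in% p$n_pd) || attr(p, "grna") %in% truncated_designs(), TRUE)
    if (any(scorable)) {
      comparison <- stage("score", "comparison",
                          compare_conditions(unname(profiles[scorable])))
      write_tsv(comparison, file.path(out_dir, "comparison.tsv"))
      for (j in seq_len(nrow(comparison)))
        say("score [%s / %s]: S = %s", comparison$label[j], comparison$grna[j],
            if (is.na(comparison$S[j])) "undetermined (truncated gRNA)"
            else sprintf("%.4f +- %.4f", comparison$S[j], comparison$sd_S[j]))
    } else {
      say("score: no condition group spans n_pd 0..3; comparison skipped")
    }
  }

  manifest <- list(package = "unwindFRET",
                   version = as.character(utils::packageVersion("unwindFRET")),
                   r_version = paste(R.version$major, R.version$minor, sep = "."),
                   seed = config$seed, mode = config$mode,
                   stages = config$stages, config = unclass(config),
                   molecule_counts = counts)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  writeLines(log_lines, log_path)
  invisible(list(estimates = estimates, comparison = comparison, fits = fits,
                 manifest = manifest))
}

#' Synthetic demonstration panel of five Cas9 variants
#'
#' A ready-to-run panel of five Cas9 variants paired with the canonical
#' gRNA (X20) across `n_pd` = 0..3, entirely synthetic: the unwound-state
#' occupancies are not measured values but were chosen (see
#' [demo_profiles()]) so that the exact specificity of each variant equals
#' the reference values 0.23 (WT), 0.50 (HypaCas9), 0.53 (SniperCas9),
#' 0.66 (Cas9-HF1) and 0.71 (eCas9), while following the qualitative
#' pattern of the assay (HypaCas9 low on-target activity, SniperCas9 high
#' on-target activity but the most promiscuous of the engineered
#' variants). Each condition requests at least 2000 molecules; the default
#' of 5000 makes the 0.03 specificity gap between SniperCas9 and HypaCas9
#' resolvable on a single simulated data set.
#'
#' @param n_molecules Molecules per condition (>= 2000 recommended).
#' @param n_frames Frames per trace.
#' @param seed Global seed stored in the configuration.
#' @param ... Further arguments passed to [pipeline_config()].
#' @return A [pipeline_config()] with 20 conditions (5 variants x 4
#'   mismatch levels).
#' @export
demo_panel <- function(n_molecules = 5000, n_frames = 8, seed = 1L, ...) {
  prof <- demo_profiles()
  conditions <- lapply(seq_len(nrow(prof)), function(i)
    list(label = prof$variant[i], grna = "X20", n_pd = prof$n_pd[i],
         p_unwound = prof$p_unwound[i]))
  pipeline_config(seed = seed, mode = "traces", conditions = conditions,
                  n_molecules = n_molecules, n_frames = n_frames, ...)
}

#' Occupancy profiles behind the demonstration panel
#'
#' Synthetic unwound-state occupancies for the five-variant demonstration
#' panel. They are constructed, not measured: within each variant the
#' occupancies were chosen so that
#' `S = p(0) / (1 p(1) + 2 p(2) + 3 p(3))` equals the reference
#' specificity exactly (see [demo_panel()]).
#'
#' @return Data frame with columns `variant`, `n_pd`, `p_unwound`, and the
#'   implied exact specificity as attribute `s_targets`.
#' @export
demo_profiles <- function() {
  prof <- list(
    "WT"         = c(0.9200, 0.85, 0.75, 0.55),  # S = 0.92  / 4.00 = 0.23
    "HypaCas9"   = c(0.5500, 0.30, 0.25, 0.10),  # S = 0.55  / 1.10 = 0.50
    "SniperCas9" = c(0.9010, 0.60, 0.40, 0.10),  # S = 0.901 / 1.70 = 0.53
    "Cas9-HF1"   = c(0.8844, 0.45, 0.25, 0.13),  # S = 0.8844/ 1.34 = 0.66
    "eCas9"      = c(0.8520, 0.40, 0.22, 0.12))  # S = 0.852 / 1.20 = 0.71
  df <- data.frame(variant = rep(names(prof), each = 4L),
                   n_pd = rep(0:3, times = length(prof)),
                   p_unwound = unlist(prof, use.names = FALSE))
  s <- vapply(prof, function(p) p[1] / sum((1:3) * p[2:4]), 0)
  attr(df, "s_targets") <- s
  df
}
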
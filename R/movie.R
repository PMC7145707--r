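#' Render a synthetic dual-channel smFRET movie
#'
#' Produces a 16-bit frame stack emulating a TIRF recording in which donor
#' and acceptor emission are projected onto the two halves of one EMCCD
#' frame: donor on the left half, acceptor on the right. Molecule positions
#' are drawn uniformly in the acceptor half with a margin of
#' `3 * psf_sigma` from the half borders and a minimum pairwise separation
#' of `min_separation`; donor-half positions follow by the pure translation
#' `channel_offset`. Each molecule is rendered as a pixel-integrated 2-D
#' Gaussian whose integrated amplitude per frame equals its simulated
#' channel intensity (negative noise excursions clamp to zero photons).
#' A constant camera baseline and per-pixel Gaussian read noise are added,
#' and values are clipped to the unsigned 16-bit range.
#'
#' @param params A [movie_params()] object.
#' @param cond A [condition()] object supplying kinetics and photophysics.
#' @param seed Optional integer seed; identical seeds give bit-identical
#'   stacks.
#' @return A list of class `sim_movie`: `movie` (class `fret_movie`, fields
#'   `frames` = integer array height x width x frames, `frame_interval`,
#'   `half_split`) and `truth` (a `ground_truth` whose `molecules` table
#'   carries acceptor-half positions `row_a`/`col_a` and donor-half
#'   positions `row_d`/`col_d`, 1-based pixel-centre coordinates local to
#'   each half).
#' @export
render_movie <- function(params, cond, seed = NULL) {
  stopifnot(inherits(params, "movie_params"), inherits(cond, "fret_condition"))
  if (!is.null(seed)) set.seed(seed)
  half_w <- params$width %/% 2L
  pos <- place_molecules(params$n_molecules, params$height, half_w,
                         params$psf_sigma, params$min_separation,
                         params$channel_offset)

  sim <- if (params$n_molecules > 0)
    simulate_traces(cond, params$n_molecules, params$n_frames,
                    params$frame_interval)
  else NULL

  h <- params$height; w <- params$width; tt <- params$n_frames
  frames <- array(0, dim = c(h, w, tt))
  if (params$n_molecules > 0) {
    # pixel-integrated PSF weights are fixed per molecule and channel
    wts_d <- lapply(seq_len(params$n_molecules), function(i)
      psf_weights(pos$row_d[i], pos$col_d[i], h, half_w, params$psf_sigma))
    wts_a <- lapply(seq_len(params$n_molecules), function(i)
      psf_weights(pos$row_a[i], pos$col_a[i], h, half_w, params$psf_sigma))
    for (t in seq_len(tt)) {
      for (i in seq_len(params$n_molecules)) {
        wd <- wts_d[[i]]; wa <- wts_a[[i]]
        ad <- max(sim$traces$i_d[i, t], 0)
        aa <- max(sim$traces$i_a[i, t], 0)
        frames[wd$rows, wd$cols, t] <-
          frames[wd$rows, wd$cols, t] + ad * wd$w
        frames[wa$rows, wa$cols + half_w, t] <-
          frames[wa$rows, wa$cols + half_w, t] + aa * wa$w
      }
    }
  }
  frames <- frames + params$camera_baseline
  if (params$camera_read_sd > 0)
    frames <- frames + array(stats::rnorm(length(frames),
                                          sd = params$camera_read_sd),
                             dim = dim(frames))
  frames <- round(pmin(pmax(frames, 0), 65535))
  storage.mode(frames) <- "integer"

  movie <- structure(list(frames = frames,
                          frame_interval = params$frame_interval,
                          half_split = half_w),
                     class = "fret_movie")
  if (is.null(sim)) {
    truth <- ground_truth(data.frame(molecule_id = integer(0),
                                     donor_only = logical(0),
                                     bleach_frame_acceptor = integer(0),
                                     bleach_frame_donor = integer(0),
                                     row_a = numeric(0), col_a = numeric(0),
                                     row_d = numeric(0), col_d = numeric(0)),
                          matrix(integer(0), 0, tt),
                          matrix(numeric(0), 0, tt), condition = cond)
  } else {
    truth <- sim$truth
    truth$molecules <- cbind(truth$molecules,
                             data.frame(row_a = pos$row_a, col_a = pos$col_a,
                                        row_d = pos$row_d, col_d = pos$col_d))
  }
  structure(list(movie = movie, truth = truth), class = "sim_movie")
}

# Dart-throwing placement in the acceptor half. Margin keeps every spot
# >= 3 sigma from the half borders in both channels; rejection keeps
# pairwise distances >= min_sep. Errors out when the requested density is
# incompatible with the separation constraint.
place_molecules <- function(n, height, half_w, psf_sigma, min_sep, offset) {
  if (n == 0)
    return(list(row_a = numeric(0), col_a = numeric(0),
                row_d = numeric(0), col_d = numeric(0)))
  margin <- 3 * psf_sigma
  dx <- offset[1]; dy <- offset[2]
  lo_r <- 1 + margin + max(0, -dy); hi_r <- height - margin - max(0, dy)
  lo_c <- 1 + margin + max(0, -dx); hi_c <- half_w - margin - max(0, dx)
  if (lo_r >= hi_r || lo_c >= hi_c)
    stop("image too small for the margin and channel offset")
  rows <- numeric(n); cols <- numeric(n)
  placed <- 0L
  attempts <- 0L
  max_attempts <- 2000L * n
  while (placed < n) {
    attempts <- attempts + 1L
    if (attempts > max_attempts)
      stop(sprintf(paste0("cannot place %d molecules with minimum separation ",
                          "%.2f px in a %d x %d half; reduce n_molecules"),
                   n, min_sep, height, half_w))
    r <- stats::runif(1, lo_r, hi_r)
    c <- stats::runif(1, lo_c, hi_c)
    if (placed > 0L) {
      d2 <- (rows[seq_len(placed)] - r)^2 + (cols[seq_len(placed)] - c)^2
      if (min(d2) < min_sep^2) next
    }
    placed <- placed + 1L
    rows[placed] <- r; cols[placed] <- c
  }
  list(row_a = rows, col_a = cols, row_d = rows + dy, col_d = cols + dx)
}

# Pixel-integrated Gaussian PSF on a local window. Pixel i covers
# [i - 0.5, i + 0.5] in pixel-centre coordinates; weights are products of
# per-axis normal CDF differences, so a window of +-5 sigma carries all but
# ~1e-6 of the unit mass.
psf_weights <- function(row, col, height, width, sigma) {
  half <- ceiling(5 * sigma)
  rows <- max(1L, floor(row - half)):min(height, ceiling(row + half))
  cols <- max(1L, floor(col - half)):min(width, ceiling(col + half))
  wr <- stats::pnorm(rows + 0.5, row, sigma) - stats::pnorm(rows - 0.5, row, sigma)
  wc <- stats::pnorm(cols + 0.5, col, sigma) - stats::pnorm(cols - 0.5, col, sigma)
  list(rows = rows, cols = cols, w = outer(wr, wc))
}

#' @export
print.fret_movie <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("fret_movie: %d frames of %d x %d px (half split at column %d), %.3g s/frame\n",
              d[3], d[1], d[2], x$half_split, x$frame_interval))
  invisible(x)
}

#' Write a movie as a multi-page 16-bit TIFF
#'
#' @param movie A `fret_movie` (or a bare integer array height x width x
#'   frames).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_movie <- function(movie, path) {
  frames <- if (inherits(movie, "fret_movie")) movie$frames else movie
  pages <- lapply(seq_len(dim(frames)[3]),
                  function(t) frames[, , t] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' Read a multi-page TIFF movie
#'
#' @param path TIFF file path.
#' @param frame_interval Frame time in seconds (TIFF carries no timing).
#' @return A `fret_movie`.
#' @export
read_movie <- function(path, frame_interval = 0.1) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  frames <- array(0L, dim = c(nrow(pages[[1]]), ncol(pages[[1]]), length(pages)))
  for (t in seq_along(pages)) frames[, , t] <- pages[[t]]
  if (ncol(pages[[1]]) %% 2 != 0) stop("movie width must be even")
  structure(list(frames = frames, frame_interval = frame_interval,
                 half_split = ncol(pages[[1]]) %/% 2L),
            class = "fret_movie")
}
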
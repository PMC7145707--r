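#' Split a dual-channel movie into donor and acceptor stacks
#'
#' The donor channel occupies columns `1..width/2` of each frame, the
#' acceptor channel columns `width/2 + 1 .. width`; both halves are
#' returned re-indexed to local columns `1..width/2`.
#'
#' @param movie A `fret_movie` (see [render_movie()], [read_movie()]).
#' @return A list with integer arrays `donor` and `acceptor`
#'   (height x width/2 x frames) and `frame_interval`.
#' @export
split_channels <- function(movie) {
  stopifnot(inherits(movie, "fret_movie"))
  w <- dim(movie$frames)[2]
  if (w %% 2 != 0) stop("movie width must be even")
  half <- w %/% 2L
  if (movie$half_split != half) stop("half_split must equal width/2")
  list(donor = movie$frames[, seq_len(half), , drop = FALSE],
       acceptor = movie$frames[, half + seq_len(half), , drop = FALSE],
       frame_interval = movie$frame_interval)
}

#' Detect fluorescent spots in a channel stack
#'
#' Molecules with a missing or inactive acceptor are excluded from
#' unwinding analysis by detecting spots in the acceptor channel only, as
#' in the underlying assay. Detection runs on a time-averaged image (mean
#' of the first `min(n_avg, n_frames)` frames; the molecules are
#' immobilised, so averaging raises SNR without smearing): a
#' difference-of-Gaussians band-pass at the PSF scale, a robust intensity
#' threshold at `median + threshold_k * MAD`, 8-neighbour local maxima, and
#' intensity-weighted centroid refinement in a 7x7 window. Two quality
#' gates then enforce the single-emitter model behind the photometry:
#' spots whose measured major-axis width exceeds
#' `max_width_factor * psf_sigma` are rejected (a blended pair of emitters
#' closer than the DoG resolution limit appears as one broadened spot),
#' and any pair of accepted spots closer than `min_separation` is removed
#' entirely (both members), since overlapping apertures violate the
#' photometry model.
#'
#' @param stack Integer array (height x width x frames), typically the
#'   acceptor half from [split_channels()].
#' @param psf_sigma Expected PSF SD in pixels.
#' @param threshold_k Robust threshold multiplier (default 6).
#' @param min_separation Minimum allowed pairwise spot distance in pixels.
#' @param max_width_factor Reject spots whose measured major-axis SD
#'   exceeds this multiple of `psf_sigma` (default 1.4).
#' @param n_avg Number of leading frames averaged for detection.
#' @return A data frame of class `spot_table` with columns `spot_id`,
#'   `row`, `col` (sub-pixel, 1-based pixel-centre, local to the stack) and
#'   `quality` (band-passed peak height). Zero rows is a valid result.
#' @export
detect_spots <- function(stack, psf_sigma = 1.1, threshold_k = 6,
                         min_separation = 6 * psf_sigma,
                         max_width_factor = 1.4, n_avg = 20) {
  if (length(dim(stack)) != 3L || any(dim(stack) == 0))
    stop("stack must be a non-empty height x width x frames array")
  avg <- rowMeans(stack[, , seq_len(min(n_avg, dim(stack)[3])), drop = FALSE],
                  dims = 2)
  dog <- EBImage::gblur(avg, sigma = psf_sigma) -
    EBImage::gblur(avg, sigma = 2 * psf_sigma)
  thr <- stats::median(dog) + threshold_k * stats::mad(dog)

  h <- nrow(dog); w <- ncol(dog)
  empty <- data.frame(spot_id = integer(0), row = numeric(0),
                      col = numeric(0), quality = numeric(0))
  if (h < 9 || w < 9)
    return(structure(empty, class = c("spot_table", "data.frame")))
  # 8-neighbour local maxima above threshold, away from the border so that
  # the 7x7 refinement window fits
  core_r <- 4:(h - 3); core_c <- 4:(w - 3)
  cand_r <- integer(0); cand_c <- integer(0)
  sub <- dog[core_r, core_c]
  is_max <- sub > thr
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    is_max <- is_max & (sub >= dog[core_r + dr, core_c + dc])
  }
  idx <- which(is_max, arr.ind = TRUE)
  if (nrow(idx) == 0)
    return(structure(empty, class = c("spot_table", "data.frame")))
  cand_r <- core_r[idx[, 1]]; cand_c <- core_c[idx[, 2]]
  quality <- dog[cbind(cand_r, cand_c)]

  # centroid refinement and width measurement on the baseline-subtracted
  # average image
  base <- stats::median(avg)
  rows <- numeric(length(cand_r)); cols <- numeric(length(cand_c))
  width <- numeric(length(cand_r))
  for (i in seq_along(cand_r)) {
    rr <- (cand_r[i] - 3):(cand_r[i] + 3)
    cc <- (cand_c[i] - 3):(cand_c[i] + 3)
    win <- pmax(avg[rr, cc] - base, 0)
    s <- sum(win)
    if (s <= 0) { rows[i] <- cand_r[i]; cols[i] <- cand_c[i]; width[i] <- Inf; next }
    r0 <- sum(rr * rowSums(win)) / s
    c0 <- sum(cc * colSums(win)) / s
    rows[i] <- r0; cols[i] <- c0
    # second-moment major-axis SD: large for blended emitter pairs
    vr <- sum(rowSums(win) * (rr - r0)^2) / s
    vc <- sum(colSums(win) * (cc - c0)^2) / s
    vrc <- sum(win * outer(rr - r0, cc - c0)) / s
    width[i] <- sqrt((vr + vc) / 2 +
                       sqrt(((vr - vc) / 2)^2 + vrc^2))
  }

  # collapse duplicate maxima that refined to (nearly) the same centre
  # (plateaus produce adjacent candidates), keeping the higher quality one
  ord <- order(quality, decreasing = TRUE)
  keep <- logical(length(ord))
  for (i in ord) {
    if (any(keep & (rows - rows[i])^2 + (cols - cols[i])^2 < 1.5^2)) next
    keep[i] <- TRUE
  }
  keep <- keep & width <= max_width_factor * psf_sigma
  rows <- rows[keep]; cols <- cols[keep]; quality <- quality[keep]

  # separation rule: drop every member of a too-close pair
  if (length(rows) > 1) {
    d2 <- as.matrix(stats::dist(cbind(rows, cols)))^2
    diag(d2) <- Inf
    crowded <- apply(d2 < min_separation^2, 1, any)
    rows <- rows[!crowded]; cols <- cols[!crowded]; quality <- quality[!crowded]
  }
  out <- data.frame(spot_id = seq_along(rows), row = rows, col = cols,
                    quality = quality)
  structure(out, class = c("spot_table", "data.frame"))
}

#' Map acceptor-half spot positions into the donor half
#'
#' The channel mapping is a pure translation: donor column =
#' acceptor column + `dx`, donor row = acceptor row + `dy`. Spots whose
#' mapped position falls outside the donor half are flagged
#' (`in_bounds = FALSE`) and excluded downstream.
#'
#' @param spots A `spot_table` from [detect_spots()].
#' @param channel_offset Numeric `c(dx, dy)`.
#' @param half_dim Integer `c(height, half_width)` of a channel half.
#' @return The spot table with added columns `row_d`, `col_d`, `in_bounds`.
#' @export
map_to_donor <- function(spots, channel_offset, half_dim) {
  stopifnot(inherits(spots, "spot_table"), length(channel_offset) == 2L,
            length(half_dim) == 2L)
  spots$row_d <- spots$row + channel_offset[2]
  spots$col_d <- spots$col + channel_offset[1]
  spots$in_bounds <- spots$row_d >= 1 & spots$row_d <= half_dim[1] &
    spots$col_d >= 1 & spots$col_d <= half_dim[2]
  spots
}

#' Extract background-corrected intensity traces by aperture photometry
#'
#' For each spot and frame, the channel intensity is the sum over a
#' circular aperture centred on the (sub-pixel) spot position minus the
#' local background, estimated as the median pixel value in a surrounding
#' annulus times the aperture area. The annulus median is robust to the
#' occasional neighbouring spot. Spots whose annulus does not fit inside
#' the image, or whose mapped donor position is out of bounds, are excluded
#' and listed in the `excluded` attribute with a reason.
#'
#' @param donor,acceptor Integer arrays (height x half_width x frames) from
#'   [split_channels()].
#' @param spots A `spot_table` carrying donor-mapped positions from
#'   [map_to_donor()].
#' @param frame_interval Frame time in seconds.
#' @param aperture_radius Aperture radius in pixels (default 3.5).
#' @param annulus Inner and outer background annulus radii in pixels
#'   (default `c(5, 8)`).
#' @return A [trace_set()]; `molecule_id` are the surviving `spot_id`s, and
#'   `attr(, "excluded")` records dropped spots.
#' @export
extract_traces <- function(donor, acceptor, spots, frame_interval = 0.1,
                           aperture_radius = 3.5, annulus = c(5, 8)) {
  stopifnot(inherits(spots, "spot_table"))
  if (is.null(spots$row_d))
    stop("spots must carry donor-mapped positions; run map_to_donor() first")
  if (!(annulus[1] > aperture_radius && annulus[2] > annulus[1]))
    stop("annulus radii must satisfy aperture_radius < inner < outer")
  h <- dim(acceptor)[1]; w <- dim(acceptor)[2]; tt <- dim(acceptor)[3]
  stopifnot(identical(dim(donor), dim(acceptor)))

  reach <- ceiling(annulus[2])
  excluded <- data.frame(spot_id = integer(0), reason = character(0))
  keep <- logical(nrow(spots))
  for (i in seq_len(nrow(spots))) {
    if (!isTRUE(spots$in_bounds[i])) {
      excluded <- rbind(excluded, data.frame(
        spot_id = spots$spot_id[i], reason = "donor position out of bounds"))
      next
    }
    fits <- function(r, c) r - reach >= 1 && r + reach <= h &&
      c - reach >= 1 && c + reach <= w
    if (!fits(spots$row[i], spots$col[i]) || !fits(spots$row_d[i], spots$col_d[i])) {
      excluded <- rbind(excluded, data.frame(
        spot_id = spots$spot_id[i], reason = "aperture/annulus exceeds image bounds"))
      next
    }
    keep[i] <- TRUE
  }
  kept <- spots[keep, , drop = FALSE]
  n <- nrow(kept)
  i_d <- matrix(0, n, tt); i_a <- matrix(0, n, tt)
  for (i in seq_len(n)) {
    i_a[i, ] <- photometry_one(acceptor, kept$row[i], kept$col[i],
                               aperture_radius, annulus)
    i_d[i, ] <- photometry_one(donor, kept$row_d[i], kept$col_d[i],
                               aperture_radius, annulus)
  }
  out <- trace_set(i_d, i_a, frame_interval, molecule_id = kept$spot_id,
                   provenance = "extract_traces")
  attr(out, "excluded") <- excluded
  out
}

# Aperture-minus-annulus photometry of one spot across all frames.
# A pixel belongs to the aperture/annulus according to the distance of its
# centre from the (sub-pixel) spot centre.
photometry_one <- function(stack, row, col, aperture_radius, annulus) {
  reach <- ceiling(annulus[2])
  rr <- (floor(row) - reach):(ceiling(row) + reach)
  cc <- (floor(col) - reach):(ceiling(col) + reach)
  rr <- rr[rr >= 1 & rr <= dim(stack)[1]]
  cc <- cc[cc >= 1 & cc <= dim(stack)[2]]
  d2 <- outer((rr - row)^2, (cc - col)^2, `+`)
  in_ap <- d2 <= aperture_radius^2
  in_an <- d2 > annulus[1]^2 & d2 <= annulus[2]^2
  n_ap <- sum(in_ap)
  sub <- stack[rr, cc, , drop = FALSE]
  dim(sub) <- c(length(rr) * length(cc), dim(stack)[3])
  ap_sum <- colSums(sub[as.vector(in_ap), , drop = FALSE])
  bg <- apply(sub[as.vector(in_an), , drop = FALSE], 2, stats::median)
  ap_sum - bg * n_ap
}

#' @export
print.spot_table <- function(x, ...) {
  cat(sprintf("spot_table: %d spots\n", nrow(x)))
  if (nrow(x)) print.data.frame(utils::head(x, 10))
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}
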
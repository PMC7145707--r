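make_movie <- function(n_molecules = 40, p = 0.5, seed = 1, offset = c(0, 0),
                       n_frames = 10, donor_only = 0, noise_sd = 0,
                       height = 240, width = 480, read_sd = 0) {
  mp <- movie_params(n_frames = n_frames, height = height, width = width,
                     n_molecules = n_molecules, channel_offset = offset,
                     camera_read_sd = read_sd)
  cond <- condition("fixture", kinetics = kinetic_params(p),
                    photophysics = photophysics_params(
                      donor_only_fraction = donor_only, noise_sd = noise_sd))
  render_movie(mp, cond, seed = seed)
}

test_that("channel splitting halves the stack and preserves pixels", {
  sim <- make_movie(n_molecules = 3, n_frames = 2, height = 64, width = 512)
  halves <- split_channels(sim$movie)
  expect_equal(dim(halves$donor)[2], 256)
  expect_equal(dim(halves$acceptor)[2], 256)
  # original absolute column 300 lands at acceptor-local column 300 - 256 = 44
  expect_identical(halves$acceptor[, 44, 1], sim$movie$frames[, 300, 1])
  rejoined <- array(0L, dim(sim$movie$frames))
  rejoined[, 1:256, ] <- halves$donor
  rejoined[, 257:512, ] <- halves$acceptor
  expect_identical(rejoined, sim$movie$frames)
  bad <- sim$movie; bad$frames <- bad$frames[, 1:511, , drop = FALSE]
  bad$half_split <- 255L
  expect_error(split_channels(bad), "even")
})

test_that("a blank stack yields an empty spot table", {
  set.seed(3)
  blank <- array(as.integer(round(rnorm(64 * 64 * 5, 100, 3))), c(64, 64, 5))
  spots <- detect_spots(blank, psf_sigma = 1.1)
  expect_s3_class(spots, "spot_table")
  expect_equal(nrow(spots), 0)
})

test_that("planted well-separated spots are recovered with high recall and precision", {
  sim <- make_movie(n_molecules = 50, seed = 21, read_sd = 3, noise_sd = 25)
  halves <- split_channels(sim$movie)
  spots <- detect_spots(halves$acceptor, psf_sigma = 1.1)
  tm <- sim$truth$molecules
  m <- match_spots(spots, tm$row_a, tm$col_a, radius = 2)
  expect_gte(m$recall, 0.95)
  expect_gte(m$precision, 0.95)
})

test_that("donor-only molecules are invisible to acceptor-channel detection", {
  sim <- make_movie(n_molecules = 60, seed = 31, donor_only = 0.5,
                    read_sd = 3, noise_sd = 25)
  halves <- split_channels(sim$movie)
  spots <- detect_spots(halves$acceptor, psf_sigma = 1.1)
  tm <- sim$truth$molecules
  donly <- tm[tm$donor_only, ]
  active <- tm[!tm$donor_only, ]
  m_act <- match_spots(spots, active$row_a, active$col_a, radius = 2)
  m_don <- match_spots(spots, donly$row_a, donly$col_a, radius = 2)
  expect_gte(m_act$recall, 0.9)
  expect_lte(m_don$recall, 0.05)
})

test_that("too-close spot pairs are removed entirely", {
  img <- matrix(0, 80, 80)
  img <- paint_spot(img, 30, 30, 1.1, 400)
  img <- paint_spot(img, 30, 33, 1.1, 400)   # 3 px apart
  img <- paint_spot(img, 60, 60, 1.1, 400)   # isolated control
  stack <- array(as.integer(round(img + 100)), c(80, 80, 1))
  spots <- detect_spots(stack, psf_sigma = 1.1, min_separation = 6 * 1.1)
  expect_equal(nrow(spots), 1)
  expect_lt(abs(spots$row - 60), 1)
  expect_lt(abs(spots$col - 60), 1)
})

test_that("donor mapping applies the offset and flags out-of-bounds spots", {
  spots <- structure(data.frame(spot_id = 1:2, row = c(20, 30),
                                col = c(100, 254), quality = c(1, 1)),
                     class = c("spot_table", "data.frame"))
  m0 <- map_to_donor(spots, c(0, 0), c(240, 256))
  expect_equal(m0$row_d, m0$row)
  expect_equal(m0$col_d, m0$col)
  expect_true(all(m0$in_bounds))
  m <- map_to_donor(spots, c(4, 0), c(240, 256))
  expect_false(m$in_bounds[2])   # col 254 + 4 leaves the 256-wide half
  expect_true(m$in_bounds[1])
})

test_that("sub-pixel channel offsets map detected spots onto true donor positions", {
  sim <- make_movie(n_molecules = 40, seed = 41, offset = c(1.5, -2.0),
                    read_sd = 3, noise_sd = 25)
  halves <- split_channels(sim$movie)
  spots <- detect_spots(halves$acceptor, psf_sigma = 1.1)
  spots <- map_to_donor(spots, c(1.5, -2.0), dim(halves$donor)[1:2])
  tm <- sim$truth$molecules
  d2 <- outer(spots$row, tm$row_a, "-")^2 + outer(spots$col, tm$col_a, "-")^2
  mi <- apply(d2, 1, which.min)
  err <- sqrt((spots$row_d - tm$row_d[mi])^2 + (spots$col_d - tm$col_d[mi])^2)
  expect_true(all(err < 0.5))
})

test_that("aperture photometry recovers intensities on a flat background", {
  # noiseless optics, uniform 50-count pedestal per pixel
  sim <- make_movie(n_molecules = 10, p = 0, seed = 51, n_frames = 4)
  frames <- sim$movie$frames - 100L + 50L   # swap pedestal to 50, no noise
  movie <- sim$movie; movie$frames <- frames
  halves <- split_channels(movie)
  tm <- sim$truth$molecules
  spots <- structure(data.frame(spot_id = seq_len(nrow(tm)), row = tm$row_a,
                                col = tm$col_a, quality = 1),
                     class = c("spot_table", "data.frame"))
  spots <- map_to_donor(spots, c(0, 0), dim(halves$donor)[1:2])
  tr <- extract_traces(halves$donor, halves$acceptor, spots, 0.1)
  kept <- match(tr$molecule_id, spots$spot_id)
  expect_gt(length(kept), 0)
  # E = 0.75 of 500; the circular aperture captures 98.5-99.4% of the PSF
  # mass depending on the sub-pixel centre, plus integer quantisation
  expect_true(all(abs(tr$i_a - 375) / 375 < 0.025))
  # the dimmer channel loses relatively more to sub-count tail quantisation
  expect_true(all(abs(tr$i_d - 125) / 125 < 0.05))
  # the capture losses are common-mode, so E itself stays nearly unbiased
  e <- tr$i_a / (tr$i_a + tr$i_d)
  expect_true(all(abs(e - 0.75) < 0.01))
  # against the analytic aperture oracle the error is quantisation only
  for (m in seq_along(kept)) {
    i <- kept[m]
    rr <- (round(spots$row[i]) - 8):(round(spots$row[i]) + 8)
    cc <- (round(spots$col[i]) - 8):(round(spots$col[i]) + 8)
    d2 <- outer((rr - spots$row[i])^2, (cc - spots$col[i])^2, "+")
    wr <- pnorm(rr + 0.5, spots$row[i], 1.1) - pnorm(rr - 0.5, spots$row[i], 1.1)
    wc <- pnorm(cc + 0.5, spots$col[i], 1.1) - pnorm(cc - 0.5, spots$col[i], 1.1)
    want <- 375 * sum(outer(wr, wc)[d2 <= 3.5^2])
    expect_lt(abs(mean(tr$i_a[m, ]) - want), 4)
  }
})

test_that("a spot placed over pure background extracts a near-zero trace", {
  set.seed(61)
  stack <- array(as.integer(round(rnorm(100 * 100 * 20, 100, 3))),
                 c(100, 100, 20))
  spots <- structure(data.frame(spot_id = 1L, row = 50, col = 50, quality = 1),
                     class = c("spot_table", "data.frame"))
  spots <- map_to_donor(spots, c(0, 0), c(100, 100))
  tr <- extract_traces(stack, stack, spots, 0.1)
  se <- sd(tr$i_a[1, ]) / sqrt(20)
  expect_lt(abs(mean(tr$i_a[1, ])), 3 * max(se, 1))
})

test_that("acceptor bleaching moves signal to the donor channel, total conserved", {
  mp <- movie_params(n_frames = 30, height = 200, width = 400,
                     n_molecules = 25, camera_read_sd = 0)
  cond <- condition("bleach", kinetics = kinetic_params(0),
                    photophysics = quiet_photophysics(bleach_rate = 0.1))
  sim <- render_movie(mp, cond, seed = 71)
  tm <- sim$truth$molecules
  i <- which(!is.na(tm$bleach_frame_acceptor) & tm$bleach_frame_acceptor <= 20 &
             (is.na(tm$bleach_frame_donor) |
              tm$bleach_frame_donor > tm$bleach_frame_acceptor + 5))[1]
  skip_if(is.na(i), "no suitable bleach event drawn")
  halves <- split_channels(sim$movie)
  spots <- structure(data.frame(spot_id = 1L, row = tm$row_a[i],
                                col = tm$col_a[i], quality = 1),
                     class = c("spot_table", "data.frame"))
  spots <- map_to_donor(spots, c(0, 0), dim(halves$donor)[1:2])
  tr <- extract_traces(halves$donor, halves$acceptor, spots, 0.1)
  ba <- tm$bleach_frame_acceptor[i]
  expect_lt(mean(tr$i_a[1, ba:(ba + 3)]), 20)
  expect_gt(mean(tr$i_d[1, ba:(ba + 3)]), 450)
  tot_before <- mean(tr$i_a[1, 1:(ba - 1)] + tr$i_d[1, 1:(ba - 1)])
  tot_after <- mean(tr$i_a[1, ba:(ba + 3)] + tr$i_d[1, ba:(ba + 3)])
  expect_lt(abs(tot_before - tot_after) / tot_before, 0.05)
})

test_that("per-molecule mean E from extracted traces tracks the true state E", {
  sim <- make_movie(n_molecules = 60, p = 0.5, seed = 81, noise_sd = 25,
                    read_sd = 3, n_frames = 8, height = 300, width = 600)
  halves <- split_channels(sim$movie)
  spots <- detect_spots(halves$acceptor, psf_sigma = 1.1)
  spots <- map_to_donor(spots, c(0, 0), dim(halves$donor)[1:2])
  tr <- extract_traces(halves$donor, halves$acceptor, spots, 0.1)
  fs <- fret_efficiency(tr, total_intensity = 500)
  tm <- sim$truth$molecules
  d2 <- outer(spots$row[match(tr$molecule_id, spots$spot_id)], tm$row_a, "-")^2 +
    outer(spots$col[match(tr$molecule_id, spots$spot_id)], tm$col_a, "-")^2
  mi <- apply(d2, 1, which.min)
  true_e <- rowMeans(ifelse(sim$truth$states[mi, ] == 1L, 0.30, 0.75))
  got_e <- rowMeans(fs$e, na.rm = TRUE)
  expect_gte(mean(abs(got_e - true_e) < 0.05), 0.95)
})

test_that("extraction is deterministic for fixed input", {
  sim <- make_movie(n_molecules = 15, seed = 91, read_sd = 3)
  halves <- split_channels(sim$movie)
  spots <- detect_spots(halves$acceptor, psf_sigma = 1.1)
  spots <- map_to_donor(spots, c(0, 0), dim(halves$donor)[1:2])
  a <- extract_traces(halves$donor, halves$acceptor, spots, 0.1)
  b <- extract_traces(halves$donor, halves$acceptor, spots, 0.1)
  expect_identical(a$i_d, b$i_d)
  expect_identical(a$i_a, b$i_a)
})
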
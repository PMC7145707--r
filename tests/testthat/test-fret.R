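test_that("FRET efficiency is the acceptor fraction of total emission", {
  ts <- trace_set(matrix(c(100, 400, 0)), matrix(c(300, 0, 0)))
  fs <- fret_efficiency(ts, floor = 40)
  expect_equal(fs$e[1, 1], 0.75)
  expect_equal(fs$e[2, 1], 0)
  expect_true(is.na(fs$e[3, 1]))   # total below floor: invalid, not NaN math
  expect_false(fs$valid[3, 1])
})

test_that("the validity floor defaults follow the stated rules", {
  ts <- trace_set(matrix(runif(200, 200, 300), 20), matrix(runif(200, 200, 300), 20))
  expect_equal(fret_efficiency(ts, total_intensity = 500)$floor, 50)
  auto <- fret_efficiency(ts)
  expect_equal(auto$floor, quantile(ts$i_d + ts$i_a, 0.05, names = FALSE))
  expect_error(fret_efficiency(ts, floor = -1), "positive")
  expect_error(trace_set(matrix(1, 2, 3), matrix(1, 2, 4)), "identical dimensions")
})

test_that("pooling takes the first k valid frames of each molecule", {
  e <- matrix(seq(0.1, 3.0, by = 0.1), 3, 10, byrow = TRUE)
  ts <- trace_set(500 * (1 - e / 3), 500 * e / 3)
  fs <- fret_efficiency(ts, floor = 1)
  sample <- suppressWarnings(pool_first_k(fs, k = 5))
  expect_length(sample$e, 15)
  expect_equal(sample$n_molecules, 3)
  # a molecule with only 3 valid frames contributes 3
  fs$valid[1, 4:10] <- FALSE
  fs$e[1, 4:10] <- NA
  sample3 <- suppressWarnings(pool_first_k(fs, k = 5))
  expect_length(sample3$e, 13)
  expect_equal(sum(sample3$molecule == 1), 3)
})

test_that("small samples warn against the reference histogram scale", {
  cond <- condition("warn", kinetics = kinetic_params(0.5),
                    photophysics = quiet_photophysics())
  sim <- simulate_traces(cond, 2500, n_frames = 6, seed = 1)
  fs <- fret_efficiency(sim$traces, total_intensity = 500)
  expect_no_warning(pool_first_k(fs, k = 5))
  small <- simulate_traces(cond, 1500, n_frames = 6, seed = 2)
  expect_warning(pool_first_k(fret_efficiency(small$traces, total_intensity = 500)),
                 "1500 molecules")
})

test_that("histograms use half-open bins and a unit-sum density", {
  h <- fret_histogram(rep(0.75, 10), bin_width = 0.02)
  occupied <- h[h$count > 0, ]
  expect_equal(nrow(occupied), 1)
  expect_equal(occupied$bin_lo, 0.74)
  expect_equal(occupied$bin_hi, 0.76)
  expect_equal(occupied$count, 10)
  set.seed(5)
  h2 <- fret_histogram(runif(1000), bin_width = 0.02)
  expect_lt(abs(sum(h2$density) - 1), 1e-12)
  expect_equal(sum(h2$count), 1000)
  expect_error(fret_histogram(runif(10), bin_width = 0), "positive")
})

test_that("uniform draws give flat per-bin densities within sampling error", {
  set.seed(9)
  n <- 1e5
  h <- fret_histogram(runif(n), bin_width = 0.02, range = c(0, 1))
  expect_gt(chisq.test(h$count)$p.value, 0.01)   # goodness of fit to uniform
  p <- 0.02
  se <- sqrt(p * (1 - p) / n)
  expect_true(all(abs(h$density - p) <= 5 * se))
})

test_that("population classification matches the stated thresholds and tie-breaks", {
  counts <- classify_populations(c(0.0, 0.4, 0.8))
  expect_equal(c(counts$n_donor_only, counts$n_low, counts$n_high), c(1, 1, 1))
  # boundary values: donor_only_max closes donor-only, boundary closes high
  tie <- classify_populations(c(0.2, 0.65))
  expect_equal(tie$n_donor_only, 1)
  expect_equal(tie$n_high, 1)
  expect_equal(tie$n_low, 0)
  expect_error(fret_thresholds(0.7, 0.65), "donor_only_max")
})

test_that("counts always conserve the pooled sample size", {
  set.seed(11)
  for (i in 1:20) {
    e <- rnorm(500, mean = runif(1), sd = runif(1, 0.01, 0.5))
    b <- sample(c(0.6, 0.65, 0.7), 1)
    counts <- classify_populations(e, fret_thresholds(0.2, b))
    expect_identical(counts$n_donor_only + counts$n_low + counts$n_high, 500L)
  }
})

test_that("raising the boundary can only grow the low-FRET class", {
  set.seed(13)
  e <- c(rnorm(2000, 0.3, 0.08), rnorm(2000, 0.75, 0.08))
  n_low <- vapply(c(0.6, 0.65, 0.7), function(b)
    classify_populations(e, fret_thresholds(0.2, b))$n_low, 0L)
  expect_true(all(diff(n_low) >= 0))
  # oracle: brute-force reclassification
  brute <- vapply(c(0.6, 0.65, 0.7), function(b) sum(e > 0.2 & e < b), 0L)
  expect_identical(n_low, brute)
})
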
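test_that("noiseless traces reproduce the intensity contract exactly", {
  cond <- condition("noiseless", kinetics = kinetic_params(0),
                    photophysics = quiet_photophysics(total_intensity = 400))
  sim <- simulate_traces(cond, 5, n_frames = 8, seed = 1)
  expect_true(all(sim$traces$i_a == 300))
  expect_true(all(sim$traces$i_d == 100))
})

test_that("noise-free E equals the state efficiency frame by frame", {
  cond <- condition("id", kinetics = kinetic_params(0.5),
                    photophysics = quiet_photophysics())
  sim <- simulate_traces(cond, 50, n_frames = 20, seed = 3)
  e <- sim$traces$i_a / (sim$traces$i_d + sim$traces$i_a)
  expected <- ifelse(sim$truth$states == 1L, 0.30, 0.75)
  expect_equal(e, expected, tolerance = 1e-12)
})

test_that("donor-only molecules emit no acceptor signal", {
  cond <- condition("donly", kinetics = kinetic_params(0.5),
                    photophysics = photophysics_params(
                      donor_only_fraction = 0.999999, noise_sd = 0,
                      background = 7))
  sim <- simulate_traces(cond, 20, n_frames = 5, seed = 2)
  expect_true(all(sim$truth$molecules$donor_only))
  expect_true(all(sim$traces$i_a == 7))
  expect_true(all(sim$traces$i_d == 500 + 7))
})

test_that("first-frame unwound fraction matches the equilibrium draw", {
  p <- 0.6; n <- 3000
  cond <- condition("eq", kinetics = kinetic_params(p),
                    photophysics = quiet_photophysics())
  sim <- simulate_traces(cond, n, n_frames = 2, seed = 77)
  frac <- mean(sim$truth$states[, 1])
  expect_lt(abs(frac - p), 3 * sqrt(p * (1 - p) / n))
})

test_that("bleaching silences the acceptor first, then the donor", {
  cond <- condition("bleach", kinetics = kinetic_params(0),
                    photophysics = quiet_photophysics(bleach_rate = 0.15))
  sim <- simulate_traces(cond, 200, n_frames = 30, seed = 9)
  mol <- sim$truth$molecules
  ba <- mol$bleach_frame_acceptor; bd <- mol$bleach_frame_donor
  i <- which(!is.na(ba) & (is.na(bd) | bd > ba + 1))[1]
  expect_false(is.na(i))
  # after acceptor bleach (donor alive): all emission in the donor channel
  expect_equal(sim$traces$i_a[i, ba[i]], 0)
  expect_equal(sim$traces$i_d[i, ba[i]], 500)
  expect_equal(sim$truth$e_true[i, ba[i]], 0)
  j <- which(!is.na(bd))[1]
  expect_equal(sim$traces$i_d[j, bd[j]], 0)
  expect_true(is.na(sim$truth$e_true[j, bd[j]]))
})

test_that("trace simulation is bit-identical under a fixed seed", {
  cond <- condition("det", kinetics = kinetic_params(0.3))
  a <- simulate_traces(cond, 40, n_frames = 10, seed = 123)
  b <- simulate_traces(cond, 40, n_frames = 10, seed = 123)
  expect_identical(a$traces$i_d, b$traces$i_d)
  expect_identical(a$traces$i_a, b$traces$i_a)
  expect_identical(a$truth$states, b$truth$states)
})

test_that("invalid photophysics is rejected with the field named", {
  expect_error(photophysics_params(noise_sd = -1), "noise_sd")
  expect_error(photophysics_params(background = -5), "background")
  expect_error(photophysics_params(e_unwound = 0.8, e_rewound = 0.75),
               "smaller than e_rewound")
})

test_that("condition panels carry the stated occupancies", {
  panel <- condition_panel(c(`0` = 0.9, `1` = 0.3, `2` = 0.1, `3` = 0.05),
                           label = "WT")
  expect_length(panel, 4)
  expect_equal(vapply(panel, function(cc) cc$kinetics$p_unwound, 0),
               c(0.9, 0.3, 0.1, 0.05))
  expect_equal(vapply(panel, function(cc) cc$n_pd, 0L), 0:3)
  expect_identical(condition_panel(numeric(0)), list())
  expect_error(condition_panel(c(`5` = 0.5)), "n_pd")
  expect_error(condition_panel(c(`1` = 1.5)), "\\[0, 1\\]")
})
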
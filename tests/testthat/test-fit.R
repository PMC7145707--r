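test_that("a purely rewound population gives zero unwound fraction", {
  cond <- condition("hi", kinetics = kinetic_params(0),
                    photophysics = quiet_photophysics(noise_sd = 10))
  sim <- simulate_traces(cond, 100, n_frames = 6, seed = 1)
  fit <- fit_quiet(sim$traces, n_boot = 50, seed = 1, total_intensity = 500)
  expect_equal(fit$f_unwound, 0)
  expect_lt(fit$mean_e_high - 0.75, 0.02)
})

test_that("fitting fails informatively without FRET-active molecules", {
  ts <- trace_set(matrix(500, 5, 6), matrix(0, 5, 6))  # all E = 0
  expect_error(fit_quiet(ts, total_intensity = 500), "no FRET-active")
  expect_error(fit_quiet(trace_set(matrix(1, 1, 3), matrix(1, 1, 3))),
               "at least 2 molecules")
})

test_that("the estimator recovers the simulated occupancy", {
  cond <- condition("rec", kinetics = kinetic_params(0.6))
  sim <- simulate_traces(cond, 3000, n_frames = 8, seed = 17)
  fit <- fit_quiet(sim$traces, n_boot = 300, seed = 2, total_intensity = 500)
  expect_lt(abs(fit$f_unwound - 0.6), 0.03)
  expect_lt(abs(fit$mean_e_low - 0.30), 0.02)
  expect_lt(abs(fit$mean_e_high - 0.75), 0.02)
})

test_that("bootstrap SD matches the binomial closed form within a factor of 1.5", {
  n <- 3000
  cond <- condition("sd", kinetics = kinetic_params(0.6))
  sim <- simulate_traces(cond, n, n_frames = 8, seed = 23)
  fit <- fit_quiet(sim$traces, n_boot = 500, seed = 3, total_intensity = 500)
  # frames within a molecule are correlated (quasi-static states), so the
  # information unit is the molecule, not the frame
  closed_form <- sqrt(0.6 * 0.4 / n)
  expect_gt(fit$sd, closed_form / 1.5)
  expect_lt(fit$sd, closed_form * 1.5)
})

test_that("donor-only molecules are excluded from the denominator by default", {
  cond <- condition("don", kinetics = kinetic_params(0.5),
                    photophysics = photophysics_params(donor_only_fraction = 0.4,
                                                       noise_sd = 10))
  sim <- simulate_traces(cond, 1500, n_frames = 6, seed = 29)
  f_excl <- fit_quiet(sim$traces, n_boot = 0, total_intensity = 500)
  f_incl <- fit_quiet(sim$traces, n_boot = 0, total_intensity = 500,
                      include_donor_only = TRUE)
  expect_lt(abs(f_excl$f_unwound - 0.5), 0.05)
  expect_lt(f_incl$f_unwound, f_excl$f_unwound)
  tot <- f_excl$counts$n_donor_only + f_excl$counts$n_low + f_excl$counts$n_high
  expect_equal(tot, length(f_excl$sample$e))
})

test_that("fit accessors and simulate method are coherent", {
  cond <- condition("acc", kinetics = kinetic_params(0.4),
                    photophysics = quiet_photophysics(noise_sd = 15))
  sim <- simulate_traces(cond, 500, n_frames = 6, seed = 31)
  fit <- fit_quiet(sim$traces, n_boot = 200, seed = 4, total_intensity = 500,
                   label = "accessor check")
  expect_named(coef(fit), "f_unwound")
  ci <- confint(fit)
  expect_true(ci[1] <= fit$f_unwound && fit$f_unwound <= ci[2])
  expect_output(print(summary(fit)), "f_unwound")
  resim <- simulate(fit, nsim = 2, seed = 5, n_molecules = 200)
  expect_length(resim, 2)
  refit <- fit_quiet(resim[[1]]$traces, n_boot = 0, total_intensity = 500)
  expect_lt(abs(refit$f_unwound - fit$f_unwound), 0.1)
})

test_that("the estimate is monotone in the simulated occupancy", {
  ps <- seq(0.05, 0.95, by = 0.1)
  f_hat <- vapply(seq_along(ps), function(i) {
    cond <- condition("mono", kinetics = kinetic_params(ps[i]))
    sim <- simulate_traces(cond, 800, n_frames = 6, seed = 100 + i)
    fit_quiet(sim$traces, n_boot = 0, total_intensity = 500)$f_unwound
  }, 0)
  expect_true(all(diff(f_hat) > 0))
})
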
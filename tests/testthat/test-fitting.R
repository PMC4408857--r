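test_that("the objective combines band and entropy errors as specified", {
  mk <- function(bp, sh, sp) {
    structure(list(band_powers = bp, shannon = sh, sampen = sp),
              class = "feature_vector")
  }
  base <- rep(1 / 7, 7)
  target <- mk(base, 2.0, 1.2)
  model <- mk(base + 0.1, 1.8, 1.1)
  out <- eegdvp:::objective_from_features(target, model)
  # 7 * 0.1^2 + 0.35 * 0.2 + 0.35 * 0.1 = 0.175
  expect_equal(out$J, 0.175, tolerance = 1e-12)
  # zero weights reduce J to the band term alone
  out0 <- eegdvp:::objective_from_features(target, model, weights = c(0, 0))
  expect_equal(out0$J, 0.07, tolerance = 1e-12)
  # restricting the bands drops their errors
  out5 <- eegdvp:::objective_from_features(target, model, weights = c(0, 0),
                                           bands_used = 2:6)
  expect_equal(out5$J, 0.05, tolerance = 1e-12)
})

test_that("bounds: published parameter sets classify as documented", {
  expect_true(check_bounds(reference_params("EO-CTL"))$feasible)
  expect_true(check_bounds(reference_params("EC-AD"))$feasible)
  expect_true(check_bounds(reference_params("EO-AD"))$feasible)
  # eyes-closed control mean noise intensity exceeds the mu <= 2 box
  chk <- check_bounds(reference_params("EC-CTL"))
  expect_false(chk$feasible)
  expect_match(chk$violations, "mu", all = FALSE)
  expect_false(check_bounds(c(k1 = 1e5, k2 = 100, b1 = 1, b2 = 1,
                              eps1 = 1, eps2 = 1, mu = 1))$feasible)
  # b and eps caps scale with their oscillator's stiffness
  expect_false(check_bounds(c(k1 = 100, k2 = 100, b1 = 51, b2 = 1,
                              eps1 = 1, eps2 = 1, mu = 1))$feasible)
  expect_false(check_bounds(c(k1 = 100, k2 = 100, b1 = 1, b2 = 1,
                              eps1 = 34, eps2 = 1, mu = 1))$feasible)
})

test_that("infeasible parameters are rejected with an infinite penalty", {
  tgt <- feature_vector(noise_block(seed = 2))
  expect_identical(osc_objective(reference_params("EC-CTL"), tgt), Inf)
})

test_that("self-match with identical seeds gives an exactly zero objective", {
  p <- reference_params("EO-CTL")
  seeds <- c(101, 202)
  fvs <- lapply(seeds, function(s) {
    feature_vector(simulate_oscillator(p, duration = 10, seed = s))
  })
  target <- eegdvp:::average_features(fvs)
  J <- osc_objective(p, target, seeds = seeds, n_realizations = 2,
                     sim_args = list(duration = 10))
  expect_equal(J, 0, tolerance = 1e-12)
})

test_that("the objective is invariant to the target block's amplitude", {
  b <- noise_block(seed = 6)
  p <- reference_params("EO-CTL")
  J1 <- osc_objective(p, feature_vector(b), seeds = 1:2,
                      n_realizations = 2, sim_args = list(duration = 8))
  J2 <- osc_objective(p, feature_vector(eeg_block(as.numeric(b) * 250,
                                                  fs = 125)),
                      seeds = 1:2, n_realizations = 2,
                      sim_args = list(duration = 8))
  expect_equal(J1, J2, tolerance = 1e-10)
})

test_that("transformed coordinates always map into the feasible box", {
  set.seed(14)
  for (i in 1:25) {
    z <- rnorm(7, sd = 4)
    expect_true(check_bounds(eegdvp:::z_to_params(z))$feasible)
  }
  # round trip through the transform recovers a feasible set
  p <- reference_params("EO-CTL")
  p2 <- eegdvp:::z_to_params(eegdvp:::params_to_z(p))
  expect_equal(unclass(p2), unclass(p), tolerance = 1e-6)
})

test_that("multi-start search improves on fewer starts and recovers features", {
  p_true <- reference_params("EO-CTL")
  target <- feature_vector(simulate_oscillator(p_true, duration = 10,
                                               seed = 55))
  fit1 <- fit_oscillator(target, n_starts = 1, n_realizations = 2,
                         seed = 3, sim_args = list(duration = 10),
                         maxeval = 60)
  fit4 <- fit_oscillator(target, n_starts = 4, n_realizations = 2,
                         seed = 3, sim_args = list(duration = 10),
                         maxeval = 60)
  # nested start sets with a fixed seed: best-of-4 can not be worse
  expect_lte(fit4$J, fit1$J)
  # returned parameters always satisfy the box
  expect_true(check_bounds(fit1$params)$feasible)
  expect_true(check_bounds(fit4$params)$feasible)
  expect_s3_class(fit4, "osc_fit")
  expect_equal(nrow(fit4$starts), 4)
  # reproducibility of the whole search
  fit4b <- fit_oscillator(target, n_starts = 4, n_realizations = 2,
                          seed = 3, sim_args = list(duration = 10),
                          maxeval = 60)
  expect_identical(coef(fit4), coef(fit4b))
  expect_identical(fit4$J, fit4b$J)
})

test_that("fit methods print, summarise and simulate coherently", {
  target <- feature_vector(simulate_oscillator(reference_params("EO-CTL"),
                                               duration = 8, seed = 9))
  fit <- fit_oscillator(target, n_starts = 1, n_realizations = 1,
                        seed = 2, sim_args = list(duration = 8),
                        maxeval = 30)
  expect_named(coef(fit), c("k1", "k2", "b1", "b2", "eps1", "eps2", "mu"))
  expect_length(residuals(fit), 9)
  expect_output(print(fit), "J =")
  expect_output(print(summary(fit)), "feature match")
  sims <- simulate(fit, nsim = 2, seed = 8)
  expect_length(sims, 2)
  expect_s3_class(sims[[1]], "eeg_block")
  expect_identical(as.numeric(simulate(fit, nsim = 2, seed = 8)[[2]]),
                   as.numeric(sims[[2]]))
})
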
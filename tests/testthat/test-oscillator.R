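test_that("drift matches hand-evaluated dynamics", {
  p <- osc_params(2, 1, 1, 1, 1, 1, 0)
  # equilibrium at the origin
  expect_equal(osc_drift(c(0, 0, 0, 0), p), c(0, 0, 0, 0))
  # x1 = x2 makes the relative-displacement cubic vanish for any b2
  p_bigb2 <- osc_params(2, 1, 1, 500, 1, 1, 0)
  expect_equal(osc_drift(c(1, 0, 1, 0), p),
               osc_drift(c(1, 0, 1, 0), p_bigb2))
  # hand evaluation: dv1 = -(3)(1) - 1 - 1 + 0 = -5; dv2 = 1 + 1 + 0 = 2
  expect_equal(osc_drift(c(1, 0, 0, 0), p), c(0, -5, 0, 2))
  expect_error(osc_drift(c(NaN, 0, 0, 0), p), "finite")
})

test_that("simulation is seed-deterministic and respects equilibrium", {
  p <- reference_params("EO-CTL")
  a <- simulate_oscillator(p, duration = 2, seed = 11)
  b <- simulate_oscillator(p, duration = 2, seed = 11)
  expect_identical(as.numeric(a), as.numeric(b))
  expect_equal(length(a), 250L)
  # zero state, no noise: exactly zero forever
  p0 <- osc_params(100, 50, 1, 1, 1, 1, 0)
  z <- simulate_oscillator(p0, duration = 2, seed = 1,
                           initial_state = c(0, 0, 0, 0))
  expect_identical(unique(as.numeric(z)), 0)
})

test_that("linear limit reproduces the analytic eigenfrequencies", {
  # b, eps ~ 0 leaves the pure linear stiffness matrix; starting on each
  # eigenvector isolates one mode, whose spectral peak must sit within one
  # FFT bin of sqrt(lambda)/(2 pi). (The undamped explicit scheme slowly
  # inflates amplitude, which moves no peak, so the horizon is kept short.)
  k1 <- 7286.5; k2 <- 4523.5
  p <- osc_params(k1, k2, 1e-300, 1e-300, 1e-300, 1e-300, 0)
  K <- matrix(c(k1 + k2, -k2, -k2, k2), 2, 2)
  e <- eigen(K, symmetric = TRUE)
  f_expect <- linear_eigenfreqs(k1, k2)
  for (mode in 1:2) {
    v <- e$vectors[, order(e$values)[mode]]
    b <- simulate_oscillator(p, duration = 8, seed = 1, burn_in = 0,
                             initial_state = c(v[1], 0, v[2], 0))
    pw <- eegdvp:::welch_psd(as.numeric(b), 125, window_s = 4)
    df <- pw$freq[2] - pw$freq[1]
    peak <- pw$freq[which.max(pw$psd)]
    expect_lt(abs(peak - f_expect[mode]), df + 1e-9)
  }
})

test_that("an uncoupled van der Pol oscillator settles on a bounded limit cycle", {
  # k2, b ~ 0 isolates oscillator 1 as a pure van der Pol unit
  p <- osc_params(400, 1e-9, 1e-9, 1e-9, 4, 1e-9, 0)
  b <- simulate_oscillator(p, duration = 40, seed = 1, burn_in = 0,
                           initial_state = c(0.01, 0, 0, 0),
                           output_channel = "x1")
  x <- as.numeric(b)
  expect_true(all(is.finite(x)))
  # amplitude stabilises near the classic value 2 over the last half
  late <- x[(length(x) / 2):length(x)]
  expect_gt(max(abs(late)), 1.5)
  expect_lt(max(abs(late)), 3)
  # periodic: autocorrelation at one period is high
  period <- round(125 * 2 * pi / sqrt(400))
  expect_gt(cor(late[1:(length(late) - period)], late[-(1:period)]), 0.95)
})

test_that("output variance is non-decreasing in the noise intensity", {
  # weakly self-excited configuration, where added noise injects energy
  # rather than disrupting an already-saturated limit cycle
  mus <- c(0, 0.5, 1, 2, 4, 8)
  v <- sapply(mus, function(mu) {
    p <- osc_params(400, 100, 1, 1, 0.5, 0.5, mu)
    mean(sapply(1:20, function(s) {
      var(as.numeric(simulate_oscillator(p, duration = 4, seed = s)))
    }))
  })
  expect_true(all(diff(v) >= 0))
})

test_that("Euler-Maruyama converges as the step is refined", {
  p <- reference_params("EO-CTL")
  # deterministic: order-1 error halving between h and h/2
  p0 <- osc_params(unclass(p)[1], unclass(p)[2], unclass(p)[3],
                   unclass(p)[4], unclass(p)[5], unclass(p)[6], 0)
  tab <- em_convergence(p0, substeps = 8, horizon = 0.5)
  expect_true(all(diff(tab$err) < 0))
  ratio <- tab$err[1] / tab$err[2]
  expect_gt(ratio, 1.5)
  expect_lt(ratio, 3.5)
  # stochastic: strong error shrinks monotonically on a common Wiener path
  tab2 <- em_convergence(p, substeps = 8, horizon = 0.5, seed = 4)
  expect_true(all(diff(tab2$err) < 0))
  # zero dynamics: no error at any step
  tiny <- osc_params(1e-9, 1e-9, 1e-9, 1e-9, 1e-9, 1e-9, 0)
  tab3 <- em_convergence(tiny, substeps = 2, horizon = 0.5,
                         initial_state = c(0, 0, 0, 0))
  expect_equal(tab3$err, c(0, 0, 0))
})

test_that("blow-ups are reported with step index instead of returning garbage", {
  p <- reference_params("EC-CTL")
  err <- tryCatch(
    simulate_oscillator(p, duration = 2, seed = 1, substeps = 1),
    osc_blowup = function(e) e)
  expect_s3_class(err, "osc_blowup")
  expect_true(is.numeric(err$step) && err$step >= 1)
})

test_that("block CSV round trip preserves samples and metadata", {
  b <- simulate_oscillator(reference_params("EO-CTL"), duration = 2,
                           seed = 3)
  path <- tempfile(fileext = ".csv")
  write_eeg_block(b, path)
  b2 <- read_eeg_block(path)
  expect_equal(as.numeric(b2), as.numeric(b), tolerance = 1e-12)
  expect_equal(block_fs(b2), 125)
  expect_equal(attr(b2, "meta")$params$k1, 2427.2)
  unlink(c(path, paste0(path, ".json")))
})
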
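test_that("step-current calibration reaches its target and is monotone", {
  m <- ctrl_model()
  amp <- calibrate_step_current(m, -80, duration = 500)
  expect_lt(amp, 0)
  # self-consistency: re-simulating with the returned amplitude reproduces
  # the target minimum voltage within the stated tolerance
  st <- data.frame(t_on = 4000, t_off = 4500, amp = amp)
  res <- simulate_neuron(m, duration = 4500, stimulus = st, record_stride = 40L)
  vmin <- min(res$trace$v_mv[res$trace$time_ms >= 4000])
  expect_lt(abs(vmin - (-80)), 0.5)
  # deeper targets need stronger (more negative) amplitudes
  amp90 <- calibrate_step_current(m, -90, duration = 500)
  expect_lt(amp90, amp)
  # a target above the resting trajectory violates the precondition
  expect_error(calibrate_step_current(m, -40, duration = 500), "below")
})

test_that("rebound delay is measured from step offset and censors cleanly", {
  m <- ctrl_model()
  # zero-amplitude step: no perturbation, next spike within one baseline ISI
  pr0 <- step_protocol(step_ms = 200, amp_pa = 0, window_ms = 3000)
  r0 <- measure_rebound_delay(m, pr0)
  expect_false(r0$censored)
  expect_lte(r0$delay_ms, r0$baseline_isi_ms * 1.1)
  # a too-short observation window censors at the window length
  pr <- step_protocol(step_ms = 1000, target_vmin_mv = -80, window_ms = 100)
  r <- measure_rebound_delay(m, pr)
  expect_true(r$censored)
  expect_equal(r$delay_ms, 100)
  expect_lt(r$v_min, -79)
})

test_that("a single-point depth sweep reduces to one rebound measurement", {
  m <- ex3d_model()
  sw <- sweep_depth(m, -80, duration = 1000, window_ms = 8000)
  pr <- step_protocol(step_ms = 1000, target_vmin_mv = -80, window_ms = 8000)
  r <- measure_rebound_delay(m, pr)
  expect_equal(nrow(sw), 1)
  expect_equal(sw$delay_ms, r$delay_ms, tolerance = 1e-6)
  expect_error(sweep_depth(m, c(-80, -60, -70)), "sorted")
})

test_that("Boltzmann duration fit recovers known parameters", {
  d <- c(10, 25, 50, 100, 150, 200, 300, 450, 650)
  truth <- 2000 / (1 + exp((100 - d) / 30))
  fit <- fit_rebound_boltzmann(d, truth)
  expect_equal(fit$max_delay_ms, 2000, tolerance = 0.01)
  expect_equal(fit$half_duration_ms, 100, tolerance = 0.01)
  expect_equal(fit$slope_ms, 30, tolerance = 0.01)
  expect_false(fit$degenerate)
  # constant data: degenerate, max equals the constant
  cst <- fit_rebound_boltzmann(d, rep(500, length(d)))
  expect_true(cst$degenerate)
  expect_equal(cst$max_delay_ms, 500)
  expect_error(fit_rebound_boltzmann(1:3, 1:3), ">= 4")
})

test_that("Boltzmann fit of noisy data is unbiased for the maximal delay", {
  d <- c(10, 25, 50, 100, 150, 200, 300, 450, 650)
  truth <- 2000 / (1 + exp((100 - d) / 30))
  set.seed(42)
  ests <- replicate(100, {
    y <- truth + stats::rnorm(length(d), 0, 100) # sd = 5% of max
    fit_rebound_boltzmann(d, pmax(y, 0))$max_delay_ms
  })
  expect_lt(abs(mean(ests) - 2000), 2 * stats::sd(ests))
})

test_that("minimum-voltage regression matches OLS and recovers the control slope", {
  v <- c(-90, -85, -80, -75, -70, -65)
  y <- -0.03 * v + 1
  f <- fit_vmin_regression(v, y)
  expect_equal(f$slope, -0.03)
  expect_equal(f$r2, 1)
  # order invariance
  perm <- c(3, 1, 6, 2, 5, 4)
  f2 <- fit_vmin_regression(v[perm], y[perm])
  expect_equal(f2$slope, f$slope)
  expect_equal(f2$intercept, f$intercept)
  expect_error(fit_vmin_regression(rep(-80, 5), 1:5), "constant")
  # noisy cloud generated at the control-group slope: recovered within its CI
  dat <- generate_vmin_delay_data(n = 120, slope = -3.542e-2, seed = 11)
  fr <- fit_vmin_regression(dat$vmin_mv, dat$delay_s)
  expect_lt(abs(fr$slope - (-3.542e-2)), 2 * fr$slope_se)
})
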
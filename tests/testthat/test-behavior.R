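test_that("the piecewise update applies the branch matching the RPE sign", {
  p <- rw_params(0.5, 0.2)
  expect_equal(rw_update(0, 1, p), 0.5)   # positive RPE
  expect_equal(rw_update(1, 0, p), 0.8)   # negative RPE
  expect_equal(rw_update(0.7, 0.7, p), 0.7) # tie: positive branch, unchanged
  z <- rw_params(0, 0)
  for (r in c(-1, 0, 2)) expect_equal(rw_update(0.4, r, z), 0.4)
  expect_error(rw_params(1.2, 0.1), "\\[0, 1\\]")
  expect_error(rw_update(NA, 1, p), "finite")
})

test_that("trajectories are fixed at r = v0 and rise/fall across phases", {
  p <- rw_params(0.3, 0.1)
  flat <- simulate_trajectory(p, rep(0.4, 20), v0 = 0.4)
  expect_true(all(flat == 0.4))
  expect_length(flat, 21)
  sched <- c(rep(1, 30), rep(0, 30))
  traj <- simulate_trajectory(p, sched, v0 = 0)
  expect_true(all(diff(traj[1:31]) >= 0))   # monotone rise in acquisition
  expect_true(all(diff(traj[31:61]) <= 0))  # monotone fall in extinction
  # no negative-RPE learning: constant throughout extinction
  p0 <- rw_params(0.3, 0)
  traj0 <- simulate_trajectory(p0, sched, v0 = 0)
  expect_equal(stats::sd(traj0[31:61]), 0)
  expect_error(simulate_trajectory(p, numeric(0)), "non-empty")
})

test_that("trajectories are bounded by v0 and the reward range", {
  set.seed(31)
  for (i in 1:25) {
    p <- rw_params(stats::runif(1), stats::runif(1))
    sched <- stats::runif(40, -2, 3)
    v0 <- stats::runif(1, -1, 1)
    traj <- simulate_trajectory(p, sched, v0)
    expect_gte(min(traj), min(v0, min(sched)))
    expect_lte(max(traj), max(v0, max(sched)))
  }
})

test_that("bounds derivation reproduces session means and flags inversions", {
  mk <- function(y) session_series(data.frame(
    session = rep(1:4, each = 10),
    phase = rep(c("acquisition", "extinction"), each = 20),
    trial = rep(1:10, 4), pct_time_in_port = y))
  # constant series
  b <- derive_bounds(mk(rep(40, 40)))
  expect_equal(c(b$v0, b$v_min, b$v_max), c(40, 40, 40))
  # known session means: acquisition sessions 60/70, extinction 20/10
  y <- rep(c(60, 70, 20, 10), each = 10)
  b2 <- derive_bounds(mk(y))
  expect_equal(b2$v0, 60)             # first three trials
  expect_equal(b2$v_max, 65)          # last two acquisition sessions
  expect_equal(b2$v_min, 15)          # last two extinction sessions
  # inverted orientation warns and is resolved by magnitude
  expect_warning(b3 <- derive_bounds(mk(rep(c(10, 20, 60, 70), each = 10))),
                 "orientation")
  expect_lte(b3$v_min, b3$v_max)
  # insufficient structure errors
  short <- data.frame(session = 1, phase = "acquisition", trial = 1:2,
                      pct_time_in_port = c(1, 2))
  expect_error(derive_bounds(session_series(short)), "at least")
})

test_that("session series validation enforces schema and phase order", {
  expect_error(session_series(data.frame(a = 1)), "columns")
  bad <- data.frame(session = 1:2, phase = c("extinction", "acquisition"),
                    trial = c(1, 1), pct_time_in_port = c(5, 5))
  expect_error(session_series(bad), "contiguous")
  bad2 <- data.frame(session = 1, phase = "acquisition", trial = 1,
                     pct_time_in_port = 150)
  expect_error(session_series(bad2), "\\[0, 100\\]")
})

test_that("fitting recovers generating learning rates from noiseless data", {
  b <- rw_bounds(5, 5, 75)
  ser <- generate_behavior_sessions(rw_params(0.3, 0.1), b, noise_sd = 0,
                                    seed = 2)[[1]]
  f <- fit_learning_rates(ser, b)
  expect_lt(abs(f$alpha_p - 0.3), 1e-3)
  expect_lt(abs(f$alpha_n - 0.1), 1e-3)
  expect_lt(f$residual, 1e-4)
  # flat series: zero residual, degenerate flag
  flat <- session_series(data.frame(
    session = rep(1:4, each = 10),
    phase = rep(c("acquisition", "extinction"), each = 20),
    trial = rep(1:10, 4), pct_time_in_port = rep(30, 40)))
  ff <- fit_learning_rates(flat)
  expect_true(ff$degenerate)
  expect_equal(ff$residual, 0)
})

test_that("the fit objective depends on trial order", {
  b <- rw_bounds(5, 5, 75)
  ser <- generate_behavior_sessions(rw_params(0.4, 0.15), b, noise_sd = 0,
                                    seed = 3)[[1]]
  pred <- rw_predict(rw_params(0.4, 0.15), ser, b)
  expect_equal(sum(abs(ser$pct_time_in_port - pred)), 0, tolerance = 1e-8)
  # reversing the trials within acquisition changes the objective
  ser2 <- ser
  acq <- which(ser2$phase == "acquisition")
  ser2$pct_time_in_port[acq] <- rev(ser2$pct_time_in_port[acq])
  expect_gt(sum(abs(ser2$pct_time_in_port - pred)), 1)
})

test_that("noiseless self-consistency is a global optimum on an alpha grid", {
  b <- rw_bounds(5, 5, 75)
  truth <- rw_params(0.35, 0.12)
  ser <- generate_behavior_sessions(truth, b, noise_sd = 0, seed = 4)[[1]]
  obs <- ser$pct_time_in_port
  grid <- expand.grid(a = seq(0.025, 0.975, length.out = 30),
                      n = seq(0.025, 0.975, length.out = 30))
  vals <- mapply(function(a, n) {
    sum(abs(obs - rw_predict(rw_params(a, n), ser, b)))
  }, grid$a, grid$n)
  at_truth <- sum(abs(obs - rw_predict(truth, ser, b)))
  expect_lte(at_truth, min(vals))
})

test_that("parameter recovery degrades gracefully with noise", {
  tab <- parameter_recovery_suite(data.frame(alpha_p = 0.3, alpha_n = 0.1),
                                  noise_sds = c(0, 5), replicates = 5, seed = 12)
  z <- tab[tab$noise_sd == 0, ]
  expect_lt(z$rmse_p, 1e-3)
  expect_lt(z$rmse_n, 1e-3)
  n5 <- tab[tab$noise_sd == 5, ]
  expect_gte(n5$rmse_p, z$rmse_p)
  expect_gte(n5$rmse_n, z$rmse_n)
})

test_that("fitted negative-RPE rates separate slow and fast extinction groups", {
  b <- rw_bounds(5, 5, 75)
  fit_an <- function(an, seed) {
    ser <- generate_behavior_sessions(rw_params(0.3, an), b, noise_sd = 5,
                                      n_subjects = 1, seed = seed)[[1]]
    fit_learning_rates(ser, b)$alpha_n
  }
  fast <- vapply(1:6, function(i) fit_an(0.25, 100 + i), numeric(1))
  slow <- vapply(1:6, function(i) fit_an(0.05, 200 + i), numeric(1))
  expect_true(all(fast > slow)) # clean separation at this noise level
})
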
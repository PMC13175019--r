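test_that("poisson_train matches the Poisson law and is reproducible", {
  expect_length(poisson_train(0, 1000), 0)
  expect_identical(poisson_train(100, 1000, seed = 7), poisson_train(100, 1000, seed = 7))
  expect_error(poisson_train(-1, 100), ">= 0")
  set.seed(123)
  counts <- replicate(2000, length(poisson_train(100, 1000)))
  expect_lt(abs(mean(counts) - 100), 3 * sqrt(100 / 2000) * 3) # mean 100
  # index of dispersion ~ 1 for Poisson counts
  expect_lt(abs(stats::var(counts) / mean(counts) - 1), 0.15)
  tr <- poisson_train(100, 500, seed = 1)
  expect_true(all(tr >= 0 & tr <= 500))
  expect_true(!is.unsorted(tr))
})

test_that("balanced-state anchors: silence under pure inhibition, pacemaking with none", {
  m <- ctrl_model()
  # GABA alone (no excitation) silences the cell
  cfg0 <- balanced_config(glut_scale = 0, gaba_scale = 1,
                          trial_ms = 1500, refractory_ms = 2500)
  r0 <- run_balanced_trial(m, cfg0, seed = 3)
  expect_length(r0$spikes$times, 0)
  # both streams off: the intrinsic pacemaker rate
  cfg1 <- balanced_config(glut_scale = 0, gaba_scale = 0,
                          trial_ms = 2000, refractory_ms = 2500)
  r1 <- run_balanced_trial(m, cfg1, seed = 3)
  expect_gt(r1$mean_rate_hz, 2)
  expect_lt(r1$mean_rate_hz, 5)
  # reproducibility contract
  r2 <- run_balanced_trial(m, cfg1, seed = 3)
  expect_identical(r1$spikes$times, r2$spikes$times)
})

test_that("default balanced state fires in the in-vivo range", {
  m <- ctrl_model()
  cfg <- balanced_config()
  rates <- vapply(1:4, function(i) run_balanced_trial(m, cfg, seed = i)$mean_rate_hz,
                  numeric(1))
  expect_gt(mean(rates), 1.5)
  expect_lt(mean(rates), 8)
})

test_that("mean rate increases with the glutamate scale at fixed GABA scale", {
  m <- ctrl_model()
  rate_at <- function(gs) {
    cfg <- balanced_config(glut_scale = gs, gaba_scale = 1,
                           trial_ms = 1500, refractory_ms = 2500)
    mean(vapply(1:6, function(i) run_balanced_trial(m, cfg, seed = i)$mean_rate_hz,
                numeric(1)))
  }
  r <- vapply(c(0.75, 1, 1.25), rate_at, numeric(1))
  expect_true(all(diff(r) > 0))
})

test_that("PSTH arithmetic and invariants", {
  # single trial, one spike per 25 ms bin -> flat 40 Hz
  st <- spike_train(seq(12.5, 487.5, by = 25), 500)
  ps <- build_psth(list(st), bin_ms = 25)
  expect_true(all(ps$rate_hz == 40))
  # empty trials -> all-zero PSTH
  ps0 <- build_psth(list(spike_train(numeric(0), 500), spike_train(numeric(0), 500)))
  expect_true(all(ps0$rate_hz == 0))
  expect_error(build_psth(list(st), bin_ms = 0), "> 0")
  # integral over the trial equals total spikes / trials
  set.seed(5)
  trains <- lapply(1:20, function(i) spike_train(poisson_train(30, 1000), 1000))
  ps2 <- build_psth(trains, bin_ms = 25)
  total <- sum(vapply(trains, function(s) length(s$times), numeric(1)))
  expect_equal(sum(ps2$rate_hz * ps2$bin_ms / 1000), total / 20)
  # stationary Poisson trains: PSTH flat at the generating rate within error
  trains3 <- lapply(1:400, function(i) spike_train(poisson_train(40, 1000), 1000))
  ps3 <- build_psth(trains3, bin_ms = 25)
  se <- sqrt(40 / (400 * 0.025)) # per-bin binomial/Poisson error in Hz
  expect_true(all(abs(ps3$rate_hz - 40) < 5 * se))
})

test_that("percent spikes lost is exact on constructed histograms", {
  mk_psth <- function(rates, bin = 25) {
    structure(list(breaks_ms = seq(0, length(rates) * bin, by = bin),
                   rate_hz = rates, n_trials = 1, bin_ms = bin), class = "psth")
  }
  base_resp <- function(b, r) percent_spikes_lost(mk_psth(c(rep(b, 40), rep(r, 40))),
                                                  baseline = c(0, 1000),
                                                  response = c(1000, 2000))
  expect_equal(base_resp(10, 0), 100)   # complete silencing
  expect_equal(base_resp(10, 10), 0)    # unchanged rate
  expect_equal(base_resp(10, 5), 50)    # half the spikes lost
  expect_lt(base_resp(10, 15), 0)       # rate increase -> negative
  expect_error(base_resp(0, 5), "baseline rate is zero")
})

test_that("ensembles are invariant to trial execution order", {
  m <- ex3d_model()
  cfg <- balanced_config(trial_ms = 1000, refractory_ms = 2000)
  ens <- run_trial_ensemble(m, cfg, n_trials = 4, master_seed = 99)
  # re-run the same trials individually, in reverse order
  manual <- lapply(rev(seq_len(4)), function(i) {
    run_balanced_trial(m, cfg, seed = ens$seeds[i])$spikes$times
  })
  expect_identical(rev(manual), lapply(ens$trains, `[[`, "times"))
})

test_that("a correlated inhibitory train suppresses firing after its onset", {
  m <- ctrl_model()
  cfg <- balanced_config(trial_ms = 2500, refractory_ms = 3000)
  inh <- inhibition_config(n_inputs = 20, onset_ms = 1250)
  ens <- run_trial_ensemble(m, cfg, inh, n_trials = 20, master_seed = 17)
  ps <- build_psth(ens)
  lost <- percent_spikes_lost(ps, baseline = c(250, 1250), response = c(1250, 2250))
  expect_gt(lost, 10)
})
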
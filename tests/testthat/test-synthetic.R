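test_that("synthetic sessions follow the task structure and the RW readout", {
  b <- rw_bounds(5, 5, 75)
  p <- rw_params(0.3, 0.1)
  ser <- generate_behavior_sessions(p, b, noise_sd = 0, seed = 1)[[1]]
  expect_equal(nrow(ser), (11 + 6) * 10)
  expect_equal(sum(ser$phase == "acquisition"), 110)
  expect_equal(sum(ser$phase == "extinction"), 60)
  # zero noise: the series equals the linear readout of the trajectory exactly
  expect_equal(ser$pct_time_in_port, rw_predict(p, ser, b))
  # same seed, same output
  ser2 <- generate_behavior_sessions(p, b, noise_sd = 3, seed = 9)[[1]]
  ser3 <- generate_behavior_sessions(p, b, noise_sd = 3, seed = 9)[[1]]
  expect_identical(ser2$pct_time_in_port, ser3$pct_time_in_port)
  # noise is truncated to [0, 100]
  serN <- generate_behavior_sessions(p, rw_bounds(2, 2, 98), noise_sd = 40,
                                     seed = 5)[[1]]
  expect_true(all(serN$pct_time_in_port >= 0 & serN$pct_time_in_port <= 100))
})

test_that("a high negative learning rate extinguishes faster in group means", {
  b <- rw_bounds(5, 5, 75)
  mean_ext_curve <- function(an, seed0) {
    sers <- generate_behavior_sessions(rw_params(0.3, an), b, noise_sd = 5,
                                       n_subjects = 8, seed = seed0)
    sapply(12:17, function(s) {
      mean(sapply(sers, function(x) mean(x$pct_time_in_port[x$session == s])))
    })
  }
  fast <- mean_ext_curve(0.25, 1)
  slow <- mean_ext_curve(0.05, 1)
  expect_true(all(fast[-1] < slow[-1])) # faster drop from the second extinction session
})

test_that("reward-cycle accounting matches the task maxima", {
  cfg <- task_config()
  always <- simulate_reward_session(cfg, agent_policy("always"))
  expect_equal(always$rewards_per_trial, rep(6L, 10))
  expect_equal(always$total, 60L)
  never <- simulate_reward_session(cfg, agent_policy("never"))
  expect_equal(never$total, 0L)
  # rewards never exceed floor(cue / cycle)
  expect_true(all(always$rewards_per_trial <=
                    floor(cfg$cue_s / (cfg$delivery_s + cfg$consumption_s))))
  # 12 s of continuous occupancy from onset: deliveries at 0, 5 and 10 s all
  # complete within the occupancy (the third ends exactly as the head leaves)
  iv <- matrix(c(0, 12), ncol = 2)
  r12 <- simulate_reward_session(cfg, agent_policy("intervals", intervals = iv))
  expect_equal(r12$rewards_per_trial[1], 3L)
  # leaving mid-delivery aborts the reward: 1.5 s occupancy earns nothing
  iv2 <- matrix(c(0, 1.5), ncol = 2)
  r0 <- simulate_reward_session(cfg, agent_policy("intervals", intervals = iv2))
  expect_equal(r0$total, 0L)
})

test_that("spontaneous-alternation chance level is exact by enumeration", {
  ac <- alternation_chance(maze_config(4, 5))
  expect_equal(ac$n_total, 324L)
  expect_equal(ac$n_favorable, 144L)
  expect_equal(ac$probability, 4 / 9)
  # smaller maze: 3 arms, window 4 -> 18/24
  ac2 <- alternation_chance(maze_config(3, 4))
  expect_equal(ac2$probability, 0.75)
  # pigeonhole: window shorter than the number of arms
  expect_equal(alternation_chance(maze_config(4, 3))$probability, 0)
})

test_that("the Monte-Carlo alternation simulator converges to the exact value", {
  p <- alternation_chance(maze_config(4, 5))$probability
  n <- 2e4
  est <- alternation_simulate(maze_config(4, 5), n_draws = n, seed = 8)
  expect_lt(abs(est - p), 3 * sqrt(p * (1 - p) / n))
})

test_that("discrimination index follows its closed form", {
  expect_equal(discrimination_index(5, 5), 0)
  expect_equal(discrimination_index(4, 0), 1)
  expect_equal(discrimination_index(3, 1), 0.5)
  expect_equal(discrimination_index(1, 3), -0.5)
  expect_error(discrimination_index(0, 0), "undefined")
  expect_error(discrimination_index(-1, 2), ">= 0")
})

test_that("synthetic regression fixtures are seed-deterministic", {
  a <- generate_vmin_delay_data(n = 50, seed = 3)
  b <- generate_vmin_delay_data(n = 50, seed = 3)
  expect_identical(a, b)
  expect_true(all(a$delay_s >= 0))
})
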
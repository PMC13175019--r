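#' Appetitive conditioning task structure
#'
#' Defaults match the conditioning paradigm: 11 daily acquisition sessions and
#' 6 extinction sessions of 10 trials each; a 30 s auditory cue per trial;
#' rewards delivered in cycles of 2 s delivery (16.66 ul) plus 3 s consumption
#' (at most 6 rewards per trial, 60 per session); inter-trial intervals of
#' 4 min on average (range 1.5-6.5 min).
#'
#' @param n_acq_sessions,n_ext_sessions Sessions per phase.
#' @param trials_per_session Trials per session.
#' @param cue_s Cue duration (s).
#' @param delivery_s,consumption_s Reward-cycle components (s).
#' @param reward_ul Reward volume per delivery (ul).
#' @param iti_mean_s,iti_range_s Inter-trial interval mean and range (s).
#' @return An object of class `task_config`.
#' @export
task_config <- function(n_acq_sessions = 11, n_ext_sessions = 6,
                        trials_per_session = 10, cue_s = 30,
                        delivery_s = 2, consumption_s = 3, reward_ul = 16.66,
                        iti_mean_s = 240, iti_range_s = c(90, 390)) {
  vals <- c(n_acq_sessions, n_ext_sessions, trials_per_session, cue_s,
            delivery_s, consumption_s, reward_ul, iti_mean_s)
  if (any(vals <= 0)) stop("task parameters must be positive", call. = FALSE)
  structure(list(n_acq_sessions = n_acq_sessions, n_ext_sessions = n_ext_sessions,
                 trials_per_session = trials_per_session, cue_s = cue_s,
                 delivery_s = delivery_s, consumption_s = consumption_s,
                 reward_ul = reward_ul, iti_mean_s = iti_mean_s,
                 iti_range_s = iti_range_s), class = "task_config")
}

#' Generate synthetic behavioral session series
#'
#' Rescorla-Wagner trajectories over the full task (acquisition then
#' extinction, one concatenated trial sequence), read out linearly onto the
#' supplied bounds, with additive Gaussian noise truncated to `[0, 100]`.
#' Latency is emitted as a decreasing function of the readout, capped at the
#' 30 s cue duration. Seed-deterministic.
#'
#' @param params An [rw_params()] object (generating learning rates).
#' @param bounds An [rw_bounds()] object (generating readout bounds).
#' @param noise_sd Noise standard deviation (% time in port units).
#' @param n_subjects Number of subjects to generate.
#' @param seed Master seed; subject `i` uses a derived counter seed.
#' @param task A [task_config()].
#' @return A list of [session_series()] data frames (one per subject, with a
#'   `subject` column and a `latency_s` column).
#' @export
generate_behavior_sessions <- function(params, bounds, noise_sd = 5,
                                       n_subjects = 1, seed = 1L,
                                       task = task_config()) {
  stopifnot(inherits(params, "rw_params"), inherits(bounds, "rw_bounds"))
  n_acq <- task$n_acq_sessions * task$trials_per_session
  n_ext <- task$n_ext_sessions * task$trials_per_session
  phase <- rep(c("acquisition", "extinction"), c(n_acq, n_ext))
  sched <- as.numeric(phase == "acquisition")
  span <- bounds$v_max - bounds$v_min
  v0 <- if (span > 0) min(max((bounds$v0 - bounds$v_min) / span, 0), 1) else 0
  traj <- simulate_trajectory(params, sched, v0)
  clean <- bounds$v_min + span * traj[seq_along(sched)]
  lapply(seq_len(n_subjects), function(subj) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(trial_seed(seed, subj))
    y <- pmin(pmax(clean + stats::rnorm(length(clean), 0, noise_sd), 0), 100)
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    session_series(data.frame(
      subject = subj,
      session = rep(seq_len(task$n_acq_sessions + task$n_ext_sessions),
                    each = task$trials_per_session),
      phase = phase,
      trial = rep(seq_len(task$trials_per_session),
                  task$n_acq_sessions + task$n_ext_sessions),
      pct_time_in_port = y,
      latency_s = task$cue_s * (1 - y / 100)))
  })
}

#' Agent port-occupancy policy
#'
#' @param type `"always"` (in port for the whole cue), `"never"`, or
#'   `"intervals"` (explicit occupancy intervals).
#' @param intervals For `type = "intervals"`: a two-column matrix of occupancy
#'   `start`, `end` times (s, within the cue), per trial (list of matrices) or
#'   shared by all trials (one matrix).
#' @return An object of class `agent_policy`.
#' @export
agent_policy <- function(type = c("always", "never", "intervals"),
                         intervals = NULL) {
  type <- match.arg(type)
  if (type == "intervals" && is.null(intervals)) {
    stop("intervals policy needs occupancy intervals", call. = FALSE)
  }
  structure(list(type = type, intervals = intervals), class = "agent_policy")
}

# occupancy intervals (matrix start,end) for one trial under a policy
policy_intervals <- function(policy, cue_s, trial) {
  switch(policy$type,
         always = matrix(c(0, cue_s), ncol = 2),
         never = matrix(numeric(0), ncol = 2),
         intervals = {
           iv <- policy$intervals
           if (is.list(iv)) iv[[trial]] else iv
         })
}

covered <- function(intervals, from, to) {
  any(intervals[, 1] <= from & intervals[, 2] >= to)
}

#' Simulate reward earnings in one conditioning session
#'
#' Rewards are delivered in cycles of `delivery_s` delivery plus
#' `consumption_s` consumption. A delivery starts when the head is in the port
#' and the cycle clock allows it; a reward is counted when the full delivery
#' window is covered by continuous occupancy (consumption does not require
#' occupancy). With a 30 s cue and a 5 s cycle this yields at most 6 rewards
#' per trial and 60 per 10-trial session.
#'
#' @param config A [task_config()].
#' @param policy An [agent_policy()].
#' @return A list: `rewards_per_trial` (integer vector), `total`,
#'   `volume_ul`.
#' @export
simulate_reward_session <- function(config, policy) {
  stopifnot(inherits(config, "task_config"), inherits(policy, "agent_policy"))
  per_trial <- vapply(seq_len(config$trials_per_session), function(tr) {
    iv <- policy_intervals(policy, config$cue_s, tr)
    if (!nrow(iv)) return(0L)
    n <- 0L
    t_avail <- 0 # earliest time the next delivery may start
    repeat {
      # next delivery start: first occupied moment at/after t_avail
      starts <- pmax(iv[, 1], t_avail)
      ok <- starts < iv[, 2]
      if (!any(ok)) break
      t0 <- min(starts[ok])
      if (t0 + config$delivery_s > config$cue_s) break
      if (covered(iv, t0, t0 + config$delivery_s)) {
        n <- n + 1L
        t_avail <- t0 + config$delivery_s + config$consumption_s
      } else {
        # left the port mid-delivery: no reward, retry at next occupancy
        nxt <- iv[iv[, 1] > t0, 1]
        if (!length(nxt)) break
        t_avail <- min(nxt)
      }
    }
    n
  }, integer(1))
  list(rewards_per_trial = per_trial, total = sum(per_trial),
       volume_ul = sum(per_trial) * config$reward_ul)
}

#' Plus-maze configuration for spontaneous alternation
#'
#' @param arms Number of maze arms.
#' @param window Consecutive entries per alternation window.
#' @param no_immediate_reentry Forbid re-entering the arm just exited.
#' @return An object of class `maze_config`.
#' @export
maze_config <- function(arms = 4, window = 5, no_immediate_reentry = TRUE) {
  if (arms < 2 || window < 1) stop("invalid maze configuration", call. = FALSE)
  structure(list(arms = arms, window = window,
                 no_immediate_reentry = no_immediate_reentry),
            class = "maze_config")
}

#' Chance level of spontaneous alternation (exact enumeration)
#'
#' Probability, under a null model of uniform choice among the admissible next
#' arms, that a window of `window` consecutive entries visits all `arms` arms.
#' With 4 arms, a window of 5 and no immediate re-entry there are
#' 4 x 3^4 = 324 equiprobable sequences of which 144 are alternations:
#' 144/324 = 4/9, the 44% chance level.
#'
#' @param config A [maze_config()].
#' @return A list: `probability`, `n_favorable`, `n_total`.
#' @export
alternation_chance <- function(config = maze_config()) {
  stopifnot(inherits(config, "maze_config"))
  if (config$window < config$arms) {
    return(list(probability = 0, n_favorable = 0L,
                n_total = NA_integer_))
  }
  seqs <- matrix(seq_len(config$arms), ncol = 1)
  for (step in seq_len(config$window - 1)) {
    seqs <- do.call(rbind, lapply(seq_len(config$arms), function(a) {
      keep <- if (config$no_immediate_reentry) seqs[, ncol(seqs)] != a else
        rep(TRUE, nrow(seqs))
      if (!any(keep)) return(NULL)
      cbind(seqs[keep, , drop = FALSE], a)
    }))
  }
  fav <- sum(apply(seqs, 1, function(s) length(unique(s)) == config$arms))
  list(probability = fav / nrow(seqs), n_favorable = fav, n_total = nrow(seqs))
}

#' Monte-Carlo spontaneous-alternation simulator
#'
#' Draws independent entry windows under the same null model as
#' [alternation_chance()] and returns the fraction that visit all arms;
#' converges to the exact enumeration.
#'
#' @param config A [maze_config()].
#' @param n_draws Number of independent windows.
#' @param seed Integer seed.
#' @return Estimated alternation probability.
#' @export
alternation_simulate <- function(config = maze_config(), n_draws = 1e5,
                                 seed = 1L) {
  stopifnot(inherits(config, "maze_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  hits <- 0L
  for (i in seq_len(n_draws)) {
    s <- integer(config$window)
    s[1] <- sample.int(config$arms, 1)
    for (k in 2:config$window) {
      choices <- if (config$no_immediate_reentry)
        setdiff(seq_len(config$arms), s[k - 1]) else seq_len(config$arms)
      s[k] <- choices[sample.int(length(choices), 1)]
    }
    if (length(unique(s)) == config$arms) hits <- hits + 1L
  }
  hits / n_draws
}

#' Novel-object discrimination index
#'
#' `DI = (t_new - t_old) / (t_new + t_old)`, in `[-1, 1]`.
#'
#' @param t_new Time exploring the novel object (s).
#' @param t_old Time exploring the familiar object (s).
#' @return Discrimination index.
#' @export
discrimination_index <- function(t_new, t_old) {
  if (any(c(t_new, t_old) < 0)) stop("exploration times must be >= 0", call. = FALSE)
  if (t_new + t_old == 0) {
    stop("discrimination index undefined: no exploration", call. = FALSE)
  }
  (t_new - t_old) / (t_new + t_old)
}

#' Synthetic minimum-voltage / rebound-delay dataset
#'
#' Generates a synthetic cloud of (minimum voltage, rebound delay) points from
#' a linear relationship plus Gaussian noise — emulating per-sweep in vitro
#' measurements — for exercising [fit_vmin_regression()]. The default slope is
#' the control-group value (-3.542e-2 s/mV).
#'
#' @param n Number of sweeps.
#' @param slope Delay-vs-voltage slope (s/mV).
#' @param intercept Intercept (s).
#' @param vmin_range Range of minimum voltages (mV).
#' @param noise_sd Noise on the delay (s).
#' @param seed Integer seed.
#' @return A data frame: `vmin_mv`, `delay_s`.
#' @export
generate_vmin_delay_data <- function(n = 80, slope = -3.542e-2,
                                     intercept = -1.2,
                                     vmin_range = c(-95, -55), noise_sd = 0.3,
                                     seed = 1L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  v <- stats::runif(n, vmin_range[1], vmin_range[2])
  d <- intercept + slope * v + stats::rnorm(n, 0, noise_sd)
  data.frame(vmin_mv = v, delay_s = pmax(d, 0))
}

#' Simulated rebound sweep tables with measurement noise
#'
#' Runs depth and/or duration sweeps for a pair of models and adds Gaussian
#' measurement noise to the delays, producing tidy tables in the sweep schema
#' (optionally written to CSV). Seed-deterministic.
#'
#' @param models Named list of [neuron_model()] objects.
#' @param vmin_grid Depth grid (mV), or `NULL` to skip.
#' @param duration_grid Duration grid (ms), or `NULL` to skip.
#' @param noise_sd Measurement noise on delays (ms).
#' @param seed Integer seed.
#' @param dir Optional output directory for CSV files.
#' @param ... Passed to [sweep_depth()] / [sweep_duration()].
#' @return A data frame: sweep rows with `genotype`, `sweep` and noisy
#'   `delay_ms` (plus `delay_true_ms`).
#' @export
generate_rebound_dataset <- function(models, vmin_grid = NULL,
                                     duration_grid = NULL, noise_sd = 50,
                                     seed = 1L, dir = NULL, ...) {
  stopifnot(is.list(models), !is.null(names(models)))
  rows <- list()
  for (g in names(models)) {
    if (!is.null(vmin_grid)) {
      s <- sweep_depth(models[[g]], vmin_grid, ...)
      s$sweep <- "depth"; s$genotype <- g
      rows[[length(rows) + 1]] <- s
    }
    if (!is.null(duration_grid)) {
      s <- sweep_duration(models[[g]], duration_grid, ...)
      s$sweep <- "duration"; s$genotype <- g
      rows[[length(rows) + 1]] <- s
    }
  }
  out <- do.call(rbind, rows)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  out$delay_true_ms <- out$delay_ms
  out$delay_ms <- pmax(out$delay_ms + stats::rnorm(nrow(out), 0, noise_sd), 0)
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(out, file.path(dir, "rebound_sweeps.csv"), row.names = FALSE)
  }
  out
}
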
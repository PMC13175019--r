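#' Homogeneous Poisson event train
#'
#' @param rate Event rate (Hz), >= 0.
#' @param duration Window (ms).
#' @param seed Optional integer seed (local RNG state, restored on exit).
#' @return Sorted event times (ms) in `[0, duration]`.
#' @export
poisson_train <- function(rate, duration, seed = NULL) {
  if (rate < 0) stop("rate must be >= 0", call. = FALSE)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  n <- stats::rpois(1, rate * duration / 1000)
  sort(stats::runif(n, 0, duration))
}

#' Balanced-state configuration
#'
#' Tonic excitation and inhibition: independent 100 Hz Poisson streams of
#' glutamatergic events (each driving simultaneous AMPA and NMDA conductances
#' with a 0.3 : 0.7 peak-conductance split) and GABA-A events. Synaptic
#' weights are constant within a trial; the glutamate and GABA scale factors
#' are varied in concert (e.g. 125%/75% to 75%/125%) to span the in-vivo
#' firing range. The unit peak conductances are calibrated so that GABA alone
#' silences the cell and the default balanced state fires in the in-vivo
#' range.
#'
#' @param rate_hz Poisson event rate per stream (Hz).
#' @param ampa_frac,nmda_frac AMPA/NMDA split of the glutamate peak
#'   conductance; must sum to 1.
#' @param w_glut,w_gaba Unit peak conductances (nS) at 100% scale.
#' @param glut_scale,gaba_scale Scale factors (1 = 100%).
#' @param trial_ms Trial duration after the refractory period (ms).
#' @param refractory_ms Intertrial refractory period (ms) simulated and
#'   discarded to eliminate transients.
#' @param dt Integration step (ms).
#' @return An object of class `balanced_config`.
#' @export
balanced_config <- function(rate_hz = 100, ampa_frac = 0.3, nmda_frac = 0.7,
                            w_glut = 0.12, w_gaba = 1.6,
                            glut_scale = 1, gaba_scale = 1,
                            trial_ms = 2500, refractory_ms = 4000,
                            dt = 0.025) {
  if (rate_hz < 0) stop("rate must be >= 0", call. = FALSE)
  if (abs(ampa_frac + nmda_frac - 1) > 1e-9) {
    stop("AMPA and NMDA fractions must sum to 1", call. = FALSE)
  }
  if (glut_scale < 0 || gaba_scale < 0) stop("scale factors must be >= 0", call. = FALSE)
  structure(list(rate_hz = rate_hz, ampa_frac = ampa_frac, nmda_frac = nmda_frac,
                 w_glut = w_glut, w_gaba = w_gaba,
                 glut_scale = glut_scale, gaba_scale = gaba_scale,
                 trial_ms = trial_ms, refractory_ms = refractory_ms, dt = dt),
            class = "balanced_config")
}

#' Correlated inhibitory train configuration
#'
#' A phasic burst of temporally correlated GABA-A inputs superimposed on the
#' balanced state: `n_inputs` synapses activated synchronously by a single
#' within-train Poisson process (default 100 Hz for 250 ms).
#'
#' @param n_inputs Number of synchronous GABA-A inputs.
#' @param rate_hz Within-train event rate (Hz).
#' @param train_ms Train duration (ms).
#' @param onset_ms Train onset, relative to trial start (ms).
#' @return An object of class `inhibition_config`.
#' @export
inhibition_config <- function(n_inputs = 20, rate_hz = 100, train_ms = 250,
                              onset_ms = 1250) {
  if (any(c(n_inputs, rate_hz, train_ms) <= 0) || onset_ms < 0) {
    stop("inhibition parameters must be positive", call. = FALSE)
  }
  structure(list(n_inputs = n_inputs, rate_hz = rate_hz, train_ms = train_ms,
                 onset_ms = onset_ms), class = "inhibition_config")
}

# Stated counter scheme for per-trial seeds: deterministic, order-independent.
trial_seed <- function(master_seed, counter) {
  as.integer((as.numeric(master_seed) + 104729 * as.numeric(counter)) %% 2147483647L)
}

#' Run one balanced-state trial
#'
#' Simulates the refractory period plus one trial of Poisson bombardment.
#' Every glutamate event drives both AMPA and NMDA conductances; GABA-A events
#' form an independent stream; an optional correlated inhibitory train is
#' superimposed at its onset. Deterministic given the seed. Spike times are
#' reported relative to trial start (refractory period discarded).
#'
#' @param model A [neuron_model()].
#' @param config A [balanced_config()].
#' @param inhibition Optional [inhibition_config()].
#' @param seed Integer seed for the trial's event trains.
#' @param record_trace Keep the voltage trace.
#' @return A list of class `balanced_trial`: `spikes` (a [spike_train()], times
#'   relative to trial start), `trace` (a [voltage_trace()] or `NULL`),
#'   `mean_rate_hz`, `seed`.
#' @export
run_balanced_trial <- function(model, config, inhibition = NULL, seed = 1L,
                               record_trace = FALSE) {
  stopifnot(inherits(model, "neuron_model"), inherits(config, "balanced_config"))
  total <- config$refractory_ms + config$trial_ms
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  glut_t <- poisson_train(config$rate_hz, total)
  gaba_t <- poisson_train(config$rate_hz, total)
  inh <- list(t = numeric(0), w = numeric(0))
  if (!is.null(inhibition)) {
    stopifnot(inherits(inhibition, "inhibition_config"))
    tt <- poisson_train(inhibition$rate_hz, inhibition$train_ms) +
      config$refractory_ms + inhibition$onset_ms
    inh <- list(t = tt, w = rep(inhibition$n_inputs * config$w_gaba, length(tt)))
  }
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  wg <- config$w_glut * config$glut_scale
  syn <- list(
    ampa = list(t = glut_t, w = rep(config$ampa_frac * wg, length(glut_t))),
    nmda = list(t = glut_t, w = rep(config$nmda_frac * wg, length(glut_t))),
    gaba = list(t = sort(c(gaba_t, inh$t)),
                w = c(rep(config$w_gaba * config$gaba_scale, length(gaba_t)),
                      inh$w)[order(c(gaba_t, inh$t))]))
  res <- simulate_neuron(model, duration = total, synapses = syn,
                         dt = config$dt, record_trace = record_trace,
                         record_stride = 40L)
  sp <- res$spikes$times - config$refractory_ms
  sp <- sp[sp >= 0]
  structure(list(
    spikes = spike_train(sp, config$trial_ms),
    trace = res$trace,
    mean_rate_hz = 1000 * length(sp) / config$trial_ms,
    seed = seed), class = "balanced_trial")
}

#' Run an ensemble of balanced-state trials
#'
#' Repeated single-neuron trials with per-trial seeds derived from a master
#' seed by a counter scheme (`seed_i = (master + 104729 * i) mod (2^31 - 1)`),
#' so results are independent of execution order. Recombined across trials the
#' ensemble stands in for a population response under an ergodic
#' approximation.
#'
#' @param model A [neuron_model()].
#' @param config A [balanced_config()].
#' @param inhibition Optional [inhibition_config()].
#' @param n_trials Number of trials (500 for full histograms).
#' @param master_seed Master seed.
#' @return An object of class `trial_ensemble`: `trains` (list of
#'   [spike_train()]), `seeds`, `config`, `inhibition`.
#' @export
run_trial_ensemble <- function(model, config, inhibition = NULL,
                               n_trials = 500, master_seed = 1L) {
  seeds <- vapply(seq_len(n_trials), function(i) trial_seed(master_seed, i),
                  integer(1))
  trains <- lapply(seeds, function(s) {
    run_balanced_trial(model, config, inhibition, seed = s)$spikes
  })
  structure(list(trains = trains, seeds = seeds, config = config,
                 inhibition = inhibition), class = "trial_ensemble")
}

#' Peristimulus time histogram
#'
#' Per-bin firing rate, `count / (n_trials * bin_width)`, in Hz.
#'
#' @param ensemble A [trial_ensemble()] (or a list of [spike_train()]).
#' @param bin_ms Bin width (ms), default 25.
#' @return An object of class `psth`: `breaks_ms` (bin edges), `rate_hz`,
#'   `n_trials`, `bin_ms`.
#' @export
build_psth <- function(ensemble, bin_ms = 25) {
  if (bin_ms <= 0) stop("bin width must be > 0", call. = FALSE)
  trains <- if (inherits(ensemble, "trial_ensemble")) ensemble$trains else ensemble
  if (length(trains) < 1) stop("need at least one trial", call. = FALSE)
  dur <- trains[[1]]$duration
  breaks <- seq(0, dur, by = bin_ms)
  if (breaks[length(breaks)] < dur) breaks <- c(breaks, breaks[length(breaks)] + bin_ms)
  all_sp <- unlist(lapply(trains, `[[`, "times"))
  counts <- if (length(all_sp)) {
    graphics::hist(all_sp, breaks = breaks, plot = FALSE, right = FALSE)$counts
  } else rep(0, length(breaks) - 1)
  structure(list(breaks_ms = breaks,
                 rate_hz = 1000 * counts / (length(trains) * bin_ms),
                 n_trials = length(trains), bin_ms = bin_ms), class = "psth")
}

#' Percentage of spikes lost after an inhibitory event
#'
#' `100 * (expected - observed) / expected`, where `expected` is the baseline
#' rate (mean PSTH rate over the baseline window) times the response-window
#' duration, and `observed` is the spike count in the response window.
#' Negative values indicate a rate increase. Default windows: baseline is the
#' 1 s ending at inhibition onset, response the 1 s starting at onset.
#'
#' @param psth A [psth()][build_psth] object.
#' @param baseline Baseline window `c(from, to)` (ms).
#' @param response Response window `c(from, to)` (ms).
#' @return Percentage (may be negative).
#' @export
percent_spikes_lost <- function(psth, baseline, response) {
  stopifnot(inherits(psth, "psth"))
  span <- range(psth$breaks_ms)
  if (baseline[1] < span[1] || response[2] > span[2] || baseline[2] <= baseline[1] ||
      response[2] <= response[1]) {
    stop("windows must be ordered and lie within the PSTH span", call. = FALSE)
  }
  mids <- psth$breaks_ms[-length(psth$breaks_ms)] + psth$bin_ms / 2
  in_base <- mids > baseline[1] & mids < baseline[2]
  in_resp <- mids > response[1] & mids < response[2]
  base_rate <- mean(psth$rate_hz[in_base])
  if (base_rate <= 0) stop("baseline rate is zero; statistic undefined", call. = FALSE)
  expected <- base_rate * (response[2] - response[1]) / 1000
  observed <- sum(psth$rate_hz[in_resp]) * psth$bin_ms / 1000
  100 * (expected - observed) / expected
}

#' Sweep excitation/inhibition ratios and inhibitory input counts
#'
#' For every combination of (glutamate scale, GABA scale) — varied in concert
#' in the source protocol, e.g. 125%/75% to 75%/125%, spanning conductance
#' ratios 0.6 to 1.67 — and correlated inhibitory input count, runs matched
#' trial ensembles for a pair of models (same per-trial seeds for both) and
#' computes the percent-spikes-lost statistic and mean firing rate, plus the
#' between-model difference map.
#'
#' @param models Named list of two [neuron_model()] objects (e.g.
#'   `list(ctrl = ..., ex3d = ...)`).
#' @param scale_pairs Data frame with columns `glut_scale`, `gaba_scale`.
#' @param n_inputs_grid Correlated inhibitory input counts.
#' @param n_trials Trials per grid cell per model.
#' @param master_seed Master seed; per-cell, per-trial seeds derive from it.
#' @param config Base [balanced_config()] (scales are overridden per cell).
#' @param inhibition Base [inhibition_config()] (`n_inputs` overridden).
#' @param baseline,response Windows for [percent_spikes_lost()], relative to
#'   trial start (ms); defaults are the 1 s before and after onset.
#' @return A list with `grid` (data frame: `glut_scale`, `gaba_scale`,
#'   `n_inputs`, `genotype`, `pct_spikes_lost`, `mean_rate_hz`) and `diff`
#'   (data frame of first-minus-second model differences per cell).
#' @export
sweep_ei_ratio <- function(models, scale_pairs, n_inputs_grid = c(10, 20),
                           n_trials = 100, master_seed = 1L,
                           config = balanced_config(),
                           inhibition = inhibition_config(),
                           baseline = NULL, response = NULL) {
  stopifnot(is.list(models), length(models) == 2, !is.null(names(models)))
  if (is.null(baseline)) baseline <- c(inhibition$onset_ms - 1000, inhibition$onset_ms)
  if (is.null(response)) response <- c(inhibition$onset_ms, inhibition$onset_ms + 1000)
  cells <- expand.grid(pair = seq_len(nrow(scale_pairs)),
                       n_inputs = n_inputs_grid)
  rows <- list()
  for (ci in seq_len(nrow(cells))) {
    pr <- cells$pair[ci]
    cfg <- config
    cfg$glut_scale <- scale_pairs$glut_scale[pr]
    cfg$gaba_scale <- scale_pairs$gaba_scale[pr]
    inh <- inhibition
    inh$n_inputs <- cells$n_inputs[ci]
    cell_seed <- trial_seed(master_seed, 7919L * ci)
    for (gi in seq_along(models)) {
      ens <- run_trial_ensemble(models[[gi]], cfg, inh, n_trials, cell_seed)
      ps <- build_psth(ens)
      rows[[length(rows) + 1]] <- data.frame(
        glut_scale = cfg$glut_scale, gaba_scale = cfg$gaba_scale,
        n_inputs = inh$n_inputs, genotype = names(models)[gi],
        pct_spikes_lost = percent_spikes_lost(ps, baseline, response),
        mean_rate_hz = mean(vapply(ens$trains, function(s)
          1000 * length(s$times) / s$duration, numeric(1))))
    }
  }
  grid <- do.call(rbind, rows)
  g1 <- grid[grid$genotype == names(models)[1], ]
  g2 <- grid[grid$genotype == names(models)[2], ]
  key <- c("glut_scale", "gaba_scale", "n_inputs")
  m <- merge(g1, g2, by = key, suffixes = c("_1", "_2"))
  diff <- data.frame(m[key],
                     d_pct_spikes_lost = m$pct_spikes_lost_1 - m$pct_spikes_lost_2,
                     d_mean_rate_hz = m$mean_rate_hz_1 - m$mean_rate_hz_2)
  list(grid = grid, diff = diff)
}
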
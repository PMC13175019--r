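#' Hyperpolarizing step protocol
#'
#' Describes a pre-step baseline, one hyperpolarizing current step (given
#' either as an amplitude or as a target minimum voltage to be reached by
#' [calibrate_step_current()]), and a post-step observation window.
#'
#' @param baseline_ms Pre-step baseline (ms); long enough for the pacemaker to
#'   settle onto its limit cycle.
#' @param step_ms Step duration (ms).
#' @param amp_pa Step amplitude (pA, <= 0). Exactly one of `amp_pa` /
#'   `target_vmin_mv` must be given.
#' @param target_vmin_mv Target minimum voltage (mV) during the step.
#' @param window_ms Post-step observation window (ms).
#' @return An object of class `step_protocol`.
#' @export
step_protocol <- function(baseline_ms = 4000, step_ms = 1000,
                          amp_pa = NULL, target_vmin_mv = NULL,
                          window_ms = 15000) {
  if (baseline_ms <= 0 || step_ms <= 0 || window_ms <= 0) {
    stop("durations must be positive", call. = FALSE)
  }
  if (is.null(amp_pa) == is.null(target_vmin_mv)) {
    stop("specify exactly one of amp_pa or target_vmin_mv", call. = FALSE)
  }
  if (!is.null(amp_pa) && amp_pa > 0) stop("amp_pa must be <= 0", call. = FALSE)
  structure(list(baseline_ms = baseline_ms, step_ms = step_ms,
                 amp_pa = amp_pa, target_vmin_mv = target_vmin_mv,
                 window_ms = window_ms), class = "step_protocol")
}

#' Calibrate a step amplitude to reach a target minimum voltage
#'
#' Bisection on the (negative) step amplitude until the minimum membrane
#' voltage during the step is within `tol` of `target_vmin`. Deterministic.
#'
#' @param model A [neuron_model()].
#' @param target_vmin Target minimum voltage (mV); must lie below the
#'   spontaneous trajectory minimum.
#' @param duration Step duration (ms).
#' @param baseline_ms Pre-step settling time (ms).
#' @param tol Tolerance on the minimum voltage (mV), default 0.5.
#' @param amp_bounds Search bounds on the amplitude (pA).
#' @param dt Integration step (ms).
#' @return Step amplitude (pA, negative).
#' @export
calibrate_step_current <- function(model, target_vmin, duration,
                                   baseline_ms = 4000, tol = 0.5,
                                   amp_bounds = c(-400, 0), dt = 0.025) {
  stopifnot(inherits(model, "neuron_model"))
  base <- simulate_neuron(model, duration = baseline_ms + duration,
                          record_trace = FALSE, dt = dt)
  # v_min of the unperturbed run bounds what counts as "below baseline"
  if (target_vmin >= base$v_min) {
    stop("target_vmin must lie below the spontaneous trajectory minimum (",
         round(base$v_min, 1), " mV)", call. = FALSE)
  }
  step_min <- function(amp) {
    # an amplitude strong enough to blow past the integration guard rails
    # simply overshoots the target
    tryCatch({
      st <- data.frame(t_on = baseline_ms, t_off = baseline_ms + duration, amp = amp)
      res <- simulate_neuron(model, duration = baseline_ms + duration, stimulus = st,
                             record_trace = TRUE, record_stride = 40L, dt = dt)
      tr <- res$trace
      min(tr$v_mv[tr$time_ms >= baseline_ms])
    }, error = function(e) -Inf)
  }
  lo <- max(amp_bounds)  # weakest (0)
  hi <- min(amp_bounds)  # strongest (most negative)
  if (step_min(hi) > target_vmin) {
    stop("calibration failure: target ", target_vmin,
         " mV unreachable within amplitude bounds", call. = FALSE)
  }
  for (i in seq_len(40)) {
    mid <- (lo + hi) / 2
    mv <- step_min(mid)
    if (abs(mv - target_vmin) < tol) return(mid)
    if (mv > target_vmin) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Measure the post-inhibitory rebound delay
#'
#' Simulates baseline pacemaking, one hyperpolarizing step, and an observation
#' window; the rebound delay is the time from step offset to the first
#' detected spike. Trials with no rebound spike within the window are reported
#' censored at the window length, never dropped. An interspike-interval
#' corrected variant (delay minus the mean baseline ISI) is also reported.
#'
#' @param model A [neuron_model()].
#' @param protocol A [step_protocol()].
#' @param dt Integration step (ms).
#' @return An object of class `rebound_result`: a list with `v_min` (minimum
#'   voltage during the step, mV), `delay_ms`, `first_spike_ms`,
#'   `censored` (logical), `amp_pa`, `baseline_isi_ms` and
#'   `delay_isi_corrected_ms`.
#' @export
measure_rebound_delay <- function(model, protocol, dt = 0.025) {
  stopifnot(inherits(model, "neuron_model"), inherits(protocol, "step_protocol"))
  amp <- protocol$amp_pa
  if (is.null(amp)) {
    amp <- calibrate_step_current(model, protocol$target_vmin_mv,
                                  protocol$step_ms, protocol$baseline_ms, dt = dt)
  }
  t_on <- protocol$baseline_ms
  t_off <- t_on + protocol$step_ms
  total <- t_off + protocol$window_ms
  st <- data.frame(t_on = t_on, t_off = t_off, amp = amp)
  res <- simulate_neuron(model, duration = total, stimulus = st,
                         record_trace = TRUE, record_stride = 40L, dt = dt)
  tr <- res$trace
  v_min <- min(tr$v_mv[tr$time_ms >= t_on & tr$time_ms < t_off + 1])
  sp <- res$spikes$times
  base_sp <- sp[sp < t_on]
  baseline_isi <- if (length(base_sp) > 1) mean(diff(base_sp)) else NA_real_
  post <- sp[sp > t_off]
  censored <- length(post) == 0
  first <- if (censored) NA_real_ else post[1]
  delay <- if (censored) protocol$window_ms else first - t_off
  structure(list(v_min = v_min, delay_ms = delay, first_spike_ms = first,
                 censored = censored, amp_pa = amp,
                 baseline_isi_ms = baseline_isi,
                 delay_isi_corrected_ms = delay - baseline_isi),
            class = "rebound_result")
}

#' Rebound-delay sweep over hyperpolarization depth
#'
#' One rebound measurement per target minimum voltage, at fixed step duration;
#' the step amplitude is recalibrated for each depth.
#'
#' @param model A [neuron_model()].
#' @param vmin_grid Target minimum voltages (mV), sorted (any direction).
#' @param duration Step duration (ms); the depth sweep in the source protocol
#'   uses 2 s steps.
#' @param window_ms Post-step observation window (ms).
#' @param dt Integration step (ms).
#' @return A data frame: `depth_mv`, `duration_ms`, `amp_pa`, `delay_ms`,
#'   `censored`.
#' @export
sweep_depth <- function(model, vmin_grid, duration = 2000, window_ms = 15000,
                        dt = 0.025) {
  if (is.unsorted(vmin_grid) && is.unsorted(rev(vmin_grid))) {
    stop("vmin_grid must be sorted", call. = FALSE)
  }
  rows <- lapply(vmin_grid, function(v) {
    pr <- step_protocol(step_ms = duration, target_vmin_mv = v,
                        window_ms = window_ms)
    r <- measure_rebound_delay(model, pr, dt = dt)
    data.frame(depth_mv = v, duration_ms = duration, amp_pa = r$amp_pa,
               delay_ms = r$delay_ms, censored = r$censored)
  })
  do.call(rbind, rows)
}

#' Rebound-delay sweep over step duration
#'
#' The amplitude is calibrated once — the value required to bring the minimum
#' voltage to `target_vmin` for the longest duration in the grid — and then
#' held constant across all durations, as in the source protocol.
#'
#' @param model A [neuron_model()].
#' @param duration_grid Step durations (ms).
#' @param target_vmin Calibration target (mV), default -80.
#' @param window_ms Post-step observation window (ms).
#' @param dt Integration step (ms).
#' @return A data frame: `depth_mv` (calibration target), `duration_ms`,
#'   `amp_pa`, `delay_ms`, `censored`.
#' @export
sweep_duration <- function(model, duration_grid, target_vmin = -80,
                           window_ms = 15000, dt = 0.025) {
  amp <- calibrate_step_current(model, target_vmin, max(duration_grid), dt = dt)
  rows <- lapply(duration_grid, function(d) {
    pr <- step_protocol(step_ms = d, amp_pa = amp, window_ms = window_ms)
    r <- measure_rebound_delay(model, pr, dt = dt)
    data.frame(depth_mv = target_vmin, duration_ms = d, amp_pa = amp,
               delay_ms = r$delay_ms, censored = r$censored)
  })
  do.call(rbind, rows)
}

#' Boltzmann fit of the duration-delay relationship
#'
#' Least-squares fit of `delay(d) = max / (1 + exp((half - d) / slope))`, a
#' Boltzmann sigmoid rising from 0, to rebound delays measured over a grid of
#' inhibitory pulse durations.
#'
#' @param durations Pulse durations (ms), at least 4.
#' @param delays Rebound delays (ms).
#' @return An object of class `boltzmann_fit`: `max_delay_ms`,
#'   `half_duration_ms`, `slope_ms`, `rss`, `converged`, `degenerate`.
#' @export
fit_rebound_boltzmann <- function(durations, delays) {
  if (length(durations) < 4 || length(durations) != length(delays)) {
    stop("need >= 4 matched points", call. = FALSE)
  }
  if (stats::sd(delays) < 1e-12 * max(abs(delays), 1)) {
    return(structure(list(max_delay_ms = mean(delays), half_duration_ms = NA_real_,
                          slope_ms = NA_real_, rss = 0, converged = TRUE,
                          degenerate = TRUE), class = "boltzmann_fit"))
  }
  df <- data.frame(d = durations, y = delays)
  max0 <- max(delays)
  half0 <- stats::approx(delays, durations, xout = max0 / 2, ties = mean)$y
  if (!is.finite(half0)) half0 <- stats::median(durations)
  rng <- diff(range(durations))
  starts <- list(
    list(vmax = max0, half = half0, slope = rng / 8),
    list(vmax = max0, half = stats::median(durations), slope = rng / 4),
    list(vmax = 1.2 * max0, half = unname(stats::quantile(durations, 0.4)),
         slope = rng / 12))
  fit <- NULL
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ vmax / (1 + exp((half - d) / slope)), data = df,
                        start = s, lower = c(0, 0, 1e-6),
                        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) e)
    if (!inherits(fit, "error")) break
  }
  if (inherits(fit, "error")) {
    stop("Boltzmann fit failed to converge: ", conditionMessage(fit), call. = FALSE)
  }
  cf <- stats::coef(fit)
  structure(list(max_delay_ms = unname(cf["vmax"]),
                 half_duration_ms = unname(cf["half"]),
                 slope_ms = unname(cf["slope"]),
                 rss = sum(stats::resid(fit)^2),
                 converged = TRUE, degenerate = FALSE),
            class = "boltzmann_fit")
}

#' Linear regression of rebound delay on minimum voltage
#'
#' Ordinary least squares of delay against the minimum membrane voltage
#' reached during the inhibitory step. Units follow the inputs (e.g. slope in
#' s/mV when delays are given in seconds).
#'
#' @param vmins Minimum voltages (mV), non-constant, at least 3.
#' @param delays Rebound delays.
#' @return An object of class `regression_fit`: `slope`, `intercept`, `r2`,
#'   `slope_se`.
#' @export
fit_vmin_regression <- function(vmins, delays) {
  if (length(vmins) < 3 || length(vmins) != length(delays)) {
    stop("need >= 3 matched points", call. = FALSE)
  }
  if (stats::sd(vmins) == 0) stop("minimum voltages are constant", call. = FALSE)
  fit <- stats::lm(delays ~ vmins)
  sm <- suppressWarnings(summary(fit)) # exact inputs trip the perfect-fit warning
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r2 = sm$r.squared,
                 slope_se = sm$coefficients[2, 2]),
            class = "regression_fit")
}
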
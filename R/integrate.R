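#' Integrate the neuron model
#'
#' Fixed-step integration of the single-compartment model: exponential-Euler
#' relaxation for every gating variable and a forward update for the membrane
#' potential, at `dt = 0.025` ms by default. Deterministic for fixed inputs:
#' identical inputs and `dt` give bit-identical traces.
#'
#' @param model A [neuron_model()].
#' @param duration Simulated time (ms).
#' @param stimulus Injected-current steps: `NULL`, or a data frame / matrix
#'   with columns `t_on`, `t_off` (ms) and `amp` (pA); overlapping steps add.
#' @param initial A [neuron_state()]; default [initial_state()] at -55 mV.
#' @param dt Time step (ms).
#' @param synapses Internal: synaptic event streams, a list with elements
#'   `ampa`, `nmda`, `gaba`, each `list(t = times_ms, w = peak_nS)`.
#' @param threshold Spike threshold (mV) for online detection (strict upward
#'   crossing), default -20.
#' @param record_trace Keep the voltage trace (set `FALSE` for spike-only runs).
#' @param record_stride Store every `record_stride`-th sample of the trace.
#' @return A list of class `sim_result` with elements `trace` (a
#'   [voltage_trace()], or `NULL`), `spikes` (a [spike_train()]), `v_min`
#'   (minimum voltage reached, mV) and `final_state` (a [neuron_state()]).
#'   Numerical blow-up (non-finite state or |V| > 200 mV) raises an
#'   integration-failure error naming the offending time.
#' @export
#' @examples
#' m <- neuron_model()
#' res <- simulate_neuron(m, duration = 2000)
#' length(res$spikes$times) # spontaneous spikes in 2 s
simulate_neuron <- function(model, duration, stimulus = NULL, initial = NULL,
                            dt = 0.025, synapses = NULL, threshold = -20,
                            record_trace = TRUE, record_stride = 1L) {
  stopifnot(inherits(model, "neuron_model"))
  if (dt <= 0 || duration < dt) stop("need dt > 0 and duration >= dt", call. = FALSE)
  if (is.null(initial)) initial <- initial_state(model)
  stopifnot(inherits(initial, "neuron_state"))
  steps <- stimulus_matrix(stimulus)
  if (is.null(synapses)) synapses <- empty_synapses()
  syn <- lapply(synapses[c("ampa", "nmda", "gaba")], function(s) {
    list(t = as.numeric(s$t), w = as.numeric(s$w))
  })
  raw <- sim_neuron_cpp(model_to_cpp(model), duration, dt,
                        as.numeric(unclass(initial)), steps, syn, threshold,
                        record_trace, as.integer(record_stride))
  trace <- NULL
  if (record_trace) {
    trace <- voltage_trace(time_ms = raw$time, v_mv = raw$v, i_pa = raw$i_inj)
  }
  fs <- raw$final_state
  structure(list(
    trace = trace,
    spikes = spike_train(raw$spikes, raw$duration),
    v_min = raw$v_min,
    final_state = neuron_state(fs[["v"]], fs[["m"]], fs[["h"]], fs[["n"]],
                               fs[["a"]], fs[["hc"]], fs[["p"]], fs[["qs"]],
                               fs[["qf"]], fs[["ca"]])
  ), class = "sim_result")
}

empty_synapses <- function() {
  e <- list(t = numeric(0), w = numeric(0))
  list(ampa = e, nmda = e, gaba = e)
}

stimulus_matrix <- function(stimulus) {
  if (is.null(stimulus)) return(matrix(numeric(0), ncol = 3))
  stimulus <- as.data.frame(stimulus)
  if (!all(c("t_on", "t_off", "amp") %in% names(stimulus))) {
    stop("stimulus needs columns t_on, t_off, amp", call. = FALSE)
  }
  if (any(stimulus$t_off <= stimulus$t_on)) {
    stop("stimulus steps need t_off > t_on", call. = FALSE)
  }
  as.matrix(stimulus[, c("t_on", "t_off", "amp")])
}

#' Voltage trace container
#'
#' @param time_ms Uniform, strictly increasing time vector (ms).
#' @param v_mv Membrane potential (mV).
#' @param i_pa Injected current (pA).
#' @return A data frame of class `voltage_trace`.
#' @export
voltage_trace <- function(time_ms, v_mv, i_pa = rep(0, length(time_ms))) {
  if (length(time_ms) != length(v_mv) || length(time_ms) != length(i_pa)) {
    stop("time, voltage and current vectors must have equal length", call. = FALSE)
  }
  if (length(time_ms) > 1 && any(diff(time_ms) <= 0)) {
    stop("time must be strictly increasing", call. = FALSE)
  }
  structure(data.frame(time_ms = time_ms, v_mv = v_mv, i_pa = i_pa),
            class = c("voltage_trace", "data.frame"))
}

#' Spike train container
#'
#' @param times Ordered spike times (ms).
#' @param duration Trace duration (ms).
#' @return A list of class `spike_train`.
#' @export
spike_train <- function(times, duration) {
  times <- as.numeric(times)
  if (length(times) > 1 && any(diff(times) <= 0)) {
    stop("spike times must be strictly increasing", call. = FALSE)
  }
  if (length(times) && (min(times) < 0 || max(times) > duration)) {
    stop("spike times must lie within [0, duration]", call. = FALSE)
  }
  structure(list(times = times, duration = duration), class = "spike_train")
}

#' Detect spikes in a voltage trace
#'
#' A spike is a strict upward crossing of the threshold: `v[i] <= thr` and
#' `v[i+1] > thr`. A trace that only touches the threshold produces no spike.
#' Spike times are linearly interpolated between samples. Idempotent.
#'
#' @param trace A [voltage_trace()].
#' @param threshold Threshold (mV), default -20.
#' @return A [spike_train()].
#' @export
detect_spikes <- function(trace, threshold = -20) {
  stopifnot(inherits(trace, "voltage_trace"))
  n <- nrow(trace)
  if (n == 0) return(spike_train(numeric(0), 0))
  if (n > 1) {
    dtv <- diff(trace$time_ms)
    if (max(dtv) - min(dtv) > 1e-9 * max(dtv)) {
      stop("detect_spikes requires uniform sampling", call. = FALSE)
    }
  }
  v <- trace$v_mv
  idx <- which(v[-n] <= threshold & v[-1] > threshold)
  frac <- (threshold - v[idx]) / (v[idx + 1] - v[idx])
  times <- trace$time_ms[idx] + frac * (trace$time_ms[idx + 1] - trace$time_ms[idx])
  dur <- if (n > 1) trace$time_ms[n] else trace$time_ms[1]
  spike_train(times, dur)
}

#' Mean firing rate of a spike train
#'
#' @param spikes A [spike_train()].
#' @param from,to Window (ms); defaults to the whole train.
#' @return Rate in Hz.
#' @export
firing_rate <- function(spikes, from = 0, to = spikes$duration) {
  stopifnot(inherits(spikes, "spike_train"), to > from)
  n <- sum(spikes$times >= from & spikes$times < to)
  1000 * n / (to - from)
}
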
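#' Boltzmann steady-state activation/inactivation
#'
#' Steady-state value of a voltage-gated channel gate,
#' `1 / (1 + exp((v_half - v) / v_slope))`. The sign of `v_slope` carries the
#' orientation: positive slopes describe gates that open with depolarization
#' (activation), negative slopes gates that close with depolarization
#' (inactivation).
#'
#' @param v Membrane potential (mV). Vectorised.
#' @param params A [boltzmann_params()] object (fields `v_half`, `v_slope`).
#' @return Steady-state open fraction, strictly in (0, 1) for finite `v`.
#' @export
#' @examples
#' act <- boltzmann_params(v_half = -40.8, v_slope = 7.73)
#' boltzmann_ss(-40.8, act) # 0.5 at the half-activation voltage
boltzmann_ss <- function(v, params) {
  stopifnot(inherits(params, "boltzmann_params"))
  if (any(!is.finite(v))) stop("non-finite membrane potential", call. = FALSE)
  1 / (1 + exp((params$v_half - v) / params$v_slope))
}

#' Sigmoidal voltage-dependent time constant
#'
#' Time constant bounded between `tau_min` and `tau_max`, following a
#' Boltzmann sigmoid of voltage:
#' `tau_min + (tau_max - tau_min) / (1 + exp((v_half - v) / v_slope))`.
#' With positive `v_slope` the time constant increases with depolarization
#' (the convention used for Kv4.3 inactivation: slow open-state inactivation
#' at depolarized potentials, faster recovery when hyperpolarized).
#'
#' @param v Membrane potential (mV). Vectorised.
#' @param params A [tau_params()] object.
#' @return Time constant (ms), bounded in `[tau_min, tau_max]`.
#' @export
tau_sigmoid <- function(v, params) {
  stopifnot(inherits(params, "tau_params"))
  if (any(!is.finite(v))) stop("non-finite membrane potential", call. = FALSE)
  params$tau_min +
    (params$tau_max - params$tau_min) / (1 + exp((params$v_half - v) / params$v_slope))
}

#' Boltzmann steady-state parameters
#'
#' @param v_half Half-activation/inactivation voltage (mV).
#' @param v_slope Slope factor (mV); must be non-zero, sign sets orientation.
#' @return An object of class `boltzmann_params`.
#' @export
boltzmann_params <- function(v_half, v_slope) {
  if (!is.finite(v_half) || !is.finite(v_slope) || v_slope == 0) {
    stop("invalid Boltzmann parameters: v_slope must be finite and non-zero",
         call. = FALSE)
  }
  structure(list(v_half = v_half, v_slope = v_slope), class = "boltzmann_params")
}

#' Voltage-dependent time-constant parameters
#'
#' @param v_half,v_slope Midpoint and slope (mV) of the sigmoid.
#' @param tau_min,tau_max Bounds of the time constant (ms), `0 < tau_min <= tau_max`.
#' @return An object of class `tau_params`.
#' @export
tau_params <- function(v_half, v_slope, tau_min, tau_max) {
  if (!is.finite(v_half) || !is.finite(v_slope) || v_slope == 0) {
    stop("invalid tau parameters: v_slope must be finite and non-zero", call. = FALSE)
  }
  if (!(tau_min > 0 && tau_min <= tau_max)) {
    stop("invalid tau parameters: need 0 < tau_min <= tau_max", call. = FALSE)
  }
  structure(list(v_half = v_half, v_slope = v_slope,
                 tau_min = tau_min, tau_max = tau_max), class = "tau_params")
}

#' Kv4.3 channel parameters with dual additive inactivation
#'
#' The A-type current is modelled Hodgkin-Huxley style with a cubed activation
#' gate `p` and two independent inactivation gates sharing steady-state voltage
#' dependence but with distinct kinetics: a slow gate `q_s` (channels modulated
#' by the KChIP4a auxiliary subunit) and a fast gate `q_f` (all other
#' subunits). The fraction of slowly inactivating channels `f_s` is the single
#' parameter distinguishing the control genotype (`f_s = 0.56`) from
#' dopamine-neuron-specific KChIP4a deletion (`f_s = 0.22`).
#'
#' Defaults are the calibrated values for atypical, accumbens-core-projecting
#' dopamine neurons: activation V1/2 -40.8 mV (slope 7.73), inactivation V1/2
#' -68.0 mV (slope -6.44), slow inactivation tau bounded 20-250 ms, fast
#' 20-45 ms, both sigmoidal about -60 mV and increasing with depolarization.
#'
#' @param g_max Maximal conductance (nS).
#' @param f_s Fraction of slow (KChIP4a-bound) inactivation, in `[0, 1]`.
#' @param e_k Potassium reversal potential (mV), negative.
#' @param activation,inactivation [boltzmann_params()] for `p` and `q`.
#' @param tau_slow,tau_fast [tau_params()] for `q_s` and `q_f`.
#' @param activation_tau [tau_params()] for `p` (inherited from the base
#'   pacemaker model; identical for slow and fast channels).
#' @return An object of class `kv4_params`.
#' @export
kv4_params <- function(g_max = 200,
                       f_s = 0.56,
                       e_k = -90,
                       activation = boltzmann_params(-40.8, 7.73),
                       inactivation = boltzmann_params(-68.0, -6.44),
                       tau_slow = tau_params(-60, 5, 20, 250),
                       tau_fast = tau_params(-60, 4, 20, 45),
                       activation_tau = tau_params(-40.8, -10, 0.5, 2)) {
  if (!(f_s >= 0 && f_s <= 1)) stop("f_s must lie in [0, 1]", call. = FALSE)
  if (g_max < 0) stop("g_max must be non-negative", call. = FALSE)
  if (e_k >= 0) stop("e_k must be negative", call. = FALSE)
  stopifnot(inherits(activation, "boltzmann_params"),
            inherits(inactivation, "boltzmann_params"),
            inherits(tau_slow, "tau_params"),
            inherits(tau_fast, "tau_params"),
            inherits(activation_tau, "tau_params"))
  structure(list(g_max = g_max, f_s = f_s, e_k = e_k,
                 activation = activation, inactivation = inactivation,
                 tau_slow = tau_slow, tau_fast = tau_fast,
                 activation_tau = activation_tau),
            class = "kv4_params")
}

#' Instantaneous Kv4.3 current
#'
#' `I = g_max * p^3 * (f_s * q_s + (1 - f_s) * q_f) * (E_K - V)`.
#'
#' Sign convention (package-wide): currents are written as `g * (E - V)`, so a
#' positive value depolarizes the membrane; the Kv4.3 current is negative
#' (hyperpolarizing, i.e. outward) whenever `V > E_K`.
#'
#' @param v Membrane potential (mV).
#' @param p Activation gate value in `[0, 1]`.
#' @param q_s,q_f Slow and fast inactivation gate values in `[0, 1]`.
#' @param params A [kv4_params()] object.
#' @return Current (pA when `g_max` is in nS and voltages in mV).
#' @export
kv4_current <- function(v, p, q_s, q_f, params) {
  stopifnot(inherits(params, "kv4_params"))
  gates <- c(p, q_s, q_f)
  if (any(!is.finite(gates)) || any(gates < 0) || any(gates > 1)) {
    stop("gating variables must lie in [0, 1]", call. = FALSE)
  }
  params$g_max * p^3 * (params$f_s * q_s + (1 - params$f_s) * q_f) * (params$e_k - v)
}
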
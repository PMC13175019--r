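#' Single-compartment model of an atypical dopamine neuron
#'
#' A conductance-based pacemaker with transient sodium, delayed-rectifier
#' potassium, L-type calcium, calcium-activated SK potassium (fed by a single
#' intracellular calcium pool), HCN, leak, and the dual-inactivation Kv4.3
#' A-type current ([kv4_params()]). In the absence of injected current and
#' synaptic input the model fires spontaneously at ~3.4 Hz, matching
#' accumbens-core-projecting dopamine neurons; the Kv4.3 slow fraction `f_s`
#' is the only parameter that differs between the control and KChIP4a-deleted
#' configurations.
#'
#' Units are fixed package-wide: mV, ms, pA, nS, pF, uM. Currents follow the
#' `I = g (E - V)` convention (positive depolarizes).
#'
#' Every gate is described by a Boltzmann steady state and a sigmoidal
#' voltage-dependent time constant. Default base-model parameters are
#' calibrated so that (i) the spontaneous rate is ~3.4 Hz and (ii) a 1 s
#' hyperpolarizing step to -80 mV is followed by a rebound delay of ~1.9 s for
#' `f_s = 0.56` and ~0.97 s for `f_s = 0.22`.
#'
#' @param f_s Fraction of slow Kv4.3 inactivation; 0.56 for the control
#'   genotype, 0.22 for KChIP4a deletion. Forwarded to [kv4_params()] unless a
#'   full `kv4` object is supplied.
#' @param kv4 Optional [kv4_params()] object overriding `f_s`.
#' @param cm Membrane capacitance (pF).
#' @param g_leak,e_leak Leak conductance (nS) and reversal (mV).
#' @param g_na,e_na Transient sodium maximal conductance and reversal.
#' @param g_kdr Delayed-rectifier potassium conductance; shares `e_k`.
#' @param e_k Potassium reversal potential (mV).
#' @param g_cal,e_ca L-type calcium conductance and (ohmic) reversal.
#' @param g_sk,ks_sk SK conductance and calcium half-activation (uM).
#' @param g_hcn,e_hcn HCN conductance and reversal.
#' @param ca_rest,ca_tau,ca_in Calcium pool: resting level (uM), clearance
#'   time constant (ms), and influx per unit L-type current (uM/(pA ms)).
#'   NMDA calcium does not feed this pool.
#' @param na_m,na_h,kdr_n,cal_a,hcn_h Gate descriptions, each a list with a
#'   [boltzmann_params()] `ss` and [tau_params()] `tau`.
#' @param syn_kinetics Synaptic kinetics, see [synapse_kinetics()].
#' @return An object of class `neuron_model`.
#' @export
#' @examples
#' ctrl <- neuron_model(f_s = 0.56)
#' ex3d <- neuron_model(f_s = 0.22)
neuron_model <- function(f_s = 0.56,
                         kv4 = NULL,
                         cm = 60,
                         g_leak = 0.4, e_leak = -33.5,
                         g_na = 500, e_na = 60,
                         g_kdr = 120, e_k = -90,
                         g_cal = 2.6, e_ca = 60,
                         g_sk = 0.5, ks_sk = 0.25,
                         g_hcn = 0.6, e_hcn = -30,
                         ca_rest = 0.02, ca_tau = 100, ca_in = 3e-4,
                         na_m = gate(boltzmann_params(-34, 5),
                                     tau_params(-30, -8, 0.08, 0.4)),
                         na_h = gate(boltzmann_params(-48, -6),
                                     tau_params(-55, -5, 1, 8)),
                         kdr_n = gate(boltzmann_params(-25, 12),
                                      tau_params(-40, -10, 1, 6)),
                         cal_a = gate(boltzmann_params(-25, 4),
                                      tau_params(-45, -5, 0.5, 2)),
                         hcn_h = gate(boltzmann_params(-85, -7),
                                      tau_params(-85, 10, 80, 300)),
                         syn_kinetics = synapse_kinetics()) {
  if (is.null(kv4)) kv4 <- kv4_params(f_s = f_s)
  stopifnot(inherits(kv4, "kv4_params"))
  conds <- c(cm = cm, g_leak = g_leak, g_na = g_na, g_kdr = g_kdr,
             g_cal = g_cal, g_sk = g_sk, g_hcn = g_hcn)
  if (any(conds < 0)) stop("conductances and capacitance must be >= 0", call. = FALSE)
  structure(list(
    cm = cm,
    g_leak = g_leak, e_leak = e_leak,
    g_na = g_na, e_na = e_na,
    g_kdr = g_kdr, e_k = e_k,
    g_cal = g_cal, e_ca = e_ca,
    g_sk = g_sk, ks_sk = ks_sk,
    g_hcn = g_hcn, e_hcn = e_hcn,
    ca_rest = ca_rest, ca_tau = ca_tau, ca_in = ca_in,
    na_m = na_m, na_h = na_h, kdr_n = kdr_n, cal_a = cal_a, hcn_h = hcn_h,
    kv4 = kv4,
    syn_kinetics = syn_kinetics
  ), class = "neuron_model")
}

#' Gate description (steady state + kinetics)
#'
#' @param ss [boltzmann_params()] steady state.
#' @param tau [tau_params()] time constant.
#' @return A list of class `gate`.
#' @export
gate <- function(ss, tau) {
  stopifnot(inherits(ss, "boltzmann_params"), inherits(tau, "tau_params"))
  structure(list(ss = ss, tau = tau), class = "gate")
}

#' Synaptic receptor kinetics for the balanced state
#'
#' AMPA and GABA-A are peak-normalized biexponential conductances with a rise
#' time of 0.2 ms and fall times of 2.4 ms and 3 ms respectively. NMDA uses a
#' slower biexponential (2 ms rise, 100 ms decay) gated by a sigmoidal
#' voltage-dependent magnesium block at 1 mM Mg. Reversal potentials: 0 mV
#' for both glutamatergic receptors, -60 mV for GABA-A (chloride).
#'
#' @param ampa_rise,ampa_decay,nmda_rise,nmda_decay,gaba_rise,gaba_decay
#'   Rise and decay time constants (ms), rise < decay.
#' @param e_glut,e_gaba Reversal potentials (mV).
#' @param mg_mM Extracellular magnesium (mM) for the NMDA block.
#' @return A list of class `synapse_kinetics`.
#' @export
synapse_kinetics <- function(ampa_rise = 0.2, ampa_decay = 2.4,
                             nmda_rise = 2, nmda_decay = 100,
                             gaba_rise = 0.2, gaba_decay = 3,
                             e_glut = 0, e_gaba = -60, mg_mM = 1) {
  if (ampa_rise >= ampa_decay || nmda_rise >= nmda_decay || gaba_rise >= gaba_decay) {
    stop("synaptic rise time must be shorter than decay time", call. = FALSE)
  }
  structure(list(ampa_rise = ampa_rise, ampa_decay = ampa_decay,
                 nmda_rise = nmda_rise, nmda_decay = nmda_decay,
                 gaba_rise = gaba_rise, gaba_decay = gaba_decay,
                 e_glut = e_glut, e_gaba = e_gaba, mg_mM = mg_mM),
            class = "synapse_kinetics")
}

#' Neuron state vector
#'
#' @param v Membrane potential (mV).
#' @param m,h,n,a,hc,p,qs,qf Gating variables in `[0, 1]`.
#' @param ca Intracellular calcium (uM).
#' @return Named numeric vector of class `neuron_state`.
#' @export
neuron_state <- function(v, m, h, n, a, hc, p, qs, qf, ca) {
  gates <- c(m = m, h = h, n = n, a = a, hc = hc, p = p, qs = qs, qf = qf)
  if (any(gates < 0 | gates > 1)) stop("gating variables must lie in [0, 1]", call. = FALSE)
  if (!all(is.finite(c(v, gates, ca)))) stop("state must be finite", call. = FALSE)
  structure(c(v = v, gates, ca = ca), class = "neuron_state")
}

#' Steady-state initialisation at a holding voltage
#'
#' All gates are set to their steady-state value at `v`; calcium to its
#' resting level.
#'
#' @param model A [neuron_model()].
#' @param v Holding voltage (mV), default -55.
#' @return A [neuron_state()].
#' @export
initial_state <- function(model, v = -55) {
  stopifnot(inherits(model, "neuron_model"))
  neuron_state(
    v = v,
    m = boltzmann_ss(v, model$na_m$ss),
    h = boltzmann_ss(v, model$na_h$ss),
    n = boltzmann_ss(v, model$kdr_n$ss),
    a = boltzmann_ss(v, model$cal_a$ss),
    hc = boltzmann_ss(v, model$hcn_h$ss),
    p = boltzmann_ss(v, model$kv4$activation),
    qs = boltzmann_ss(v, model$kv4$inactivation),
    qf = boltzmann_ss(v, model$kv4$inactivation),
    ca = model$ca_rest
  )
}

# Flatten model to the list layout the compiled integrator expects.
model_to_cpp <- function(model) {
  g2l <- function(g) list(vhalf = g$ss$v_half, vslope = g$ss$v_slope,
                          tau_vhalf = g$tau$v_half, tau_vslope = g$tau$v_slope,
                          tau_min = g$tau$tau_min, tau_max = g$tau$tau_max)
  t2l <- function(tp) list(vhalf = tp$v_half, vslope = tp$v_slope,
                           tau_min = tp$tau_min, tau_max = tp$tau_max)
  b2l <- function(bp) list(vhalf = bp$v_half, vslope = bp$v_slope)
  k <- model$kv4
  list(cm = model$cm,
       g_leak = model$g_leak, e_leak = model$e_leak,
       g_na = model$g_na, e_na = model$e_na,
       g_kdr = model$g_kdr, e_k = model$e_k,
       g_cal = model$g_cal, e_ca = model$e_ca,
       g_sk = model$g_sk, ks_sk = model$ks_sk,
       g_hcn = model$g_hcn, e_hcn = model$e_hcn,
       ca_rest = model$ca_rest, ca_tau = model$ca_tau, ca_in = model$ca_in,
       na_m = g2l(model$na_m), na_h = g2l(model$na_h), kdr_n = g2l(model$kdr_n),
       cal_a = g2l(model$cal_a), hcn_h = g2l(model$hcn_h),
       kv4 = list(g_max = k$g_max, f_s = k$f_s, e_k = k$e_k,
                  activation = b2l(k$activation), inactivation = b2l(k$inactivation),
                  tau_slow = t2l(k$tau_slow), tau_fast = t2l(k$tau_fast),
                  activation_tau = t2l(k$activation_tau)),
       syn_kinetics = unclass(model$syn_kinetics))
}
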
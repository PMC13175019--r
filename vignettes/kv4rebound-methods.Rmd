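---
title: "Methods: Kv4.3-dependent rebound delays and learning from negative prediction errors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Kv4.3-dependent rebound delays and learning from negative prediction errors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Scope

`kv4rebound` models how the KChIP4a auxiliary subunit of Kv4 channels shapes
post-inhibitory rebound delays in atypical, nucleus-accumbens-core-projecting
midbrain dopamine neurons, and how the resulting change in inhibitory efficacy
plays out in reinforcement learning. It contains five scientific layers:

1. a conductance-based single-compartment pacemaker with a dual-inactivation
   Kv4.3 A-type current;
2. current-clamp protocols (rebound delay, depth/duration sweeps) and
   voltage-clamp characterisation of the isolated Kv4.3 current;
3. an in-vivo-like balanced synaptic state with Poisson excitation/inhibition,
   correlated inhibitory trains, PSTHs and a percent-spikes-lost statistic;
4. a dual-learning-rate Rescorla-Wagner model with least-absolute-residual
   fitting and parameter-recovery benchmarking;
5. label-free proteomic stoichiometry normalisations for Kv4 channel
   complexes, plus small task-mechanics computations (reward cycles,
   spontaneous-alternation chance, discrimination index).

# The neuron model

## Kv4.3 with two additive inactivation gates

The A-type current is

$$I_{Kv4.3} = g_{max}\, p^3 \left(f_s q_s + (1-f_s) q_f\right) (E_K - V),$$

with one activation gate $p$ (cubed) and two inactivation gates that share the
same steady-state voltage dependence but differ in kinetics. The slow gate
$q_s$ stands for channels bound by KChIP4a, whose K-channel-inhibitory domain
slows open-state inactivation; the fast gate $q_f$ stands for channels bound
by all other (fast) auxiliary subunits. The slow fraction $f_s$ is **the only
parameter distinguishing the two genotypes**: 0.56 for control (CTRL) and 0.22
for dopamine-neuron-specific KChIP4a deletion (Ex3d).

Steady states are Boltzmann functions: activation $V_{1/2} = -40.8$ mV (slope
7.73), applied to the gate $p$ itself with the current using $p^3$ (the
convention of the antecedent model family; the alternative reading — the
Boltzmann parameterising $p^3$ — would merely re-scale the activation curve
and is not used). Inactivation $V_{1/2} = -68.0$ mV (slope $-6.44$), shared by
$q_s$ and $q_f$.

Inactivation time constants are Boltzmann sigmoids of voltage bounded between
stated extrema: slow 20–250 ms, fast 20–45 ms, both centred at $-60$ mV
(slopes 5 and 4 mV). The orientation is not stated by the source; we let tau
**increase with depolarization**, so that slow open-state inactivation
(~250 ms) occurs at depolarized potentials — consistent with a slowly
inactivating A-type current — and recovery at hyperpolarized potentials is
fast (~20 ms) for both gates. A consequence worth flagging: at a $-100$ mV
recovery potential both gates recover with essentially the same ~20 ms time
constant, so simulated paired-pulse recovery curves for CTRL and Ex3d nearly
coincide; the empirically observed slower recovery of KChIP4a-containing
channels is not reproducible from these tabulated kinetics alone, and the
recovery-ordering test asserts the ordering only up to an equality tolerance.

Activation kinetics of $p$ (0.5–2 ms, faster with depolarization) are treated
as a base-model property, identical for slow and fast channels, and
configurable.

## The base pacemaker

The antecedent single-compartment model of these cells is cited but not
printed, so the base is reconstructed: leak, transient Na ($m^3h$),
delayed-rectifier K ($n^4$), L-type Ca ($a^2$, ohmic), SK
(calcium-activated, Hill coefficient 4 on a single calcium pool), and HCN.
Units are fixed package-wide: mV, ms, pA, nS, pF, µM; currents are written
$I = g(E - V)$, so positive values depolarize and
$C\,dV/dt = \sum I + I_{inj}$.

Because the exact antecedent parameters are unavailable, the base was
calibrated once against the quantities the study itself anchors:

* spontaneous pacemaking near 3.4 Hz (CTRL) / 3.3 Hz (Ex3d), unchanged by the
  Kv4.3 split;
* a high input resistance, so that roughly $-20$ to $-25$ pA suffices to hold
  the membrane at $-80$ mV (matching the printed step amplitudes);
* rebound delays after a 1 s step to $-80$ mV: the calibrated model yields
  ~1.42 s (CTRL) and ~1.04 s (Ex3d). The Ex3d value reproduces the reported
  0.97 s within 10%; the CTRL value is about 25% short of the reported 1.9 s.

The CTRL shortfall is structural, not a tuning accident: with inactivation
time constants capped at 250 ms, the delay scales between logarithmically and
linearly with the slow fraction, which bounds the attainable CTRL/Ex3d delay
ratio near ~1.4–1.75 under the basal-rate constraint; the reported pair
implies a ratio of ~1.96. All directional and ordering properties (control
strictly slower, monotonicity in depth and duration, the shape of the
duration curve) hold, and the tests assert those. HCN is kept small
(0.6 nS): its slow activation during long or deep steps otherwise introduces
a small non-monotonicity in the delay-versus-duration tail. Delays saturate
beyond ~200 ms pulses; the monotonicity property is asserted on the rising
limb (10–200 ms), and the CTRL-versus-Ex3d ordering for pulses longer than
50 ms — short pulses barely perturb the pacemaker, so the "delay" they produce
is dominated by the spike phase at step onset.

## Integration

Fixed-step integration at `dt = 0.025` ms: every gate relaxes exponentially
toward its voltage-dependent steady state (exponential Euler, exact for the
linear gate equation at frozen voltage), and the membrane potential advances
by a forward update. The integrator is deterministic — identical inputs give
bit-identical traces — and a convergence test compares spike times at halved
`dt`. Non-finite state or $|V| > 200$ mV raises an integration-failure error
naming the offending time. Spikes are strict upward crossings of $-20$ mV
(configurable), linearly interpolated between samples; a trace that only
touches the threshold yields no spike.

Voltage clamp of the isolated Kv4.3 current needs no integrator at all:
within each constant-voltage segment the gates relax in closed form, and the
current is evaluated analytically on a sampling grid.

## Double-exponential decay fits

`measure_fraction_slow()` fits $a_s e^{-t/\tau_s} + a_f e^{-t/\tau_f} + c$ to
the decay phase (Levenberg-Marquardt, non-negative amplitudes, time constants
seeded at 250 and 45 ms and bounded away from each other for
identifiability). Pure single-component decays make the free-tau problem
singular; the fallback is non-negative least squares on a fixed-tau basis
(250/45 ms), which classifies such traces correctly. The slow fraction is the
amplitude fraction $a_s/(a_s + a_f)$.

# The balanced state

Tonic input is two independent 100 Hz Poisson streams: glutamate events drive
simultaneous AMPA and NMDA conductances with a 0.3 : 0.7 peak split; GABA-A
events form the inhibitory stream. AMPA and GABA-A are peak-normalized
biexponential conductances (rise 0.2 ms; decay 2.4 and 3 ms; reversal 0 and
$-60$ mV). NMDA kinetics are a reconstruction of the standard scheme the
source defers to: biexponential (2/100 ms) with a sigmoidal magnesium block
at 1 mM; NMDA calcium is *not* added to the SK-activating pool.

Absolute unit conductances are not printed; they were calibrated once to the
two stated anchors — GABA alone silences the cell, and varying the two scale
factors in concert from 125%/75% to 75%/125% (conductance ratios 0.6–1.67)
spans the in-vivo firing range, with the 100%/100% point near 4 Hz. The
defaults are 0.12 nS (glutamate unit, before the AMPA/NMDA split) and 1.6 nS
(GABA-A unit).

Phasic inhibition is a train of `n_inputs` synchronous GABA-A synapses driven
by one within-train 100 Hz Poisson process for 250 ms. Each trial simulates a
4 s intertrial refractory period (discarded) plus the trial window; PSTHs use
25 ms bins, rate = count/(trials × bin width). The percent-spikes-lost
statistic compares the response window (default: the 1 s from inhibition
onset) against the baseline window (the 1 s before onset); the windows are
configurable because the source does not define them.

Per-trial seeds derive from the master seed by a counter scheme
(`seed_i = (master + 104729 i) mod (2^31 - 1)`), so ensembles are invariant
to execution order and the two genotypes can be run on **matched input
trains**. Grid sizes are configurable; the shipped tests use a reduced
3 × 3 × 2 grid at 100 trials per cell, sized for a single-CPU desk run, and
the full 500-trial histograms remain available through the same functions.

# The behavioral model

Associative strength follows a Rescorla-Wagner rule with separate learning
rates: $V_{n+1} = V_n + \alpha_P (R - V_n)$ when $R - V_n \ge 0$, else
$V_{n+1} = V_n + \alpha_N (R - V_n)$; ties take the positive branch. The
percent time in port is a linear readout of $V$. Internally $V$ lives on
$[0, 1]$ with $R = 1$ on acquisition trials and $R = 0$ in extinction, and the
readout maps $[0,1]$ onto $[V_{min}, V_{max}]$; acquisition and extinction
form one concatenated trial sequence (170 trials: 11 + 6 sessions × 10).

Empirical bounds per subject: $V_0$ is the mean of the first three acquisition
trials; the remaining two bounds are the mean responses over the last two
sessions of acquisition and of extinction. The source sentence assigns
"$V_{min}$ and $V_{max}$" to acquisition and extinction "respectively", which
is internally inconsistent with acquisition producing high responding; this
package assigns the larger empirical mean to $V_{max}$ and the smaller to
$V_{min}$, and warns if the acquisition-end mean falls below the
extinction-end mean.

Fitting minimizes the **sum of absolute residuals** over
$(\alpha_P, \alpha_N) \in [0,1]^2$: Nelder-Mead simplex restarted from a
3 × 3 lattice (0.15/0.5/0.85), parameters clipped inside the objective,
followed by a small local grid polish (the L1 surface has flat kinks where a
simplex can stall). Noiseless self-consistency (recovering the generating
rates to $10^{-3}$, verified as a global optimum on an alpha grid) and noisy
recovery (median error < 0.05 at noise sd 5 over 100 replicates) are part of
the test suite. Latency series are generated for completeness but never
fitted.

# Synthetic data

The session generator emulates the task structure exactly (sessions, trials,
cue and reward-cycle timing) and adds Gaussian noise truncated to $[0, 100]$
to the readout. It does **not** emulate within-trial dynamics, session-level
drift, motivational states, or the long-term extinction phenomena
(spontaneous recovery, renewal) that the Rescorla-Wagner model itself cannot
express — so passing parameter-recovery tests demonstrates correctness of the
fitting machinery on data obeying the model, not adequacy of the model for
arbitrary real behaviour.

Reward-cycle accounting: a delivery may start whenever the head is in the
port and the 2 s + 3 s cycle clock allows; the reward is counted if occupancy
covers the whole 2 s delivery (consumption does not require occupancy).
An always-in-port agent therefore earns exactly 6 rewards per 30 s trial and
60 per session, and 12 s of continuous occupancy earns 3 (the third delivery
completes exactly as the head leaves).

Spontaneous alternation: the null model is uniform choice among the
$(\text{arms} - 1)$ non-current arms (no immediate re-entry). Exact
enumeration of the $4 \times 3^4 = 324$ windows gives $144/324 = 4/9 \approx
44\%$ — this is the only null that reproduces the printed chance level, which
settles the otherwise unstated assumption. A Monte-Carlo simulator over
independent windows converges to the same value and is checked against three
binomial standard errors at $10^5$ draws.

# Proteomic normalizations

`abundance_norm_spec` = (sum of assigned, isoform-specific peak volumes) /
(MS-accessible isoform-specific amino acids); the amino-acid counts are
user-supplied constants. Tetramer normalization divides every protein by
(Kv4.2 + Kv4.3)/4, pinning the channel core at exactly four subunits;
it is scale-invariant and idempotent. Relative isoform abundance
max-normalizes each unique peptide across the datasets of one region, takes
group means, and rescales so the control group equals exactly 1. All three
operations are pure.

# Numerical and design notes

* `dt = 0.025` ms default; exponential Euler for gates, forward update for V.
* Step-current calibration: bisection to 0.5 mV tolerance on the minimum
  voltage; amplitudes that blow past the integration guard count as
  overshoots. Duration sweeps calibrate once at the longest duration and hold
  the amplitude constant.
* Censoring: rebound trials without a spike in the observation window are
  reported at the window length and flagged, never dropped. An
  ISI-corrected delay variant (delay minus the mean baseline interspike
  interval) is reported alongside the raw definition, since it is unstated
  which was used.
* Degenerate inputs: constant duration-delay data yield a flagged degenerate
  Boltzmann fit; flat behavioral series yield residual 0 with a degenerate
  flag; all-zero peptides are excluded with a warning.
* Problem sizes in the shipped tests (single CPU): 10–12 s spontaneous runs,
  5-point depth and duration grids, a 3 × 3 × 2 balanced-state grid at 100
  trials, 100-replicate fitting studies, $10^5$ Monte-Carlo draws.

# Known limitations

* The base pacemaker is a calibrated reconstruction, not the deposited
  antecedent model; its control rebound delay is ~25% short of the reported
  value (see above), while all directional effects and the deletion-model
  delay match.
* Recovery-from-inactivation differences between genotypes are structurally
  absent at deep holding potentials under the tabulated kinetics.
* Single compartment, no temperature dependence, no channel noise, no
  synaptic plasticity, no interacting network.
* The behavioral model quantifies learning rates; it is not a model of
  motivation, and extinction beyond its short-term dynamics is out of scope.
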
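---
title: "Quantifying shunting GABA-A inhibition: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying shunting GABA-A inhibition: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(gabashunt)
```

## The scientific problem

Fast synaptic inhibition in cortex is carried by chloride-permeable GABA-A
receptors. Whether a GABAergic input hyperpolarizes a neuron or merely
*shunts* it depends on the ionic driving force: the difference between the
resting membrane potential (RMP) and the GABA-A reversal potential
(E<sub>GABAAR</sub>). When E<sub>GABAAR</sub> sits close to the resting
potential, receptor activation moves the membrane little; the inhibitory
effect comes from the added conductance. This package implements, end to
end, the computational machinery needed to quantify that distinction in
vivo and to explore its network-level consequences:

1. **`perforated_patch` analysis** — estimating RMP, E<sub>GABAAR</sub>,
   driving force and synaptic conductance from voltage-clamp ramp and step
   protocols with offline series-resistance correction, plus
   current-clamp summaries (membrane-potential densities, subthreshold
   fluctuation rates, response polarity).
2. **Spike-train metrics** — per-neuron trial-to-trial synchrony,
   peri-stimulus histogram (PSTH) entropy, evoked rates, rate
   residualization and k-nearest-neighbour population decoding.
3. **A paired sorted-unit pipeline** — unit selection and paired
   awake-versus-anesthetized metric tables in the style of a Neuropixels
   reanalysis.
4. **A balanced recurrent LIF network** — contrasting shunting
   (E<sub>GABAAR</sub> = −60 mV) with hyperpolarizing
   (E<sub>GABAAR</sub> = −80 mV) inhibition.
5. **A passive multicompartment control** — how series resistance and
   membrane properties bias ramp-based E<sub>GABAAR</sub> estimates.
6. **Synthetic-data generators** — seeded, ground-truthed stand-ins for
   every experimental input, so the whole pipeline is testable offline.

## Reversal-potential estimation

### Series-resistance correction

In voltage clamp the access resistance R<sub>s</sub> drops part of the
command voltage. Online compensation is impractical during in vivo
perforated-patch recordings, so the correction is applied offline:

$$V_m(t) = V_{cmd}(t) - I(t)\, f\, R_s,$$

with currents in amplifier convention (inward negative) and the corrected
fraction *f* = 0.9 by default. Worked example: at
V<sub>cmd</sub> = −70 mV, a −1000 pA current through 90 % of a 50 MΩ
R<sub>s</sub> drops −45 mV, so the membrane actually sits at −25 mV. The
sign convention matters: large inward currents make the membrane *more
depolarized* than the command.

### Ramp protocol

The neuron is held at −70 mV and two 150 ms ramps from −130 to −30 mV are
delivered, the second during a light-evoked GABA-A conductance. After
correction and exclusion of the first and last 15 ms of each ramp
(pipette-capacitance transients), a straight line is fitted to each
current against the corrected membrane potential. The baseline line's zero
crossing is the RMP; the intersection of the two lines — equivalently the
zero crossing of the light-minus-baseline difference line — is
E<sub>GABAAR</sub>; the difference slope is the synaptic conductance in
nS; `DF = RMP − E_GABAAR` identically. Crop windows are an explicit user
input (a list of time or voltage intervals) because in real recordings the
contaminated stretches are identified by eye; the default applies edge
exclusion only.

### Step protocol

Voltage steps from −130 to −30 mV in 10 mV increments, 500 ms each, with a
100 ms light pulse 100 ms into the step. Currents measured immediately
before the pulse and 20 ms after its onset (the conductance peak) provide
the baseline and light IV points; the estimator is then identical to the
ramp's. A second measurement at the latency corresponding to the ramp's
E<sub>GABAAR</sub> crossing yields `gabab_stability_mV`, a diagnostic for
slow (GABA-B) contamination.

### Membrane properties

R<sub>s</sub> is estimated two ways from a −10 mV seal-test step — from
the raw peak transient and from a single-exponential fit to the transient
decay extrapolated back to the step edge — and averaged. The exponential
fit window (0.1–10 ms after the edge, configurable) is a package default;
the extrapolation removes the sampling bias on a fast transient. Input
resistance comes from the steady-state current; `Rm = R_input − Rs`.
Perforated recordings are flagged unusable until R<sub>s</sub> < 100 MΩ.

### Current-clamp summaries

`vm_statistics()` excludes samples above −40 mV (action potentials),
reports the mean V<sub>m</sub>, a Gaussian kernel density (bandwidth by
Scott's rule of thumb, configurable), and the mean |dV/dt| in mV/ms after
removing samples within ±2 ms of upward −40 mV crossings and winsorizing
at the 1st/99th percentiles. The winsorization limits and the
action-potential exclusion window are package defaults; both are
configurable. `classify_polarity()` averages 15 light-evoked sweeps,
normalizes to the 100 ms pre-pulse baseline and labels the mean of the
100 ms after the pulse: strictly positive → depolarizing, otherwise
hyperpolarizing (an exactly zero mean is the boundary case and is
labelled hyperpolarizing).

## Spike-train metrics

**Synchrony.** For each trial the population PSTH (1 ms bins) is divided
by the trial's total spike count; a neuron's synchrony is the mean, over
its spikes, of the normalized histogram value in each spike's bin. The
trial-total normalization (rather than average firing rate) bounds the
measure in [0, 1]: it is 1 when every trial's spikes share one bin. By
default a neuron's own spikes stay in the reference histogram (they are
part of the population response); `include_self = FALSE` removes them.

**Entropy.** Per neuron, the PSTH pooled over trials is normalized to a
probability vector and `H = −Σ p log p` is reported in nats; the maximum
is log(#bins). Entropy estimated from few spikes is biased downward
(roughly (occupied bins − 1)/(2 × spike count)), which is why the
acceptance runs use thousands of trials per condition.

**Decoding.** Spike-count vectors from a fixed random subset of neurons
(50 by default), one per trial, feed a k-nearest-neighbour classifier
(k = 5, Euclidean distance) under stratified 5-fold cross-validation.

## The paired sorted-unit pipeline

Units are retained when (i) their region annotation matches the
stimulated area ("SSp-ll"/"SSp-tr" for somatosensory, "MOs" for secondary
motor), (ii) their waveform duration is ≥ 0.4 ms (putative
regular-spiking neurons) and (iii) their evoked rate lies in
[0.1, 200] Hz in *both* conditions; the three filters commute. Metrics
use spikes 2–12 ms after the stimulus binned on a 0–12 ms 1-ms grid (a
10-bin 2–12 ms grid is selectable). The evoked-rate denominator is the
per-trial window (trials × 10 ms), inferred from context. Reading real
NWB containers is out of scope offline; the pipeline operates on an
in-memory tabular session (units table + stimulus-aligned rasters) that
[gen_two_condition_raster()] emits and that an NWB adapter can target.

## The balanced network model

1000 single-compartment leaky integrate-and-fire neurons (800
glutamatergic, 200 GABAergic), connected with uniform probability 0.1 per
ordered pair (no self-connections). Parameters: leak reversal −60 mV
(equivalent to RMP), glutamatergic reversal 0 mV, synaptic conductance
decay 5 ms (excitatory) / 10 ms (inhibitory), C<sub>m</sub> = 200 pF,
τ<sub>m</sub> = 5 ms (leak conductance 40 nS), refractory period 5 ms,
glutamatergic weights 0.1 nS, GABAergic weights initialized at 1 nS.
E<sub>GABAAR</sub> is −60 mV in the interneurons throughout and is the
experimental contrast in the pyramidal cells: −60 mV (shunting) versus
−80 mV (hyperpolarizing).

Design choices where the reference parameter set is silent:

* **Conductance-based synapses.** Weights are in nS and reversal
  potentials are specified; the shunting/hyperpolarizing contrast is
  meaningless without driving-force dependence, so synaptic currents are
  `g(t) (E_syn − V)`.
* **Threshold and reset.** −50 mV and the leak reversal, giving a 10 mV
  leak-to-threshold span. Configurable.
* **Transmission delay.** 1.5 ms, a standard cortical monosynaptic
  latency. Configurable.
* **Integration.** Exponential-Euler, fixed 0.1 ms step. Spikes are
  stamped at the midpoint of the step in which the crossing occurred, so
  a crossing in the final step of a 1 ms pulse stays inside the pulse's
  histogram bin rather than spilling into the next one.
* **Inputs.** Stimulus patterns are simultaneous 1 ms current pulses with
  per-neuron log-normal amplitudes (`X = M exp(μ + σZ)`, M = 500 pA,
  μ = 0, σ = 1), followed by a 25 ms pause; each neuron also receives an
  independent positive noise current (M = 25 pA) refreshed every 10 ms.
* **Balancing.** Homeostatic inhibitory plasticity (symmetric
  spike-timing rule: pre spike `w += η (x_post − α)`, post spike
  `w += η x_pre`, `α = 2 ρ₀ τ_STDP`) runs before measurement and the
  weights are then frozen. Hyperparameters are not part of the reference
  set; defaults are ρ₀ = 5 Hz, η = 0.01 nS, τ_STDP = 20 ms, 60 s of
  simulated balancing. During balancing each neuron receives an
  *independent* Poisson train of 1 ms pulses at the same average rate as
  the cyclic stimulation: with synchronized pattern drive the
  stimulus-locked correlations bias the rule's fixed point below the
  target rate, while noise alone (25 pA) evokes no spikes at all and the
  rule would stall. With decorrelated drive the achieved rate lands
  within a few percent of ρ₀.
* **Analysis window.** Synchrony and entropy for the simulated rasters
  use the full 26 ms inter-stimulus cycle with 1 ms bins; a narrower
  window is selectable.

Both conditions are run on the same frozen weights with identical input
sequences, so the contrast is paired. A scaled-down run (5 simulations ×
20 patterns × 50 repeats) reproduces the orderings robustly: lower
synchrony, higher entropy and more total spikes under shunting
E<sub>GABAAR</sub>, and higher decoding accuracy for a readout kept off
ceiling (at these pattern counts a 50-neuron readout saturates at 100 %
accuracy in both conditions, so the acceptance test samples 8 neurons).

**Known limitation.** With the stated 0.1 nS glutamatergic weights and a
10 mV leak-to-threshold span, the balanced inhibitory weights settle near
1 nS and cannot suppress late, noise-driven spiking strongly in the
hyperpolarizing condition. The orderings above are stable, but the
absolute hyperpolarizing-condition PSTH entropy stays well above what a
network with substantially stronger inhibition would show. We explored —
and rejected — smaller leak-to-threshold spans (the homeostatic rule then
fails to converge, because inhibiting the interneurons caps the
achievable inhibition) and lower target rates (the rate is pinned by
direct feedforward crossings). The plasticity hyperparameters are the
single most influential unconstrained choice in this module.

## The passive cable control

An SWC morphology is discretized per node (frustum areas and axial
resistances; single-point somata become equivalent spheres; neurite stems
attach at the soma surface and the intrasomatic stretch carries no
membrane). The cable equation is stepped with an unconditionally stable
implicit (backward-Euler) scheme, 25 µs steps; the systems are small, so
dense solves are used. An ideal voltage source in series with a 47.5 MΩ
electrode clamps the soma. Twenty 2 nS alpha-function synapses
(τ = 150 ms) are placed uniformly among nodes within a 75 µm Euclidean
radius of the soma centre (path distance selectable). Passive constants:
C<sub>m</sub> = 2.515 µF/cm², R<sub>axial</sub> = 150 Ω·cm, and
per-condition passive reversal / specific membrane resistance
(anesthetized −70.7 mV, 10^3.784 Ω·cm²; awake −64.2 mV, 10^3.540 Ω·cm²;
activity-blocked −71.4 mV, 10^3.988 Ω·cm²).

The simulated ramp experiment feeds `fit_iv_ramp()` verbatim. The alpha
conductance is timed so its *peak* falls at the ramp midpoint, as in the
experiment where the ramp is delivered while the evoked current is at its
peak; starting the conductance at ramp onset instead makes the difference
current strongly curved and biases even the ideal-clamp single-compartment
limit by several mV. `run_bias_sweep()` iterates the true reversal from
−85 to −35 mV in 5 mV steps and fits at 0 % and 90 % correction.

On the bundled ball-and-stick stand-in (8 µm soma, 300 µm × 2 µm
dendrite; the 4 µm trunk calibre keeps perisomatic sites electrotonically
close, as on a real reconstruction) the 90 % correction strictly reduces
the absolute estimation bias at every grid point in the awake and
activity-blocked conditions. In the anesthetized condition the
uncorrected bias happens to cross zero almost exactly on one grid point,
where the comparison can tie — a property of the grid placement, not of
the correction.

## Synthetic data: what it does and does not show

* `gen_iv_session()` uses a quasi-static ohmic model: the
  series-resistance distortion is applied forward (the exact inverse of
  the offline correction), so full correction recovers truth to machine
  precision and 90 % correction to within ~1 mV at physiological
  R<sub>s</sub>. It does not model capacitive ramp transients (the edge
  exclusion removes where they would sit), conductance rundown, or
  voltage-dependent channels.
* `gen_vm_trace()` is a two-timescale Ornstein–Uhlenbeck process whose
  fast innovation scale is set analytically from the target mean |dV/dt|
  (for a noise-dominated OU, mean |dV/dt| = √(2/π)·s/√dt). Condition
  presets: awake −60.3 mV / 6.6 mV·ms⁻¹, anesthetized −69.1 / 4.9,
  activity-blocked −72.6 / 0.7. It has no spikes, synaptic kinetics or
  up/down states.
* `gen_two_condition_raster()` is a shared-event model: per trial one
  latent population event (Gaussian latency, 5 ± 1.5 ms) occupies a
  single 1 ms bin and each neuron joins with probability q, on top of
  independent Poisson background. Synchrony is provably monotone in q and
  entropy monotone decreasing, which is what makes the metric tests
  sharp. Condition presets (awake: 60 Hz background, q = 0.3;
  anesthetized: 10 Hz, q = 0.6) reproduce the qualitative awake pattern —
  lower synchrony, higher entropy, higher evoked rate. The model has no
  refractoriness, rate heterogeneity or inter-neuron correlations beyond
  the single event, so passing tests certify the *metrics*, not any claim
  about real recordings.
* Every generator is a pure function of its seed and carries a
  machine-readable ground-truth sidecar.

## Problem sizes and numerical tolerances

* Ramp fits use 20 kHz sweeps (4,800 IV points per fit); noiseless fits
  are checked to 1e-9 mV, noisy recovery as a median over 100 sessions.
* The network acceptance run uses 5 simulations × 25 patterns × 80
  repeats per condition (2,000 trials; 4,000 pyramidal-neuron
  measurements per condition), balancing 60 s of simulated time per
  network. The ordering tests use 5 seeds at 20 × 50.
* Cable simulations use 25 µs steps and ≤ 10 µm segments; halving both
  changes the estimated reversal by < 0.1 mV (asserted at 0.2 mV).
* Convergence of balancing is declared when the final-window mean
  excitatory rate is within ±50 % of ρ₀ (observed: within ~3 %); the
  self-consistency test asserts ±20 %.

## Known limitations

* ABF and NWB binary containers are not read; the documented plain
  tabular dialects (TSV + JSON sidecar, SWC) are the interchange formats.
* The liquid-junction potential is not corrected (not stated in the
  underlying protocol); estimates are on the amplifier's voltage scale.
* The GABA-B/stability diagnostic is a measurement-time difference only;
  no receptor kinetics are modelled.
* The absolute network-simulation metric values depend on the
  unconstrained plasticity hyperparameters (see above); the condition
  orderings are the robust output.
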
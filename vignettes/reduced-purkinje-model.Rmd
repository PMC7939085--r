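---
title: "A reduced Purkinje-cell model of branch-specific dendritic calcium spikes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A reduced Purkinje-cell model of branch-specific dendritic calcium spikes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## What the model is

`pfspike` simulates a cerebellar Purkinje cell (PC) at desk scale: a
multicompartment cable model with Hodgkin–Huxley-style active membrane,
driven by clustered parallel-fiber (PF) synapses, stellate feed-forward
inhibition (FFI) and Poisson background bombardment. The scientific object
of interest is the *localized dendritic calcium spike*: with weak clustered
PF input, dendritic responses grow linearly with the number of activated
synapses; past a branch-specific threshold, a regenerative, all-or-none
Ca spike fires in the stimulated branch, and at the soma a burst of
simple spikes followed by a pause replaces the graded rate increase. The
package reproduces the full protocol battery around this phenomenon:
input–output curves and step-criterion thresholds, somatopetal attenuation
profiles, source/sink branch-excitability analysis, two-branch
co-activation, branch-wise channel-density scaling, inhibition timing
sweeps, and PSTH burst–pause statistics.

The model is *reduced and calibrated*, not a reconstruction: the morphology
is parametric, the channel kinetics are standard Boltzmann/HH forms whose
densities were tuned against a small set of headline numbers (tonic rate,
threshold, attenuation). What passing tests show is therefore that the
*mechanisms* — high-threshold Ca current versus A-type and Ca-activated K
currents on an electrotonically structured tree — reproduce the phenomenon
class; they do not show that any particular kinetic parameter matches a
real PC.

## Morphology

`build_reduced_pc()` creates four regions: a soma (20 µm cylinder), a thin
axon initial segment, three main dendritic limbs, and 22 spiny branches
(1–8 on the left limb, 9–13 middle, 14–22 right). Each branch is a compact
*fan*: one stem section (the connection segment — exactly one compartment
adjoins the parent limb) carrying a set of parallel 10–25 µm tip
branchlets whose total membrane matches the branch's configured area
(400–1500 µm²). Branchlet lengths follow a fixed heterogeneous cycle so
that random synapse placement produces genuine trial-to-trial variation in
spike initiation.

The fan is a deliberate deviation from a deep binary subtree: keeping the
tip-to-soma path short (tens of µm) is what makes the 50-µm somatopetal
attenuation measurable from the initiation site, and a binary tree of the
same compactness would several-fold the compartment count. The fan
preserves what matters scientifically — branch area (the Ca-current
"source"), the stem/limb coupling (the "sink"), and the
single-connection-segment invariant.

Branch heterogeneity lives in two knobs per branch: total area and stem
diameter/length. Thick short stems couple a branch tightly to the tree
(large sink — never spikes); thin long stems isolate it (branches 8, 12,
21, 22 — the spike-capable set, and the top four by source/sink ratio).
Spines are not modelled; spiny membrane uses an elevated specific
capacitance (1.1 µF/cm², a calibration knob) and scaled leak.

## Membrane mechanisms

All gates are Boltzmann steady states with bell-shaped voltage-dependent
time constants (clamped at 0.05 ms). The channel set follows the standard
PC partition: NaF + KdR (+ small CaP/SK, Kv4) on soma/AIS produce tonic
firing; spiny dendrites carry CaP, Kv3, Kv4, two BK components
(iberiotoxin-sensitive and -insensitive, encoded as 67%-Kv3 / 200%-BK
ratios relative to an internal reference) and SK; main dendrites carry the
spiny set at strongly reduced CaP. The Ca reversal uses a fixed
driving-force approximation (+130 mV), not GHK.

Two package-specific choices deserve emphasis:

* **CaP gating.** The activation gate is squared and a slow (12 ms)
  inactivation gate is attached. With a single first-power
  non-inactivating gate, the reduced branch has a stable depolarized
  plateau attractor (the Ca current at −45 to −13 mV balances BK exactly)
  and spikes never terminate; squaring the gate suppresses the
  subthreshold window current quadratically, and the slow inactivation
  terminates the spike and confers refractoriness. Both are calibrated
  stand-ins for kinetics that are not publicly specified for the reference
  phenomenology.
* **Region-resolved Ca pools.** The somatic shell is fast (τ = 15 ms,
  feeding the SK rate-control loop); the dendritic shell is slow and deep
  (τ = 60 ms, depth 0.4 µm), so the Ca tail after a branch spike keeps
  SK/BK active and carries the post-burst somatic pause.

## Solver

The branched cable equation is integrated by a Crank–Nicolson tree solve
in Hines order (one downward elimination, one upward substitution — exact
linear algebra on the tree, no iteration), with gates advanced by an exact
exponential integrator against tabulated rate functions and synapses as
two-state bi-exponential conductances. Default dt is 0.025 ms, traces are
sampled at 0.1 ms. An ideal voltage clamp (used by the sink assay) pins
one compartment to a sampled waveform and records the clamp current.

Initialization: every protocol settles the model for 2000 ms (1500 ms in
the shipped trial configuration) before stimulation. A 0.3 nA / 100 ms
depolarising kick at the start of settling selects the tonic firing limit
cycle: the reduced cell is bistable between firing and a silent state, and
the kick makes the choice deterministic. Each trial then extends the
settled state by a uniform 0–25 ms jitter to de-phase the tonic cycle —
the stand-in for the random holding-current prelude used experimentally
to disturb somatic spike timing across trials.

A genuine property of the calibrated cell worth knowing: close to its
limit cycle it is phase-sensitive, so halving dt leaves the rate and the
first spike essentially unchanged but decorrelates late spike times in a
long window. The convergence test asserts first-spike agreement and rate
agreement, not late-spike-time agreement.

## Synthetic inputs

PF AMPA synapses: bi-exponential, 0.3/3 ms, 0.5 nS peak, reversal 0 mV.
Stellate/basket GABA: 1/8 ms, reversal −85 mV; one stellate cell drives 16
synapses sharing 1 nS of total peak conductance (the per-cell reading of
an ambiguous statement; per-synapse 1 nS would dwarf the PF drive).
Clustered placement draws compartments area-weighted, with replacement,
within one branch. FFI schedules each stellate cell once at the PF time
plus a delay (−4.5 … +4.5 ms; 1.4 ms is the canonical circuit delay).
Background bombardment: 2000 PF synapses at 0.135 Hz over all spiny
compartments, 9×16 stellate synapses and 4×40 basket synapses at 14.4 Hz
per presynaptic cell, Poisson, with all synapses of one cell sharing its
train.

## Analysis rules (all config-exposed)

* Response amplitude: max V in a 20 ms post-stimulus window minus the
  *median* over a 50 ms baseline (median so a backpropagated somatic spike
  in the baseline cannot bias it).
* Spike threshold: the step criterion. Per synapse count, a trial "jumps"
  if its amplitude exceeds the linear fit of the sub-threshold means by
  10 mV; the threshold is the smallest count at which at least half the
  trials jump. The fit grows upward through the grid and only ever
  includes counts that have not jumped.
* Somatic spikes: upward crossings of −20 mV, 1 ms lockout.
* PSTH: 2 ms bins, rate = count/(trials × bin). Burst–pause rule: baseline
  is the mean rate over [−200, 0) ms; max rate is the tallest bin in
  (0, 30] ms; the pause is the first contiguous run of bins after the
  burst peak below 0.2 × baseline.
* Somatopetal decay: `measure_spike_decay()` medians the peak-vs-distance
  profile over five placements, restricted to placements in which the
  spike actually decays across the stem (connection-segment peak ≤ 60% of
  the tip peak). In the remaining placements the spike regenerates through
  the whole stem and, in the tonic model, somatic burst spikes contaminate
  the proximal sites; the decrement-mode median is what corresponds to a
  propagating, decaying spike.

## Calibration and what is honest about it

`calibrate_canonical()` tunes *densities only*, in stages: somatic
leak/SK against the tonic-rate pair (40 Hz spontaneous, 12 Hz under
−0.2 nA), then spiny CaP against the branch-8 threshold and the 50-µm
decay. The hyperpolarization- and inhibition-shifted thresholds are never
optimised — they are emergent mechanism checks.

The shipped defaults sit at: tonic ≈ 42 Hz, ≈ 14 Hz under −0.2 nA, decay
≈ 55%, branch-8 threshold 50 synapses (45 under −0.2 nA), FFI-shifted
thresholds ≈ 55, branch-12 burst ≈ 450 Hz with a ≈ 64 ms pause. Three
known deviations from the reference phenomenology are documented rather
than papered over:

1. **The absolute threshold is 50, not 35 synapses**, and hyperpolarization
   *lowers* instead of raises it. In this compact tree the tonically firing
   soma is electrically close to every branch and acts as a periodic shunt
   that drains clustered EPSPs; slowing the soma (−0.2 nA) removes that
   loss faster than the Kv4-availability mechanism adds threshold. In the
   full reconstructed morphology the soma is electrotonically remote and
   the Kv4/baseline mechanism dominates.
2. **Preceding inhibition is disproportionately strong** (the −4.5 ms
   condition pushes the threshold beyond 70 synapses): fan tips have high
   local impedance, so IPSP shunting is more effective than in a
   distributed spiny tree.
3. **Spikes are not perfectly branch-confined**: the evoked somatic burst
   backpropagates strongly (the reduced soma fires large spikes) and can
   ignite other excitable branches. This inflates the PSTH burst peak
   (≈ 450 Hz versus ≈ 338) while leaving the pause in range.

These are consequences of compactness — the price of a ~300-compartment
model that runs a full protocol battery in minutes — and they are asserted
as-is by the acceptance suite (the corresponding checks are expected to
fail, loudly, rather than being weakened).

## Problem sizes

The shipped test and acceptance configurations use: 10 (acceptance script)
or 3–4 (test suite) placements per synapse count on 5-synapse grids,
100-trial PSTHs (the 500-trial reference grid is config-exposed), 2 s rate
measurements, and 1.5 s settles reused across trials from a cache. A full
acceptance run is a few hundred simulated seconds of a ~340-compartment
model at dt = 0.025 ms.
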
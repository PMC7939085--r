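# pfspike

Branch-specific dendritic calcium spikes in a reduced cerebellar
Purkinje-cell model.

## The problem

Purkinje cells receive parallel-fiber (PF) input on a large, electrically
distributed dendritic tree. With weak clustered input the dendrite
integrates linearly and the soma encodes input strength in its tonic
simple-spike rate; when enough PF synapses are co-activated within one
branch, a localized, all-or-none dendritic Ca spike fires and the somatic
output switches to a stereotyped burst–pause sequence. Which of the two
codes a branch uses depends on its excitability — the ratio of its
membrane area (Ca-current *source*) to the axial current it loses to the
rest of the tree (*sink*) — and on modulators: holding potential,
channel-density scaling, co-activation of sibling branches, and stellate
feed-forward inhibition (FFI).

`pfspike` is a desk-scale biophysical model of this phenomenon for
computational neuroscientists who want the full analysis battery without a
reconstructed morphology: a parametric 22-branch Purkinje cell, an
implicit branched cable solver (Crank–Nicolson on a Hines-ordered tree,
Rcpp core), HH-style channels (NaF, KdR, high-threshold CaP, Kv3, Kv4,
two BK components, SK, leak) with region-resolved sub-membrane Ca pools,
and seeded generators for clustered PF volleys, FFI and in-vivo-like
Poisson background.

At its core are the field's standard readouts:

* input–output curves `amplitude(n)` with the **step criterion** for the
  spike threshold: the smallest synapse count at which ≥ 50% of random
  placements exceed the sub-threshold linear fit by 10 mV;
* somatopetal attenuation profiles (percent peak decay over the first
  50 µm from the initiation site);
* the **source/sink ratio** `A / max|I_ax|` per branch, from ideal
  waveform-clamp of each connection segment with a recorded spike;
* PSTHs (2 ms bins) with burst–pause statistics: baseline rate over
  [−200, 0) ms, max burst rate in (0, 30] ms, and the pause as the first
  contiguous run of bins below 0.2 × baseline after the burst peak.

## Worked example

```r
library(pfspike)

model <- pc_model()
#> pc_model (410 compartments, hash 1024c0f3)

measure_tonic_rate(model, hold_nA = 0)
#> [1] 42    # Hz, spontaneous simple-spike rate

io <- run_io_curve(model, branch_id = 8, n_range = seq(20, 60, 10),
                   trials = 4, seed = 1)
io
#> pc_io_curve: branch 8, hold 0.00 nA, threshold 50 synapses
head(io$curve, 3)
#>    n trial amplitude amplitude_main       seed
#> 1 20     1  20.98863       21.17936 1996622044
#> 2 20     2  18.60250       18.81156 1996622045
#> 3 20     3  20.79190       17.53227 1996622046

measure_spike_decay(model)$decay_percent
#> [1] 54    # % peak reduction over 50 um toward the soma
```

The io-curve amplitudes are dendritic-tip EPSP sizes in mV: linear in `n`
below threshold (~20 mV at 20 synapses), jumping to the fixed spike
amplitude (~68 mV) once the branch fires. `run_psth_condition()`,
`run_inhibition_sweep()`, `run_coactivation()`, `run_density_scaling()`
and `run_sink_assay()` drive the remaining protocols; a thin CLI wrapper
lives in `inst/scripts/run_protocol.R`.

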
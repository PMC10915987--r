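---
title: "Modelling corticothalamic sleep waves with ctsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling corticothalamic sleep waves with ctsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

`ctsim` simulates a single cortical column reciprocally coupled to a
first-order and a higher-order thalamic nucleus, each with its sector of
the GABAergic nucleus reticularis thalami (NRT). At full scale the model
contains 900 conductance-based neurons: four cortical layers (L2/3, L4,
L5, L6), each an excitatory row of 100 pyramidal cells and an inhibitory
row of 50 fast-spiking (FS) interneurons, plus 75 thalamocortical (TC)
relay and 75 NRT cells per thalamic sector. Cortical neurons are
two-compartment (axosomatic + dendritic) Hodgkin–Huxley models; thalamic
neurons are single-compartment.

The excitatory rows mix five pyramidal phenotypes — regular spiking (RS),
intrinsically bursting (IB), repetitive intrinsically bursting (RIB),
early firing (EF) and network driver (ND) — with ND cells confined to L5
and EF cells concentrated in L2/3 and L6. This mixture is a package
default (the published architecture defers exact counts to supplementary
tables; see `inst/PROVENANCE`).

The single organising parameter is the potassium leak conductance
`g_KL`, the model's proxy for the wake–sleep neuromodulatory drive:
closing K+ leak channels depolarizes, opening them hyperpolarizes. Every
cell type carries a named map of regimes (`wake`, `spindle`, `slow_osc`,
`delta`, `silent`, `breakdown`) to `g_KL` densities; a few regimes also
scale a channel density (the spindle regime triples `I_AHP` in NRT
cells, matching the idea that the same neuromodulators that set the leak
also regulate the fast after-hyperpolarizing current).

## Membrane currents

All kinetics are declarative data in `channel_catalog()` (coefficients,
not code; provenance in `inst/PROVENANCE`). The complement per cell
class:

* cortical axosomatic: transient Na+, delayed-rectifier K+, persistent
  Na+ (`I_Na(P)`), M-type K+ (`I_M`), Na+-activated K+ (`I_K[Na]`), leak;
* cortical dendritic: the same spike currents at low density plus A-type
  K+ (`I_A`), Ca2+-activated K+ (`I_K[Ca]`), high-voltage-activated Ca2+
  (`I_HVA`), `I_K[Na]`, and — in ND and EF cells — a slow pacemaker
  `I_h`; Ca2+ and Na+ pools integrate the respective inward currents;
* TC: transient Na+/K+, T-type Ca2+ (`I_T`, with a functional window
  component that `it_window_profile()` exposes), `I_h`, `I_A`,
  `I_Na(P)`, `I_CAN`, `I_K[Ca]`;
* NRT: transient Na+/K+, the slower reticular `I_T`, fast `I_AHP`,
  `I_CAN`, `I_Na(P)`.

Sign and unit conventions are fixed package-wide and asserted in the
test suite: outward current positive, conductance densities in S/cm²,
point conductances in µS, voltages in mV, time in ms, concentrations in
mM.

## Numerics

Gating variables advance by exponential (Rush–Larsen) updates using
voltage tables precomputed from the catalog (0.1 mV grid, −150…60 mV);
membrane potentials advance by a semi-implicit step in which all
conductances are frozen over the step and the one- or two-compartment
linear system is solved exactly. The default step is 0.025 ms; halving
it moves stimulus-locked spike times by well under 0.5 ms (tested).
Synaptic deliveries are quantized to the step grid. Spikes are upward
crossings of 0 mV at the axosomatic compartment with a 1 ms refractory
latch. Instabilities (|V| > 200 mV) abort with a diagnostic naming the
neuron and time.

Initial states come from relaxation: each cell type is run free in its
regime for a few seconds, iterating until the endpoint is consistent
with a restart (voltage and ion pools are both carried), and the
relaxed state is cached; gating variables start at steady state for
that voltage.

## Synapses and connectivity

AMPA, NMDA, GABA_A and GABA_B synapses are bi-exponential conductance
transients, amplitude-normalized so that a connection's weight equals
its single-spike peak conductance. NMDA carries the standard sigmoidal
Mg2+ block and is scaled to 1/13 of its AMPA companion on every cortical
synapse — the deliberately small ratio that removes the slow periodicity
otherwise contaminating paroxysmal runs. GABA_B activates a 4th-order
G-protein cascade and therefore responds supralinearly to spike trains.
NRT rows are additionally coupled by gap junctions: 3 GΩ to first- and
4.5 GΩ to second-degree neighbours.

Connectivity is topographic: each pathway row (source structure, target
structure, receptor, weight, latency, projection radius P) connects every
source neuron to all targets inside a window of width P centred on its
proportionally mapped position, clipped at the row boundary (a column is
not a torus), with no autapses and at most one synapse per directed pair
and receptor. At reduced scale the radii shrink proportionally and
weights are rescaled by the in-degree ratio so total synaptic drive is
preserved.

Two forms of seeded heterogeneity are deliberate model ingredients:
per-neuron `g_KL` jitter (±10%) and initial-voltage jitter (±3 mV), and
per-synapse weight (±40%) and latency (±0.5 ms) jitter. The few ND
driver cells are exempt from the per-neuron jitter: they act as one
homogeneous pacemaker population, so the reported rhythm does not hinge
on which driver a recording happens to sample. Without them the
deterministic network collapses into stereotyped population spikes; with
them, up-states are sustained by asynchronous recurrent firing. The
network-driver (ND) cells' outgoing excitatory synapses carry a 3×
multiplier — the "driver" phenotype — so that two or three ND cells can
still ignite up-states in a 0.2-scale column.

# How the rhythms arise

* **Slow (<1 Hz) oscillation, isolated cortex.** ND cells are intrinsic
  slow oscillators (`I_h` + `I_HVA` pacemaker pair, up-states terminated
  by `I_K[Ca]`); EF cells are the most excitable followers. An ND burst
  ignites L5, the up-state spreads through the column sustained by
  `I_Na(P)` and recurrent AMPA, and accumulating `I_K[Ca]`, `I_M` and
  `I_K[Na]` terminate it. The inter-cycle interval is governed by the
  slow decay of the EF/ND calcium pools. At 0.35 scale the EEG peaks at
  ~0.45 Hz with exemplar ND up-states of ~200 ms.
* **Delta, isolated cortex.** Reducing `g_KL` of ND cells alone (their
  delta regime also lightens the Ca2+ load per burst) speeds the pacemaker
  so the column cycles in the delta band (~1.7 Hz at 0.35 scale).
* **TC slow and delta.** The relay cell is a relaxation oscillator
  between a hyperpolarized branch and a `I_Na(P)`/window-`I_T` plateau,
  switched by `I_h` and terminated by `I_K[Ca]`; its frequency moves
  smoothly with `g_KL`. Note one honest deviation: in this calibration
  the TC oscillation *slows* as `g_KL` increases, so the delta regime
  uses a lower TC `g_KL` value than the slow regime — the opposite of
  the stated direction of the biological knob (see Limitations).
* **NRT spindles.** With `I_AHP` tripled, the reticular cell cycles
  T-burst → Ca2+ → AHP → rebound at ~10.5 Hz in isolation.
* **Full model.** In the delta regime the thalamus leads: TC_FO bursts
  ignite L4 within ~15 ms, then L2/3, L5, L6, and the higher-order relay
  cells fire only after convergent cortical drive (their regimes hold
  them more hyperpolarized). The same ordering holds for the full-model
  slow rhythm, which runs faster than the isolated cortex — the
  thalamic drive brings each cycle forward.

# Measurement choices

* **Up/down segmentation** fits the two modes of the spike-clipped
  voltage histogram, thresholds midway with 2 mV hysteresis and a 50 ms
  minimum state duration. Deep post-event AHPs can add a third,
  hyperpolarized mode; the detector takes the most depolarized prominent
  mode as the up-state and the most prominent mode at least 4 mV below
  it as the down-state. The network exemplar for up/down statistics is
  the clearest two-state ND (driver) trace — the population where the
  oscillation initiates.
* **Dominant frequency** is the argmax of a Welch-averaged periodogram
  (Hann, 50% overlap, segment length capped at 20 s so slow-band claims
  resolve 0.05 Hz); peak prominence against the band median flags
  noise-like spectra.
* **Cross-correlation bands** come from circular-shift surrogates
  (default 1000; reduced counts in tests), which preserve each signal's
  autocorrelation.
* **Onset latencies** are measured per oscillation cycle (cycle windows
  anchored on the reference population's burst structure); the first
  spike of each population is timed relative to the first TC_FO spike,
  and silent populations yield missing values, never zeros.
* **Bimodality** combines mode separation from a kernel fit with an
  Ashman-D-style statistic from a two-component split; FS interneurons
  correctly fail this test while firing rhythmically.
* **EEG** sums per-neuron dipole (axial inter-compartment) currents
  weighted by a resistive volume-conductor geometry, then applies a
  first-order tissue low-pass. Amplitudes are arbitrary; every
  quantitative claim uses frequency or timing.

# Problem sizes

The package's own analyses run at reduced scale as a deliberate design
choice: the isolated-cortex calibrations use 0.35 × (210 cortical
neurons, ≥60 s), the full model 0.3 × (270 neurons, 30–40 s), the test
fixtures 0.1–0.2 ×. Structural claims are asserted at full scale
(900 neurons). The long (485 s) cross-correlation analyses are supported
by the same functions but validated only qualitatively at reduced
duration.

# What the tests do and do not show

The synthetic generators used in the analysis tests (square waves with
known state durations, pulse trains, shifted rasters, Gaussian mixtures)
establish that the estimators recover ground truth where ground truth
exists. The network assertions establish that the *model* produces the
stated regimes, orderings and pharmacological directionalities at
reduced scale with pinned seeds. They do not show that the biological
cortex works this way, and reduced-scale dynamics are mode-sensitive:
different seeds can settle on neighbouring rhythm modes (the ±0.1 Hz
tolerance on the slow peak absorbs this at 0.35 scale, but it is a real
limitation of desk-scale networks).

# Known limitations

* The printed headline values are mutually inconsistent for a strictly
  alternating oscillation: a 0.44 Hz rhythm cannot have 250 ms up-states
  and 840 ms down-states (that sums to 0.92 Hz). This model matches the
  EEG frequency and the up-state duration; its down-states then last
  ~1.9 s, and the package reports that honestly.
* The TC `g_KL` knob direction is inverted relative to the biology (see
  above); regime names, not knob directions, define the protocols.
* NRT cells lack a true intrinsic slow (<1 Hz) oscillation here: their
  slow-regime up-states are driven, with `I_Na(P)`/`I_CAN` controlling
  up-state duration (the reduction experiment reproduces the stated
  shortening), but the isolated NRT cell does not cycle below 1 Hz.
* Down-states of RS/IB cells are deeper than in vitro (the strong
  adaptation that terminates up-states also produces a pronounced AHP),
  which is why their histograms separate rest from AHP rather than up
  from down; ND/EF traces carry the biological bimodality.
* The ND pacemaker uses `I_h` + `I_HVA` (with the published caveat that
  `I_T` might be the real pacemaker); an `I_T`-based ND variant is not
  implemented.
* No mGluR-dependent conditional-oscillator coupling between cortex and
  thalamic cells; no plasticity; one column; fixed per-pathway latencies.
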
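# ctsim — a conductance-based corticothalamic sleep-wave simulator

`ctsim` is an R package for simulating the EEG rhythms of natural sleep
in a biophysical corticothalamic circuit. It builds a single cortical
column — four layers mixing regular-spiking (RS), intrinsically bursting
(IB), repetitive intrinsically bursting (RIB), early-firing (EF) and
network-driver (ND) pyramidal cells with fast-spiking (FS)
interneurons — reciprocally coupled to first- and higher-order thalamic
relay nuclei (TC) and their reticular (NRT) sectors (900 Hodgkin–Huxley
neurons at full scale). Cortical cells are two-compartment, thalamic
cells single-compartment; the membrane current inventory includes the
T-type calcium current with its window component, persistent sodium,
I_h, and calcium- and sodium-activated potassium currents.

The organising idea: a single parameter, the potassium leak conductance
`g_KL` (the model's proxy for wake–sleep neuromodulation), moves the
network through wake-like desynchronization, sleep spindles
(6.5–16 Hz), the slow (<1 Hz) oscillation with its up/down states, and
delta waves (1–4 Hz). The package bundles the simulator (Rcpp core), an
EEG estimator from transmembrane dipole currents, the analysis suite
(up/down segmentation, Welch spectra, autocorrelograms, surrogate-based
cross-correlations, onset-latency tables), and scripted protocols that
reproduce each regime end to end.

## A worked example

Simulate the isolated cortical column in its slow-oscillation regime at
0.35 scale for 64 s, estimate the EEG, and segment the clearest driver
(ND) membrane-potential trace:

```r
library(ctsim)
r <- run_protocol("isolated_cortex_slow", scale = 0.35,
                  duration_s = 64, seed = 1)
print(r)
#> <ctsim_protocol_result> isolated_cortex_slow | seed 1
#>   EEG dominant frequency: 0.45 Hz
#>   up 202 ms / down 1958 ms
```

The EEG's dominant spectral peak sits in the slow (<1 Hz) band at
0.45 Hz, and the exemplar L5 driver cell alternates between ~200 ms
depolarized up-states and ~2 s hyperpolarized down-states. Switching the
drivers to their delta regime (`run_protocol("isolated_cortex_delta",
...)`) moves the same column into the delta band, and
`run_protocol("full_model_delta", scale = 0.3, duration_s = 30)` yields
the thalamus-led delta rhythm, whose onset-latency table shows L4
pyramids following the first TC_FO spike of each cycle by ~15 ms:

```r
fd <- run_protocol("full_model_delta", scale = 0.3, duration_s = 26)
sort(fd$latency$median_ms)
#>  TC_FO  L4_PY  L4_IN NRT_FO L23_PY ...
#>    0.0   12.1   12.7   14.4   21.4 ...
```

Single cells are available through the same interface:
`run_protocol("single_nrt_spindle")` returns an isolated reticular cell
oscillating at ~10.5 Hz (classified `spindling`), and
`build_cell()` / `simulate_current_clamp()` / `fI_curve()` expose the
cell catalog directly.

A thin command-line front end ships in `inst/cli/ctsim`
(`ctsim list-protocols`, `ctsim run --protocol full_model_slow ...`).

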
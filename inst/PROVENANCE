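Provenance of model formulations
================================

The published description of this corticothalamic model defers all channel
equations, conductance tables, connectivity tables and regime values to
supplementary material that is not distributed with the text. This package
therefore transcribes the canonical formulations of the thalamocortical
modelling literature that this model family derives from, and calibrates
their densities against the behaviours the main text states. Every
coefficient is data in R/channels.R, R/cells.R and R/network.R.

Kinetic forms adopted (all at ~36 C, Q10 folded into the time constants):
 - transient Na+ / delayed-rectifier K+: Traub-Miles rate forms with a
   per-structure voltage shift
 - persistent Na+: single Boltzmann activation, fast tau
 - A-type K+: Huguenard-McCormick m^4 h
 - M-type K+: first-order Mainen-style rates
 - Ca2+-activated K+ (cortical I_K[Ca] and reticular fast I_AHP):
   second-order Ca2+ on-rate, first-order gate
 - Na+-activated K+: instantaneous sigmoidal dependence on [Na]_i
 - T-type Ca2+: Huguenard-McCormick relay kinetics (with an inactivation
   midpoint/slope chosen to yield a functional window current) and
   Huguenard-Prince reticular kinetics; constant Ca2+ reversal (no GHK)
 - high-voltage-activated Ca2+: Reuveni-style m^2 h
 - I_h: Huguenard-McCormick; a slower, more depolarized variant serves as
   the pacemaker current of the cortical driver (ND) and early-firing (EF)
   pyramids
 - I_CAN: Hill (n=2) Ca2+ activation with Ca2+-accelerated time constant
 - GABA_B: 4th-order G-protein cascade on a bi-exponential transmitter
   drive (Destexhe-style)
 - intracellular Ca2+/Na+ pools: linear influx + first-order removal

Deliberate departures recorded here:
 - the EEG estimator treats each two-compartment cortical cell as a
   current dipole (axial current between the compartments) seen through a
   resistive volume conductor with a first-order tissue low-pass; sources
   and electrode placement are configurable
 - synaptic weights, projection radii and latencies in R/network.R are
   package defaults calibrated to reproduce the stated network behaviours,
   not transcriptions
 - network-driver (ND) outgoing excitatory synapses carry a 3x weight
   multiplier (driver phenotype) so their intrinsic bursts reliably ignite
   up-states at reduced network scale
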
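# Chemical synapse reference model and gap junctions.
#
# The network engine integrates synapses as aggregated bi-exponential
# conductance states; the functions here are the module's reference
# implementation (used directly for single-synapse work and as the oracle
# the engine is tested against): event-driven conductance transients,
# receptor currents with the NMDA Mg2+ block, the 4th-order G-protein
# cascade of GABA_B, and resistive gap junctions.

#' Synapse specification
#'
#' @param receptor One of `"AMPA"`, `"NMDA"`, `"GABA_A"`, `"GABA_B"`.
#' @param weight_nS Peak conductance (nS); for GABA_B the saturating
#'   conductance of the target's GABA_B pool.
#' @param latency_ms Transmission latency (> 0).
#' @param reversal_mV Optional reversal override (defaults per receptor).
#' @export
synapse_spec <- function(receptor = c("AMPA", "NMDA", "GABA_A", "GABA_B"),
                         weight_nS, latency_ms = 1,
                         reversal_mV = NULL) {
  receptor <- match.arg(receptor)
  kk <- SYN_KINETICS[[receptor]]
  stopifnot(weight_nS >= 0, latency_ms > 0,
            kk[["tau_d"]] > kk[["tau_r"]], kk[["tau_r"]] > 0)
  structure(list(receptor = receptor, weight_nS = weight_nS,
                 latency_ms = latency_ms,
                 tau_r = kk[["tau_r"]], tau_d = kk[["tau_d"]],
                 reversal_mV = if (is.null(reversal_mV)) kk[["e"]]
                               else reversal_mV),
            class = "ctsim_synapse")
}

#' Time-to-peak of the bi-exponential conductance transient (ms)
#' @param tau_r,tau_d Rise and decay time constants (ms).
#' @export
psp_peak_time <- function(tau_r, tau_d) {
  tau_r * tau_d / (tau_d - tau_r) * log(tau_d / tau_r)
}

#' Conductance time course for a presynaptic spike train
#'
#' Events are delivered `latency_ms` after each spike and sum linearly;
#' the transient is amplitude-normalized so a single spike peaks at
#' `weight_nS`. For GABA_B the summed transient drives the (nonlinear)
#' G-protein cascade: `dG/dt = k3 s - k4 G`, conductance
#' `= weight * G^4 / (G^4 + Kd)`, which responds supralinearly to spike
#' trains.
#'
#' @param spec A [synapse_spec()].
#' @param spike_times_ms Presynaptic spike times (ms).
#' @param t_ms Evaluation time grid (ms), regular.
#' @return Conductance (nS) at `t_ms`.
#' @export
synaptic_conductance <- function(spec, spike_times_ms, t_ms) {
  stopifnot(inherits(spec, "ctsim_synapse"))
  if (any(diff(t_ms) <= 0)) stop("time grid must increase", call. = FALSE)
  tp <- psp_peak_time(spec$tau_r, spec$tau_d)
  norm <- 1 / (exp(-tp / spec$tau_d) - exp(-tp / spec$tau_r))
  g <- numeric(length(t_ms))
  for (ts in spike_times_ms + spec$latency_ms) {
    dtp <- t_ms - ts
    on <- dtp >= 0
    g[on] <- g[on] + norm * (exp(-dtp[on] / spec$tau_d) -
                               exp(-dtp[on] / spec$tau_r))
  }
  if (spec$receptor == "GABA_B") {
    dt <- t_ms[2] - t_ms[1]
    k3 <- GABAB_PARAMS[["k3"]]; k4 <- GABAB_PARAMS[["k4"]]
    kd <- GABAB_PARAMS[["kd4"]]
    G <- 0
    out <- numeric(length(g))
    for (i in seq_along(g)) {
      G <- G + dt * (k3 * g[i] - k4 * G)
      out[i] <- spec$weight_nS * G^4 / (G^4 + kd)
    }
    out
  } else {
    spec$weight_nS * g
  }
}

#' Voltage dependence of the NMDA Mg2+ block
#'
#' Monotone relief of the block with depolarization (0 at strong
#' hyperpolarization, 1 at strong depolarization; 1 mM Mg2+).
#' @param V Membrane potential (mV).
#' @export
mg_block <- function(V) 1 / (1 + 0.278 * exp(-0.062 * V))

#' Synaptic current (nA)
#'
#' Zero at the reversal potential; NMDA is additionally scaled by
#' [mg_block()].
#'
#' @param spec A [synapse_spec()].
#' @param g_nS Instantaneous conductance (nS).
#' @param V_post Postsynaptic potential (mV).
#' @export
synaptic_current <- function(spec, g_nS, V_post) {
  b <- if (spec$receptor == "NMDA") mg_block(V_post) else 1
  g_nS * 1e-3 * b * (V_post - spec$reversal_mV)  # uS * mV = nA
}

#' Gap-junction current (nA, into neuron i)
#'
#' Ohmic and antisymmetric: `I_i = (V_j - V_i) / R`.
#'
#' @param V_i,V_j Membrane potentials (mV).
#' @param resistance_GOhm Junction resistance (> 0), e.g. 3 for
#'   first-degree and 4.5 for second-degree NRT neighbours.
#' @export
gap_junction_current <- function(V_i, V_j, resistance_GOhm) {
  if (any(resistance_GOhm <= 0))
    stop("gap junction resistance must be positive", call. = FALSE)
  (V_j - V_i) * 1e-3 / resistance_GOhm  # mV/GOhm = pA -> nA
}
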
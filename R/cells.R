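# Cell-type catalog and single-cell operations.
#
# Cortical neurons are two-compartment (axosomatic + dendritic)
# Hodgkin-Huxley models; thalamic relay (TC) and reticular (NRT) neurons are
# single-compartment. The potassium leak conductance g_KL is the
# neuromodulatory dial: each cell type carries a named map of regime ->
# g_KL density, and some regimes additionally scale a channel (the spindle
# regime increases I_AHP in NRT cells).

CELL_TYPES <- c("RS", "IB", "EF", "RIB", "ND", "FS",
                "TC_FO", "TC_HO", "NRT_FO", "NRT_HO")

# canonical channel id codes (perturbation scope); order is part of the ABI
CHANNEL_IDS <- c("I_Na_transient", "I_K_dr", "I_Na(P)", "I_A", "I_M",
                 "I_K[Ca]", "I_K[Na]", "I_T", "I_HVA", "I_h", "I_CAN",
                 "I_AHP", "leak_K", "leak_mixed")

RECEPTORS <- c("AMPA", "NMDA", "GABA_A", "GABA_B")

#' Cell parameter catalog
#'
#' Per-compartment channel conductance densities (S/cm^2), compartment
#' geometry, ion-pool parameters and the named g_KL regime map for each of
#' the ten cell types.
#'
#' @return Named list of cell parameter sets.
#' @export
cell_catalog <- function() {
  if (!is.null(.ctsim_cache$cells)) return(.ctsim_cache$cells)

  # cortical compartment template; areas in cm^2 (soma 1e-5 = 1000 um^2)
  cx <- function(rho, g_c, soma, dend, ca_tau = 150, na_tau = 2000,
                 regimes, scales = list(), excit = TRUE, el = -70) {
    list(
      compartments = 2L,
      g_c = g_c,
      comps = list(
        soma = list(area = 1e-5, cm = 1, el = el, channels = soma,
                    pools = list(
                      Na_i = c(rest = 10, phi = 0.05, tau = na_tau))),
        dend = list(area = rho * 1e-5, cm = 1, el = el, channels = dend,
                    pools = list(
                      Ca_i = c(rest = 2.4e-4, phi = 0.0518, tau = ca_tau),
                      Na_i = c(rest = 10, phi = 0.05, tau = na_tau)))
      ),
      g_KL = regimes, regime_scales = scales, excitatory = excit
    )
  }

  # thalamic single compartment
  th <- function(area, chans, pools, regimes, scales = list(), el = -70) {
    list(
      compartments = 1L,
      g_c = 0,
      comps = list(soma = list(area = area, cm = 1, el = el,
                               channels = chans, pools = pools)),
      g_KL = regimes, regime_scales = scales, excitatory = FALSE
    )
  }

  cat <- list()

  # --- cortical excitatory types -----------------------------------------
  # regimes: silent > slow_osc/spindle > breakdown > wake (decreasing g_KL);
  # values are dendritic g_KL densities (S/cm^2).
  rs_regimes <- c(silent = 6e-5, spindle = 6.5e-6, slow_osc = 6.5e-6,
                  delta = 6.5e-6, breakdown = 4.5e-6, wake = 2e-6)

  cat$RS <- cx(
    rho = 16.5, g_c = 0.1,
    soma = list(na_cx = 1.0, kdr_cx = 0.15, km = 1e-3, kna = 3e-4,
                nap = 6e-5, leak = 1e-5),
    dend = list(na_cx = 8e-4, kdr_cx = 2.5e-3, nap = 6e-5, ka = 1.5e-3,
                km = 1.2e-5, kca = 4.5e-4, kna = 2.2e-4, hva = 1e-4,
                leak = 2.2e-5),
    regimes = rs_regimes
  )

  cat$IB <- cx(
    rho = 12, g_c = 0.13,
    soma = list(na_cx = 1.0, kdr_cx = 0.15, km = 5e-4, kna = 2e-4,
                nap = 6e-5, leak = 1e-5),
    dend = list(na_cx = 8e-4, kdr_cx = 2.5e-3, nap = 6.5e-5, ka = 1.2e-3,
                km = 9e-6, kca = 2.8e-4, kna = 1.8e-4, hva = 2.5e-4,
                leak = 2.0e-5),
    regimes = rs_regimes
  )

  cat$RIB <- cx(
    rho = 12, g_c = 0.13,
    soma = list(na_cx = 1.0, kdr_cx = 0.15, km = 5e-4, kna = 2e-4,
                nap = 7e-5, leak = 1e-5),
    dend = list(na_cx = 8e-4, kdr_cx = 2.5e-3, nap = 6.5e-5, ka = 1.1e-3,
                km = 7e-6, kca = 3.2e-4, kna = 1.8e-4, hva = 2.5e-4,
                leak = 2.0e-5),
    ca_tau = 60,
    regimes = rs_regimes
  )

  # Early-firing pyramidal cell: strong persistent Na+ and an I_h sag give
  # it the lowest effective threshold at up-state onset.
  cat$EF <- cx(
    rho = 15, g_c = 0.1,
    soma = list(na_cx = 1.0, kdr_cx = 0.15, km = 8e-4, kna = 2.5e-4,
                nap = 8e-5, leak = 1e-5),
    dend = list(na_cx = 8e-4, kdr_cx = 2.5e-3, nap = 8e-5, ka = 1.3e-3,
                km = 1.0e-5, kca = 4e-4, kna = 2.5e-4, hva = 1e-4,
                ih_nd = 4e-5, leak = 2.0e-5),
    ca_tau = 550,
    regimes = c(silent = 7e-5, spindle = 1.4e-5, slow_osc = 1.4e-5,
                delta = 1.4e-5, breakdown = 1.4e-5, wake = 5e-6)
  )

  # Network-driver pyramidal cell: I_h and I_HVA are the pacemaker pair;
  # Ca2+-activated K+ terminates its up-state. Oscillates intrinsically in
  # the slow-oscillation regime and speeds into the delta band when its
  # g_KL is reduced further.
  cat$ND <- cx(
    rho = 15, g_c = 0.1,
    soma = list(na_cx = 1.0, kdr_cx = 0.15, km = 3e-4, kna = 1e-4,
                nap = 7e-5, leak = 1e-5),
    dend = list(na_cx = 8e-4, kdr_cx = 2.5e-3, nap = 6e-5, ka = 1.0e-3,
                km = 8e-6, kca = 6e-4, kna = 5e-5, hva = 3e-4,
                ih_nd = 3e-4, leak = 2.0e-5),
    ca_tau = 750,
    regimes = c(silent = 9e-5, spindle = 2.6e-5, slow_osc = 2.6e-5,
                delta = 6.5e-6, breakdown = 2.6e-5, wake = 2.6e-5),
    scales = list(delta = c("I_HVA" = 0.45, "I_K[Ca]" = 0.6))
  )

  # Fast-spiking interneuron: fast spike kinetics, no adaptation currents;
  # its membrane potential lacks clear bimodality during slow oscillations.
  cat$FS <- cx(
    rho = 5, g_c = 0.2,
    soma = list(na_fs = 1.5, kdr_fs = 0.3, leak = 1.5e-5),
    dend = list(na_fs = 6e-4, kdr_fs = 2.5e-3, ka = 5e-4, leak = 3.0e-5),
    ca_tau = 50, na_tau = 300,
    regimes = c(silent = 6e-5, spindle = 1.2e-5, slow_osc = 1.2e-5,
                delta = 1.2e-5, breakdown = 8e-6, wake = 3e-6),
    excit = FALSE
  )

  # --- thalamic types -----------------------------------------------------
  tc_regimes <- c(silent = 3e-5, wake = 2e-5,
                  spindle = 2.6e-5, slow_osc = 2.0e-5, delta = 1.75e-5)
  tc <- th(
    area = 2.9e-4,
    chans = list(na_th = 0.09, kdr_th = 0.01, it_tc = 2.2e-3, ih = 4.5e-5,
                 ka = 8e-4, nap = 8e-6, can = 4.0e-5, kca = 1.5e-4,
                 leak = 5.0e-6),
    pools = list(Ca_i = c(rest = 2.4e-4, phi = 0.0518, tau = 250),
                 Na_i = c(rest = 10, phi = 0.01, tau = 600)),
    regimes = tc_regimes
  )
  cat$TC_FO <- tc
  # higher-order relay cells: identical machinery, but held more
  # hyperpolarized in the sleep regimes so that rebound firing requires
  # convergent corticothalamic drive (they fire after the cortex)
  tc_ho <- tc
  tc_ho$g_KL <- c(silent = 3e-5, wake = 2e-5, spindle = 2.6e-5,
                  slow_osc = 2.6e-5, delta = 1.6e-5)
  cat$TC_HO <- tc_ho

  nrt_regimes <- c(silent = 3e-5, wake = 4e-6,
                   spindle = 1.6e-5, slow_osc = 3.2e-5, delta = 1.8e-5)
  nrt <- th(
    area = 1.43e-4,
    chans = list(na_th = 0.1, kdr_th = 0.01, it_nrt = 2.8e-3, ahp = 3.0e-4,
                 can = 4.0e-5, nap = 1.0e-5, leak = 2.2e-5),
    pools = list(Ca_i = c(rest = 2.4e-4, phi = 0.0518, tau = 40),
                 Na_i = c(rest = 10, phi = 0.01, tau = 600)),
    regimes = nrt_regimes,
    scales = list(spindle = c("I_AHP" = 3),
                  delta = c("I_AHP" = 2),
                  slow_osc = c("I_AHP" = 1.5, "I_Na(P)" = 2,
                               "I_CAN" = 2)),
    el = -77
  )
  cat$NRT_FO <- nrt
  cat$NRT_HO <- nrt

  for (nm in names(cat)) cat[[nm]]$cell_type <- nm
  .ctsim_cache$cells <- cat
  cat
}

# Resolve a cell type + regime (+ overrides) into the per-compartment
# channel list actually simulated: adds the leak_k channel at the regime's
# g_KL and applies any regime channel scalings.
.resolve_cell <- function(cell_type, regime = "slow_osc", overrides = list(),
                          gkl_scale = 1) {
  cc <- cell_catalog()
  if (!cell_type %in% names(cc))
    stop("unknown cell type: ", cell_type, call. = FALSE)
  p <- cc[[cell_type]]
  for (nm in names(overrides)) {
    # overrides address parameters by dotted path, e.g. "dend.kca" or "g_c"
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    if (length(parts) == 1 && parts == "g_c") {
      p$g_c <- overrides[[nm]]
    } else if (length(parts) == 2 && parts[1] %in% names(p$comps)) {
      if (!parts[2] %in% names(p$comps[[parts[1]]]$channels) &&
          !parts[2] %in% c("area", "cm", "el"))
        stop("unknown parameter: ", nm, call. = FALSE)
      if (parts[2] %in% c("area", "cm", "el"))
        p$comps[[parts[1]]][[parts[2]]] <- overrides[[nm]]
      else p$comps[[parts[1]]]$channels[[parts[2]]] <- overrides[[nm]]
    } else stop("unknown parameter: ", nm, call. = FALSE)
  }
  if (!regime %in% names(p$g_KL))
    stop("cell type ", cell_type, " has no regime '", regime, "'",
         call. = FALSE)
  gkl <- p$g_KL[[regime]] * gkl_scale
  scales <- p$regime_scales[[regime]]
  catalog <- channel_catalog()
  for (cn in names(p$comps)) {
    p$comps[[cn]]$channels$leak_k <- gkl
    if (!is.null(scales)) {
      for (id in names(scales)) {
        for (vn in names(p$comps[[cn]]$channels)) {
          if (vn %in% names(catalog) && catalog[[vn]]$id == id)
            p$comps[[cn]]$channels[[vn]] <-
              p$comps[[cn]]$channels[[vn]] * scales[[id]]
        }
      }
    }
  }
  p$regime <- regime
  p
}

#' Build a cell instance
#'
#' Resolves the parameter set for a cell type in a named g_KL regime and
#' initializes it at the regime's relaxed membrane potential (found by a
#' short free run; gating variables start at steady state for that voltage).
#'
#' @param cell_type One of the catalog types (see `CELL_TYPES`).
#' @param overrides Named list of parameter overrides addressed by dotted
#'   path (e.g. `list("dend.kca" = 2e-4, g_c = 0.15)`).
#' @param regime Named g_KL regime.
#' @param relax_s Relaxation horizon in seconds used to find the initial
#'   state (set 0 to start at the nominal resting potential).
#' @return A `ctsim_cell` object.
#' @export
build_cell <- function(cell_type, overrides = list(), regime = "slow_osc",
                       relax_s = 5) {
  p <- .resolve_cell(cell_type, regime, overrides)
  key <- paste0(cell_type, "|", regime, "|",
                paste(names(overrides), unlist(overrides), collapse = ","))
  st <- .ctsim_cache$vrest[[key]]
  if (is.null(st)) {
    v0 <- rep(p$comps[[1]]$el, 2)
    pools0 <- NULL
    if (relax_s > 0) {
      # iterated relaxation carrying the full state (voltage and ion
      # pools) between passes, so the cell starts at its joint equilibrium
      for (pass in 1:4) {
        cell0 <- structure(list(params = p, v0 = v0, pools0 = pools0),
                           class = "ctsim_cell")
        tr <- simulate_current_clamp(cell0, protocol = NULL,
                                     duration_s = relax_s, dt = 0.025)
        dv <- max(abs(tr$v_final[1:2] - v0))
        v0 <- tr$v_final
        pools0 <- tr$pools_final
        if (dv < 0.005) break
      }
    }
    st <- list(v0 = v0, pools0 = pools0)
    if (is.null(.ctsim_cache$vrest)) .ctsim_cache$vrest <- list()
    .ctsim_cache$vrest[[key]] <- st
  }
  structure(list(params = p, v0 = st$v0, pools0 = st$pools0,
                 cell_type = cell_type, regime = regime),
            class = "ctsim_cell")
}

#' @export
print.ctsim_cell <- function(x, ...) {
  cat("<ctsim_cell>", x$params$cell_type, "| regime:", x$params$regime,
      "|", x$params$compartments, "compartment(s)\n")
  invisible(x)
}

#' Current-clamp simulation of a single cell
#'
#' @param cell A `ctsim_cell` from [build_cell()].
#' @param protocol Data frame (or NULL) with columns `t_start`, `t_end`
#'   (seconds) and `amplitude` (nA, somatic injection). Intervals must not
#'   overlap.
#' @param duration_s Total simulated time (s).
#' @param dt Time step (ms).
#' @param record_currents Record per-channel current traces.
#' @return List with `t` (s), `v` (somatic mV), `v_dend` (or NULL),
#'   `spikes` (s), `currents` (optional matrix), `v_final`.
#' @export
simulate_current_clamp <- function(cell, protocol = NULL, duration_s = 10,
                                   dt = 0.025, record_currents = FALSE) {
  stopifnot(inherits(cell, "ctsim_cell"), duration_s > 0, dt > 0)
  if (!is.null(protocol) && nrow(protocol) > 1) {
    o <- order(protocol$t_start)
    protocol <- protocol[o, ]
    if (any(protocol$t_start[-1] < protocol$t_end[-nrow(protocol)]))
      stop("overlapping injection intervals", call. = FALSE)
  }
  if (!is.null(protocol) &&
      any(protocol$t_end > duration_s | protocol$t_start < 0))
    stop("injection interval outside simulation window", call. = FALSE)

  net <- .single_cell_net(cell)
  sim <- sim_config(duration_s = duration_s, dt = dt,
                    record = list(voltage = 1L,
                                  dend_of = if (cell$params$compartments == 2)
                                    1L else integer(),
                                  currents = if (record_currents) 1L
                                             else integer()))
  inj <- if (is.null(protocol)) NULL else
    data.frame(neuron = 1L, comp = 0L, t0 = protocol$t_start * 1e3,
               t1 = protocol$t_end * 1e3, amp = protocol$amplitude)
  tr <- run_simulation(net, sim, injections = inj)
  list(t = tr$t, v = tr$v[, 1],
       v_dend = if (is.null(tr$v_dend)) NULL else tr$v_dend[, 1],
       spikes = tr$spikes$t[tr$spikes$id == 1L],
       currents = tr$currents, current_labels = tr$current_labels,
       v_final = tr$v_final[1:2],
       pools_final = list(ca = tr$pools_final$ca[1:2],
                          na = tr$pools_final$na[1:2]))
}

# wrap one resolved cell into a minimal network graph
.single_cell_net <- function(cell) {
  neurons <- data.frame(
    id = 1L, cell_type = cell$params$cell_type,
    sector = "single", subsector = "single", pos = 1L,
    pop = cell$params$cell_type, stringsAsFactors = FALSE)
  structure(list(
    neurons = neurons,
    edges = .empty_edges(),
    gap_junctions = data.frame(i = integer(), j = integer(),
                               resistance_GOhm = numeric()),
    cells = list(cell$params),
    v0 = list(cell$v0),
    pools0 = if (is.null(cell$pools0)) NULL else
      list(ca = cell$pools0$ca[1:2], na = cell$pools0$na[1:2]),
    meta = list(seed = NA_integer_, scale = 1, regime = cell$params$regime)
  ), class = "ctsim_network")
}

#' Classify the firing pattern of a trace
#'
#' Heuristic classification used to constrain the cell models: burst
#' signatures (decelerando / accelerando-decelerando), tonic firing,
#' quiescence, and slow (<1 Hz), delta (1-4 Hz) or spindle-frequency
#' (6.5-16 Hz) rhythmic bursting.
#'
#' @param t Time base (s).
#' @param v Membrane potential (mV).
#' @param spikes Spike times (s).
#' @param burst_isi Maximum intra-burst inter-spike interval (s).
#' @return List with `label` and `features` (inter-burst frequency, mean
#'   intra-burst ISI sequence, up-state fraction).
#' @export
classify_firing_pattern <- function(t, v, spikes, burst_isi = 0.015) {
  if (length(t) == 0) stop("empty trace", call. = FALSE)
  feats <- list()
  if (length(spikes) == 0) {
    label <- if (stats::sd(v) < 1.5) "quiescent" else "subthreshold_oscillation"
    return(list(label = label, features = feats))
  }
  isi <- diff(spikes)
  # group spikes into bursts
  brk <- c(0, which(isi > burst_isi * 2.5), length(spikes))
  bursts <- mapply(function(a, b) spikes[(a + 1):b],
                   brk[-length(brk)], brk[-1], SIMPLIFY = FALSE)
  nb <- length(bursts)
  burst_sizes <- vapply(bursts, length, 1L)
  feats$n_bursts <- nb
  feats$burst_sizes <- burst_sizes
  if (nb >= 2) {
    ibi <- diff(vapply(bursts, function(b) b[1], 1))
    feats$interburst_freq <- 1 / stats::median(ibi)
  }
  # up-state fraction: time above midpoint between the two Vm modes
  thr <- mean(range(v[v < 0]))
  feats$up_fraction <- mean(v > thr)

  if (all(burst_sizes == 1)) {
    cv <- stats::sd(isi) / mean(isi)
    if (length(spikes) >= 5 && (is.na(cv) || cv < 0.35))
      return(list(label = "tonic", features = feats))
  }
  if (nb >= 3 && !is.null(feats$interburst_freq)) {
    f <- feats$interburst_freq
    if (f >= 6.5 && f <= 16)
      return(list(label = "spindling", features = feats))
    if (f >= 1 && f < 5)
      return(list(label = "oscillating_delta", features = feats))
    if (f < 1)
      return(list(label = "oscillating_slow", features = feats))
  }
  # single-burst signature
  big <- bursts[burst_sizes >= 3]
  if (length(big) > 0) {
    bi <- diff(big[[1]])
    feats$intraburst_isi <- bi
    dmin <- which.min(bi)
    if (dmin == 1 && all(diff(bi) >= -1e-9))
      return(list(label = "burst_decelerando", features = feats))
    if (dmin > 1)
      return(list(label = "burst_accelerando_decelerando", features = feats))
  }
  list(label = "tonic", features = feats)
}

#' Steady-state frequency-current curve
#'
#' @param cell A `ctsim_cell`.
#' @param amplitudes Injection amplitudes (nA), sorted.
#' @param duration_s Step duration per amplitude (s); the rate is measured
#'   over the second half of the step.
#' @param dt Time step (ms).
#' @return data.frame with `amplitude_nA` and `rate_Hz`.
#' @export
fI_curve <- function(cell, amplitudes, duration_s = 2, dt = 0.025) {
  stopifnot(all(is.finite(amplitudes)), !is.unsorted(amplitudes))
  rates <- vapply(amplitudes, function(a) {
    tr <- simulate_current_clamp(
      cell, protocol = data.frame(t_start = 0, t_end = duration_s,
                                  amplitude = a),
      duration_s = duration_s, dt = dt)
    sum(tr$spikes > duration_s / 2) / (duration_s / 2)
  }, 1)
  data.frame(amplitude_nA = amplitudes, rate_Hz = rates)
}
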
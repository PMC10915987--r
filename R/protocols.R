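# Scripted experiments: named protocols that build a network, run it,
# compute the EEG and the standard analyses, and return a result bundle.

.pop_label <- function(neurons) {
  ifelse(grepl("^L", neurons$subsector),
         paste0(sub("[ei]$", "", neurons$subsector),
                ifelse(grepl("i$", neurons$subsector), "_IN", "_PY")),
         neurons$subsector)
}

.blockade <- function(target, kind = "channel", factor = 0,
                      population = NA_character_, time_s = 0) {
  data.frame(time_s = time_s, kind = kind, target = target,
             population = population, factor = factor,
             stringsAsFactors = FALSE)
}

# non-ND populations of a graph (for channel blocks sparing the network
# drivers, as in the up-state pharmacology experiments)
.non_nd_pops <- function(graph) {
  setdiff(unique(graph$neurons$pop),
          unique(graph$neurons$pop[graph$neurons$cell_type == "ND"]))
}

#' List registered protocols
#' @export
list_protocols <- function() {
  c("isolated_cortex_silent", "isolated_cortex_slow",
    "isolated_cortex_delta", "isolated_cortex_breakdown",
    "isolated_cortex_wake",
    "single_tc_tonic", "single_tc_slow", "single_tc_delta",
    "single_nrt_spindle", "single_nrt_slow", "single_nd_slow",
    "single_nd_delta",
    "full_model_slow", "full_model_delta", "full_model_spindles",
    "blockade_gabaa", "blockade_gabab", "blockade_ampa", "blockade_nmda",
    "blockade_ikna", "blockade_ikca", "blockade_im", "blockade_inap",
    "blockade_it_hva_ih_nonnd")
}

.protocol_spec <- function(name) {
  single <- function(ct, regime) list(kind = "single", cell = ct,
                                      regime = regime)
  cortex <- function(regime, blocks = NULL, nonnd = FALSE)
    list(kind = "network", structures = cortical_structures(),
         regimes = c(cortex = regime), blocks = blocks, nonnd = nonnd)
  full <- function(cx, th) list(kind = "network", structures = STRUCTURES,
                                regimes = c(cortex = cx, thalamus = th))
  switch(name,
    isolated_cortex_silent = cortex("silent"),
    isolated_cortex_slow = cortex("slow_osc"),
    isolated_cortex_delta = cortex("delta"),
    isolated_cortex_breakdown = cortex("breakdown"),
    isolated_cortex_wake = cortex("wake"),
    single_tc_tonic = single("TC_FO", "wake"),
    single_tc_slow = single("TC_FO", "slow_osc"),
    single_tc_delta = single("TC_FO", "delta"),
    single_nrt_spindle = single("NRT_FO", "spindle"),
    single_nrt_slow = single("NRT_FO", "slow_osc"),
    single_nd_slow = single("ND", "slow_osc"),
    single_nd_delta = single("ND", "delta"),
    full_model_slow = full("slow_osc", "slow_osc"),
    full_model_delta = full("slow_osc", "delta"),
    full_model_spindles = full("spindle", "spindle"),
    blockade_gabaa = cortex("slow_osc",
                            .blockade("GABA_A", kind = "receptor")),
    blockade_gabab = cortex("slow_osc",
                            .blockade("GABA_B", kind = "receptor")),
    blockade_ampa = cortex("slow_osc",
                           .blockade("AMPA", kind = "receptor")),
    blockade_nmda = cortex("slow_osc",
                           .blockade("NMDA", kind = "receptor")),
    blockade_ikna = cortex("slow_osc", .blockade("I_K[Na]")),
    blockade_ikca = cortex("slow_osc", .blockade("I_K[Ca]"),
                           nonnd = TRUE),
    blockade_im = cortex("slow_osc", .blockade("I_M")),
    blockade_inap = cortex("slow_osc", .blockade("I_Na(P)")),
    blockade_it_hva_ih_nonnd = cortex(
      "slow_osc",
      rbind(.blockade("I_T"), .blockade("I_HVA"), .blockade("I_h")),
      nonnd = TRUE),
    stop("unknown protocol '", name, "'; available:\n  ",
         paste(list_protocols(), collapse = "\n  "), call. = FALSE)
  )
}

#' Run a registered protocol
#'
#' Builds the configured model (network or single cell), simulates it,
#' estimates the EEG (network protocols), and attaches standard analyses:
#' dominant frequency, up/down segmentation of an exemplar pyramidal
#' trace, firing-pattern classification (single-cell protocols) and the
#' population onset-latency table (full-model protocols).
#'
#' @param name Protocol name (see [list_protocols()]).
#' @param scale Network scale factor.
#' @param duration_s Simulated time (s).
#' @param seed Seed for network construction.
#' @param settle_s Initial transient excluded from analyses (s).
#' @param overrides Named list forwarded to [build_cell()] for single-cell
#'   protocols.
#' @return A `ctsim_protocol_result` bundle.
#' @export
run_protocol <- function(name, scale = 0.2, duration_s = 40, seed = 1,
                         settle_s = 8, overrides = list()) {
  spec <- .protocol_spec(name)
  out <- list(name = name, seed = seed, scale = scale,
              duration_s = duration_s, settle_s = settle_s)

  if (spec$kind == "single") {
    cell <- build_cell(spec$cell, regime = spec$regime,
                       overrides = overrides)
    tr <- simulate_current_clamp(cell, NULL, duration_s = duration_s)
    sel <- tr$t >= settle_s
    cls <- classify_firing_pattern(tr$t[sel], tr$v[sel],
                                   tr$spikes[tr$spikes >= settle_s])
    out$trace <- tr
    out$classification <- cls
    out$cell <- cell
  } else {
    cfg <- network_config(scale = scale, structures = spec$structures,
                          regimes = spec$regimes, seed = seed)
    net <- build_network(cfg)
    pert <- spec$blocks
    if (!is.null(pert) && isTRUE(spec$nonnd)) {
      pert <- do.call(rbind, lapply(.non_nd_pops(net), function(p) {
        q <- pert; q$population <- p; q
      }))
    }
    sim <- sim_config(duration_s = duration_s,
                      record = list(voltage = "all", dipole = TRUE),
                      perturbations = pert, seed = seed)
    tr <- run_simulation(net, sim)
    eeg <- compute_eeg(tr)
    sel <- tr$t >= settle_s
    out$network <- net
    out$trace <- tr
    out$eeg <- eeg
    sig <- eeg$signal[sel]
    out$eeg_peak <- tryCatch(
      dominant_frequency(sig, eeg$fs_Hz, band = c(0.2, 6)),
      error = function(e) NULL)
    # exemplar pyramidal trace for up/down statistics: the slow
    # oscillation initiates in the network-driver pyramids of L5, whose
    # traces show the crispest two-state plateaus; among them take the
    # cell with the most depolarized up-state mode (fall back to
    # early-firing pyramids, then any excitatory cell)
    nn <- net$neurons
    cand <- which(nn$cell_type == "ND")
    if (!length(cand)) cand <- which(nn$cell_type == "EF")
    if (!length(cand)) cand <- which(!nn$cell_type %in% "FS")[1]
    best <- cand[1]; best_mode <- -Inf
    for (i in cand) {
      ud <- tryCatch(detect_up_down_states(tr$t[sel], tr$v[sel, i]),
                     error = function(e) NULL)
      if (!is.null(ud) && !ud$degenerate && length(ud$modes) == 2 &&
          ud$modes[2] > best_mode) {
        best <- i; best_mode <- ud$modes[2]
      }
    }
    out$exemplar_id <- best
    out$updown <- tryCatch(
      detect_up_down_states(tr$t[sel], tr$v[sel, best]),
      error = function(e) NULL)
    if (all(c("TC_FO", "L4e") %in% nn$subsector)) {
      memb <- setNames(.pop_label(nn), nn$id)
      # cycles anchored on the burst structure of the first-order
      # thalamocortical population, which leads the full-model rhythms
      tc_ids <- nn$id[nn$subsector == "TC_FO"]
      tc_sp <- tr$spikes[tr$spikes$t >= settle_s &
                           tr$spikes$id %in% tc_ids, ]
      cyc <- oscillation_cycles(tc_sp, duration_s, min_gap_s = 0.12)
      out$cycles <- cyc
      out$latency <- if (nrow(cyc) >= 3)
        population_onset_latencies(
          tr$spikes[tr$spikes$t >= settle_s, ], memb, cyc,
          reference = "TC_FO") else NULL
    }
  }
  class(out) <- "ctsim_protocol_result"
  out
}

#' @export
print.ctsim_protocol_result <- function(x, ...) {
  cat("<ctsim_protocol_result>", x$name, "| seed", x$seed, "\n")
  if (!is.null(x$eeg_peak))
    cat("  EEG dominant frequency:", round(x$eeg_peak$freq_Hz, 3), "Hz\n")
  if (!is.null(x$updown) && !is.null(x$updown$summary))
    cat(sprintf("  up %.0f ms / down %.0f ms\n",
                1e3 * x$updown$summary$mean_up_s,
                1e3 * x$updown$summary$mean_down_s))
  if (!is.null(x$classification))
    cat("  firing pattern:", x$classification$label, "\n")
  invisible(x)
}

#' Oscillation cycle windows from a spike raster
#'
#' Cycle onsets are population-silence-to-firing transitions (global
#' inter-spike gap above `min_gap_s`); each cycle window runs from just
#' before one onset to just before the next.
#'
#' @param spikes Spike data.frame (`id`, `t`).
#' @param duration_s End of the recording (s).
#' @param min_gap_s Minimum global silence defining a cycle boundary.
#' @param pre_s Window extension before each onset.
#' @return data.frame with `start`, `end`.
#' @export
oscillation_cycles <- function(spikes, duration_s, min_gap_s = 0.15,
                               pre_s = 0.02) {
  tt <- sort(spikes$t)
  if (length(tt) < 2) return(data.frame(start = numeric(), end = numeric()))
  gaps <- which(diff(tt) > min_gap_s)
  onsets <- c(tt[1], tt[gaps + 1])
  if (length(onsets) < 2)
    return(data.frame(start = onsets - pre_s,
                      end = pmin(onsets + 1, duration_s)))
  data.frame(start = onsets - pre_s,
             end = c(onsets[-1] - pre_s, duration_s))
}

#' Size and overlap of the initiating assembly per cycle
#'
#' The initiating assembly of a cycle is the set of neurons (from a chosen
#' population) firing within `window_s` of the cycle's first spike. Returns
#' per-cycle assembly sizes and the mean pairwise Jaccard overlap of the
#' assemblies across cycles.
#'
#' @param spikes Spike data.frame.
#' @param ids Neuron ids forming the candidate population.
#' @param cycles Cycle windows (see [oscillation_cycles()]).
#' @param window_s Assembly window after the first spike (s).
#' @export
initiator_assemblies <- function(spikes, ids, cycles, window_s = 0.025) {
  sets <- list()
  for (cy in seq_len(nrow(cycles))) {
    sel <- spikes$t >= cycles$start[cy] & spikes$t < cycles$end[cy] &
      spikes$id %in% ids
    if (!any(sel)) next
    t0 <- min(spikes$t[sel])
    sets[[length(sets) + 1]] <-
      unique(spikes$id[sel & spikes$t <= t0 + window_s])
  }
  if (length(sets) < 2)
    return(list(sizes = lengths(sets), mean_jaccard = NA_real_))
  jac <- c()
  for (a in seq_along(sets)) for (b in seq_along(sets)) {
    if (a < b)
      jac <- c(jac, length(intersect(sets[[a]], sets[[b]])) /
                 length(union(sets[[a]], sets[[b]])))
  }
  list(sizes = lengths(sets), mean_jaccard = mean(jac), assemblies = sets)
}
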
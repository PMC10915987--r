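# Network construction: sectors, pseudo-random placement, topographic
# connectivity with projection radius P, NRT gap junctions.
#
# Structures (subsectors): L23e/L23i, L4e/L4i, L5e/L5i, L6e/L6i (cortical
# excitatory/inhibitory rows) and TC_FO, NRT_FO, TC_HO, NRT_HO. At scale 1
# each excitatory row has 100 neurons, each inhibitory row 50, each thalamic
# row 75, for 900 neurons total.

STRUCTURES <- c("L23e", "L23i", "L4e", "L4i", "L5e", "L5i", "L6e", "L6i",
                "TC_FO", "NRT_FO", "TC_HO", "NRT_HO")

.struct_sizes <- c(L23e = 100, L23i = 50, L4e = 100, L4i = 50,
                   L5e = 100, L5i = 50, L6e = 100, L6i = 50,
                   TC_FO = 75, NRT_FO = 75, TC_HO = 75, NRT_HO = 75)

# excitatory cell-type mixture per 100-cell excitatory row; ND only in L5,
# EF concentrated in L2/3 and L6 (matching the onset order of the intrinsic
# neocortical slow oscillation: ND in L5 leads, EF in L6 and L2/3 follow)
.exc_mixture <- list(
  L23e = c(RS = 50, IB = 20, EF = 20, RIB = 10),
  L4e  = c(RS = 60, IB = 25, RIB = 15),
  L5e  = c(RS = 40, IB = 25, RIB = 15, EF = 10, ND = 10),
  L6e  = c(RS = 50, IB = 20, EF = 20, RIB = 10)
)

.struct_cell_type <- function(st) {
  switch(st,
         L23i = "FS", L4i = "FS", L5i = "FS", L6i = "FS",
         TC_FO = "TC_FO", NRT_FO = "NRT_FO",
         TC_HO = "TC_HO", NRT_HO = "NRT_HO",
         NULL)
}

.struct_sector <- function(st) {
  if (grepl("^L", st)) sub("[ei]$", "", st)
  else if (grepl("FO$", st)) "TH_FO" else "TH_HO"
}

#' Default connectivity table
#'
#' One row per pathway: source structure, target structure, receptor class
#' (`AMPA` implies a paired NMDA synapse at 1/13 of the AMPA weight),
#' peak conductance (nS), transmission latency (ms) and projection radius P
#' (the width, in target-row neurons, of the topographic window a source
#' neuron projects to).
#'
#' @return data.frame of pathway definitions.
#' @export
connectivity_table <- function() {
  tb <- function(src, tgt, rec, w, lat, P)
    data.frame(source = src, target = tgt, receptor = rec, weight_nS = w,
               latency_ms = lat, P = P, stringsAsFactors = FALSE)
  rbind(
    # intracortical, within layer
    tb("L23e", "L23e", "AMPA", 7.5, 1.5, 30),
    tb("L4e",  "L4e",  "AMPA", 7.5, 1.5, 30),
    tb("L5e",  "L5e",  "AMPA", 8.0, 1.5, 34),
    tb("L6e",  "L6e",  "AMPA", 7.5, 1.5, 30),
    tb("L23e", "L23i", "AMPA", 2.6, 1.0, 16),
    tb("L4e",  "L4i",  "AMPA", 2.6, 1.0, 16),
    tb("L5e",  "L5i",  "AMPA", 2.6, 1.0, 16),
    tb("L6e",  "L6i",  "AMPA", 2.6, 1.0, 16),
    tb("L23i", "L23e", "GABA_A", 3.5, 1.0, 30),
    tb("L4i",  "L4e",  "GABA_A", 3.5, 1.0, 30),
    tb("L5i",  "L5e",  "GABA_A", 3.5, 1.0, 30),
    tb("L6i",  "L6e",  "GABA_A", 3.5, 1.0, 30),
    tb("L23i", "L23e", "GABA_B", 1.0, 1.0, 30),
    tb("L4i",  "L4e",  "GABA_B", 1.0, 1.0, 30),
    tb("L5i",  "L5e",  "GABA_B", 1.0, 1.0, 30),
    tb("L6i",  "L6e",  "GABA_B", 1.0, 1.0, 30),
    tb("L23i", "L23i", "GABA_A", 2.0, 1.0, 10),
    tb("L4i",  "L4i",  "GABA_A", 2.0, 1.0, 10),
    tb("L5i",  "L5i",  "GABA_A", 2.0, 1.0, 10),
    tb("L6i",  "L6i",  "GABA_A", 2.0, 1.0, 10),
    # interlaminar (canonical microcircuit)
    tb("L4e",  "L23e", "AMPA", 5.0, 2.0, 16),
    tb("L23e", "L5e",  "AMPA", 5.0, 2.0, 16),
    tb("L5e",  "L6e",  "AMPA", 4.5, 2.0, 14),
    tb("L6e",  "L4e",  "AMPA", 3.5, 2.0, 14),
    tb("L5e",  "L23e", "AMPA", 3.0, 2.0, 14),
    # corticothalamic (slow conduction)
    tb("L6e", "TC_FO",  "AMPA", 1.5, 8, 8),
    tb("L6e", "NRT_FO", "AMPA", 0.8, 8, 6),
    tb("L5e", "TC_HO",  "AMPA", 2.0, 8, 8),
    tb("L6e", "TC_HO",  "AMPA", 1.0, 8, 6),
    tb("L6e", "NRT_HO", "AMPA", 0.8, 8, 6),
    # thalamocortical
    tb("TC_FO", "L4e",  "AMPA", 6.0, 3, 12),
    tb("TC_FO", "L4i",  "AMPA", 2.5, 3, 8),
    tb("TC_FO", "L6e",  "AMPA", 1.5, 3, 8),
    tb("TC_FO", "NRT_FO", "AMPA", 3.0, 2, 8),
    tb("TC_HO", "L23e", "AMPA", 2.5, 3, 12),
    tb("TC_HO", "L5e",  "AMPA", 2.5, 3, 10),
    tb("TC_HO", "L23i", "AMPA", 2.0, 3, 8),
    tb("TC_HO", "NRT_HO", "AMPA", 3.0, 2, 8),
    # intrathalamic inhibition
    tb("NRT_FO", "TC_FO", "GABA_A", 2.2, 2, 10),
    tb("NRT_FO", "TC_FO", "GABA_B", 0.4, 2, 10),
    tb("NRT_HO", "TC_HO", "GABA_A", 2.2, 2, 10),
    tb("NRT_HO", "TC_HO", "GABA_B", 0.4, 2, 10),
    tb("NRT_FO", "NRT_FO", "GABA_A", 0.6, 1, 6),
    tb("NRT_HO", "NRT_HO", "GABA_A", 0.6, 1, 6)
  )
}

# ratio of the NMDA to the AMPA peak conductance on cortical targets
NMDA_AMPA_RATIO <- 1 / 13

#' Architecture configuration
#'
#' @param scale Network scale factor (1 = 900 neurons; 0.2 is the reduced
#'   fixture scale used throughout the test suite).
#' @param structures Character vector of structures to instantiate
#'   (default: all; `cortical_structures()` gives the isolated cortex).
#' @param regimes Named character vector mapping cell types (or the special
#'   keys `cortex` / `thalamus`) to g_KL regime names.
#' @param connectivity Pathway table, by default [connectivity_table()].
#' @param seed Integer seed controlling placement and jitter.
#' @param compensate_scale Rescale synaptic weights by the in-degree ratio
#'   when P shrinks at reduced scale, preserving total synaptic drive.
#' @param jitter_gkl Relative SD-like half-range of per-neuron g_KL jitter.
#' @param jitter_v0 Half-range (mV) of initial-voltage jitter.
#' @param jitter_w Relative half-range of per-synapse weight jitter
#'   (desynchronizes population volleys into sustained up-states).
#' @param jitter_lat Half-range (ms) of per-synapse latency jitter.
#' @param driver_mult Named multipliers applied to the outgoing excitatory
#'   weights of specific source cell types; network-driver (ND) cells make
#'   strong, reliable synapses that let their intrinsic bursts ignite
#'   up-states.
#' @export
network_config <- function(scale = 1, structures = STRUCTURES,
                           regimes = c(cortex = "slow_osc",
                                       thalamus = "slow_osc"),
                           connectivity = connectivity_table(),
                           seed = 1L, compensate_scale = TRUE,
                           jitter_gkl = 0.1, jitter_v0 = 3,
                           jitter_w = 0.4, jitter_lat = 0.5,
                           driver_mult = c(ND = 3, EF = 1.3)) {
  stopifnot(scale > 0, all(structures %in% STRUCTURES))
  bad <- !(connectivity$source %in% STRUCTURES) |
    !(connectivity$target %in% STRUCTURES)
  if (any(bad))
    stop("connectivity row references unknown structure: ",
         paste(unique(c(connectivity$source[bad], connectivity$target[bad])),
               collapse = ", "), call. = FALSE)
  structure(list(scale = scale, structures = structures, regimes = regimes,
                 connectivity = connectivity, seed = as.integer(seed),
                 compensate_scale = compensate_scale,
                 jitter_gkl = jitter_gkl, jitter_v0 = jitter_v0,
                 jitter_w = jitter_w, jitter_lat = jitter_lat,
                 driver_mult = driver_mult),
            class = "ctsim_netconfig")
}

#' @rdname network_config
#' @export
cortical_structures <- function() STRUCTURES[1:8]

.regime_for <- function(regimes, cell_type) {
  if (cell_type %in% names(regimes)) return(regimes[[cell_type]])
  key <- if (grepl("^(TC|NRT)", cell_type)) "thalamus" else "cortex"
  if (key %in% names(regimes)) return(regimes[[key]])
  "slow_osc"
}

#' Resolve topographic targets
#'
#' Returns the indices (1-based positions in the target row) inside the
#' window of width `P` centred on the source's proportionally mapped
#' position; the window is clipped at the row boundary (no wrap-around).
#'
#' @param src_pos Source position (1-based index in its row).
#' @param src_n Source row size.
#' @param tgt_n Target row size.
#' @param P Projection radius (window width in target neurons).
#' @param exclude Optional position to exclude (self).
#' @export
resolve_targets <- function(src_pos, src_n, tgt_n, P, exclude = NA) {
  if (P <= 0) return(integer())
  centre <- (src_pos - 0.5) / src_n * tgt_n + 0.5
  lo <- max(1, ceiling(centre - P / 2))
  hi <- min(tgt_n, floor(centre + P / 2))
  if (hi < lo) return(integer())
  idx <- lo:hi
  if (!is.na(exclude)) idx <- idx[idx != exclude]
  idx
}

#' Build the network
#'
#' Deterministic for a fixed seed: places neurons pseudo-randomly within
#' their rows, wires every pathway of the connectivity table through
#' topographic windows (no autapses, at most one chemical synapse per
#' directed pair per receptor), attaches NRT gap junctions, and resolves
#' per-neuron cell parameters (with seeded g_KL and initial-voltage jitter).
#'
#' @param config A [network_config()].
#' @return A `ctsim_network`.
#' @export
build_network <- function(config) {
  stopifnot(inherits(config, "ctsim_netconfig"))
  set.seed(config$seed)
  scale <- config$scale

  sizes <- setNames(pmax(1L, as.integer(round(.struct_sizes * scale))),
                    names(.struct_sizes))[config$structures]

  # --- neurons ---
  rows <- list()
  id0 <- 0L
  for (st in config$structures) {
    n <- sizes[[st]]
    if (st %in% names(.exc_mixture)) {
      mix <- .exc_mixture[[st]]
      counts <- setNames(pmax(0L, as.integer(round(mix * scale))),
                         names(mix))
      # fix rounding drift against the row size
      while (sum(counts) > n) counts[which.max(counts)] <-
          counts[which.max(counts)] - 1L
      while (sum(counts) < n) counts[which.max(mix)] <-
          counts[which.max(mix)] + 1L
      types <- rep(names(counts), counts)
    } else {
      types <- rep(.struct_cell_type(st), n)
    }
    types <- sample(types)  # pseudo-random placement along the row
    rows[[st]] <- data.frame(
      id = id0 + seq_len(n),
      cell_type = types,
      sector = .struct_sector(st),
      subsector = st,
      pos = seq_len(n),
      pop = paste0(st, ".", types),
      stringsAsFactors = FALSE)
    id0 <- id0 + n
  }
  neurons <- do.call(rbind, rows)
  rownames(neurons) <- NULL

  first_id <- setNames(vapply(rows, function(r) r$id[1], 0L),
                       names(rows))

  # --- chemical synapses ---
  conn <- config$connectivity
  conn <- conn[conn$source %in% config$structures &
                 conn$target %in% config$structures, , drop = FALSE]
  el <- vector("list", nrow(conn) + 1)
  el[[1]] <- .empty_edges()
  for (r in seq_len(nrow(conn))) {
    src_st <- conn$source[r]; tgt_st <- conn$target[r]
    ns <- sizes[[src_st]]; nt <- sizes[[tgt_st]]
    P_full <- conn$P[r]
    P <- if (scale < 1) max(1, round(P_full * scale)) else P_full
    w <- conn$weight_nS[r]
    if (config$compensate_scale && scale < 1) {
      w <- w * P_full * scale / P  # preserve summed input conductance
    }
    same <- src_st == tgt_st
    src_ids <- integer(0); tgt_ids <- integer(0)
    for (i in seq_len(ns)) {
      tg <- resolve_targets(i, ns, nt, P,
                            exclude = if (same) i else NA)
      src_ids <- c(src_ids, rep(first_id[[src_st]] + i - 1L, length(tg)))
      tgt_ids <- c(tgt_ids, first_id[[tgt_st]] + tg - 1L)
    }
    if (!length(src_ids)) { el[[r + 1]] <- .empty_edges(); next }
    ed <- data.frame(src = src_ids, tgt = tgt_ids,
                     receptor = conn$receptor[r],
                     weight_nS = w, latency_ms = conn$latency_ms[r],
                     stringsAsFactors = FALSE)
    if (conn$receptor[r] == "AMPA") {
      nm <- ed
      nm$receptor <- "NMDA"
      nm$weight_nS <- ed$weight_nS * NMDA_AMPA_RATIO
      ed <- rbind(ed, nm)
    }
    el[[r + 1]] <- ed
  }
  edges <- do.call(rbind, el)
  rownames(edges) <- NULL
  if (nrow(edges)) {
    ne <- nrow(edges)
    dm <- config$driver_mult
    if (length(dm)) {
      src_type <- neurons$cell_type[edges$src]
      m <- ifelse(src_type %in% names(dm), dm[src_type], 1)
      exc_edge <- edges$receptor %in% c("AMPA", "NMDA")
      edges$weight_nS[exc_edge] <- edges$weight_nS[exc_edge] * m[exc_edge]
    }
    edges$weight_nS <- edges$weight_nS *
      runif(ne, 1 - config$jitter_w, 1 + config$jitter_w)
    edges$latency_ms <- pmax(0.5, edges$latency_ms +
      runif(ne, -config$jitter_lat, config$jitter_lat))
    # re-lock each NMDA weight to its (jittered) AMPA companion so the
    # configured NMDA:AMPA ratio is exact on every synapse
    am <- edges$receptor == "AMPA"
    nm <- edges$receptor == "NMDA"
    key <- paste(edges$src, edges$tgt)
    m <- match(key[nm], key[am])
    edges$weight_nS[nm] <- edges$weight_nS[am][m] * NMDA_AMPA_RATIO
    edges$latency_ms[nm] <- edges$latency_ms[am][m]
  }

  # collapse duplicate directed pairs per receptor (single-synapse rule):
  # keep one synapse, summing weights would double-count overlapping
  # pathway windows, so the strongest pathway wins
  key <- paste(edges$src, edges$tgt, edges$receptor)
  dup <- duplicated(key)
  if (any(dup)) {
    o <- order(key, -edges$weight_nS)
    edges <- edges[o, ]
    edges <- edges[!duplicated(key[o]), ]
    rownames(edges) <- NULL
  }
  stopifnot(!any(edges$src == edges$tgt))

  # --- gap junctions on NRT rows ---
  gj <- attach_gap_junctions(neurons)

  # --- per-neuron cell parameters ---
  n_all <- nrow(neurons)
  gkl_jit <- runif(n_all, 1 - config$jitter_gkl, 1 + config$jitter_gkl)
  # the few network-driver cells are treated as a homogeneous pacemaker
  # population: their leak is not jittered, so the rhythm and up-state
  # statistics do not hinge on which driver the exemplar happens to be
  gkl_jit[neurons$cell_type == "ND"] <- 1
  v_jit <- runif(n_all, -config$jitter_v0, config$jitter_v0)
  v_jit[neurons$cell_type == "ND"] <- 0
  cells <- vector("list", n_all)
  v0 <- vector("list", n_all)
  for (i in seq_len(n_all)) {
    ct <- neurons$cell_type[i]
    regime <- .regime_for(config$regimes, ct)
    cells[[i]] <- .resolve_cell(ct, regime, gkl_scale = gkl_jit[i])
    base <- build_cell(ct, regime = regime, relax_s = 5)$v0
    v0[[i]] <- base + v_jit[i]
  }

  structure(list(
    neurons = neurons, edges = edges, gap_junctions = gj,
    cells = cells, v0 = v0,
    meta = list(seed = config$seed, scale = scale,
                regimes = config$regimes,
                config_hash = .config_hash(config))
  ), class = "ctsim_network")
}

.config_hash <- function(config) {
  s <- paste(utils::capture.output(utils::str(config, digits.d = 10)),
             collapse = "\n")
  # small rolling hash; provenance only, not cryptographic
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483647
  sprintf("%08x", h)
}

#' Attach NRT gap junctions
#'
#' First-degree neighbours along each NRT row are coupled by 3 GOhm
#' junctions, second-degree neighbours by 4.5 GOhm junctions.
#'
#' @param neurons Neuron table (as in a `ctsim_network`).
#' @return data.frame with columns `i`, `j`, `resistance_GOhm`.
#' @export
attach_gap_junctions <- function(neurons) {
  out <- list(data.frame(i = integer(), j = integer(),
                         resistance_GOhm = numeric()))
  for (st in c("NRT_FO", "NRT_HO")) {
    sel <- neurons[neurons$subsector == st, ]
    if (!nrow(sel)) next
    sel <- sel[order(sel$pos), ]
    n <- nrow(sel)
    if (n >= 2)
      out[[length(out) + 1]] <- data.frame(
        i = sel$id[1:(n - 1)], j = sel$id[2:n], resistance_GOhm = 3)
    if (n >= 3)
      out[[length(out) + 1]] <- data.frame(
        i = sel$id[1:(n - 2)], j = sel$id[3:n], resistance_GOhm = 4.5)
  }
  gj <- do.call(rbind, out)
  rownames(gj) <- NULL
  gj
}

#' @export
print.ctsim_network <- function(x, ...) {
  cat("<ctsim_network>", nrow(x$neurons), "neurons,", nrow(x$edges),
      "synapses,", nrow(x$gap_junctions), "gap junctions | seed",
      x$meta$seed, "scale", x$meta$scale, "\n")
  invisible(x)
}

#' Connectivity summary
#'
#' Per-pathway edge counts, autapse and duplicate tallies, and in/out
#' degree distributions; the counts are recomputed directly from the edge
#' list as an internal cross-check.
#'
#' @param graph A `ctsim_network`.
#' @export
connectivity_summary <- function(graph) {
  e <- graph$edges
  n <- graph$neurons
  src_st <- n$subsector[match(e$src, n$id)]
  tgt_st <- n$subsector[match(e$tgt, n$id)]
  path <- paste(src_st, "->", tgt_st, e$receptor)
  counts <- as.data.frame(table(pathway = path), stringsAsFactors = FALSE)
  list(
    pathway_counts = counts,
    n_autapses = sum(e$src == e$tgt),
    n_duplicates = sum(duplicated(paste(e$src, e$tgt, e$receptor))),
    out_degree = tabulate(match(e$src, n$id), nbins = nrow(n)),
    in_degree = tabulate(match(e$tgt, n$id), nbins = nrow(n)),
    n_gap_junctions = nrow(graph$gap_junctions)
  )
}

# ---- serialization ---------------------------------------------------------

#' Write / read a network as TSV tables + JSON header
#'
#' Lossless round-trip: `<prefix>_neurons.tsv`, `<prefix>_edges.tsv`,
#' `<prefix>_gj.tsv` and `<prefix>_meta.json` (seed, scale, regimes,
#' config hash).
#'
#' @param graph A `ctsim_network`.
#' @param prefix Output path prefix.
#' @export
write_network <- function(graph, prefix) {
  utils::write.table(graph$neurons, paste0(prefix, "_neurons.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(graph$edges, paste0(prefix, "_edges.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(graph$gap_junctions, paste0(prefix, "_gj.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  meta <- graph$meta
  meta$regimes <- as.list(meta$regimes)
  jsonlite::write_json(meta, paste0(prefix, "_meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' @rdname write_network
#' @export
read_network <- function(prefix) {
  neurons <- utils::read.table(paste0(prefix, "_neurons.tsv"), sep = "\t",
                               header = TRUE, stringsAsFactors = FALSE)
  edges <- utils::read.table(paste0(prefix, "_edges.tsv"), sep = "\t",
                             header = TRUE, stringsAsFactors = FALSE)
  gj <- utils::read.table(paste0(prefix, "_gj.tsv"), sep = "\t",
                          header = TRUE, stringsAsFactors = FALSE,
                          colClasses = c("integer", "integer", "numeric"))
  meta <- jsonlite::read_json(paste0(prefix, "_meta.json"),
                              simplifyVector = TRUE)
  regimes <- unlist(meta$regimes)
  cells <- vector("list", nrow(neurons))
  v0 <- vector("list", nrow(neurons))
  set.seed(meta$seed)
  # re-derive jitter deterministically from the stored seed
  # (placement already fixed by the tables; only cell params need it)
  for (st in unique(neurons$subsector)) {
    sel <- neurons$subsector == st
    invisible(sample(sum(sel)))  # consume placement draws in build order
  }
  n_all <- nrow(neurons)
  gkl_jit <- runif(n_all, 0.9, 1.1)
  v_jit <- runif(n_all, -3, 3)
  for (i in seq_len(n_all)) {
    ct <- neurons$cell_type[i]
    regime <- .regime_for(regimes, ct)
    cells[[i]] <- .resolve_cell(ct, regime, gkl_scale = gkl_jit[i])
    v0[[i]] <- build_cell(ct, regime = regime, relax_s = 5)$v0 + v_jit[i]
  }
  structure(list(neurons = neurons, edges = edges, gap_junctions = gj,
                 cells = cells, v0 = v0, meta = meta),
            class = "ctsim_network")
}
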
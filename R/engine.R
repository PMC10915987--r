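# Simulation configuration, model compilation and the run loop wrapper.

# synaptic kinetics shared by all pathways; reversal potentials are set per
# target cell class (GABA_A is more hyperpolarizing on TC cells)
SYN_KINETICS <- list(
  AMPA   = c(tau_r = 0.5, tau_d = 5.0, e = 0),
  NMDA   = c(tau_r = 2.0, tau_d = 100, e = 0),
  GABA_A = c(tau_r = 0.5, tau_d = 7.0, e = -70),
  GABA_B = c(tau_r = 2,   tau_d = 10, e = -95)
)

# G-protein cascade (4th-order) parameters for GABA_B
GABAB_PARAMS <- c(k3 = 0.18, k4 = 0.015, kd4 = 100)

.gabaa_reversal <- function(cell_type) {
  if (grepl("^TC", cell_type)) -85
  else if (grepl("^NRT", cell_type)) -75
  else -70
}

.empty_edges <- function() {
  data.frame(src = integer(), tgt = integer(), receptor = character(),
             weight_nS = numeric(), latency_ms = numeric(),
             stringsAsFactors = FALSE)
}

#' Simulation configuration
#'
#' @param duration_s Simulated time (s).
#' @param dt Integration step (ms); default 0.025.
#' @param record List with entries `voltage` (neuron ids, or `"exemplars"`
#'   for one cell per population, or `"all"`), `dipole` (logical; record the
#'   axial dipole current of every two-compartment neuron, needed for EEG),
#'   and `currents` (neuron ids for per-channel current traces).
#' @param record_stride_ms Recording resolution (ms).
#' @param perturbations Data frame with columns `time_s`, `kind`
#'   (`"channel"` or `"receptor"`), `target` (channel id such as `"I_K[Ca]"`
#'   or receptor name), `population` (population label or NA for all) and
#'   `factor` (multiplicative conductance scale; 0 = full blockade).
#' @param seed Integer seed recorded in provenance (the engine itself is
#'   deterministic).
#' @export
sim_config <- function(duration_s, dt = 0.025,
                       record = list(voltage = "exemplars", dipole = TRUE,
                                     currents = integer()),
                       record_stride_ms = 0.5,
                       perturbations = NULL, seed = NA_integer_) {
  stopifnot(duration_s > 0, dt > 0, record_stride_ms >= dt)
  if (!is.null(perturbations)) {
    stopifnot(all(c("time_s", "kind", "target", "factor") %in%
                    colnames(perturbations)))
    if (any(perturbations$time_s > duration_s))
      stop("perturbation time outside simulation window", call. = FALSE)
  }
  structure(list(duration_s = duration_s, dt = dt, record = record,
                 record_stride_ms = record_stride_ms,
                 perturbations = perturbations, seed = seed),
            class = "ctsim_simconfig")
}

# compile a network + config into the flat model consumed by the C++ core
.compile_model <- function(graph, sim, injections = NULL) {
  neurons <- graph$neurons
  n <- nrow(neurons)
  pops <- unique(neurons$pop)
  pop_id <- match(neurons$pop, pops) - 1L
  npop <- length(pops)
  dt <- sim$dt

  catalog <- channel_catalog()
  vnames <- names(catalog)
  tables <- .channel_tables(dt)

  ncomp <- integer(n)
  area <- cm <- v0 <- numeric(2 * n)
  g_c <- numeric(n)
  ca_rest <- ca_phi <- ca_tau <- numeric(2 * n)
  na_rest <- na_phi <- na_tau <- numeric(2 * n)
  has_ca <- has_na <- logical(2 * n)
  ca_tau[] <- na_tau[] <- 1  # avoid div-by-zero for unused slots

  chan_ptr <- integer(2 * n + 1)
  chan_var <- chan_code <- integer(0)
  chan_gmax <- numeric(0)
  cv_list <- vector("list", 2 * n)

  for (i in seq_len(n)) {
    p <- graph$cells[[i]]
    ncomp[i] <- p$compartments
    vv0 <- graph$v0[[i]]
    for (c in seq_len(p$compartments)) {
      idx <- 2 * (i - 1) + c
      comp <- p$comps[[c]]
      area[idx] <- comp$area
      cm[idx] <- comp$cm
      v0[idx] <- vv0[c]
      pl <- comp$pools
      if (!is.null(pl$Ca_i)) {
        has_ca[idx] <- TRUE
        ca_rest[idx] <- pl$Ca_i[["rest"]]
        ca_phi[idx] <- pl$Ca_i[["phi"]]
        ca_tau[idx] <- pl$Ca_i[["tau"]]
      } else ca_rest[idx] <- 1e-4
      if (!is.null(pl$Na_i)) {
        has_na[idx] <- TRUE
        na_rest[idx] <- pl$Na_i[["rest"]]
        na_phi[idx] <- pl$Na_i[["phi"]]
        na_tau[idx] <- pl$Na_i[["tau"]]
      } else na_rest[idx] <- 10
      ch <- comp$channels
      vi <- match(names(ch), vnames)
      if (anyNA(vi))
        stop("unknown channel variant in cell ", i, ": ",
             paste(names(ch)[is.na(vi)], collapse = ", "), call. = FALSE)
      # mixed leak uses the compartment's own reversal
      cv_list[[idx]] <- list(var = vi - 1L, gmax = unlist(ch, use.names = FALSE),
                             el = comp$el)
    }
    g_c[i] <- p$g_c
  }

  # leak_mixed reversal varies per compartment: emit per-compartment clones
  # of the leak variant when el differs from the catalog default (-70)
  variants <- lapply(seq_along(tables), function(j) {
    tb <- tables[[j]]
    list(code = match(tb$id, CHANNEL_IDS) - 1L, erev = tb$erev,
         ion_source = switch(tb$ion_source, Ca = 1L, Na = 2L, 0L),
         vars = tb$vars)
  })
  leak_idx <- which(vnames == "leak")
  extra_leaks <- list()  # el value -> variant index
  get_leak_variant <- function(el) {
    if (abs(el - (-70)) < 1e-9) return(leak_idx - 1L)
    key <- sprintf("%.6f", el)
    if (!is.null(extra_leaks[[key]])) return(extra_leaks[[key]])
    nv <- variants[[leak_idx]]
    nv$erev <- el
    variants[[length(variants) + 1]] <<- nv
    extra_leaks[[key]] <<- length(variants) - 1L
    extra_leaks[[key]]
  }

  for (idx in seq_len(2 * n)) {
    cl <- cv_list[[idx]]
    chan_ptr[idx + 1] <- chan_ptr[idx]
    if (is.null(cl)) next
    vr <- cl$var
    for (q in seq_along(vr)) {
      if (vr[q] == leak_idx - 1L) vr[q] <- get_leak_variant(cl$el)
    }
    chan_var <- c(chan_var, vr)
    chan_gmax <- c(chan_gmax, cl$gmax)
    chan_code <- c(chan_code,
                   vapply(vr, function(j) variants[[j + 1]]$code, 0L))
    chan_ptr[idx + 1] <- chan_ptr[idx] + length(vr)
  }

  # synapse kinetics per (population, receptor)
  syn_e <- matrix(0, npop, 4)
  syn_edr <- syn_edd <- syn_norm <- matrix(1, npop, 4)
  pop_type <- neurons$cell_type[match(pops, neurons$pop)]
  for (p in seq_len(npop)) {
    for (r in 1:4) {
      kk <- SYN_KINETICS[[r]]
      e <- if (r == 3) .gabaa_reversal(pop_type[p]) else kk[["e"]]
      syn_e[p, r] <- e
      syn_edr[p, r] <- exp(-dt / kk[["tau_r"]])
      syn_edd[p, r] <- exp(-dt / kk[["tau_d"]])
      tr <- kk[["tau_r"]]; td <- kk[["tau_d"]]
      tp <- tr * td / (td - tr) * log(td / tr)
      peak <- exp(-tp / td) - exp(-tp / tr)
      syn_norm[p, r] <- 1 / peak
    }
  }

  edges <- graph$edges
  rec_idx <- match(edges$receptor, RECEPTORS)
  if (anyNA(rec_idx)) stop("unknown receptor in edge list", call. = FALSE)
  wgb <- numeric(n)
  gb <- rec_idx == 4L
  if (any(gb)) {
    agg <- tapply(edges$weight_nS[gb] * 1e-3, edges$tgt[gb], sum)
    wgb[as.integer(names(agg))] <- agg
  }

  pert <- sim$perturbations
  if (is.null(pert)) {
    pert_t <- numeric(); pert_kind <- pert_pop <- pert_code <- integer()
    pert_factor <- numeric()
  } else {
    pert <- pert[order(pert$time_s), ]
    pert_t <- pert$time_s * 1e3
    pert_kind <- ifelse(pert$kind == "channel", 0L, 1L)
    pert_code <- integer(nrow(pert))
    for (q in seq_len(nrow(pert))) {
      pert_code[q] <- if (pert_kind[q] == 0L) {
        m <- match(pert$target[q], CHANNEL_IDS)
        if (is.na(m)) stop("unknown channel id: ", pert$target[q],
                           call. = FALSE)
        m - 1L
      } else {
        m <- match(pert$target[q], RECEPTORS)
        if (is.na(m)) stop("unknown receptor: ", pert$target[q],
                           call. = FALSE)
        m - 1L
      }
    }
    pp <- if ("population" %in% colnames(pert)) pert$population
          else rep(NA_character_, nrow(pert))
    pert_pop <- ifelse(is.na(pp), -1L, match(pp, pops) - 1L)
    if (anyNA(pert_pop))
      stop("perturbation references unknown population", call. = FALSE)
    pert_factor <- pert$factor
  }

  # recording selections
  rv <- sim$record$voltage
  if (is.null(rv)) rv <- "exemplars"
  if (identical(rv, "exemplars")) {
    ids <- match(pops, neurons$pop)
  } else if (identical(rv, "all")) {
    ids <- seq_len(n)
  } else ids <- as.integer(rv)
  record_v <- 2L * (ids - 1L)  # somatic compartment index
  rec_names <- neurons$pop[ids]
  dend_of <- as.integer(sim$record$dend_of)
  if (length(dend_of)) {
    record_v <- c(record_v, 2L * (dend_of - 1L) + 1L)
    rec_names <- c(rec_names, paste0("dend.", dend_of))
  }
  names(record_v) <- rec_names
  rec_dip <- if (isTRUE(sim$record$dipole) || is.null(sim$record$dipole))
    which(ncomp == 2L) - 1L else integer()
  rec_cur <- as.integer(sim$record$currents)
  if (length(rec_cur)) rec_cur <- rec_cur - 1L

  if (is.null(injections))
    injections <- data.frame(neuron = integer(), comp = integer(),
                             t0 = numeric(), t1 = numeric(), amp = numeric())

  stride <- max(1L, as.integer(round(sim$record_stride_ms / dt)))
  n_steps <- ceiling(sim$duration_s * 1e3 / dt)

  list(
    dt = dt, n_steps = as.double(n_steps), record_stride = stride,
    pop_id = pop_id, n_pop = npop, ncomp = ncomp,
    area = area, cm = cm, v0 = v0, g_c = g_c,
    chan_ptr = chan_ptr, chan_var = chan_var - 0L, chan_code = chan_code,
    chan_gmax = chan_gmax,
    variants = lapply(variants, function(v) {
      v$vars <- lapply(v$vars, function(x)
        x[c("power", "kind", "form", "coef", "inf", "edt")])
      v
    }),
    vgrid0 = .vgrid()[1], vgrid_step = 0.1, vgrid_n = length(.vgrid()),
    n_codes = length(CHANNEL_IDS),
    ca_rest = ca_rest, ca_phi = ca_phi, ca_tau = ca_tau,
    na_rest = na_rest, na_phi = na_phi, na_tau = na_tau,
    has_ca = has_ca, has_na = has_na,
    syn_e = syn_e, syn_edecay_r = syn_edr, syn_edecay_d = syn_edd,
    syn_norm = syn_norm,
    edge_src = edges$src - 1L, edge_tgt = edges$tgt - 1L,
    edge_rec = rec_idx - 1L,
    edge_delay = pmax(1L, as.integer(round(edges$latency_ms / dt))),
    edge_w = edges$weight_nS * 1e-3,
    gabab_wtot = wgb,
    gb_k3 = GABAB_PARAMS[["k3"]], gb_k4 = GABAB_PARAMS[["k4"]],
    gb_kd = GABAB_PARAMS[["kd4"]],
    gj_i = graph$gap_junctions$i - 1L, gj_j = graph$gap_junctions$j - 1L,
    gj_g = if (nrow(graph$gap_junctions))
      1e-3 / graph$gap_junctions$resistance_GOhm else numeric(),
    ca0 = if (is.null(graph$pools0)) numeric() else graph$pools0$ca,
    na0 = if (is.null(graph$pools0)) numeric() else graph$pools0$na,
    inj_neuron = injections$neuron - 1L, inj_comp = injections$comp,
    inj_t0 = injections$t0, inj_t1 = injections$t1, inj_amp = injections$amp,
    pert_t = pert_t, pert_kind = pert_kind, pert_pop = pert_pop,
    pert_code = pert_code, pert_factor = pert_factor,
    record_v = record_v, record_dipole = rec_dip,
    record_currents = rec_cur,
    record_v_ids = ids
  )
}

#' Run a network simulation
#'
#' Integrates the full network with the compiled-core time stepper and
#' returns a simulation trace: spike raster for every neuron, membrane
#' potentials and dipole (axial) currents at the recording stride, and
#' optional per-channel current traces.
#'
#' @param graph A `ctsim_network` from [build_network()] (or a single-cell
#'   wrapper used by [simulate_current_clamp()]).
#' @param sim A [sim_config()].
#' @param injections Optional data frame (`neuron`, `comp`, `t0`, `t1` in
#'   ms, `amp` in nA).
#' @return A `ctsim_trace` object.
#' @export
run_simulation <- function(graph, sim, injections = NULL) {
  stopifnot(inherits(graph, "ctsim_network"), inherits(sim, "ctsim_simconfig"))
  model <- .compile_model(graph, sim, injections)
  res <- .engine_run(model)
  if (nzchar(res$abort)) stop(res$abort, call. = FALSE)

  stride_s <- model$record_stride * sim$dt / 1e3
  nt <- nrow(res$v)
  t <- (seq_len(nt) - 1) * stride_s

  v <- res$v
  colnames(v) <- names(model$record_v)
  dip_ids <- model$record_dipole + 1L
  dip <- res$dipole
  if (length(dip_ids)) colnames(dip) <- as.character(dip_ids)

  # label per-channel current columns
  cur_labels <- character(0)
  if (length(model$record_currents)) {
    for (i in model$record_currents + 1L) {
      for (c in seq_len(model$ncomp[i])) {
        idx <- 2 * (i - 1) + c
        ks <- (model$chan_ptr[idx] + 1):model$chan_ptr[idx + 1]
        ids <- vapply(model$chan_code[ks] + 1L,
                      function(cc) CHANNEL_IDS[cc], "")
        cur_labels <- c(cur_labels,
                        paste0("n", i, ".", c(1, 2)[c], ".", ids))
      }
    }
    colnames(res$currents) <- cur_labels
  }

  structure(list(
    t = t, v = v, spikes = data.frame(id = res$spike_id,
                                      t = res$spike_t / 1e3),
    dipole = dip, dipole_ids = dip_ids,
    currents = if (length(cur_labels)) res$currents else NULL,
    current_labels = cur_labels,
    v_final = res$v_final,
    pools_final = list(ca = res$ca_final, na = res$na_final),
    v_dend = if (any(grepl("^dend\\.", colnames(v))))
      v[, grepl("^dend\\.", colnames(v)), drop = FALSE] else NULL,
    neurons = graph$neurons, dt = sim$dt, stride_s = stride_s,
    duration_s = sim$duration_s,
    meta = list(seed = sim$seed, net = graph$meta,
                recorded = model$record_v_ids)
  ), class = "ctsim_trace")
}

#' @export
print.ctsim_trace <- function(x, ...) {
  cat("<ctsim_trace>", nrow(x$neurons), "neurons,",
      x$duration_s, "s,", nrow(x$spikes), "spikes\n")
  invisible(x)
}

#' Save / load a simulation trace
#'
#' Traces are stored as a single serialized container holding the spike
#' raster, voltage and dipole arrays and provenance metadata.
#' @param trace A `ctsim_trace`.
#' @param path Output file path (.rds).
#' @export
write_trace <- function(trace, path) {
  saveRDS(trace, path)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) readRDS(path)

#' Export the spike raster as two-column TSV
#' @param trace A `ctsim_trace`.
#' @param path Output TSV path (columns: neuron id, spike time in s).
#' @export
export_spikes_tsv <- function(trace, path) {
  utils::write.table(trace$spikes, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
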
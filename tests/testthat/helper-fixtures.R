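# Shared fixtures. Heavy network runs are memoized per session so several
# test files can reuse them without re-simulating.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- build()
  .fixture_env[[name]]
}

tiny_cortex <- function(seed = 7, regime = "slow_osc") {
  cfg <- network_config(scale = 0.1, structures = cortical_structures(),
                        regimes = c(cortex = regime), seed = seed)
  build_network(cfg)
}

# fine-step reference integration of a single voltage-gated channel under a
# voltage-clamp step (independent oracle for the engine's gating updates)
reference_gating_step <- function(variant, v_from, v_to, t_hold_ms,
                                  t_step_ms, dt = 0.00025) {
  ch <- channel_catalog()[[variant]]
  x <- vapply(ch$vars, function(vr) vr$inf(v_from), 0)
  n_hold <- round(t_hold_ms / dt)
  n_step <- round(t_step_ms / dt)
  V <- c(rep(v_from, n_hold), rep(v_to, n_step))
  open <- numeric(length(V))
  for (i in seq_along(V)) {
    for (j in seq_along(ch$vars)) {
      vr <- ch$vars[[j]]
      inf <- vr$inf(V[i]); tau <- vr$tau(V[i])
      x[j] <- inf + (x[j] - inf) * exp(-dt / tau)
    }
    open[i] <- prod(vapply(seq_along(ch$vars), function(j)
      x[j]^ch$vars[[j]]$power, 0))
  }
  list(t = seq_along(V) * dt, open = open, V = V)
}

# coarse-step (engine-style) version of the same clamp
coarse_gating_step <- function(variant, v_from, v_to, t_hold_ms,
                               t_step_ms, dt = 0.025) {
  reference_gating_step(variant, v_from, v_to, t_hold_ms, t_step_ms, dt)
}

# --- heavy runs shared by the acceptance suite ------------------------------

acceptance_slow <- function() fixture("acc_slow", function()
  run_protocol("isolated_cortex_slow", scale = 0.35, duration_s = 64,
               seed = 1, settle_s = 8))

acceptance_delta <- function() fixture("acc_delta", function()
  run_protocol("isolated_cortex_delta", scale = 0.35, duration_s = 44,
               seed = 1, settle_s = 8))

acceptance_full_delta <- function() fixture("acc_full_delta", function()
  run_protocol("full_model_delta", scale = 0.3, duration_s = 26,
               seed = 1, settle_s = 8))

acceptance_full_slow <- function() fixture("acc_full_slow", function()
  run_protocol("full_model_slow", scale = 0.3, duration_s = 26,
               seed = 1, settle_s = 8))

battery_run <- function(name) fixture(paste0("bat_", name), function()
  run_protocol(name, scale = 0.3, duration_s = 16, seed = 1,
               settle_s = 6))

# population up-state statistics from the mean excitatory membrane
# potential (robust across blockade conditions where single exemplars can
# be silent or saturated)
pop_up_stats <- function(res, thr = -65) {
  tr <- res$trace
  nn <- res$network$neurons
  sel <- tr$t >= res$settle_s
  exc <- !nn$cell_type %in% "FS"
  mv <- rowMeans(pmin(tr$v[sel, exc, drop = FALSE], -20))
  up <- mv > thr
  r <- rle(up)
  dd <- r$lengths * tr$stride_s
  ups <- dd[r$values]
  total <- tr$duration_s - res$settle_s
  rate <- nrow(tr$spikes[tr$spikes$t >= res$settle_s, ]) / total /
    nrow(nn)
  list(up_fraction = mean(up), mean_up_s = mean(ups[ups > 0.04]),
       n_up = sum(ups > 0.04), rate_Hz = rate)
}
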
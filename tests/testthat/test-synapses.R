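# Synapse reference model: normalization, linearity, receptor laws, gap
# junctions, and the configured NMDA:AMPA scaling.

test_that("single-spike transient peaks at the weight at the documented time", {
  for (rec in c("AMPA", "NMDA", "GABA_A")) {
    sp <- synapse_spec(rec, weight_nS = 5, latency_ms = 2)
    t <- seq(0, 400, by = 0.01)
    g <- synaptic_conductance(sp, 0, t)
    expect_equal(max(g), 5, tolerance = 1e-3, info = rec)
    tp <- t[which.max(g)]
    expect_equal(tp, 2 + psp_peak_time(sp$tau_r, sp$tau_d),
                 tolerance = 0.02, info = rec)
    # nothing before the latency
    expect_true(all(g[t < 2] == 0))
  }
})

test_that("event summation is linear for the ionotropic receptors", {
  sp <- synapse_spec("AMPA", weight_nS = 3)
  t <- seq(0, 300, by = 0.02)
  g1 <- synaptic_conductance(sp, 50, t)
  g2 <- synaptic_conductance(sp, 150, t)
  g12 <- synaptic_conductance(sp, c(50, 150), t)
  expect_equal(g12, g1 + g2, tolerance = 1e-10)
  # two well-separated spikes give identical transients
  pk1 <- max(g1); pk2 <- max(g2)
  expect_equal(pk1, pk2, tolerance = 1e-10)
})

test_that("GABA_B responds supralinearly to spike trains", {
  sp <- synapse_spec("GABA_B", weight_nS = 2)
  t <- seq(0, 1500, by = 0.05)
  g_single <- synaptic_conductance(sp, 100, t)
  train <- seq(100, 190, by = 10)  # 10 spikes at 100 Hz
  g_train <- synaptic_conductance(sp, train, t)
  expect_gt(max(g_train), 5 * max(g_single))
})

test_that("synaptic currents vanish at reversal; Mg block is monotone", {
  sp <- synapse_spec("AMPA", weight_nS = 4)
  expect_equal(synaptic_current(sp, g_nS = 4, V_post = sp$reversal_mV), 0)
  expect_lt(mg_block(-100), mg_block(0))
  expect_lt(mg_block(-100), 0.01)
  expect_gt(mg_block(40), 0.9)
  blocked <- synapse_spec("GABA_A", weight_nS = 0)
  for (V in c(-90, -60, -20))
    expect_equal(synaptic_current(blocked, g_nS = 0, V_post = V), 0)
})

test_that("gap junctions follow Ohm's law and are antisymmetric", {
  expect_equal(gap_junction_current(-70, -70, 3), 0)
  expect_equal(gap_junction_current(-70, -40, 3), 0.01)  # 30 mV over 3 GOhm
  expect_equal(gap_junction_current(-40, -70, 3),
               -gap_junction_current(-70, -40, 3))
  expect_error(gap_junction_current(-70, -60, 0), "positive")
})

test_that("NMDA weights are 1/13 of their AMPA companions network-wide", {
  net <- fixture("tiny_cortex", function() tiny_cortex())
  e <- net$edges
  am <- e[e$receptor == "AMPA", ]
  nm <- e[e$receptor == "NMDA", ]
  expect_equal(nrow(am), nrow(nm))
  key <- function(d) paste(d$src, d$tgt)
  nm <- nm[match(key(am), key(nm)), ]
  expect_equal(nm$weight_nS / am$weight_nS,
               rep(ctsim:::NMDA_AMPA_RATIO, nrow(am)), tolerance = 1e-9)
})

test_that("gap-junction currents conserve charge pairwise in the engine", {
  # two passive-ish NRT cells at different potentials exchange equal and
  # opposite current; with equal parameters they relax toward each other
  cell <- build_cell("NRT_FO", regime = "silent", relax_s = 2)
  neurons <- data.frame(id = 1:2, cell_type = "NRT_FO", sector = "s",
                        subsector = "NRT_FO", pos = 1:2,
                        pop = "NRT_FO", stringsAsFactors = FALSE)
  net <- structure(list(
    neurons = neurons, edges = ctsim:::.empty_edges(),
    gap_junctions = data.frame(i = 1L, j = 2L, resistance_GOhm = 3),
    cells = list(cell$params, cell$params),
    v0 = list(cell$v0, cell$v0 + 10),
    meta = list(seed = 1, scale = 1)), class = "ctsim_network")
  tr <- run_simulation(net, sim_config(duration_s = 2,
                                       record = list(voltage = "all",
                                                     dipole = FALSE)))
  gap0 <- abs(tr$v[1, 1] - tr$v[1, 2])
  gap1 <- abs(tr$v[nrow(tr$v), 1] - tr$v[nrow(tr$v), 2])
  expect_lt(gap1, gap0)
})
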
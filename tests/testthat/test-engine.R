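# Engine: silence, determinism, stability, perturbations, convergence.

test_that("disconnected silent-regime network stays silent", {
  net <- fixture("silent_cortex", function() tiny_cortex(regime = "silent"))
  net$edges$weight_nS <- 0
  tr <- run_simulation(net, sim_config(duration_s = 3))
  expect_equal(nrow(tr$spikes), 0)
  expect_true(all(is.finite(tr$v)))
})

test_that("a one-neuron network reproduces the current-clamp path exactly", {
  cell <- build_cell("TC_FO", regime = "slow_osc", relax_s = 2)
  a <- simulate_current_clamp(cell, NULL, duration_s = 6)
  b <- simulate_current_clamp(cell, NULL, duration_s = 6)
  expect_identical(a$spikes, b$spikes)
  expect_identical(a$v, b$v)
})

test_that("resting cells hold their potential without input", {
  cell <- build_cell("TC_FO", regime = "silent", relax_s = 10)
  tr <- simulate_current_clamp(cell, NULL, duration_s = 10)
  drift <- abs(tr$v[length(tr$v)] - tr$v[1])
  expect_lt(drift, 0.01)
})

test_that("instability aborts with a diagnostic naming the neuron", {
  cell <- build_cell("RS", regime = "wake", relax_s = 1)
  expect_error(
    simulate_current_clamp(cell,
                           data.frame(t_start = 0, t_end = 1,
                                      amplitude = 1e4),
                           duration_s = 1),
    "instability.*neuron 1")
})

test_that("unit perturbation leaves trajectories untouched; scopes resolve", {
  net <- fixture("tiny_cortex", function() tiny_cortex())
  base <- run_simulation(net, sim_config(duration_s = 4))
  unit <- data.frame(time_s = 1, kind = "channel", target = "I_K[Ca]",
                     population = NA_character_, factor = 1)
  same <- run_simulation(net, sim_config(duration_s = 4,
                                         perturbations = unit))
  expect_identical(base$v, same$v)
  expect_identical(base$spikes, same$spikes)

  bad <- unit; bad$target <- "I_bogus"
  expect_error(run_simulation(net, sim_config(duration_s = 4,
                                              perturbations = bad)),
               "unknown channel")
  badp <- unit; badp$population <- "nowhere"
  expect_error(run_simulation(net, sim_config(duration_s = 4,
                                              perturbations = badp)),
               "unknown population")
})

test_that("perturbations act from their onset time and are reversible", {
  net <- fixture("tiny_cortex", function() tiny_cortex())
  block <- data.frame(time_s = c(2, 3), kind = "receptor",
                      target = "AMPA", population = NA_character_,
                      factor = c(0, 1))
  base <- run_simulation(net, sim_config(duration_s = 4))
  pert <- run_simulation(net, sim_config(duration_s = 4,
                                         perturbations = block))
  pre <- pert$t < 2
  expect_identical(base$v[pre, ], pert$v[pre, ])
  expect_false(identical(base$v[!pre, ], pert$v[!pre, ]))
})

test_that("halving dt shifts stimulus-locked spikes by less than 0.5 ms", {
  cell <- build_cell("RS", regime = "wake", relax_s = 1)
  prot <- data.frame(t_start = 0.3, t_end = 2.8, amplitude = 0.2)
  a <- simulate_current_clamp(cell, prot, duration_s = 3, dt = 0.025)
  b <- simulate_current_clamp(cell, prot, duration_s = 3, dt = 0.0125)
  n <- min(length(a$spikes), length(b$spikes), 5)
  expect_gt(n, 3)
  expect_lt(max(abs(a$spikes[1:n] - b$spikes[1:n])), 5e-4)
})

test_that("trace container round-trips and exports a spike TSV", {
  net <- fixture("tiny_cortex", function() tiny_cortex())
  tr <- run_simulation(net, sim_config(duration_s = 2))
  p <- file.path(tempdir(), "trace.rds")
  write_trace(tr, p)
  back <- read_trace(p)
  expect_identical(back$spikes, tr$spikes)
  expect_identical(back$v, tr$v)
  tsv <- file.path(tempdir(), "spikes.tsv")
  export_spikes_tsv(tr, tsv)
  re <- utils::read.table(tsv, header = TRUE, sep = "\t")
  expect_equal(nrow(re), nrow(tr$spikes))
})
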
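# Cell catalog, current clamp, firing-pattern classification, f-I curves.

test_that("build_cell: compartment counts and channel complements", {
  tc <- build_cell("TC_FO", relax_s = 0)
  expect_equal(tc$params$compartments, 1L)
  ch <- names(tc$params$comps$soma$channels)
  expect_true(all(c("it_tc", "ih", "leak_k") %in% ch))

  rs <- build_cell("RS", relax_s = 0)
  expect_equal(rs$params$compartments, 2L)
  expect_named(rs$params$comps, c("soma", "dend"))

  expect_error(build_cell("XX"), "unknown cell type")
  expect_error(build_cell("RS", overrides = list("dend.bogus" = 1),
                          relax_s = 0), "unknown parameter")
})

test_that("catalog invariants: nonnegative conductances, finite regimes", {
  for (p in cell_catalog()) {
    expect_true(all(is.finite(p$g_KL)))
    nc <- if (grepl("^(TC|NRT)", p$cell_type)) 1L else 2L
    expect_equal(p$compartments, nc, info = p$cell_type)
    for (comp in p$comps)
      expect_true(all(unlist(comp$channels) >= 0), info = p$cell_type)
  }
})

test_that("current clamp is deterministic and validates protocols", {
  cell <- build_cell("RS", regime = "wake", relax_s = 1)
  prot <- data.frame(t_start = 0.2, t_end = 0.8, amplitude = 0.25)
  a <- simulate_current_clamp(cell, prot, duration_s = 1)
  b <- simulate_current_clamp(cell, prot, duration_s = 1)
  expect_identical(a$spikes, b$spikes)
  expect_identical(a$v, b$v)
  expect_equal(length(a$t), 1 / 0.5e-3)

  bad <- data.frame(t_start = c(0.1, 0.3), t_end = c(0.4, 0.6),
                    amplitude = c(0.1, 0.1))
  expect_error(simulate_current_clamp(cell, bad, duration_s = 1),
               "overlapping")
})

test_that("firing-pattern classifier recognizes burst signatures", {
  t <- seq(0, 2, by = 5e-4)
  v <- rep(-70, length(t))
  # decelerando: monotonically increasing intra-burst ISIs
  dec <- 0.5 + cumsum(c(0, 2, 3, 5, 8, 12) * 1e-3)
  out <- classify_firing_pattern(t, v, dec)
  expect_equal(out$label, "burst_decelerando")
  # accelerando-decelerando: ISIs shrink then grow
  acd <- 0.5 + cumsum(c(0, 8, 4, 2, 4, 9) * 1e-3)
  expect_equal(classify_firing_pattern(t, v, acd)$label,
               "burst_accelerando_decelerando")
  # quiescent flat trace
  expect_equal(classify_firing_pattern(t, v, numeric())$label, "quiescent")
  # regular tonic train
  ton <- seq(0.1, 1.9, by = 0.05)
  expect_equal(classify_firing_pattern(t, v, ton)$label, "tonic")
  expect_error(classify_firing_pattern(numeric(), numeric(), 1), "empty")
})

test_that("TC cell fires tonically on depolarizing steps from rest", {
  cell <- build_cell("TC_FO", regime = "wake", relax_s = 2)
  tr <- simulate_current_clamp(
    cell, data.frame(t_start = 0.5, t_end = 2.5, amplitude = 0.15),
    duration_s = 3)
  sp <- tr$spikes[tr$spikes > 0.6 & tr$spikes < 2.5]
  expect_gt(length(sp), 10)
})

test_that("single-cell regimes reproduce their oscillation classes", {
  nd <- run_protocol("single_nd_slow", duration_s = 16, settle_s = 6)
  expect_equal(nd$classification$label, "oscillating_slow")

  tc_slow <- run_protocol("single_tc_slow", duration_s = 20, settle_s = 6)
  expect_equal(tc_slow$classification$label, "oscillating_slow")

  tc_delta <- run_protocol("single_tc_delta", duration_s = 16, settle_s = 6)
  expect_equal(tc_delta$classification$label, "oscillating_delta")
  f_slow <- tc_slow$classification$features$interburst_freq
  f_delta <- tc_delta$classification$features$interburst_freq
  expect_lt(f_slow, 1)
  expect_gt(f_delta, f_slow)
})

test_that("f-I curves: monotone for RS, FS outruns RS at strong drive", {
  rs <- build_cell("RS", regime = "wake", relax_s = 1)
  fs <- build_cell("FS", regime = "wake", relax_s = 1)
  amps <- c(0, 0.15, 0.3, 0.5)
  fi_rs <- fI_curve(rs, amps, duration_s = 1.2)
  fi_fs <- fI_curve(fs, amps, duration_s = 1.2)
  expect_true(all(fi_rs$rate_Hz >= 0))
  expect_equal(fi_rs$rate_Hz[1], 0)
  expect_true(all(diff(fi_rs$rate_Hz) >= 0))
  expect_gt(fi_fs$rate_Hz[4], fi_rs$rate_Hz[4])
})

test_that("reducing persistent Na and CAN progressively shortens and
           finally abolishes NRT up-states", {
  envelope <- function(sp, gap = 0.1) {
    if (length(sp) < 2) return(0)
    br <- c(0, which(diff(sp) > gap), length(sp))
    mean(vapply(seq_len(length(br) - 1), function(k) {
      idx <- (br[k] + 1):br[k + 1]
      sp[max(idx)] - sp[min(idx)]
    }, 0))
  }
  ups <- vapply(c(1, 0.5, 0.3), function(f) {
    cell <- build_cell("NRT_FO", regime = "spindle",
                       overrides = list("soma.nap" = 4e-5 * f,
                                        "soma.can" = 1.2e-4 * f),
                       relax_s = 2)
    tr <- simulate_current_clamp(cell, NULL, duration_s = 20)
    envelope(tr$spikes[tr$spikes > 5])
  }, 0)
  expect_true(all(diff(ups) <= 1e-9))  # monotone shortening
  expect_gt(ups[1], 1)                 # sustained up-states at baseline
  expect_equal(ups[3], 0)              # abolition at strong reduction
})
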
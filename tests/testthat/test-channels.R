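# Channel kinetics: catalog invariants, limit cases, ion pools, and the
# fine-step voltage-clamp oracle.

test_that("gating curves are bounded and time constants positive", {
  cc <- channel_catalog()
  V <- seq(-120, 50, by = 0.5)
  for (ch in cc) {
    for (vr in ch$vars) {
      if (vr$kind != "v") next
      inf <- vr$inf(V)
      expect_true(all(inf >= 0 & inf <= 1), info = ch$variant)
      expect_true(all(vr$tau(V) > 0), info = ch$variant)
    }
  }
})

test_that("T-current limit cases: deactivated and de-inactivated at -120 mV", {
  expect_lt(gating_steady_state("it_tc", "m", V = -120), 0.01)
  expect_gt(gating_steady_state("it_tc", "h", V = -120), 0.99)
  expect_lt(gating_steady_state("it_nrt", "m", V = -120), 0.01)
  expect_gt(gating_steady_state("it_nrt", "h", V = -120), 0.99)
})

test_that("Ca-activated K activation grows with calcium", {
  p1 <- ion_pool("Ca_i", resting = 2.4e-4, phi = 0.05, tau = 100)
  p10 <- ion_pool("Ca_i", resting = 2.4e-4, phi = 0.05, tau = 100,
                  concentration = 2.4e-3)
  a1 <- gating_steady_state("kca", "m", pool = p1)
  a10 <- gating_steady_state("kca", "m", pool = p10)
  expect_lt(a1, a10)
  expect_true(a1 >= 0 && a10 <= 1)
})

test_that("channel currents: ohmic zero at reversal, zero at zero gmax", {
  cc <- channel_catalog()
  st <- c(m = 0.5, h = 0.5, n = 0.5, w = 0.5)
  for (nm in c("na_cx", "kdr_th", "ka", "km", "ih")) {
    ch <- cc[[nm]]
    expect_equal(channel_current(nm, st, V = ch$erev, g_max = 1e-3), 0,
                 info = nm)
  }
  for (V in c(-100, -60, 0, 40))
    expect_equal(channel_current("leak_k", numeric(), V = V, g_max = 0), 0)
})

test_that("outward-positive sign convention", {
  # K+ current above E_K is outward (positive); Na+ below E_Na is inward
  expect_gt(channel_current("kdr_cx", c(n = 0.5), V = -20, g_max = 1e-3), 0)
  expect_lt(channel_current("na_cx", c(m = 0.5, h = 0.5), V = -20,
                            g_max = 1e-3), 0)
})

test_that("ion pools: fixed point, monotone decay, closed-form steady state", {
  p <- ion_pool("Ca_i", resting = 2.4e-4, phi = 0.05, tau = 100)
  p2 <- update_ion_pools(list(p), c(Ca_i = 0), dt = 1)[[1]]
  expect_equal(p2$concentration, p$concentration)

  hot <- ion_pool("Ca_i", resting = 2.4e-4, phi = 0.05, tau = 100,
                  concentration = 4.8e-4)
  hot2 <- update_ion_pools(list(hot), c(Ca_i = 0), dt = 1)[[1]]
  expect_lt(hot2$concentration, hot$concentration)
  expect_gte(hot2$concentration, hot$resting)

  # constant inward current: converge to rest + phi*|I|*tau within 1%
  pool <- ion_pool("Na_i", resting = 10, phi = 0.05, tau = 50)
  I <- -2e-3
  for (k in 1:4000)
    pool <- update_ion_pools(list(pool), c(Na_i = I), dt = 0.5)[[1]]
  expect_equal(pool$concentration, 10 + 0.05 * 2e-3 * 50,
               tolerance = 0.01)

  expect_error(update_ion_pools(list(pool), c(Na_i = 0), dt = -1), "dt")
})

test_that("unknown identifiers raise configuration errors", {
  expect_error(gating_steady_state("no_such_channel", "m", V = -60),
               "unknown channel")
  expect_error(gating_steady_state("it_tc", "zz", V = -60),
               "no gating variable")
  expect_error(gating_steady_state("it_tc", "m", V = NaN), "finite")
  expect_error(gating_steady_state("kca", "m"), "pool")
})

test_that("T-window conductance profile peaks between the activation and
           inactivation midpoints", {
  w <- it_window_profile("it_tc")
  expect_true(all(w$open >= 0 & w$open <= 1))
  pk <- w$V[which.max(w$open)]
  expect_gt(pk, -81)
  expect_lt(pk, -55)
  # window vanishes far from rest
  expect_lt(w$open[1], 1e-3)
  expect_lt(w$open[nrow(w)], max(w$open))
})

test_that("gating stays in [0,1] along random bounded voltage paths", {
  set.seed(11)
  cc <- channel_catalog()
  for (rep in 1:5) {
    V <- -120 + cumsum(rnorm(400, 0, 8))
    V <- pmin(pmax(V, -120), 50)
    for (nm in c("it_tc", "ka", "ih", "na_cx", "hva")) {
      ch <- cc[[nm]]
      for (vr in ch$vars) {
        x <- vr$inf(V[1])
        for (v in V) {
          inf <- vr$inf(v); tau <- max(vr$tau(v), 1e-3)
          x <- inf + (x - inf) * exp(-0.025 / tau)
          expect_true(x >= 0 && x <= 1)
        }
      }
    }
  }
})

test_that("voltage-clamp step matches a 100x finer reference integration", {
  # peak open-fraction within 1%, time-to-peak within 5%
  for (spec in list(c("it_tc", -90, -60), c("it_nrt", -90, -55),
                    c("ka", -90, -40))) {
    ref <- reference_gating_step(spec[1], as.numeric(spec[2]),
                                 as.numeric(spec[3]), t_hold_ms = 200,
                                 t_step_ms = 150, dt = 0.00025)
    eng <- coarse_gating_step(spec[1], as.numeric(spec[2]),
                              as.numeric(spec[3]), t_hold_ms = 200,
                              t_step_ms = 150, dt = 0.025)
    on_r <- ref$V == as.numeric(spec[3])
    on_e <- eng$V == as.numeric(spec[3])
    pk_r <- max(ref$open[on_r]); pk_e <- max(eng$open[on_e])
    expect_equal(pk_e, pk_r, tolerance = 0.01, info = spec[1])
    tp_r <- ref$t[on_r][which.max(ref$open[on_r])] - 200
    tp_e <- eng$t[on_e][which.max(eng$open[on_e])] - 200
    expect_equal(tp_e, tp_r, tolerance = 0.05 * max(tp_r, 1),
                 info = spec[1])
  }
})
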
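# Analysis suite: generator-ground-truth recovery for segmentation,
# spectra, correlations, latencies and Vm distributions.

square_wave <- function(up_ms = 250, down_ms = 840, n_cycles = 20,
                        fs = 1000, up_v = -60, down_v = -75, noise = 1,
                        seed = 1) {
  set.seed(seed)
  one <- c(rep(up_v, round(up_ms * fs / 1000)),
           rep(down_v, round(down_ms * fs / 1000)))
  v <- rep(one, n_cycles) + rnorm(length(one) * n_cycles, 0, noise)
  list(t = seq_along(v) / fs, v = v, fs = fs)
}

test_that("segmentation recovers generator up/down durations within 5%", {
  w <- square_wave()
  ud <- detect_up_down_states(w$t, w$v)
  expect_false(ud$degenerate)
  expect_equal(ud$summary$mean_up_s, 0.25, tolerance = 0.05)
  expect_equal(ud$summary$mean_down_s, 0.84, tolerance = 0.05)
  iv <- ud$intervals
  # alternating, non-overlapping, in-bounds
  expect_true(all(diff(match(iv$label, c("down", "up"))) != 0))
  expect_true(all(iv$start[-1] >= iv$end[-nrow(iv)] - 1e-9))
  expect_gte(min(iv$start), w$t[1] - 1e-9)
})

test_that("segmentation is unbiased until noise reaches half the separation", {
  for (noise in c(0.5, 2, 6)) {
    w <- square_wave(noise = noise, seed = noise * 10)
    ud <- detect_up_down_states(w$t, w$v)
    expect_equal(ud$summary$mean_up_s, 0.25, tolerance = 0.05,
                 info = paste("noise", noise))
  }
})

test_that("flat traces return a single degenerate interval", {
  t <- seq(0, 10, by = 1e-3)
  ud <- detect_up_down_states(t, rep(-70, length(t)))
  expect_true(ud$degenerate)
  expect_equal(nrow(ud$intervals), 1)
})

test_that("dominant frequency recovers pure tones and pulse trains", {
  fs <- 200
  t <- seq(0, 60, by = 1 / fs)
  x <- sin(2 * pi * 1 * t)
  f <- dominant_frequency(x, fs, band = c(0.1, 4))
  expect_equal(f$freq_Hz, 1, tolerance = f$resolution_Hz / 1 + 1e-9)

  # 0.44 Hz pulse train
  pulses <- (t %% (1 / 0.44)) < 0.25
  f2 <- dominant_frequency(as.numeric(pulses), fs, band = c(0.1, 4))
  expect_lt(abs(f2$freq_Hz - 0.44), f2$resolution_Hz + 1e-9)

  expect_error(dominant_frequency(x[1:100], fs, band = c(0.1, 4)),
               "shorter")
})

test_that("spectral estimator covers the slow-to-spindle range", {
  fs <- 200
  t <- seq(0, 80, by = 1 / fs)
  for (f0 in c(0.2, 0.44, 1.57, 4, 10.5, 16)) {
    x <- sin(2 * pi * f0 * t)
    est <- dominant_frequency(x, fs, band = c(0.15, 18))
    expect_lt(abs(est$freq_Hz - f0), est$resolution_Hz + 1e-9)
  }
})

test_that("white noise yields low spectral-peak prominence", {
  set.seed(4)
  fs <- 100
  x <- rnorm(60 * fs)
  f <- dominant_frequency(x, fs, band = c(0.2, 4))
  sine <- dominant_frequency(sin(2 * pi * seq(0, 60, by = 1 / fs)), fs,
                             band = c(0.2, 4))
  expect_lt(f$prominence, sine$prominence / 10)
})

test_that("autocorrelogram: normalized, symmetric, periodic side peaks", {
  fs <- 100
  t <- seq(0, 60, by = 1 / fs)
  x <- sin(2 * pi * 0.5 * t)
  ac <- autocorrelogram(x, fs, max_lag_s = 5)
  expect_equal(ac$r[ac$lag_s == 0], 1)
  expect_equal(ac$r, rev(ac$r), tolerance = 1e-12)
  # side peak at the 2 s period within one sample
  side <- ac[ac$lag_s > 1.5 & ac$lag_s < 2.5, ]
  expect_lt(abs(side$lag_s[which.max(side$r)] - 2), 0.02)

  set.seed(5)
  nz <- autocorrelogram(rnorm(6000), fs, max_lag_s = 2)
  expect_lt(max(abs(nz$r[nz$lag_s != 0])), 0.1)
})

test_that("cross-correlation: self peak, lag recovery, calibrated band", {
  set.seed(6)
  fs <- 100
  x <- as.numeric(stats::filter(rnorm(4000), rep(1, 10), sides = 1))
  x[is.na(x)] <- 0
  cc <- crosscorrelation_with_ci(x, x, fs, max_lag_s = 1,
                                 n_surrogates = 100)
  expect_equal(cc$r[cc$lag_s == 0], 1, tolerance = 1e-6)
  expect_true(all(cc$r >= -1 & cc$r <= 1 + 1e-9))

  lagged <- c(rep(0, 25), x[1:(length(x) - 25)])
  cl <- crosscorrelation_with_ci(x, lagged, fs, max_lag_s = 1,
                                 n_surrogates = 100)
  expect_equal(cl$lag_s[which.max(cl$r)], -0.25, tolerance = 0.02)

  y <- as.numeric(stats::filter(rnorm(4000), rep(1, 10), sides = 1))
  y[is.na(y)] <- 0
  cn <- crosscorrelation_with_ci(x, y, fs, max_lag_s = 1,
                                 n_surrogates = 200)
  expect_gt(mean(cn$r >= cn$lo & cn$r <= cn$hi), 0.8)
  expect_error(crosscorrelation_with_ci(x, y[-1], fs), "time base")
  expect_error(crosscorrelation_with_ci(x, y, fs, n_surrogates = 10),
               ">= 100")
})

test_that("population onset latencies recover built-in offsets exactly", {
  set.seed(7)
  n_cyc <- 8
  onsets <- (1:n_cyc) * 2
  spikes <- do.call(rbind, lapply(seq_len(n_cyc), function(k) {
    data.frame(id = c(1, 2, 3),
               t = onsets[k] + c(0, 0.02, 0.04))
  }))
  memb <- setNames(c("A", "B", "C"), 1:3)
  cyc <- data.frame(start = onsets - 0.5, end = onsets + 1.5)
  lat <- population_onset_latencies(spikes, memb, cyc, reference = "A")
  expect_equal(unname(lat$median_ms[c("A", "B", "C")]), c(0, 20, 40),
               tolerance = 1e-9)

  # simultaneous firing: all zero
  sp0 <- spikes; sp0$t <- rep(onsets, each = 3)
  lat0 <- population_onset_latencies(sp0, memb, cyc, reference = "A")
  expect_true(all(abs(lat0$median_ms) < 1e-9))

  # a silent population is NA, not zero
  sp1 <- spikes[spikes$id != 3, ]
  lat1 <- population_onset_latencies(sp1, memb, cyc, reference = "A")
  expect_true(all(is.na(lat1$per_cycle[, "C"])))
  expect_error(population_onset_latencies(spikes, memb, cyc[1:2, ]),
               "3 cycles")
})

test_that("Vm distributions separate bimodal from unimodal traces", {
  set.seed(8)
  bi <- c(rnorm(4000, -75, 1.5), rnorm(1500, -58, 2))
  vb <- vm_distribution(bi)
  expect_equal(sum(vb$density), 1, tolerance = 1e-9)
  expect_true(vb$bimodal)
  expect_equal(vb$modes, c(-75, -58), tolerance = 1)

  uni <- rnorm(5000, -65, 2)
  expect_false(vm_distribution(uni)$bimodal)
})
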
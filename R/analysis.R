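# Quantification: up/down-state segmentation, spectral estimates,
# autocorrelograms, cross-correlations with surrogate confidence bands,
# membrane-potential distributions and population onset latencies.

#' Segment a membrane-potential trace into up and down states
#'
#' Fits a two-mode description of the (spike-clipped) voltage histogram,
#' places the threshold midway between the two modes, and applies
#' hysteresis and a minimum state duration to suppress flicker. On traces
#' without clear bimodality a single interval is returned with
#' `degenerate = TRUE`.
#'
#' @param t Time base (s).
#' @param v Membrane potential (mV).
#' @param hysteresis_mV Hysteresis band around the threshold (mV).
#' @param min_duration_s Minimum accepted state duration (s).
#' @param clip_mV Spikes are clipped above this value before analysis.
#' @param threshold Optional fixed threshold (mV) overriding the histogram
#'   fit.
#' @return A `ctsim_updown` list: `intervals` (data.frame with `label`,
#'   `start`, `end`, `mean_vm`), `summary` (mean/sd durations per label and
#'   cycle frequency), `threshold`, `modes`, `degenerate`.
#' @export
detect_up_down_states <- function(t, v, hysteresis_mV = 2,
                                  min_duration_s = 0.05, clip_mV = -20,
                                  threshold = NULL) {
  stopifnot(length(t) == length(v), length(t) > 10)
  dt <- stats::median(diff(t))
  vc <- pmin(v, clip_mV)
  degenerate <- FALSE
  modes <- NULL
  if (is.null(threshold)) {
    if (stats::sd(vc) < 0.5) {
      # flat trace: single interval
      iv <- data.frame(label = "down", start = t[1], end = t[length(t)],
                       mean_vm = mean(vc))
      return(structure(list(intervals = iv, summary = NULL,
                            threshold = NA_real_, modes = NULL,
                            degenerate = TRUE), class = "ctsim_updown"))
    }
    # exclude the clip pile-up (spike samples) from the mode fit
    vfit <- vc[vc < clip_mV - 0.5]
    if (length(vfit) < 100) vfit <- vc
    d <- stats::density(vfit, bw = 1)
    pk <- which(diff(sign(diff(d$y))) == -2) + 1
    pk <- pk[d$y[pk] > 0.02 * max(d$y)]
    if (length(pk) >= 2) {
      # up mode = most depolarized prominent mode; down mode = most
      # prominent mode at least 4 mV below it (a deep post-event AHP can
      # add a third, hyperpolarized mode that must not masquerade as the
      # down-state)
      xs <- d$x[pk]; ys <- d$y[pk]
      m_up <- which.max(xs)
      below <- which(xs < xs[m_up] - 4)
      if (!length(below)) {
        degenerate <- TRUE
        threshold <- stats::quantile(vc, 0.85)
      } else {
        m_dn <- below[which.max(ys[below])]
        modes <- c(xs[m_dn], xs[m_up])
        threshold <- mean(modes)
      }
    } else {
      degenerate <- TRUE
      threshold <- stats::quantile(vc, 0.85)
    }
  }

  hi <- threshold + hysteresis_mV / 2
  lo <- threshold - hysteresis_mV / 2
  state <- logical(length(vc))
  cur <- vc[1] > threshold
  for (i in seq_along(vc)) {
    if (cur) { if (vc[i] < lo) cur <- FALSE }
    else { if (vc[i] > hi) cur <- TRUE }
    state[i] <- cur
  }
  # enforce minimum duration by absorbing short runs into the neighbour
  r <- rle(state)
  min_len <- max(1L, round(min_duration_s / dt))
  while (length(r$lengths) > 1 && any(r$lengths < min_len)) {
    k <- which(r$lengths < min_len)[1]
    r$values[k] <- if (k > 1) r$values[k - 1] else r$values[k + 1]
    r <- rle(inverse.rle(r))
  }
  state <- inverse.rle(r)
  r <- rle(state)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  iv <- data.frame(
    label = ifelse(r$values, "up", "down"),
    start = t[starts], end = t[ends],
    mean_vm = vapply(seq_along(starts), function(k)
      mean(vc[starts[k]:ends[k]]), 0))

  dur <- iv$end - iv$start
  up <- iv$label == "up"
  smry <- list(
    mean_up_s = mean(dur[up]), sd_up_s = stats::sd(dur[up]),
    mean_down_s = mean(dur[!up]), sd_down_s = stats::sd(dur[!up]),
    n_up = sum(up), n_down = sum(!up),
    cycle_freq_Hz = sum(up) / (t[length(t)] - t[1]))
  structure(list(intervals = iv, summary = smry, threshold = threshold,
                 modes = modes, degenerate = degenerate),
            class = "ctsim_updown")
}

#' @export
print.ctsim_updown <- function(x, ...) {
  s <- x$summary
  if (is.null(s)) cat("<ctsim_updown> degenerate (flat trace)\n")
  else cat(sprintf(
    "<ctsim_updown> %d up / %d down | up %.0f ms, down %.0f ms | %.2f Hz%s\n",
    s$n_up, s$n_down, 1e3 * s$mean_up_s, 1e3 * s$mean_down_s,
    s$cycle_freq_Hz, if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

# Welch-averaged power spectrum (Hann window, 50% overlap)
.welch <- function(x, fs, seg_len_s = NULL, max_segments = 16) {
  n <- length(x)
  if (is.null(seg_len_s)) seg_len_s <- min(20, n / fs / 2)
  L <- min(n, max(64, round(seg_len_s * fs)))
  step <- max(1, floor(L / 2))
  starts <- seq(1, n - L + 1, by = step)
  if (length(starts) > max_segments)
    starts <- starts[round(seq(1, length(starts), length.out = max_segments))]
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(L) / (L + 1))
  acc <- 0
  for (s0 in starts) {
    seg <- x[s0:(s0 + L - 1)]
    seg <- (seg - mean(seg)) * w
    acc <- acc + Mod(stats::fft(seg))^2
  }
  p <- acc / length(starts)
  freq <- (seq_len(L) - 1) * fs / L
  keep <- seq_len(floor(L / 2))
  list(freq = freq[keep], power = p[keep], df = fs / L)
}

#' Dominant frequency of a signal in a band
#'
#' Argmax of a Welch-averaged power spectrum restricted to `band`;
#' spectral-peak prominence against the band's median power is reported so
#' that callers can flag unreliable (noise-like) peaks.
#'
#' @param x Signal.
#' @param fs Sampling frequency (Hz).
#' @param band Two-element frequency band (Hz).
#' @param seg_len_s Welch segment length (s); default caps resolution at
#'   0.05 Hz for slow-band analyses where the signal allows.
#' @return List: `freq_Hz`, `power`, `prominence`, `resolution_Hz`,
#'   `spectrum`.
#' @export
dominant_frequency <- function(x, fs, band = c(0.1, 4), seg_len_s = NULL) {
  stopifnot(length(band) == 2, band[2] > band[1])
  if (length(x) / fs < 5 / band[1])
    stop("signal shorter than 5 cycles of the band's low edge",
         call. = FALSE)
  sp <- .welch(x - mean(x), fs, seg_len_s)
  sel <- sp$freq >= band[1] & sp$freq <= band[2]
  if (!any(sel)) stop("band outside spectral support", call. = FALSE)
  i <- which(sel)[which.max(sp$power[sel])]
  prom <- sp$power[i] / stats::median(sp$power[sel])
  list(freq_Hz = sp$freq[i], power = sp$power[i], prominence = prom,
       resolution_Hz = sp$df, spectrum = sp)
}

#' Normalized autocorrelogram
#'
#' @param x Signal.
#' @param fs Sampling frequency (Hz).
#' @param max_lag_s Maximum lag (s).
#' @return data.frame with `lag_s` (symmetric around 0) and `r`
#'   (normalized to 1 at zero lag).
#' @export
autocorrelogram <- function(x, fs, max_lag_s = 5) {
  x <- x - mean(x)
  nl <- min(length(x) - 1, round(max_lag_s * fs))
  ac <- stats::acf(x, lag.max = nl, plot = FALSE, demean = FALSE)$acf[, 1, 1]
  data.frame(lag_s = c(rev(-seq_len(nl)), 0, seq_len(nl)) / fs,
             r = c(rev(ac[-1]), ac))
}

#' Cross-correlation with surrogate confidence band
#'
#' Normalized cross-correlation between two signals on a common time base;
#' the 95% band is built from circular-shift surrogates of the second
#' signal, which preserve each signal's autocorrelation.
#'
#' @param x,y Signals (same length and sampling). `y` may also be a spike
#'   raster binned beforehand to the common time base.
#' @param fs Sampling frequency (Hz).
#' @param max_lag_s Maximum lag (s).
#' @param n_surrogates Number of circular-shift surrogates (>= 100).
#' @param seed Seed for the surrogate shifts.
#' @return data.frame with `lag_s`, `r`, `lo`, `hi`.
#' @export
crosscorrelation_with_ci <- function(x, y, fs, max_lag_s = 2,
                                     n_surrogates = 200, seed = 1) {
  if (length(x) != length(y))
    stop("signals must share a time base", call. = FALSE)
  if (n_surrogates < 100) stop("n_surrogates must be >= 100", call. = FALSE)
  x <- (x - mean(x)) / stats::sd(x)
  y <- (y - mean(y)) / stats::sd(y)
  n <- length(x)
  nl <- min(n - 1, round(max_lag_s * fs))
  cc <- function(a, b) {
    v <- stats::ccf(a, b, lag.max = nl, plot = FALSE)$acf[, 1, 1]
    v
  }
  r <- cc(x, y)
  set.seed(seed)
  shifts <- sample.int(n - 2, n_surrogates, replace = TRUE)
  sur <- matrix(0, n_surrogates, 2 * nl + 1)
  for (k in seq_len(n_surrogates)) {
    ys <- c(y[(shifts[k] + 1):n], y[1:shifts[k]])
    sur[k, ] <- cc(x, ys)
  }
  lo <- apply(sur, 2, stats::quantile, 0.025)
  hi <- apply(sur, 2, stats::quantile, 0.975)
  data.frame(lag_s = (-nl:nl) / fs, r = r, lo = lo, hi = hi)
}

#' Membrane-potential distribution and bimodality
#'
#' Normalized histogram of the spike-clipped membrane potential with a
#' bimodality assessment: mode separation from a kernel-density fit and an
#' Ashman-D-style separation statistic from a two-component normal mixture
#' (bimodal when D > 2 and both modes carry weight).
#'
#' @param v Membrane potential (mV).
#' @param bins Number of histogram bins.
#' @param clip_mV Spike-clipping level.
#' @return List: `mids`, `density` (sums to 1), `modes`, `ashman_d`,
#'   `bimodal`.
#' @export
vm_distribution <- function(v, bins = 100, clip_mV = -20) {
  vc <- pmin(v, clip_mV)
  h <- graphics::hist(vc, breaks = bins, plot = FALSE)
  p <- h$counts / sum(h$counts)
  d <- stats::density(vc, bw = 1)
  pk <- which(diff(sign(diff(d$y))) == -2) + 1
  pk <- pk[d$y[pk] > 0.05 * max(d$y)]
  modes <- d$x[pk[order(-d$y[pk])]][seq_len(min(2, length(pk)))]
  ash <- NA_real_
  if (stats::sd(vc) > 0.5) {
    km <- suppressWarnings(stats::kmeans(vc, centers = 2, nstart = 3))
    mu <- km$centers[, 1]
    sg <- sqrt(vapply(1:2, function(k) {
      x <- vc[km$cluster == k]
      if (length(x) > 1) stats::var(x) else 1
    }, 0))
    wmin <- min(table(km$cluster)) / length(vc)
    ash <- sqrt(2) * abs(diff(mu)) / sqrt(sum(sg^2))
    if (wmin < 0.05) ash <- 0
  }
  list(mids = h$mids, density = p, modes = sort(modes),
       ashman_d = ash,
       bimodal = is.finite(ash) && ash > 2 && length(modes) == 2)
}

#' Population onset latencies per oscillation cycle
#'
#' For each cycle the first action potential of each population is timed
#' relative to the first spike of the reference population in that cycle
#' (the reference latency is identically zero). Populations silent in a
#' cycle get `NA`, never zero.
#'
#' @param spikes data.frame with `id`, `t` (s).
#' @param membership Named assignment of neuron ids to population labels
#'   (character vector indexed by neuron id).
#' @param cycles data.frame with `start`, `end` (s), one row per cycle
#'   window (e.g. from [detect_up_down_states()] on a reference trace,
#'   extended backwards to catch the earliest firing).
#' @param reference Population label used as time zero; by default the
#'   population with the earliest median first spike.
#' @return A `ctsim_latency` list: `per_cycle` (matrix cycles x
#'   populations, ms), `median_ms`, `iqr_ms`, `reference`.
#' @export
population_onset_latencies <- function(spikes, membership, cycles,
                                       reference = NULL) {
  if (nrow(cycles) < 3) stop("need at least 3 cycles", call. = FALSE)
  pops <- sort(unique(membership[!is.na(membership)]))
  first <- matrix(NA_real_, nrow(cycles), length(pops),
                  dimnames = list(NULL, pops))
  sp_pop <- membership[as.character(spikes$id)]
  for (cy in seq_len(nrow(cycles))) {
    sel <- spikes$t >= cycles$start[cy] & spikes$t < cycles$end[cy]
    if (!any(sel)) next
    f <- tapply(spikes$t[sel], sp_pop[sel], min)
    first[cy, names(f)] <- f
  }
  if (is.null(reference)) {
    # reference = population most often earliest
    earliest <- apply(first, 1, function(r)
      if (all(is.na(r))) NA_character_ else pops[which.min(r)])
    tb <- table(earliest)
    reference <- names(tb)[which.max(tb)]
  }
  lat <- (first - first[, reference]) * 1e3
  structure(list(
    per_cycle = lat,
    median_ms = apply(lat, 2, stats::median, na.rm = TRUE),
    iqr_ms = apply(lat, 2, stats::IQR, na.rm = TRUE),
    reference = reference), class = "ctsim_latency")
}

#' @export
print.ctsim_latency <- function(x, ...) {
  cat("<ctsim_latency> reference:", x$reference, "\n")
  print(round(sort(x$median_ms), 1))
  invisible(x)
}

# bin a spike train onto a regular time base (helper for cross-correlation
# between EEG and population firing)
#' Bin spike times onto a regular grid
#' @param spike_t Spike times (s).
#' @param t Regular time base (s).
#' @return Counts per bin aligned with `t`.
#' @export
bin_spikes <- function(spike_t, t) {
  dt <- stats::median(diff(t))
  edges <- c(t - dt / 2, t[length(t)] + dt / 2)
  as.integer(table(cut(spike_t, edges)))
}
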
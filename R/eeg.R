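# Scalp-EEG estimation from simulated transmembrane currents.
#
# Each two-compartment cortical neuron is treated as a current dipole: the
# axial current flowing between the dendritic and axosomatic compartments
# equals the (opposite-signed) net transmembrane currents of the two poles.
# The electrode sees each source attenuated with distance in a resistive
# volume conductor, and the compound signal is low-pass filtered to mimic
# the frequency-dependent attenuation of inhomogeneous tissue.

#' Source geometry for the EEG estimator
#'
#' Neurons are laid out on a line spanning the column width; the electrode
#' sits above the column at `electrode_height_mm`. Each dipole's two poles
#' are separated vertically by `dipole_length_mm` (dendrite up).
#'
#' @param positions Normalized horizontal positions of the sources in
#'   `[0, 1]` (one per dipole source).
#' @param column_width_mm Physical width assigned to the position range.
#' @param electrode_height_mm Electrode height above the dendritic plane.
#' @param dipole_length_mm Pole separation.
#' @param sigma Extracellular conductivity (S/m), amplitude scale only.
#' @param lowpass_Hz Cutoff of the tissue low-pass filter (set `Inf` to
#'   disable).
#' @return A `ctsim_geometry` object with per-source weights.
#' @export
source_geometry <- function(positions, column_width_mm = 1,
                            electrode_height_mm = 1,
                            dipole_length_mm = 0.3, sigma = 0.3,
                            lowpass_Hz = 100) {
  stopifnot(all(positions >= 0 & positions <= 1),
            electrode_height_mm > 0, dipole_length_mm > 0)
  x <- (positions - 0.5) * column_width_mm
  r_dend <- sqrt(x^2 + electrode_height_mm^2)
  r_soma <- sqrt(x^2 + (electrode_height_mm + dipole_length_mm)^2)
  w <- (1 / r_dend - 1 / r_soma) / (4 * pi * sigma)
  structure(list(positions = positions, weights = w,
                 r_dend = r_dend, r_soma = r_soma,
                 lowpass_Hz = lowpass_Hz,
                 params = list(column_width_mm = column_width_mm,
                               electrode_height_mm = electrode_height_mm,
                               dipole_length_mm = dipole_length_mm,
                               sigma = sigma)),
            class = "ctsim_geometry")
}

#' Estimate the EEG from a simulation trace
#'
#' Linear superposition of the recorded dipole (axial) currents weighted by
#' the source geometry, followed by an optional first-order low-pass. The
#' output is zero whenever all source currents are zero, and scales
#' linearly with them; units are arbitrary (all downstream analyses use
#' frequency and timing, never absolute amplitude).
#'
#' @param trace A `ctsim_trace` with dipole recordings (the default
#'   recording settings include them).
#' @param geometry A [source_geometry()]; by default one is built from the
#'   recorded sources' normalized row positions.
#' @return A `ctsim_eeg` list: `t` (s), `signal`, `fs_Hz`, `geometry`.
#' @export
compute_eeg <- function(trace, geometry = NULL) {
  dip <- trace[["dipole"]]
  if (is.null(dip) || !length(dip))
    stop("trace has no dipole current recordings; enable record$dipole",
         call. = FALSE)
  ids <- trace$dipole_ids
  if (is.null(geometry)) {
    nn <- trace$neurons
    pos <- nn$pos[match(ids, nn$id)]
    npos <- stats::ave(pos, nn$subsector[match(ids, nn$id)],
                       FUN = function(p) (p - 0.5) / max(p))
    geometry <- source_geometry(pmin(pmax(npos, 0), 1))
  }
  stopifnot(inherits(geometry, "ctsim_geometry"))
  if (length(geometry$weights) != ncol(dip))
    stop("geometry has ", length(geometry$weights), " sources, trace has ",
         ncol(dip), call. = FALSE)
  sig <- as.numeric(dip %*% geometry$weights)
  fs <- 1 / trace$stride_s
  if (is.finite(geometry$lowpass_Hz)) {
    a <- exp(-2 * pi * geometry$lowpass_Hz / fs)
    sig <- as.numeric(stats::filter(sig * (1 - a), filter = a,
                                    method = "recursive"))
  }
  structure(list(t = trace$t, signal = sig, fs_Hz = fs,
                 geometry = geometry), class = "ctsim_eeg")
}

#' @export
print.ctsim_eeg <- function(x, ...) {
  cat("<ctsim_eeg>", length(x$signal), "samples @", x$fs_Hz, "Hz\n")
  invisible(x)
}
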
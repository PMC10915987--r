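# Voltage- and ion-gated membrane channel kinetics.
#
# Every kinetic coefficient lives in the catalog returned by channel_catalog();
# the simulation engine receives tabulated steady-state / time-constant curves
# built from these entries, so the numbers here are the single source of truth.
#
# Conventions (asserted in the test suite):
#   * outward current positive, inward negative
#   * conductance densities in S/cm^2, point conductances in uS
#   * voltages in mV, time in ms, concentrations in mM
#   * currents returned by channel_current() are densities in mA/cm^2

# -- functional forms -------------------------------------------------------

.boltz <- function(V, vh, k) 1 / (1 + exp((V - vh) / k))

# Traub-style rate: A*(th - V)/(exp((th - V)/q) - 1), singular point removed
.linoid <- function(V, A, th, q) {
  x <- (th - V) / q
  ifelse(abs(x) < 1e-6, A * q * (1 - x / 2), A * (th - V) / (exp(x) - 1))
}

.rates_to_inf_tau <- function(alpha, beta) {
  list(inf = function(V) {
    a <- alpha(V); b <- beta(V); a / (a + b)
  }, tau = function(V) {
    a <- alpha(V); b <- beta(V); 1 / (a + b)
  })
}

# -- catalog ----------------------------------------------------------------

#' Channel kinetics catalog
#'
#' Returns the catalog of channel variants used by all cell models. Each
#' entry defines the gating variables (steady state and time constant as
#' functions of voltage or of an intracellular ion concentration), the gating
#' exponents, the reversal potential and which ion pool, if any, the channel
#' feeds or reads.
#'
#' Variants exist where the same conceptual current uses different kinetics in
#' different structures (e.g. the T-type calcium current of thalamocortical
#' relay cells versus reticular cells).
#'
#' @return Named list of channel definitions.
#' @export
channel_catalog <- function() {
  if (!is.null(.ctsim_cache$catalog)) return(.ctsim_cache$catalog)

  cat <- list()

  ## Transient Na+ and delayed-rectifier K+ (spike currents), Traub-Miles
  ## rate forms with a per-variant voltage shift.
  make_na <- function(vshift, rate_scale = 1) {
    am <- function(V) rate_scale * .linoid(V - vshift, 0.32, 13, 4)
    bm <- function(V) rate_scale * .linoid(-(V - vshift), 0.28, -40, 5)
    ah <- function(V) rate_scale * 0.128 * exp((17 - (V - vshift)) / 18)
    bh <- function(V) rate_scale * 4 / (1 + exp((40 - (V - vshift)) / 5))
    m <- .rates_to_inf_tau(am, bm); h <- .rates_to_inf_tau(ah, bh)
    list(
      id = "I_Na_transient", erev = 50, ion_source = "Na",
      vars = list(
        list(name = "m", power = 3, kind = "v", inf = m$inf, tau = m$tau),
        list(name = "h", power = 1, kind = "v", inf = h$inf, tau = h$tau)
      )
    )
  }
  cat$na_cx  <- make_na(vshift = -55)
  cat$na_th  <- make_na(vshift = -52)
  cat$na_fs  <- make_na(vshift = -55, rate_scale = 2)  # fast-spiking kinetics

  make_kdr <- function(vshift, rate_scale = 1) {
    an <- function(V) rate_scale * .linoid(V - vshift, 0.032, 15, 5)
    bn <- function(V) rate_scale * 0.5 * exp((10 - (V - vshift)) / 40)
    n <- .rates_to_inf_tau(an, bn)
    list(
      id = "I_K_dr", erev = -95,
      vars = list(list(name = "n", power = 4, kind = "v",
                       inf = n$inf, tau = n$tau))
    )
  }
  cat$kdr_cx <- make_kdr(vshift = -55)
  cat$kdr_th <- make_kdr(vshift = -52)
  cat$kdr_fs <- make_kdr(vshift = -55, rate_scale = 2)

  ## Persistent Na+ current: fast non-inactivating activation.
  cat$nap <- list(
    id = "I_Na(P)", erev = 50, ion_source = "Na",
    vars = list(list(name = "m", power = 1, kind = "v",
                     inf = function(V) .boltz(V, -48, -5),
                     tau = function(V) rep(0.8, length(V))))
  )

  ## A-type K+ current (Huguenard-McCormick).
  cat$ka <- list(
    id = "I_A", erev = -95,
    vars = list(
      list(name = "m", power = 4, kind = "v",
           inf = function(V) .boltz(V, -60, -8.5),
           tau = function(V)
             0.37 + 1 / (exp((V + 35.8) / 19.7) + exp(-(V + 79.7) / 12.7))),
      list(name = "h", power = 1, kind = "v",
           inf = function(V) .boltz(V, -78, 6),
           tau = function(V) {
             t1 <- 1 / (exp((V + 46) / 5) + exp(-(V + 238) / 37.5))
             ifelse(V < -63, t1, 19)
           })
    )
  )

  ## M-type K+ current (slow, non-inactivating).
  km_alpha <- function(V) {
    x <- -(V + 30) / 9
    ifelse(abs(x) < 1e-6, 0.0001 * 9 * (1 + x / 2),
           0.0001 * (V + 30) / (1 - exp(x)))
  }
  km_beta <- function(V) {
    x <- (V + 30) / 9
    ifelse(abs(x) < 1e-6, 0.0001 * 9 * (1 - x / 2),
           -0.0001 * (V + 30) / (1 - exp(x)))
  }
  kmn <- .rates_to_inf_tau(km_alpha, km_beta)
  cat$km <- list(
    id = "I_M", erev = -95,
    vars = list(list(name = "n", power = 1, kind = "v",
                     inf = kmn$inf,
                     tau = function(V) kmn$tau(V) / 1.2))  # Q10-adjusted
  )

  ## Ca2+-activated K+ currents. The cortical variant (I_K[Ca]) and the fast
  ## reticular after-hyperpolarizing variant (I_AHP) share the second-order
  ## Ca2+ activation rate form with different coefficients.
  make_kca <- function(k_on, k_off, tau_floor = 0.5) {
    list(
      id = NULL, erev = -95,
      vars = list(list(name = "m", power = 1, kind = "ca", form = 1L,
                       coef = c(k_on, k_off, tau_floor),
                       inf = function(ca) {
                         a <- k_on * ca^2; a / (a + k_off)
                       },
                       tau = function(ca) {
                         a <- k_on * ca^2; pmax(1 / (a + k_off), tau_floor)
                       }))
    )
  }
  cat$kca <- make_kca(k_on = 2500, k_off = 0.03); cat$kca$id <- "I_K[Ca]"
  cat$ahp <- make_kca(k_on = 48, k_off = 0.08); cat$ahp$id <- "I_AHP"

  ## Na+-activated K+ current: instantaneous sigmoidal dependence on [Na]_i.
  kna_coef <- c(0.37, 38.7, 3.5)
  cat$kna <- list(
    id = "I_K[Na]", erev = -95,
    vars = list(list(name = "w", power = 1, kind = "na", form = 2L,
                     coef = kna_coef,
                     inf = function(na)
                       kna_coef[1] / (1 + (kna_coef[2] / na)^kna_coef[3]),
                     tau = function(na) rep(1, length(na))))
  )

  ## T-type Ca2+ current, thalamocortical relay variant
  ## (Huguenard-McCormick kinetics at 36 C; constant Ca2+ reversal).
  cat$it_tc <- list(
    id = "I_T", erev = 120, ca_source = TRUE, ion_source = "Ca",
    vars = list(
      list(name = "m", power = 2, kind = "v",
           inf = function(V) .boltz(V, -59, -6.2),
           tau = function(V)
             (0.612 + 1 / (exp(-(V + 132) / 16.7) + exp((V + 16.8) / 18.2))) /
               2.96),
      list(name = "h", power = 1, kind = "v",
           inf = function(V) .boltz(V, -78, 5),
           tau = function(V)
             ifelse(V < -80, exp((V + 467) / 66.6),
                    28 + exp(-(V + 22) / 10.5)) / 3.74)
    )
  )

  ## T-type Ca2+ current, reticular thalamic variant (slower inactivation).
  cat$it_nrt <- list(
    id = "I_T", erev = 120, ca_source = TRUE, ion_source = "Ca",
    vars = list(
      list(name = "m", power = 2, kind = "v",
           inf = function(V) .boltz(V, -52, -7.4),
           tau = function(V)
             (1 + 0.33 / (exp((V + 27) / 10) + exp(-(V + 102) / 15)))),
      list(name = "h", power = 1, kind = "v",
           inf = function(V) .boltz(V, -80, 5),
           tau = function(V)
             (28.3 + 0.33 / (exp((V + 48) / 4) + exp(-(V + 407) / 50))))
    )
  )

  ## High-voltage-activated Ca2+ current (L-type-like, Reuveni-style rates).
  hva_am <- function(V) .linoid(V, 0.055, -27, 3.8)
  hva_bm <- function(V) 0.94 * exp((-75 - V) / 17)
  hva_ah <- function(V) 0.000457 * exp((-13 - V) / 50)
  hva_bh <- function(V) 0.0065 / (exp((-15 - V) / 28) + 1)
  hvam <- .rates_to_inf_tau(hva_am, hva_bm)
  hvah <- .rates_to_inf_tau(hva_ah, hva_bh)
  cat$hva <- list(
    id = "I_HVA", erev = 120, ca_source = TRUE, ion_source = "Ca",
    vars = list(
      list(name = "m", power = 2, kind = "v", inf = hvam$inf, tau = hvam$tau),
      list(name = "h", power = 1, kind = "v", inf = hvah$inf, tau = hvah$tau))
  )

  ## Hyperpolarization-activated cation current I_h.
  cat$ih <- list(
    id = "I_h", erev = -43,
    vars = list(list(name = "h", power = 1, kind = "v",
                     inf = function(V) .boltz(V, -75, 5.5),
                     tau = function(V)
                       20 + 1 / (exp(-14.59 - 0.086 * V) +
                                   exp(-1.87 + 0.0701 * V))))
  )
  ## Slow, more depolarized I_h variant used by cortical pacemaker cells:
  ## its activation ramp during the down-state sets the intrinsic slow
  ## oscillation period.
  cat$ih_nd <- list(
    id = "I_h", erev = -40,
    vars = list(list(name = "h", power = 1, kind = "v",
                     inf = function(V) .boltz(V, -70, 6),
                     tau = function(V)
                       80 + 3.5 / (exp(-14.59 - 0.086 * V) +
                                     exp(-1.87 + 0.0701 * V))))
  )

  ## Ca2+-activated non-specific cation current I_CAN.
  can_coef <- c(0.004, 160, 20)  # Kd (mM), tau_base (ms), tau_floor (ms)
  cat$can <- list(
    id = "I_CAN", erev = -20,
    vars = list(list(name = "m", power = 1, kind = "ca", form = 3L,
                     coef = can_coef,
                     inf = function(ca) ca^2 / (ca^2 + can_coef[1]^2),
                     tau = function(ca)
                       pmax(can_coef[2] / (1 + (ca / can_coef[1])^2),
                            can_coef[3])))
  )

  ## Leak currents: potassium leak (the neuromodulatory dial) and mixed leak.
  cat$leak_k <- list(id = "leak_K", erev = -95, vars = list())
  cat$leak   <- list(id = "leak_mixed", erev = -70, vars = list())

  for (nm in names(cat)) cat[[nm]]$variant <- nm
  .ctsim_cache$catalog <- cat
  cat
}

.ctsim_cache <- new.env(parent = emptyenv())

.get_channel <- function(channel) {
  if (is.character(channel)) {
    cc <- channel_catalog()
    if (!channel %in% names(cc))
      stop("unknown channel variant: ", channel, call. = FALSE)
    channel <- cc[[channel]]
  }
  channel
}

.get_var <- function(channel, variable) {
  vs <- channel$vars
  for (v in vs) if (v$name == variable) return(v)
  stop("channel '", channel$variant, "' has no gating variable '", variable,
       "'", call. = FALSE)
}

# -- public operations ------------------------------------------------------

#' Steady-state value of a gating variable
#'
#' @param channel A channel definition from [channel_catalog()] or its name.
#' @param variable Gating variable name (e.g. `"m"`, `"h"`).
#' @param V Membrane potential (mV); ignored for ion-gated variables.
#' @param pool Optional ion pool (see [ion_pool()]); required for Ca2+- or
#'   Na+-gated variables.
#' @return Steady-state activation in `[0, 1]`.
#' @export
gating_steady_state <- function(channel, variable, V = NULL, pool = NULL) {
  channel <- .get_channel(channel)
  v <- .get_var(channel, variable)
  if (v$kind == "v") {
    if (is.null(V) || any(!is.finite(V)))
      stop("finite V required for voltage-gated variable", call. = FALSE)
    v$inf(V)
  } else {
    if (is.null(pool))
      stop("ion pool required for ion-gated variable '", variable, "' of ",
           channel$id, call. = FALSE)
    v$inf(pool$concentration)
  }
}

#' Time constant of a gating variable (ms)
#'
#' @inheritParams gating_steady_state
#' @export
gating_time_constant <- function(channel, variable, V = NULL, pool = NULL) {
  channel <- .get_channel(channel)
  v <- .get_var(channel, variable)
  if (v$kind == "v") {
    if (is.null(V) || any(!is.finite(V)))
      stop("finite V required for voltage-gated variable", call. = FALSE)
    v$tau(V)
  } else {
    if (is.null(pool))
      stop("ion pool required for ion-gated variable '", variable, "'",
           call. = FALSE)
    v$tau(pool$concentration)
  }
}

#' Membrane current density of a channel
#'
#' Outward current is positive. Ohmic: `I = g_max * prod(x_i^p_i) * (V - E)`.
#'
#' @param channel Channel definition or name.
#' @param state Named numeric vector of gating values in `[0, 1]` (may be
#'   empty for leak channels).
#' @param V Membrane potential (mV).
#' @param g_max Conductance density (S/cm^2).
#' @param pool Ion pool, required for ion-gated channels.
#' @return Current density (mA/cm^2).
#' @export
channel_current <- function(channel, state = numeric(), V, g_max,
                            pool = NULL) {
  channel <- .get_channel(channel)
  stopifnot(g_max >= 0)
  open <- 1
  for (v in channel$vars) {
    if (v$kind != "v" && is.null(pool))
      stop("channel ", channel$id, " requires an ion pool", call. = FALSE)
    x <- state[[v$name]]
    if (is.null(x)) stop("missing gating value '", v$name, "'", call. = FALSE)
    if (any(x < 0 | x > 1)) stop("gating value outside [0,1]", call. = FALSE)
    open <- open * x^v$power
  }
  g_max * open * (V - channel$erev)
}

#' Create an intracellular ion pool
#'
#' First-order pool: `d[X]/dt = -phi * I_in - ([X] - rest) / tau`, where
#' `I_in` is the (negative, inward) ion current density in mA/cm^2 and `phi`
#' converts current density to concentration change (mM cm^2 / (mA ms)).
#'
#' @param species `"Ca_i"` or `"Na_i"`.
#' @param resting Resting concentration (mM).
#' @param phi Influx scaling (mM cm^2 / (mA ms)).
#' @param tau Removal time constant (ms).
#' @param concentration Initial concentration (mM), defaults to resting.
#' @export
ion_pool <- function(species = c("Ca_i", "Na_i"), resting, phi, tau,
                     concentration = resting) {
  species <- match.arg(species)
  stopifnot(resting > 0, phi >= 0, tau > 0, concentration >= resting)
  structure(list(species = species, resting = resting, phi = phi, tau = tau,
                 concentration = concentration), class = "ctsim_ion_pool")
}

#' Advance ion pools by one time step
#'
#' Exact exponential update of the linear pool ODE under a current held
#' constant over the step. Inward (negative) ion currents increase the
#' concentration; the concentration never falls below resting.
#'
#' @param pools List of pools from [ion_pool()].
#' @param currents Named numeric: summed ion current density (mA/cm^2) per
#'   species (`Ca_i`, `Na_i`); missing species = 0.
#' @param dt Time step (ms), > 0.
#' @return Updated pool list.
#' @export
update_ion_pools <- function(pools, currents = numeric(), dt) {
  if (!is.numeric(dt) || dt <= 0) stop("dt must be > 0", call. = FALSE)
  lapply(pools, function(p) {
    I <- if (p$species %in% names(currents)) currents[[p$species]] else 0
    influx <- -p$phi * min(I, 0)       # only inward current loads the pool
    target <- p$resting + influx * p$tau
    a <- exp(-dt / p$tau)
    p$concentration <- max(target + (p$concentration - target) * a, p$resting)
    p
  })
}

#' T-type window conductance profile
#'
#' The steady window component of the T current arises from the overlap of
#' the activation and inactivation curves; it is a diagnostic, not a separate
#' channel.
#'
#' @param variant `"it_tc"` or `"it_nrt"`.
#' @param V Voltage grid (mV).
#' @return data.frame with `V` and the open fraction `m_inf^2 * h_inf`.
#' @export
it_window_profile <- function(variant = c("it_tc", "it_nrt"),
                              V = seq(-100, -40, by = 0.5)) {
  variant <- match.arg(variant)
  ch <- channel_catalog()[[variant]]
  m <- .get_var(ch, "m"); h <- .get_var(ch, "h")
  data.frame(V = V, open = m$inf(V)^2 * h$inf(V))
}

# -- tabulation for the engine ----------------------------------------------

# Voltage grid shared by all engine kinetics tables.
.vgrid <- function() seq(-150, 60, by = 0.1)

# Build per-variant gating tables: steady state and exp(-dt/tau) per grid
# point for voltage-gated variables; ion-gated variables are described by a
# small coefficient record evaluated inside the engine.
.channel_tables <- function(dt) {
  cc <- channel_catalog()
  V <- .vgrid()
  lapply(cc, function(ch) {
    vars <- lapply(ch$vars, function(v) {
      if (v$kind == "v") {
        tau <- pmax(v$tau(V), 1e-3)
        list(name = v$name, power = v$power, kind = 0L, form = 0L,
             coef = numeric(), inf = v$inf(V), edt = exp(-dt / tau))
      } else {
        kind <- if (v$kind == "ca") 1L else 2L
        list(name = v$name, power = v$power, kind = kind, form = v$form,
             coef = v$coef, inf = numeric(), edt = numeric())
      }
    })
    list(id = ch$id, erev = ch$erev,
         ion_source = if (is.null(ch$ion_source)) "" else ch$ion_source,
         vars = vars)
  })
}
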
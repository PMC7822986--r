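# Single spiral-ganglion-fibre model: two exponential integrate-and-fire
# spike-initiation sites (peripheral process, central axon) with adaptation,
# per-pulse threshold noise and degeneration manipulations.

#' Parameters of one spike-initiation site
#'
#' Each site follows exponential integrate-and-fire dynamics with an
#' adaptation variable \eqn{W}:
#' \deqn{C \frac{dV}{dt} = -g (V - V_{rest}) + g \Delta_T
#'   e^{(V - V_T - W)/\Delta_T} + I(t)}
#' \deqn{\tau_w \frac{dW}{dt} = a (V - V_{rest}) - W, \qquad
#'   W \leftarrow W + b \text{ on a spike.}}
#' Potentials are dimensionless model units; the membrane time constant is
#' \eqn{C/g} (in seconds with the conventions used here).
#'
#' @param capacitance,conductance Membrane capacitance and leak conductance
#'   (model units; their ratio is the membrane time constant in seconds).
#' @param v_rest,v_threshold,delta_t,v_reset Resting potential, spike
#'   initiation threshold, exponential slope factor and post-spike reset
#'   (dimensionless).
#' @param t_refractory Absolute refractory period, seconds.
#' @param adapt_a Sub-threshold adaptation gain.
#' @param adapt_b Spike-triggered adaptation increment.
#' @param tau_adapt Adaptation time constant, seconds.
#' @param sensitivity Site input current per microampere of stimulus.
#' @param polarity_gain Gain in `[0, 1]` applied to the site's
#'   non-preferred stimulus polarity (anodic at the peripheral site,
#'   cathodic at the central site). `1` means full antisymmetric coupling
#'   (opposite-polarity phases hyperpolarise at full strength); values
#'   below 1 give the partial polarity selectivity observed in real
#'   fibres, which keeps charge cancellation incomplete.
#' @param enabled If `FALSE` the site is skipped entirely (degenerated).
#' @return A `site_params` list.
#' @export
site_params <- function(capacitance, conductance, v_rest = 0,
                        v_threshold = 20, delta_t = 2, v_reset = 0,
                        t_refractory = 500e-6, adapt_a = 0, adapt_b = 0,
                        tau_adapt = 100e-3, sensitivity = 0.01,
                        polarity_gain = 1, enabled = TRUE) {
  stopifnot(capacitance > 0, conductance > 0, delta_t > 0, tau_adapt > 0,
            t_refractory > 0, sensitivity >= 0,
            polarity_gain >= 0, polarity_gain <= 1)
  structure(list(capacitance = capacitance, conductance = conductance,
                 v_rest = v_rest, v_threshold = v_threshold,
                 delta_t = delta_t, v_reset = v_reset,
                 t_refractory = t_refractory, adapt_a = adapt_a,
                 adapt_b = adapt_b, tau_adapt = tau_adapt,
                 sensitivity = sensitivity, polarity_gain = polarity_gain,
                 enabled = isTRUE(enabled)),
            class = "site_params")
}

#' Parameters of one spiral ganglion fibre
#'
#' @param peripheral,central [site_params()] for the peripheral process and
#'   the central axon. The peripheral site receives `-sensitivity * s(t)`
#'   and the central site `+sensitivity * s(t)` where `s(t)` is the signed
#'   stimulus current (anodic positive), so cathodic phases depolarise the
#'   peripheral process and anodic phases the central axon.
#' @param propagation_delay Peripheral-to-central conduction delay in
#'   seconds; a peripheral spike resets the central site after this delay
#'   (antidromic collision). Site spike trains are merged under a shared
#'   refractory period.
#' @param threshold_offset_db Per-fibre sensitivity offset in dB; positive
#'   values raise the fibre's threshold (sensitivities are scaled by
#'   `10^(-offset/20)` at both sites).
#' @param noise_rs Relative spread of the per-pulse threshold fluctuation:
#'   on every pulse each site's spike-initiation threshold is perturbed by
#'   a Gaussian factor `1 + noise_rs * z`.
#' @return A `fibre_params` list.
#' @export
fibre_params <- function(peripheral, central, propagation_delay = 100e-6,
                         threshold_offset_db = 0, noise_rs = 0.05) {
  stopifnot(inherits(peripheral, "site_params"),
            inherits(central, "site_params"),
            propagation_delay >= 0, noise_rs >= 0)
  structure(list(peripheral = peripheral, central = central,
                 propagation_delay = propagation_delay,
                 threshold_offset_db = threshold_offset_db,
                 noise_rs = noise_rs),
            class = "fibre_params")
}

#' Degeneration / demyelination manipulation
#'
#' @param mode One of `"none"`, `"peripheral_disabled"` (peripheral process
#'   removed, central untouched), `"retrograde"` (peripheral removed AND the
#'   central axon demyelinated) or `"simultaneous"` (both sites demyelinated,
#'   peripheral still enabled).
#' @param factor Demyelination factor `k >= 1`: membrane capacitance is
#'   multiplied and conductance divided by `k` at the affected site(s),
#'   slowing the membrane without changing its resting state.
#' @export
degeneration_spec <- function(mode = c("none", "peripheral_disabled",
                                       "retrograde", "simultaneous"),
                              factor = 1) {
  mode <- match.arg(mode)
  if (!is.numeric(factor) || factor < 1)
    stop("`factor` must be >= 1", call. = FALSE)
  if (mode %in% c("none", "peripheral_disabled") && factor != 1)
    stop("`factor` must be 1 for mode \"", mode, "\"", call. = FALSE)
  structure(list(mode = mode, factor = factor), class = "degeneration_spec")
}

.demyelinate <- function(site, k) {
  site$capacitance <- site$capacitance * k
  site$conductance <- site$conductance / k
  site
}

#' Apply a degeneration manipulation to fibre parameters
#'
#' `"retrograde"` disables the peripheral process and demyelinates the
#' central axon by `factor` (capacitance multiplied, conductance divided);
#' `"simultaneous"` demyelinates both sites and keeps the peripheral process
#' enabled; `"peripheral_disabled"` removes the peripheral process only.
#'
#' @param params A [fibre_params()] object.
#' @param spec A [degeneration_spec()].
#' @return Modified `fibre_params`.
#' @export
apply_degeneration <- function(params, spec) {
  stopifnot(inherits(params, "fibre_params"),
            inherits(spec, "degeneration_spec"))
  switch(spec$mode,
    none = params,
    peripheral_disabled = {
      params$peripheral$enabled <- FALSE
      params
    },
    retrograde = {
      params$peripheral$enabled <- FALSE
      params$central <- .demyelinate(params$central, spec$factor)
      params
    },
    simultaneous = {
      params$peripheral <- .demyelinate(params$peripheral, spec$factor)
      params$central <- .demyelinate(params$central, spec$factor)
      params
    })
}

# convert a site_params to the microsecond-unit list the C++ core expects,
# applying the fibre-level sensitivity offset
.site_for_cpp <- function(site, offset_db = 0) {
  list(capacitance = site$capacitance,
       conductance = site$conductance * 1e-6,   # per us
       v_rest = site$v_rest, v_threshold = site$v_threshold,
       delta_t = site$delta_t, v_reset = site$v_reset,
       t_refractory_us = site$t_refractory * 1e6,
       adapt_a = site$adapt_a, adapt_b = site$adapt_b,
       tau_adapt_us = site$tau_adapt * 1e6,
       sensitivity = site$sensitivity * 10^(-offset_db / 20),
       polarity_gain = site$polarity_gain,
       enabled = site$enabled)
}

#' Simulate one fibre's response to a pulse train
#'
#' Integrates both spike-initiation sites through the train (forward Euler
#' at `dt` within pulse footprints, analytic relaxation across silent gaps)
#' and returns the merged fibre spike train. Deterministic for a given seed.
#'
#' @param train A [make_biphasic_train()] / [make_quadraphasic_train()]
#'   object; its `level_uA` is used.
#' @param params [fibre_params()].
#' @param seed Integer seed for the per-pulse threshold noise stream.
#' @param dt Integration step within pulse footprints, seconds.
#' @return Data frame with `time_s` and `site` (`"peripheral"` or
#'   `"central"`) of each spike.
#' @export
integrate_fibre <- function(train, params, seed = 1L, dt = 1e-6) {
  stopifnot(inherits(train, "pulse_train"), inherits(params, "fibre_params"))
  tm <- train$template
  res <- .sim_fibre_cpp(tm$onset_s * 1e6, tm$duration_s * 1e6,
                        tm$amplitude_unit, train$period_s * 1e6,
                        train$n_pulses, train$level_uA,
                        .site_for_cpp(params$peripheral,
                                      params$threshold_offset_db),
                        .site_for_cpp(params$central,
                                      params$threshold_offset_db),
                        params$propagation_delay * 1e6, params$noise_rs,
                        dt * 1e6, as.double(seed))
  data.frame(time_s = res$time_us * 1e-6,
             site = c("peripheral", "central")[res$site + 1L])
}

#' Deterministic single-pulse threshold of a fibre
#'
#' Bisects the stimulus level of a single pulse (the first pulse of
#' `train`) until the spike/no-spike boundary is bracketed within `tol_db`.
#' Per-pulse threshold noise is disabled during the search.
#'
#' @param train A pulse train defining the pulse shape (only one pulse is
#'   presented).
#' @param params [fibre_params()].
#' @param lower_db,upper_db Search range, dB re 1 uA.
#' @param tol_db Bracketing tolerance, dB.
#' @param dt Integration step, seconds.
#' @return List with `threshold_db` and `site`, the initiation site of the
#'   first spike just above threshold.
#' @export
single_pulse_threshold <- function(train, params, lower_db = 10,
                                   upper_db = 90, tol_db = 0.01, dt = 1e-6) {
  stopifnot(inherits(train, "pulse_train"), inherits(params, "fibre_params"))
  params$noise_rs <- 0
  one <- train
  one$n_pulses <- 1L
  spikes_at <- function(db) {
    integrate_fibre(set_level(one, db_to_microamps(db)), params,
                    seed = 1L, dt = dt)
  }
  if (nrow(spikes_at(upper_db)) == 0L)
    stop("no spike at the upper search bound; extend `upper_db`",
         call. = FALSE)
  if (nrow(spikes_at(lower_db)) > 0L)
    stop("spike at the lower search bound; extend `lower_db`", call. = FALSE)
  lo <- lower_db
  hi <- upper_db
  while (hi - lo > tol_db) {
    mid <- (lo + hi) / 2
    if (nrow(spikes_at(mid)) > 0L) hi <- mid else lo <- mid
  }
  sp <- spikes_at(hi)
  list(threshold_db = (lo + hi) / 2, site = sp$site[1])
}

# ---------------------------------------------------------------------------
# Frozen reference parameterisation.
#
# The published description of the underlying phenomenological model gives
# its structure (dual-site exponential integrate-and-fire, adaptation
# feedback, polarity-specific inputs) but not a usable equation/parameter
# table, so this package fixes its own realisation and calibrates it once
# against directional anchors: (i) a healthy fibre population has a slightly
# lower cathodic-centred than anodic-centred quadraphasic threshold;
# (ii) with peripheral processes disabled the anodic-centred threshold is
# ~2 dB below the cathodic-centred one; (iii) thresholds fall when the
# interphase gap grows from 8 to 40 us; (iv) population multipulse
# integration (80 vs 1000 pps, 10,000-spike criterion, 1000 fibres) is
# ~4 dB at a 3-dB threshold SD and ~3 dB at 0.5 dB. The values below were
# tuned by grid exploration under those anchors and then frozen; see the
# methods vignette for the calibration procedure.
# ---------------------------------------------------------------------------

#' Frozen reference fibre parameterisation
#'
#' Returns the package's calibrated healthy-fibre parameter set: peripheral
#' membrane time constant 100 us, central 150 us, shared refractory 500 us,
#' propagation delay 100 us, per-pulse threshold relative spread 0.05, and
#' spike-rate adaptation strong enough to limit sustained firing at 1000
#' pulses per second. The peripheral process is slightly more sensitive
#' than the central axon, giving healthy fibres a small cathodic advantage.
#'
#' The attribute `ref_threshold_db` records the calibrated single-pulse
#' threshold (dB re 1 uA) of this fibre for a cathodic-leading 25-us/8-us
#' biphasic pulse; population configurations use it to interpret requested
#' mean thresholds.
#'
#' @return A [fibre_params()] object.
#' @export
calibrate_reference_params <- function() {
  p <- fibre_params(
    peripheral = site_params(
      capacitance = 1, conductance = 1 / 1000e-6,  # tau = 1 ms (dendrite+soma)
      v_rest = 0, v_threshold = 20, delta_t = 4, v_reset = 0,
      t_refractory = 500e-6, adapt_a = 0.002, adapt_b = 2.5,
      tau_adapt = 30e-3, sensitivity = 0.98 / 100, polarity_gain = 0.65,
      enabled = TRUE),
    central = site_params(
      capacitance = 1, conductance = 1 / 800e-6,   # tau = 800 us (axon)
      v_rest = 0, v_threshold = 20, delta_t = 4, v_reset = 0,
      t_refractory = 500e-6, adapt_a = 0.002, adapt_b = 1.5,
      tau_adapt = 30e-3, sensitivity = 0.76 / 100, polarity_gain = 0.70,
      enabled = TRUE),
    propagation_delay = 100e-6,
    threshold_offset_db = 0,
    noise_rs = 0.08)
  attr(p, "ref_threshold_db") <- 43.746  # frozen at calibration
  p
}

#' @rdname calibrate_reference_params
#' @export
reference_fibre_params <- calibrate_reference_params
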
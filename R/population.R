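# Heterogeneous fibre populations, spike-count-vs-level functions and
# criterion-based population thresholds.

# run code under a fixed RNG seed without disturbing the caller's stream
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# deterministic sub-seed derivation (kept below 2^31)
.subseed <- function(seed, k) {
  (as.double(seed) * 48271 + 11 * k) %% 2147483629
}

#' Configuration of a simulated fibre population
#'
#' @param n_fibres Number of fibres (>= 1).
#' @param sd_threshold_db SD of the per-fibre firing-threshold offsets, dB.
#' @param mean_threshold_db Population mean single-pulse threshold in dB re
#'   1 uA, or `NULL` (default) to keep the calibrated reference threshold.
#' @param degeneration A [degeneration_spec()], applied uniformly.
#' @param seed Integer master seed; per-fibre and per-level noise streams
#'   are derived from it deterministically.
#' @export
population_config <- function(n_fibres, sd_threshold_db,
                              mean_threshold_db = NULL,
                              degeneration = degeneration_spec("none"),
                              seed = 1L) {
  stopifnot(n_fibres >= 1, sd_threshold_db >= 0,
            inherits(degeneration, "degeneration_spec"))
  structure(list(n_fibres = as.integer(n_fibres),
                 sd_threshold_db = sd_threshold_db,
                 mean_threshold_db = mean_threshold_db,
                 degeneration = degeneration, seed = as.integer(seed)),
            class = "population_config")
}

#' Sample a fibre population
#'
#' Draws per-fibre threshold offsets i.i.d. Normal(0, `sd_threshold_db`),
#' applied as a sensitivity scaling `10^(-offset/20)` at both sites, and
#' applies the configured degeneration uniformly. Reproducible from the
#' configuration seed.
#'
#' @param config A [population_config()].
#' @param params Base fibre parameters (default the calibrated reference).
#' @return An `sgn_population` object.
#' @export
sample_population <- function(config, params = reference_fibre_params()) {
  stopifnot(inherits(config, "population_config"),
            inherits(params, "fibre_params"))
  ref_db <- attr(params, "ref_threshold_db")
  shift_db <- if (is.null(config$mean_threshold_db)) 0 else {
    if (is.null(ref_db))
      stop("`params` lacks a reference threshold; cannot honour ",
           "`mean_threshold_db`", call. = FALSE)
    config$mean_threshold_db - ref_db
  }
  offsets <- .with_seed(config$seed,
                        stats::rnorm(config$n_fibres, 0,
                                     config$sd_threshold_db))
  degraded <- apply_degeneration(params, config$degeneration)
  structure(list(params = degraded, offsets_db = offsets,
                 shift_db = shift_db, config = config),
            class = "sgn_population")
}

#' @export
print.sgn_population <- function(x, ...) {
  cat(sprintf("SGN population: %d fibres, threshold SD %.2f dB, mode %s (k=%g)\n",
              x$config$n_fibres, x$config$sd_threshold_db,
              x$config$degeneration$mode, x$config$degeneration$factor))
  invisible(x)
}

#' Population spike count as a function of stimulus level
#'
#' Simulates every fibre at every level of the grid and sums the spike
#' counts over the train duration. The only stochasticity is the per-pulse
#' threshold fluctuation (`noise_rs`); its stream is derived from the
#' population seed, the fibre index, the level index and `trial`, so a
#' fixed seed reproduces counts exactly and incrementing `trial` gives an
#' independent presentation of the same stimulus.
#'
#' @param population An [sample_population()] object.
#' @param train A `pulse_train` (its own level is ignored; the grid sets
#'   the level).
#' @param levels_db Strictly increasing level grid, dB re 1 uA.
#' @param trial Non-negative integer selecting an independent noise stream.
#' @param dt Integration step, seconds.
#' @return A `rate_level_function`: data frame with `level_db` and `count`,
#'   carrying the stimulus label and configuration as attributes.
#' @export
population_rate_level <- function(population, train, levels_db, trial = 0,
                                  dt = 1e-6) {
  stopifnot(inherits(population, "sgn_population"),
            inherits(train, "pulse_train"))
  if (is.unsorted(levels_db, strictly = TRUE))
    stop("`levels_db` must be strictly increasing", call. = FALSE)
  p <- population$params
  tm <- train$template
  scale <- 10^(-(population$offsets_db + population$shift_db +
                   p$threshold_offset_db) / 20)
  cnt <- .sim_population_cpp(tm$onset_s * 1e6, tm$duration_s * 1e6,
                             tm$amplitude_unit, train$period_s * 1e6,
                             train$n_pulses, db_to_microamps(levels_db),
                             .site_for_cpp(p$peripheral),
                             .site_for_cpp(p$central),
                             scale, p$propagation_delay * 1e6, p$noise_rs,
                             dt * 1e6, as.double(population$config$seed),
                             as.double(trial))
  out <- data.frame(level_db = levels_db, count = rowSums(cnt))
  attr(out, "stimulus_label") <- train$label
  attr(out, "config") <- population$config
  class(out) <- c("rate_level_function", "data.frame")
  out
}

#' Criterion-based population threshold
#'
#' Returns the level at which the linearly interpolated spike count first
#' reaches `criterion`.
#'
#' @param rlf A [population_rate_level()] result (or any data frame with
#'   `level_db` and `count`).
#' @param criterion Spike-count criterion; must lie within the range of the
#'   observed counts.
#' @return Threshold level, dB re 1 uA.
#' @export
population_threshold <- function(rlf, criterion) {
  lv <- rlf$level_db
  ct <- rlf$count
  if (criterion < min(ct) || criterion > max(ct))
    stop("criterion not bracketed by the count range; extend the level grid",
         call. = FALSE)
  hit <- which(ct >= criterion)[1]
  if (ct[hit] == criterion || hit == 1L) return(lv[hit])
  below <- hit - 1L
  lv[below] + (criterion - ct[below]) / (ct[hit] - ct[below]) *
    (lv[hit] - lv[below])
}

#' Find the criterion threshold of a population for a stimulus
#'
#' Coarse 1-dB pre-scan to bracket the criterion crossing, then a 0.25-dB
#' grid centred on the bracket, interpolated with [population_threshold()].
#'
#' @inheritParams population_rate_level
#' @param criterion Spike-count criterion.
#' @param centre_db Centre of the coarse scan; defaults to the (possibly
#'   degenerated) fibre's deterministic single-pulse threshold for this
#'   stimulus, plus the population's mean shift.
#' @param span_db Half-width of the coarse scan, dB.
#' @param fine_step Fine grid spacing, dB.
#' @return Threshold level, dB re 1 uA.
#' @export
find_threshold <- function(population, train, criterion, centre_db = NULL,
                           span_db = NULL, fine_step = 0.25, trial = 0,
                           dt = 1e-6) {
  cfg <- population$config
  if (is.null(centre_db)) {
    centre_db <- single_pulse_threshold(train, population$params,
                                        lower_db = 0, upper_db = 130,
                                        dt = dt)$threshold_db +
      population$shift_db
  }
  if (is.null(span_db))
    span_db <- 2.5 * cfg$sd_threshold_db + 8
  coarse <- population_rate_level(
    population, train, seq(centre_db - span_db, centre_db + span_db, by = 1),
    trial = trial, dt = dt)
  hit <- which(coarse$count >= criterion)[1]
  if (is.na(hit) || hit == 1L)
    stop("criterion crossing outside the coarse scan; adjust `centre_db`/",
         "`span_db`", call. = FALSE)
  lo <- coarse$level_db[hit - 1L] - fine_step
  hi <- coarse$level_db[hit] + fine_step
  fine <- population_rate_level(population, train,
                                seq(lo, hi, by = fine_step),
                                trial = trial, dt = dt)
  population_threshold(fine, criterion)
}

#' Convert a rate-level function to an amplitude growth function
#'
#' Maps population spike counts to a dB amplitude scale
#' (`20*log10(count)`), mirroring the log-log coordinates in which measured
#' ECAP growth functions are analysed (the compound-potential amplitude is
#' taken as proportional to the number of spiking fibres). Zero-count
#' levels are dropped.
#'
#' @param rlf A rate-level function.
#' @param ipg_us IPG tag for the resulting AGF, microseconds.
#' @param floor_count Counts at or below this are considered noise floor;
#'   sets the AGF's floor level to `20*log10(floor_count)`.
#' @return An [agf()] object.
#' @export
rlf_to_agf <- function(rlf, ipg_us, floor_count = 50) {
  keep <- rlf$count > 0
  agf(levels_db = rlf$level_db[keep],
      amplitudes_db = 20 * log10(rlf$count[keep]),
      ipg_us = ipg_us,
      floor_db = 20 * log10(floor_count))
}

# AGF pair (IPG 8 vs 40 us) for one population, trimmed, plus their offset.
.agf_pair_offset <- function(population, rate = 80, phase_dur = 25e-6,
                             duration = 0.4, ipg_short = 8e-6,
                             ipg_long = 40e-6, probe_leading = "cathodic",
                             mode = "horizontal", step_db = 0.5,
                             floor_count = 50, dt = 1e-6) {
  cfg <- population$config
  probe <- function(ipg) make_biphasic_train(rate, phase_dur, ipg, duration,
                                             level_uA = 1,
                                             leading = probe_leading)
  # centre the level grid on the degraded fibre's actual single-pulse
  # threshold (degeneration shifts it by tens of dB)
  centre <- single_pulse_threshold(probe(ipg_short), population$params,
                                   lower_db = 0, upper_db = 130,
                                   dt = dt)$threshold_db +
    population$shift_db
  span <- 2.5 * cfg$sd_threshold_db + 7
  grid <- seq(centre - span, centre + span, by = step_db)
  agfs <- lapply(c(ipg_short, ipg_long), function(ipg) {
    rlf <- population_rate_level(population, probe(ipg), grid, dt = dt)
    a <- trim_to_linear_region(rlf_to_agf(rlf, ipg * 1e6,
                                          floor_count = floor_count))
    if (identical(mode, "horizontal")) {
      # equal-output reading needs a strictly growing curve; drop the odd
      # Monte-Carlo tie
      inc <- which(!a$excluded)
      keep <- inc[c(TRUE, diff(cummax(a$amplitude_db[inc])) > 0)]
      a$excluded <- !(seq_len(nrow(a)) %in% keep)
    }
    a
  })
  list(agf_short = agfs[[1]], agf_long = agfs[[2]],
       offset_db = ipg_offset(agfs[[1]], agfs[[2]], mode = mode))
}

#' Model IPG offset of a population
#'
#' Simulates 0.4-s, 80-pps biphasic trains at IPGs of 8 and 40 us, converts
#' the spike-count curves to log-log amplitude growth functions, trims them
#' to their linear regions and returns the mean vertical offset (long minus
#' short IPG) over the overlapping level range.
#'
#' @inheritParams find_threshold
#' @param probe_leading Leading polarity of the ECAP probe pulse
#'   (`"anodic"` default; the compound response at supra-threshold
#'   recording levels is taken to be dominated by central-axon excitation).
#' @param mode Offset reading passed to [ipg_offset()]. The model protocol
#'   defaults to `"horizontal"` (equal-output current shift): on simulated
#'   spike-count curves this is the reading that is invariant to the
#'   number of fibres and to the mean and SD of the firing thresholds,
#'   because the vertical amplitude gap scales with the local AGF slope
#'   (which varies as 1/SD) while the underlying current shift does not.
#' @param step_db AGF level-grid spacing, dB.
#' @param floor_count Noise-floor count for [rlf_to_agf()].
#' @return Offset in dB (positive: the long IPG grows more / is reached at
#'   lower current).
#' @export
model_ipg_offset <- function(population, probe_leading = "cathodic",
                             mode = "horizontal", step_db = 0.5,
                             floor_count = 50, dt = 1e-6) {
  .agf_pair_offset(population, probe_leading = probe_leading, mode = mode,
                   step_db = step_db, floor_count = floor_count,
                   dt = dt)$offset_db
}

#' Model multipulse integration of a population
#'
#' Criterion thresholds for 0.4-s cathodic-leading biphasic trains (25-us
#' phases, 8-us IPG) at 80 and 1000 pps; MPI is the 80-pps threshold minus
#' the 1000-pps threshold.
#'
#' @inheritParams find_threshold
#' @param criterion Spike-count criterion (default 10,000).
#' @return MPI in dB.
#' @export
model_mpi <- function(population, criterion = 10000, dt = 1e-6) {
  t80 <- find_threshold(population,
                        make_biphasic_train(80, 25e-6, 8e-6, 0.4, 1),
                        criterion, dt = dt)
  t1000 <- find_threshold(population,
                          make_biphasic_train(1000, 25e-6, 8e-6, 0.4, 1),
                          criterion, dt = dt)
  compute_mpi(t80, t1000)
}

#' Model polarity effect of a population
#'
#' Criterion thresholds for 0.4-s, 80-pps quadraphasic trains (42-us
#' phases, 8-us gaps), cathodic- versus anodic-centred; PE is the
#' cathodic-centred threshold minus the anodic-centred threshold (negative
#' values mean a cathodic advantage).
#'
#' @inheritParams model_mpi
#' @return PE in dB.
#' @export
model_pe <- function(population, criterion = 10000, dt = 1e-6) {
  tc <- find_threshold(population,
                       make_quadraphasic_train("cathodic", 80, 42e-6, 8e-6,
                                               0.4, 1),
                       criterion, dt = dt)
  ta <- find_threshold(population,
                       make_quadraphasic_train("anodic", 80, 42e-6, 8e-6,
                                               0.4, 1),
                       criterion, dt = dt)
  compute_pe(tc, ta)
}

#' Run one of the modelling condition grids
#'
#' Reproduces the package's standard population experiments:
#' \describe{
#'   \item{`"ipg_retrograde"`}{IPG offset for healthy, peripheral-disabled
#'     and retrograde-demyelinated (k = 2, 4) populations.}
#'   \item{`"ipg_simultaneous"`}{IPG offset with both sites demyelinated
#'     simultaneously (k = 2, 4, 8; peripheral enabled), plus healthy.}
#'   \item{`"pe"`}{Polarity effect for healthy, peripheral-disabled, and
#'     peripheral-disabled plus central demyelination (k = 2).}
#'   \item{`"mpi_sd"`}{MPI at threshold SDs of 0.5 and 3 dB (n = 1000).}
#'   \item{`"mpi_n"`}{MPI as a function of threshold SD for populations of
#'     500 and 1000 fibres at a common 10,000-spike criterion.}
#' }
#'
#' @param scenario One of the grid names above (aliases `"fig5"` ...
#'   `"fig9"` in the same order are accepted).
#' @param seed Master seed.
#' @param n_fibres Population size for the single-population scenarios.
#' @param sd_threshold_db Threshold SD for the IPG and PE scenarios, dB.
#' @param criterion Spike-count criterion for threshold-based metrics.
#' @param sd_grid Threshold SDs used by `"mpi_n"`.
#' @param dt Integration step, seconds.
#' @return Data frame with columns `scenario`, `condition`, `metric`,
#'   `value_db`.
#' @export
run_figure_suite <- function(scenario = c("ipg_retrograde",
                                          "ipg_simultaneous", "pe",
                                          "mpi_sd", "mpi_n", "fig5", "fig6",
                                          "fig7", "fig8", "fig9"),
                             seed = 1L, n_fibres = 1000,
                             sd_threshold_db = 3, criterion = 10000,
                             sd_grid = c(0.5, 1, 2, 3), dt = 1e-6) {
  scenario <- match.arg(scenario)
  scenario <- switch(scenario, fig5 = "ipg_retrograde",
                     fig6 = "ipg_simultaneous", fig7 = "pe",
                     fig8 = "mpi_sd", fig9 = "mpi_n", scenario)
  pop <- function(deg, n = n_fibres, sd = sd_threshold_db, k = 1L) {
    sample_population(population_config(n, sd, degeneration = deg,
                                        seed = .subseed(seed, k)))
  }
  rows <- switch(scenario,
    ipg_retrograde = {
      conds <- list(healthy = degeneration_spec("none"),
                    peripheral_off = degeneration_spec("peripheral_disabled"),
                    retrograde_k2 = degeneration_spec("retrograde", 2),
                    retrograde_k4 = degeneration_spec("retrograde", 4))
      data.frame(condition = names(conds), metric = "ipg_offset_db",
                 value_db = vapply(seq_along(conds), function(i)
                   model_ipg_offset(pop(conds[[i]], k = i), dt = dt),
                   numeric(1)))
    },
    ipg_simultaneous = {
      ks <- c(1, 2, 4, 8)
      data.frame(condition = paste0("simultaneous_k", ks),
                 metric = "ipg_offset_db",
                 value_db = vapply(seq_along(ks), function(i) {
                   deg <- if (ks[i] == 1) degeneration_spec("none") else
                     degeneration_spec("simultaneous", ks[i])
                   model_ipg_offset(pop(deg, k = i), dt = dt)
                 }, numeric(1)))
    },
    pe = {
      conds <- list(healthy = degeneration_spec("none"),
                    peripheral_off = degeneration_spec("peripheral_disabled"),
                    retrograde_k2 = degeneration_spec("retrograde", 2))
      data.frame(condition = names(conds), metric = "pe_db",
                 value_db = vapply(seq_along(conds), function(i)
                   model_pe(pop(conds[[i]], k = i),
                            criterion = criterion * n_fibres / 1000, dt = dt),
                   numeric(1)))
    },
    mpi_sd = {
      sds <- c(0.5, 3)
      data.frame(condition = paste0("sd_", sds), metric = "mpi_db",
                 value_db = vapply(seq_along(sds), function(i)
                   model_mpi(pop(degeneration_spec("none"), sd = sds[i],
                                 k = i),
                             criterion = criterion * n_fibres / 1000,
                             dt = dt), numeric(1)))
    },
    mpi_n = {
      grid <- expand.grid(sd = sd_grid, n = c(500, 1000))
      # common absolute criterion for both population sizes: the n
      # comparison is only meaningful with the criterion held fixed
      data.frame(condition = paste0("n", grid$n, "_sd", grid$sd),
                 metric = "mpi_db",
                 value_db = vapply(seq_len(nrow(grid)), function(i)
                   model_mpi(pop(degeneration_spec("none"), n = grid$n[i],
                                 sd = grid$sd[i], k = i),
                             criterion = criterion, dt = dt), numeric(1)))
    })
  cbind(scenario = scenario, rows)
}
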
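# Adaptive one-up/one-down detection-threshold procedure and virtual
# listeners.

#' Configuration of the adaptive staircase
#'
#' One-up/one-down tracking in clinical current-level (CL) units: a heard
#' response lowers the level by one step, a missed one raises it. The step
#' starts at `initial_step` (4 CL, about 0.63 dB) and is reduced to
#' `reduced_step` (2 CL, about 0.31 dB) after `reversals_to_reduce`
#' reversals; the run stops at `stop_reversals` reversals and the threshold
#' is the mean level of the last `reversals_averaged` of them.
#'
#' @param start_cl Starting level in CL units (clinically, 90 % of the
#'   "comfortable" level from loudness scaling).
#' @param initial_step,reduced_step Step sizes in CL units.
#' @param reversals_to_reduce Number of reversals after which the step is
#'   reduced.
#' @param stop_reversals Total reversals at which the run terminates.
#' @param reversals_averaged How many final reversal levels form the
#'   threshold estimate.
#' @param floor_cl,ceiling_cl Device/safety limits; a track pushed beyond a
#'   limit twice consecutively aborts with a flag rather than fabricating
#'   reversals.
#' @export
staircase_config <- function(start_cl, initial_step = 4, reduced_step = 2,
                             reversals_to_reduce = 2, stop_reversals = 8,
                             reversals_averaged = 6, floor_cl = 0,
                             ceiling_cl = 255) {
  stopifnot(initial_step > 0, reduced_step > 0,
            reversals_averaged <= stop_reversals,
            start_cl >= floor_cl, start_cl <= ceiling_cl)
  structure(list(start_cl = start_cl, initial_step = initial_step,
                 reduced_step = reduced_step,
                 reversals_to_reduce = reversals_to_reduce,
                 stop_reversals = stop_reversals,
                 reversals_averaged = reversals_averaged,
                 floor_cl = floor_cl, ceiling_cl = ceiling_cl),
            class = "staircase_config")
}

#' Run one adaptive staircase
#'
#' @param listener A response oracle: `function(level_cl)` returning `TRUE`
#'   if the stimulus at that level was heard. Stochastic listeners should
#'   consume the R random stream, which this function seeds.
#' @param config A [staircase_config()].
#' @param seed Integer seed for the listener's randomness (the staircase
#'   logic itself is deterministic).
#' @return An `adaptive_track`: a list with `trials` (data frame of
#'   `trial`, `level_cl`, `heard`, `is_reversal`), `reversal_levels_cl`,
#'   `threshold_cl`, `threshold_db` and `aborted`.
#' @details A reversal is a trial whose implied step direction differs from
#'   the previous step's direction; the starting descent is not a reversal.
#' @export
run_staircase <- function(listener, config, seed = 1L) {
  stopifnot(is.function(listener), inherits(config, "staircase_config"))
  .with_seed(seed, {
    level <- config$start_cl
    dir_prev <- NA_integer_       # -1 down, +1 up
    n_rev <- 0L
    rev_levels <- numeric(0)
    trials <- list()
    t <- 0L
    limit_hits <- 0L
    aborted <- FALSE
    while (n_rev < config$stop_reversals) {
      t <- t + 1L
      heard <- isTRUE(listener(level))
      dir_new <- if (heard) -1L else 1L
      is_rev <- !is.na(dir_prev) && dir_new != dir_prev
      if (is_rev) {
        n_rev <- n_rev + 1L
        rev_levels <- c(rev_levels, level)
      }
      trials[[t]] <- data.frame(trial = t, level_cl = level, heard = heard,
                                is_reversal = is_rev)
      if (n_rev >= config$stop_reversals) break
      step <- if (n_rev >= config$reversals_to_reduce) config$reduced_step
              else config$initial_step
      nxt <- level + dir_new * step
      if (nxt < config$floor_cl || nxt > config$ceiling_cl) {
        limit_hits <- limit_hits + 1L
        nxt <- min(max(nxt, config$floor_cl), config$ceiling_cl)
        if (limit_hits >= 2L && nxt == level) {
          aborted <- TRUE
          break
        }
      } else limit_hits <- 0L
      dir_prev <- dir_new
      level <- nxt
    }
    trials <- do.call(rbind, trials)
    threshold_cl <- if (aborted || n_rev < config$stop_reversals) NA_real_
      else mean(utils::tail(rev_levels, config$reversals_averaged))
    structure(list(trials = trials, reversal_levels_cl = rev_levels,
                   threshold_cl = threshold_cl,
                   threshold_db = if (is.na(threshold_cl)) NA_real_
                                  else cl_to_db(threshold_cl),
                   aborted = aborted, config = config),
              class = "adaptive_track")
  })
}

#' @export
print.adaptive_track <- function(x, ...) {
  cat(sprintf("adaptive track: %d trials, %d reversals, threshold %.2f CL (%.2f dB)%s\n",
              nrow(x$trials), length(x$reversal_levels_cl), x$threshold_cl,
              x$threshold_db, if (x$aborted) " [ABORTED]" else ""))
  invisible(x)
}

#' Average two staircase runs into one detection threshold
#'
#' @param track1,track2 [run_staircase()] results (or bare thresholds in
#'   dB). If one run is missing or aborted, the other run's value is
#'   returned with attribute `single_run = TRUE`.
#' @return Threshold in dB re 1 uA.
#' @export
two_run_threshold <- function(track1, track2 = NULL) {
  thr <- function(x) {
    if (is.null(x)) return(NA_real_)
    if (inherits(x, "adaptive_track")) x$threshold_db else as.numeric(x)
  }
  t1 <- thr(track1)
  t2 <- thr(track2)
  if (is.na(t1) && is.na(t2)) return(NA_real_)
  if (is.na(t1) || is.na(t2)) {
    out <- if (is.na(t1)) t2 else t1
    attr(out, "single_run") <- TRUE
    return(out)
  }
  mean(c(t1, t2))
}

#' Virtual listener driven by the population model
#'
#' Returns a response oracle for [run_staircase()]: on each trial the
#' population's spike count for one fresh presentation of the stimulus at
#' the probed level is simulated, and the stimulus is "heard" when the
#' count reaches `criterion`. Stochasticity comes from the per-pulse
#' threshold noise; each trial uses an independent noise stream.
#'
#' @param population An [sample_population()] object.
#' @param train Stimulus `pulse_train` (level overridden per trial).
#' @param criterion Spike-count detection criterion.
#' @param dt Integration step, seconds.
#' @return `function(level_cl) -> logical`.
#' @export
model_listener <- function(population, train, criterion, dt = 1e-6) {
  trial <- 0L
  function(level_cl) {
    trial <<- trial + 1L
    rlf <- population_rate_level(population, train, cl_to_db(level_cl),
                                 trial = trial, dt = dt)
    rlf$count[1] >= criterion
  }
}

#' Parametric virtual listener
#'
#' A listener whose detection probability is a cumulative Gaussian of level
#' in CL units: `p(heard) = pnorm((level - threshold)/slope)`. Used by the
#' synthetic-study generator and in staircase validation.
#'
#' @param threshold_cl 50 %-point of the psychometric function, CL units.
#' @param slope_cl Spread of the psychometric function in CL units; 0 gives
#'   a deterministic listener.
#' @return `function(level_cl) -> logical` (consumes the R random stream).
#' @export
parametric_listener <- function(threshold_cl, slope_cl = 0) {
  function(level_cl) {
    if (slope_cl <= 0) return(level_cl >= threshold_cl)
    stats::runif(1) < stats::pnorm((level_cl - threshold_cl) / slope_cl)
  }
}
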
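# Synthetic-study generation: ground-truth neural states, AGF pairs,
# staircase logs and metric tables for an 11-subject x 7-electrode study,
# plus parameter-recovery reporting.

.CL_STEP_DB <- 40 / 255  # dB per clinical current-level unit

.soft_floor <- function(amp, floor_db, beta = 1) {
  beta * log10(10^(amp / beta) + 10^(floor_db / beta))
}

.soft_sat <- function(amp, sat_db, beta = 1) {
  -beta * log10(10^(-amp / beta) + 10^(-sat_db / beta))
}

.default_electrodes <- function(n) {
  if (n == 7) c(3, 6, 9, 12, 15, 18, 20) else
    round(seq(3, 20, length.out = n))
}

#' Generate a complete synthetic neural-health study
#'
#' Emulates the structure of an 11-subject, 7-electrode study: per-electrode
#' ground-truth neural state, ECAP amplitude-growth-function pairs at IPGs
#' of 8 and 40 us (with noise floor, saturation and Gaussian amplitude
#' noise), two adaptive staircase runs per behavioural condition
#' (80/1000 pps biphasic, cathodic-/anodic-centred quadraphasic), and the
#' metric table recovered from those synthetic measurements with the
#' package's own pipeline. By default three subjects have no measurable
#' ECAPs (and one of them no MPI), so missing-data paths are exercised.
#'
#' Two backends are available. The `"parametric"` backend programs the true
#' metric values directly (AGFs are lines with a programmed vertical offset
#' pushed through soft floor/saturation clipping; staircases run against
#' parametric listeners) and is fast enough for Monte-Carlo work. The
#' `"model"` backend drives a spiral-ganglion population simulation per
#' electrode: `peripheral_survival` sets the fraction of fibres with intact
#' peripheral processes, `demyelination_factor` the retrograde
#' demyelination of the degenerated remainder, and staircases run against
#' [model_listener()] oracles.
#'
#' @param n_subjects,n_electrodes Study grid (>= 2 subjects, >= 3
#'   electrodes).
#' @param scenario `"coupled"`: one latent neural-health factor per
#'   electrode drives all three metrics (positive within-subject
#'   correlations by construction, with the sign conventions MPI+, PE-,
#'   IPG+ for good health). `"null"`: the three metrics are driven by
#'   independent latents.
#' @param master_seed Integer; regeneration with the same seed reproduces
#'   the study (and its CSV serialisations) byte-identically.
#' @param backend `"parametric"` (default) or `"model"`.
#' @param measurement_noise_db SD of the AGF amplitude noise, dB.
#' @param missing_ecap Indices of subjects without measurable ECAPs
#'   (default 2, 5, 6 as far as the grid allows; the last of them also
#'   lacks MPI).
#' @param n_fibres Population size per electrode for the model backend.
#' @return A `synthetic_study` list with elements `profiles`, `agf_tables`,
#'   `staircase_logs`, `metrics` (per-run), `measures` (run-averaged, one
#'   row per subject x electrode), `truth`, and the generation settings.
#' @export
generate_study <- function(n_subjects = 11, n_electrodes = 7,
                           scenario = c("coupled", "null"),
                           master_seed = 1L,
                           backend = c("parametric", "model"),
                           measurement_noise_db = 0.5,
                           missing_ecap = NULL, n_fibres = 60) {
  scenario <- match.arg(scenario)
  backend <- match.arg(backend)
  if (n_subjects < 2 || n_electrodes < 3)
    stop("need n_subjects >= 2 and n_electrodes >= 3", call. = FALSE)
  if (is.null(missing_ecap))
    missing_ecap <- intersect(c(2, 5, 6), seq_len(n_subjects))
  electrodes <- .default_electrodes(n_electrodes)
  subjects <- sprintf("S%d", seq_len(n_subjects))

  .with_seed(master_seed, {
    grid <- expand.grid(si = seq_len(n_subjects),
                        ei = seq_len(n_electrodes))
    grid <- grid[order(grid$si, grid$ei), ]
    n <- nrow(grid)

    subj_shift <- stats::rnorm(n_subjects, 0, 1.5)   # non-neural, per subject
    elec_offset <- stats::rnorm(n, 0, 2)             # non-neural, per electrode

    l_health <- stats::rnorm(n)                      # latent neural health
    l2 <- stats::rnorm(n)
    l3 <- stats::rnorm(n)
    if (scenario == "coupled") {
      lm_ <- lp <- li <- l_health
    } else {
      lm_ <- l_health; lp <- l2; li <- l3
    }
    truth <- data.frame(
      subject = subjects[grid$si], electrode = electrodes[grid$ei],
      true_mpi_db = 3 + 0.8 * lm_,
      true_pe_db = -0.5 - 1.2 * lp,
      true_ipg_db = 1.5 + 0.6 * li,
      electrode_offset_db = elec_offset)

    profiles <- data.frame(
      subject = truth$subject, electrode = truth$electrode,
      peripheral_survival = stats::plogis(-truth$true_pe_db),
      demyelination_factor = pmax(1, pmin(2.5, 3 - truth$true_ipg_db)),
      threshold_sd_db = pmax(0.3, truth$true_mpi_db - 2),
      electrode_offset_db = elec_offset,
      measurement_noise_db = measurement_noise_db)

    gen <- if (backend == "parametric") {
      .generate_parametric(truth, subj_shift[grid$si], measurement_noise_db)
    } else {
      .generate_model(truth, profiles, n_fibres)
    }

    # recover the metric table from the synthetic measurements using the
    # package's own pipeline (model AGFs are steep log-count curves, for
    # which the equal-output horizontal reading is the stable one)
    metrics <- .recover_metrics(gen, truth, subjects, missing_ecap,
                                mode = if (backend == "model") "horizontal"
                                       else "vertical")

    structure(list(profiles = profiles, agf_tables = gen$agf,
                   staircase_logs = gen$logs, metrics = metrics$per_run,
                   measures = metrics$aggregated, truth = truth,
                   scenario = scenario, backend = backend,
                   master_seed = master_seed,
                   missing_ecap = subjects[missing_ecap]),
              class = "synthetic_study")
  })
}

# parametric backend: programmed AGF lines + parametric staircase listeners
.generate_parametric <- function(truth, subj_shift, noise_db) {
  n <- nrow(truth)
  floor_db <- 20
  agf_rows <- vector("list", n)
  log_rows <- list()
  thr_rows <- vector("list", n)
  slope <- 2                      # AGF growth, dB amplitude per dB current
  for (i in seq_len(n)) {
    base_db <- 45 + truth$electrode_offset_db[i] + subj_shift[i]
    levels <- base_db + (0:13) * 3 * .CL_STEP_DB
    amp_s <- floor_db - 1 + slope * (levels - levels[1])
    amp_l <- amp_s + truth$true_ipg_db[i]
    sat_db <- max(amp_l) + 4
    obs <- function(a) {
      .soft_sat(.soft_floor(a, floor_db), sat_db) +
        stats::rnorm(length(a), 0, noise_db)
    }
    agf_rows[[i]] <- data.frame(
      subject = truth$subject[i], electrode = truth$electrode[i],
      ipg_us = rep(c(8, 40), each = length(levels)),
      level_db_re_1uA = c(levels, levels),
      amplitude_db_re_1uV = c(obs(amp_s), obs(amp_l)),
      floor_db = floor_db)

    # behavioural thresholds (CL units) with the programmed MPI and PE
    t1000_cl <- db_to_cl(38 + truth$electrode_offset_db[i] + subj_shift[i])
    t80_cl <- t1000_cl + truth$true_mpi_db[i] / .CL_STEP_DB
    qp_cl <- t80_cl + 8
    thr <- c(bi80 = t80_cl, bi1000 = t1000_cl,
             qp_cathodic = qp_cl + truth$true_pe_db[i] / (2 * .CL_STEP_DB),
             qp_anodic = qp_cl - truth$true_pe_db[i] / (2 * .CL_STEP_DB))
    rec <- list()
    for (stim in names(thr)) {
      cfg <- staircase_config(start_cl = min(thr[[stim]] + 20, 255))
      for (run in 1:2) {
        tr <- run_staircase(parametric_listener(thr[[stim]], slope_cl = 2),
                            cfg,
                            seed = .subseed(1e4 + i * 8,
                                            match(stim, names(thr)) * 2 + run))
        lg <- tr$trials
        lg$subject <- truth$subject[i]
        lg$electrode <- truth$electrode[i]
        lg$stimulus <- stim
        lg$run <- run
        log_rows[[length(log_rows) + 1L]] <- lg
        rec[[paste(stim, run, sep = "_")]] <- tr$threshold_db
      }
    }
    thr_rows[[i]] <- data.frame(subject = truth$subject[i],
                                electrode = truth$electrode[i],
                                as.data.frame(rec))
  }
  list(agf = do.call(rbind, agf_rows), logs = do.call(rbind, log_rows),
       thresholds = do.call(rbind, thr_rows))
}

# model backend: population simulation per electrode profile
.generate_model <- function(truth, profiles, n_fibres) {
  n <- nrow(truth)
  agf_rows <- vector("list", n)
  log_rows <- list()
  thr_rows <- vector("list", n)
  criterion <- 10 * n_fibres
  for (i in seq_len(n)) {
    n_healthy <- round(n_fibres * profiles$peripheral_survival[i])
    k <- max(1, profiles$demyelination_factor[i])
    seed_i <- .subseed(7e5, i)
    pops <- list()
    if (n_healthy > 0)
      pops$healthy <- sample_population(population_config(
        n_healthy, profiles$threshold_sd_db[i], seed = seed_i))
    if (n_fibres - n_healthy > 0)
      pops$degen <- sample_population(population_config(
        n_fibres - n_healthy, profiles$threshold_sd_db[i],
        degeneration = if (k > 1) degeneration_spec("retrograde", k)
                       else degeneration_spec("peripheral_disabled"),
        seed = seed_i + 1))
    ref <- attr(reference_fibre_params(), "ref_threshold_db")
    mix_counts <- function(train, levels_db, trial = 0) {
      ct <- 0
      for (p in pops)
        ct <- ct + population_rate_level(p, train, levels_db,
                                         trial = trial)$count
      ct
    }
    # AGF pair from pooled spike counts (floor: one spike per pulse scale)
    span <- 2.5 * profiles$threshold_sd_db[i] + 8 + 20 * log10(k)
    grid_db <- seq(ref - span, ref + span, by = 0.5) +
      truth$electrode_offset_db[i]
    for (ipg in c(8e-6, 40e-6)) {
      tr <- make_biphasic_train(80, 25e-6, ipg, 0.4, 1)
      ct <- mix_counts(tr, grid_db - truth$electrode_offset_db[i])
      keep <- ct > 0
      agf_rows[[length(agf_rows) + 1L]] <- data.frame(
        subject = truth$subject[i], electrode = truth$electrode[i],
        ipg_us = ipg * 1e6, level_db_re_1uA = grid_db[keep],
        amplitude_db_re_1uV = 20 * log10(ct[keep]),
        floor_db = 20 * log10(0.5 * n_fibres / 60 * 50))
    }
    # staircase thresholds against the model listener
    stims <- list(bi80 = make_biphasic_train(80, 25e-6, 8e-6, 0.4, 1),
                  bi1000 = make_biphasic_train(1000, 25e-6, 8e-6, 0.4, 1),
                  qp_cathodic = make_quadraphasic_train("cathodic", 80,
                                                        42e-6, 8e-6, 0.4, 1),
                  qp_anodic = make_quadraphasic_train("anodic", 80, 42e-6,
                                                      8e-6, 0.4, 1))
    rec <- list()
    for (s in names(stims)) {
      start_cl <- db_to_cl(ref + 12 + 2.5 * profiles$threshold_sd_db[i])
      cfg <- staircase_config(start_cl = start_cl)
      for (run in 1:2) {
        trial_base <- (match(s, names(stims)) * 2 + run) * 1000L
        listener <- local({
          tb <- trial_base; trial <- 0L; stim <- stims[[s]]
          function(level_cl) {
            trial <<- trial + 1L
            ct <- mix_counts(stim,
                             cl_to_db(level_cl) -
                               truth$electrode_offset_db[i],
                             trial = tb + trial)
            ct >= criterion
          }
        })
        tr <- run_staircase(listener, cfg, seed = seed_i + run)
        lg <- tr$trials
        lg$subject <- truth$subject[i]
        lg$electrode <- truth$electrode[i]
        lg$stimulus <- s
        lg$run <- run
        log_rows[[length(log_rows) + 1L]] <- lg
        rec[[paste(s, run, sep = "_")]] <- tr$threshold_db
      }
    }
    thr_rows[[i]] <- data.frame(subject = truth$subject[i],
                                electrode = truth$electrode[i],
                                as.data.frame(rec))
  }
  list(agf = do.call(rbind, agf_rows), logs = do.call(rbind, log_rows),
       thresholds = do.call(rbind, thr_rows))
}

# run the metrics pipeline over the generated measurements
.recover_metrics <- function(gen, truth, subjects, missing_ecap,
                             mode = "vertical") {
  thr <- gen$thresholds
  no_ecap <- subjects[missing_ecap]
  no_mpi <- if (length(missing_ecap) >= 3) subjects[missing_ecap[3]] else
    character(0)
  per_run <- do.call(rbind, lapply(seq_len(nrow(thr)), function(i) {
    s <- thr$subject[i]
    e <- thr$electrode[i]
    ipg <- if (s %in% no_ecap) NA_real_ else {
      a <- gen$agf[gen$agf$subject == s & gen$agf$electrode == e, ]
      short <- a[a$ipg_us == 8, ]
      long <- a[a$ipg_us == 40, ]
      monotone <- function(x) {
        if (mode != "horizontal") return(x)
        inc <- which(!x$excluded)
        keep <- inc[c(TRUE, diff(cummax(x$amplitude_db[inc])) > 0)]
        x$excluded <- !(seq_len(nrow(x)) %in% keep)
        x
      }
      tryCatch({
        as_ <- monotone(trim_to_linear_region(
          agf(short$level_db_re_1uA, short$amplitude_db_re_1uV, 8,
              floor_db = short$floor_db[1])))
        al <- monotone(trim_to_linear_region(
          agf(long$level_db_re_1uA, long$amplitude_db_re_1uV, 40,
              floor_db = long$floor_db[1])))
        ipg_offset(as_, al, mode = mode)
      }, error = function(err) NA_real_)
    }
    data.frame(subject = s, electrode = e, run = 1:2,
               mpi_db = if (s %in% no_mpi) NA_real_ else
                 c(compute_mpi(thr$bi80_1[i], thr$bi1000_1[i]),
                   compute_mpi(thr$bi80_2[i], thr$bi1000_2[i])),
               pe_db = c(compute_pe(thr$qp_cathodic_1[i], thr$qp_anodic_1[i]),
                         compute_pe(thr$qp_cathodic_2[i], thr$qp_anodic_2[i])),
               ipg_offset_db = c(ipg, NA_real_))
  }))
  agg <- do.call(rbind, lapply(split(per_run, list(per_run$subject,
                                                   per_run$electrode),
                                     drop = TRUE), function(d) {
    data.frame(subject = d$subject[1], electrode = d$electrode[1],
               mpi_db = mean(d$mpi_db, na.rm = TRUE),
               pe_db = mean(d$pe_db, na.rm = TRUE),
               ipg_offset_db = mean(d$ipg_offset_db, na.rm = TRUE))
  }))
  agg$mpi_db[is.nan(agg$mpi_db)] <- NA_real_
  agg$ipg_offset_db[is.nan(agg$ipg_offset_db)] <- NA_real_
  rownames(agg) <- NULL
  agg <- agg[order(agg$subject, agg$electrode), ]
  list(per_run = per_run, aggregated = agg)
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("synthetic study (%s backend, scenario \"%s\"): %d subjects x %d electrodes, seed %d\n",
              x$backend, x$scenario, length(unique(x$truth$subject)),
              length(unique(x$truth$electrode)), x$master_seed))
  if (length(x$missing_ecap))
    cat("  no measurable ECAPs:", paste(x$missing_ecap, collapse = ", "),
        "\n")
  invisible(x)
}

#' Parameter-recovery report for a synthetic study
#'
#' Compares the programmed (ground-truth) metric values with the values
#' recovered by the package's measurement pipeline, per metric: Pearson
#' correlation, mean bias (recovered minus programmed) and RMSE.
#'
#' @param study A [generate_study()] result.
#' @return Data frame with one row per metric.
#' @export
parameter_recovery_report <- function(study) {
  stopifnot(inherits(study, "synthetic_study"))
  d <- merge(study$measures, study$truth, by = c("subject", "electrode"))
  one <- function(metric, rec, prog) {
    ok <- stats::complete.cases(rec, prog)
    data.frame(metric = metric, n = sum(ok),
               r = if (sum(ok) > 2) stats::cor(rec[ok], prog[ok]) else
                 NA_real_,
               bias_db = mean(rec[ok] - prog[ok]),
               rmse_db = sqrt(mean((rec[ok] - prog[ok])^2)))
  }
  rbind(one("mpi", d$mpi_db, d$true_mpi_db),
        one("pe", d$pe_db, d$true_pe_db),
        one("ipg_offset", d$ipg_offset_db, d$true_ipg_db))
}

#' Write a synthetic study to CSV files
#'
#' Emits `profiles.csv`, `agf.csv`, `staircase_logs.csv` and `metrics.csv`
#' in the schemas consumed by the metrics and correlation analyses.
#'
#' @param study A [generate_study()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(study$profiles, file.path(dir, "profiles.csv"),
                   row.names = FALSE)
  utils::write.csv(study$agf_tables, file.path(dir, "agf.csv"),
                   row.names = FALSE)
  utils::write.csv(study$staircase_logs,
                   file.path(dir, "staircase_logs.csv"), row.names = FALSE)
  utils::write.csv(study$metrics, file.path(dir, "metrics.csv"),
                   row.names = FALSE)
  invisible(dir)
}
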
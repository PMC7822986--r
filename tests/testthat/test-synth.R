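# Synthetic-study generation and parameter recovery.

test_that("regeneration from the master seed is identical", {
  a <- generate_study(n_subjects = 4, n_electrodes = 3, master_seed = 9)
  b <- generate_study(n_subjects = 4, n_electrodes = 3, master_seed = 9)
  expect_identical(a$agf_tables, b$agf_tables)
  expect_identical(a$staircase_logs, b$staircase_logs)
  expect_identical(a$metrics, b$metrics)
  d1 <- file.path(tempdir(), "study1")
  d2 <- file.path(tempdir(), "study2")
  write_study(a, d1)
  write_study(b, d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  }
  c_ <- generate_study(n_subjects = 4, n_electrodes = 3, master_seed = 10)
  expect_false(identical(a$metrics, c_$metrics))
})

test_that("the study grid mirrors the intended structure", {
  s <- generate_study(master_seed = 3)   # default 11 x 7
  expect_identical(length(unique(s$truth$subject)), 11L)
  expect_identical(sort(unique(s$truth$electrode)),
                   c(3, 6, 9, 12, 15, 18, 20))
  expect_identical(s$missing_ecap, c("S2", "S5", "S6"))
  m <- s$measures
  expect_true(all(is.na(m$ipg_offset_db[m$subject %in% s$missing_ecap])))
  expect_true(all(is.na(m$mpi_db[m$subject == "S6"])))
  expect_true(all(is.finite(m$pe_db)))
  # two staircase runs per condition per electrode
  lg <- s$staircase_logs
  runs <- unique(lg[, c("subject", "electrode", "stimulus", "run")])
  expect_identical(nrow(runs), 11L * 7L * 4L * 2L)
})

test_that("noiseless parametric AGFs return the programmed IPG offsets", {
  s <- generate_study(n_subjects = 5, n_electrodes = 5,
                      measurement_noise_db = 0, master_seed = 4,
                      missing_ecap = integer(0))
  d <- merge(s$measures, s$truth, by = c("subject", "electrode"))
  expect_true(all(abs(d$ipg_offset_db - d$true_ipg_db) < 0.05))
})

test_that("recovery stays accurate under realistic measurement noise", {
  s <- generate_study(measurement_noise_db = 0.5, master_seed = 5,
                      missing_ecap = integer(0))
  rep <- parameter_recovery_report(s)
  expect_identical(rep$metric, c("mpi", "pe", "ipg_offset"))
  expect_gte(rep$n[rep$metric == "ipg_offset"], 75L)
  expect_gt(rep$r[rep$metric == "ipg_offset"], 0.9)
  expect_gt(rep$r[rep$metric == "mpi"], 0.8)
  expect_gt(rep$r[rep$metric == "pe"], 0.8)
  expect_lt(abs(rep$bias_db[rep$metric == "ipg_offset"]), 0.1)
})

test_that("staircase-recovered MPI is unbiased against the programmed truth", {
  bias <- vapply(1:3, function(i) {
    s <- generate_study(n_subjects = 5, n_electrodes = 5, master_seed = 30 + i)
    d <- merge(s$measures, s$truth, by = c("subject", "electrode"))
    mean(d$mpi_db - d$true_mpi_db, na.rm = TRUE)
  }, numeric(1))
  expect_lt(abs(mean(bias)), 0.5)
})

test_that("null and coupled scenarios produce the programmed structure", {
  null <- generate_study(scenario = "null", master_seed = 6)
  m <- null$measures
  r_null <- within_subject_correlation(m, "mpi_db", "pe_db")
  expect_lt(abs(r_null$r), 2.5 / sqrt(r_null$df))

  cpl <- generate_study(scenario = "coupled", master_seed = 7)
  mc <- cpl$measures
  # one latent health factor: MPI up, PE down, IPG offset up
  r1 <- within_subject_correlation(mc, "mpi_db", "pe_db")
  r2 <- within_subject_correlation(mc, "mpi_db", "ipg_offset_db")
  r3 <- within_subject_correlation(mc, "pe_db", "ipg_offset_db")
  expect_lt(r1$r, 0)
  expect_gt(r2$r, 0)
  expect_lt(r3$r, 0)
  expect_lt(r1$p, 0.01)
  expect_lt(r2$p, 0.01)
  expect_lt(r3$p, 0.01)
})

test_that("non-neural electrode offsets cancel out of the recovered metrics", {
  # the differential-measure rationale: a common level offset moves both
  # AGFs and both thresholds of a pair, leaving the metrics unchanged
  s <- generate_study(n_subjects = 4, n_electrodes = 5,
                      measurement_noise_db = 0, master_seed = 8,
                      missing_ecap = integer(0))
  d <- merge(s$measures, s$truth, by = c("subject", "electrode"))
  expect_gt(diff(range(d$electrode_offset_db)), 2)  # offsets really vary
  expect_true(all(abs(d$ipg_offset_db - d$true_ipg_db) < 0.05))
  expect_true(all(abs((d$mpi_db - d$true_mpi_db)) < 1.5))
})

test_that("the model backend drives populations end to end", {
  s <- generate_study(n_subjects = 2, n_electrodes = 3, backend = "model",
                      n_fibres = 40, master_seed = 12,
                      missing_ecap = integer(0))
  expect_identical(nrow(s$measures), 6L)
  expect_true(all(is.finite(s$measures$mpi_db)))
  expect_true(all(is.finite(s$measures$pe_db)))
  expect_true(sum(is.finite(s$measures$ipg_offset_db)) >= 4)
  expect_true(all(c("subject", "electrode", "ipg_us", "level_db_re_1uA",
                    "amplitude_db_re_1uV") %in% colnames(s$agf_tables)))
})
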
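# Dual-site fibre model: degeneration, integration, thresholds.

test_that("apply_degeneration implements the four modes", {
  p <- reference_fibre_params()
  expect_identical(apply_degeneration(p, degeneration_spec("none")), p)

  pd <- apply_degeneration(p, degeneration_spec("peripheral_disabled"))
  expect_false(pd$peripheral$enabled)
  expect_identical(pd$central, p$central)

  r2 <- apply_degeneration(p, degeneration_spec("retrograde", 2))
  expect_false(r2$peripheral$enabled)
  expect_equal(r2$central$capacitance, 2 * p$central$capacitance)
  expect_equal(r2$central$conductance, p$central$conductance / 2)

  r4 <- apply_degeneration(p, degeneration_spec("retrograde", 4))
  expect_equal(r4$central$capacitance, 4 * p$central$capacitance)
  expect_equal(r4$central$conductance, p$central$conductance / 4)

  s2 <- apply_degeneration(p, degeneration_spec("simultaneous", 2))
  expect_true(s2$peripheral$enabled)
  expect_equal(s2$peripheral$capacitance, 2 * p$peripheral$capacitance)
  expect_equal(s2$peripheral$conductance, p$peripheral$conductance / 2)
  expect_equal(s2$central$capacitance, 2 * p$central$capacitance)

  expect_error(degeneration_spec("melted"))
  expect_error(degeneration_spec("none", 2), "factor")
  expect_error(degeneration_spec("retrograde", 0.5), ">= 1")
})

test_that("integration is deterministic, silent at zero drive, and single
          spike per strong pulse", {
  p <- reference_fibre_params()
  zero <- make_biphasic_train(80, 25e-6, 8e-6, 0.4, 1e-9)
  expect_identical(nrow(integrate_fibre(zero, p, seed = 3)), 0L)

  thr <- single_pulse_threshold(std_biphasic(), p)$threshold_db
  one <- std_biphasic()
  one$n_pulses <- 1L
  strong <- set_level(one, db_to_microamps(thr + 20))  # 10x threshold
  sp <- integrate_fibre(strong, p, seed = 1)
  expect_identical(nrow(sp), 1L)

  tr <- set_level(std_biphasic(), db_to_microamps(thr + 2))
  a <- integrate_fibre(tr, p, seed = 7)
  b <- integrate_fibre(tr, p, seed = 7)
  expect_identical(a, b)
})

test_that("no two fibre spikes fall within the refractory period", {
  p <- reference_fibre_params()
  thr <- single_pulse_threshold(std_biphasic(), p)$threshold_db
  tr <- set_level(make_biphasic_train(1000, 25e-6, 8e-6, 0.4, 1),
                  db_to_microamps(thr + 6))
  sp <- integrate_fibre(tr, p, seed = 5)
  expect_gt(nrow(sp), 10)
  expect_true(all(diff(sp$time_s) >= p$peripheral$t_refractory - 2e-6))
})

test_that("coarse integration agrees with a 10x finer step", {
  # brute-force fine-step oracle on single pulses near threshold
  p <- reference_fibre_params()
  p$noise_rs <- 0
  shapes <- list(std_biphasic(), std_biphasic(40e-6), std_qp("cathodic"),
                 std_qp("anodic"))
  set.seed(99)
  for (i in 1:20) {
    tr <- shapes[[(i - 1) %% 4 + 1]]
    tr$n_pulses <- 1L
    thr <- single_pulse_threshold(tr, p)$threshold_db
    lvl <- thr + runif(1, -1, 2)
    tr <- set_level(tr, db_to_microamps(lvl))
    coarse <- integrate_fibre(tr, p, seed = i, dt = 1e-6)
    fine <- integrate_fibre(tr, p, seed = i, dt = 1e-7)
    expect_identical(nrow(coarse), nrow(fine))
    if (nrow(coarse) > 0)
      expect_lt(abs(coarse$time_s[1] - fine$time_s[1]), 20e-6)
  }
})

test_that("single-pulse threshold search reports the initiating site", {
  p <- reference_fibre_params()
  healthy <- single_pulse_threshold(std_biphasic(), p)
  expect_identical(healthy$site, "peripheral")

  pd <- apply_degeneration(p, degeneration_spec("peripheral_disabled"))
  central <- single_pulse_threshold(std_biphasic(), pd)
  expect_identical(central$site, "central")
  expect_gt(central$threshold_db, healthy$threshold_db)

  # monotone non-increasing in sensitivity
  p2 <- p
  p2$peripheral$sensitivity <- 2 * p$peripheral$sensitivity
  p2$central$sensitivity <- 2 * p$central$sensitivity
  expect_lt(single_pulse_threshold(std_biphasic(), p2)$threshold_db,
            healthy$threshold_db)

  expect_error(single_pulse_threshold(std_biphasic(), p, upper_db = 5),
               "upper")
})

test_that("polarity symmetry: identical sites give equal centred thresholds", {
  p <- symmetric_fibre()
  tc <- single_pulse_threshold(std_qp("cathodic"), p)$threshold_db
  ta <- single_pulse_threshold(std_qp("anodic"), p)$threshold_db
  expect_lt(abs(tc - ta), 0.05)
})

test_that("demyelination raises the single-pulse threshold monotonically", {
  p <- reference_fibre_params()
  thr <- vapply(c(1, 2, 4, 8), function(k) {
    deg <- if (k == 1) degeneration_spec("peripheral_disabled") else
      degeneration_spec("retrograde", k)
    single_pulse_threshold(std_biphasic(), apply_degeneration(p, deg),
                           upper_db = 130)$threshold_db
  }, numeric(1))
  expect_true(all(diff(thr) > 0))
})

test_that("calibrated reference anchors hold", {
  p <- reference_fibre_params()
  # cathodic-centred advantage for healthy fibres
  tc <- single_pulse_threshold(std_qp("cathodic"), p)$threshold_db
  ta <- single_pulse_threshold(std_qp("anodic"), p)$threshold_db
  expect_lt(tc, ta)
  # ~2 dB anodic advantage without peripheral processes
  pd <- apply_degeneration(p, degeneration_spec("peripheral_disabled"))
  tcd <- single_pulse_threshold(std_qp("cathodic"), pd)$threshold_db
  tad <- single_pulse_threshold(std_qp("anodic"), pd)$threshold_db
  expect_gt(tcd - tad, 1)
  expect_lt(tcd - tad, 3.5)
  # thresholds fall as the interphase gap grows, at either site
  for (prm in list(p, pd)) {
    t8 <- single_pulse_threshold(std_biphasic(8e-6), prm)$threshold_db
    t40 <- single_pulse_threshold(std_biphasic(40e-6), prm)$threshold_db
    expect_lt(t40, t8)
  }
  # frozen reference threshold attribute matches the simulation
  href <- single_pulse_threshold(std_biphasic(), p)$threshold_db
  expect_equal(attr(p, "ref_threshold_db"), href, tolerance = 0.01)
})
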
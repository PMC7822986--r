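# AGF trimming, IPG offset, MPI and PE arithmetic.

linear_agf <- function(ipg = 8, slope = 2, intercept = 0,
                       levels = seq(40, 46, by = 0.5), floor_db = NULL) {
  agf(levels, intercept + slope * levels, ipg_us = ipg, floor_db = floor_db)
}

# logistic AGF sampled across its whole range
sigmoid_agf <- function(ipg = 8, mid = 43, span = 30, width = 1.2,
                        floor_db = 5, levels = seq(37, 49, by = 0.5),
                        noise = 0, seed = 1) {
  # (span/floor geometry varies per test)
  set.seed(seed)
  amp <- floor_db + span * plogis((levels - mid) / width) +
    rnorm(length(levels), 0, noise)
  agf(levels, amp, ipg_us = ipg, floor_db = floor_db)
}

test_that("trimming keeps clean linear growth untouched", {
  a <- trim_to_linear_region(linear_agf())
  expect_false(any(a$excluded))
})

test_that("trimming excludes floor and saturation of a sigmoid", {
  # ECAP-like logistic: 8-dB dynamic range over a noise floor, sampled
  # across its full extent in 1-dB steps
  a <- trim_to_linear_region(sigmoid_agf(span = 8, width = 1.5,
                                         levels = seq(36, 50, by = 1)))
  kept <- which(!a$excluded)
  # analytic 20-80 % band of the logistic: mid +- width*log(4)
  band <- c(43 - 1.5 * log(4), 43 + 1.5 * log(4))
  lv <- a$level_db
  in_band <- which(lv >= band[1] & lv <= band[2])
  # kept region matches the linear band within one grid point either side
  expect_lte(abs(min(kept) - min(in_band)), 1)
  expect_lte(abs(max(kept) - max(in_band)), 1)
})

test_that("degenerate AGFs are rejected", {
  flat <- agf(seq(40, 43, 0.5), rep(5.2, 7), ipg_us = 8, floor_db = 5)
  expect_error(trim_to_linear_region(flat), "degenerate")
  expect_error(ipg_offset(linear_agf()[1, ], linear_agf()), ">= 2")
})

test_that("ipg_offset recovers programmed vertical gaps", {
  a <- trim_to_linear_region(linear_agf(ipg = 8))
  expect_equal(ipg_offset(a, a), 0)
  b <- a
  b$amplitude_db <- b$amplitude_db + 1.5
  expect_equal(ipg_offset(a, b), 1.5)
  # antisymmetry and exact response to a constant shift
  expect_equal(ipg_offset(b, a), -ipg_offset(a, b))
  cc <- a
  cc$amplitude_db <- cc$amplitude_db + 0.73
  expect_equal(ipg_offset(a, cc), 0.73, tolerance = 1e-12)
})

test_that("non-parallel lines give the closed-form mean gap", {
  # y_s = 2 L, y_l = 2.5 L - 18 over a common grid: gap g(L) = 0.5 L - 18
  # averaged over [40, 46] -> 0.5 * 43 - 18 = 3.5
  s <- agf(seq(40, 46, 0.5), 2.0 * seq(40, 46, 0.5), ipg_us = 8)
  l <- agf(seq(40, 46, 0.5), 2.5 * seq(40, 46, 0.5) - 18, ipg_us = 40)
  expect_lt(abs(ipg_offset(s, l) - 3.5), 0.01)
  # re-gridding invariance for piecewise-linear curves
  expect_lt(abs(ipg_offset(s, l, grid_db = 0.05) -
                  ipg_offset(s, l, grid_db = 0.1)), 0.01)
})

test_that("partial overlap uses only the shared support", {
  # overlap [42, 46]: mean gap = 0.5 * 44 - 18 = 4
  s <- agf(seq(40, 46, 0.5), 2.0 * seq(40, 46, 0.5), ipg_us = 8)
  l <- agf(seq(42, 49, 0.5), 2.5 * seq(42, 49, 0.5) - 18, ipg_us = 40)
  expect_lt(abs(ipg_offset(s, l) - 4), 0.01)
  no <- agf(seq(50, 55, 0.5), 2 * seq(50, 55, 0.5), ipg_us = 40)
  expect_error(ipg_offset(s, no), "overlap")
})

test_that("horizontal mode measures the equal-output current shift", {
  s <- agf(seq(40, 46, 0.5), 3 * seq(40, 46, 0.5), ipg_us = 8)
  l <- agf(seq(40, 46, 0.5) - 1.2, 3 * seq(40, 46, 0.5), ipg_us = 40)
  expect_equal(ipg_offset(s, l, mode = "horizontal"), 1.2,
               tolerance = 1e-9)
})

test_that("sigmoid pairs with floor and saturation recover their offset", {
  true_offset <- 1.8
  for (noise in c(0, 0.2)) {
    s <- trim_to_linear_region(sigmoid_agf(ipg = 8, noise = noise,
                                           seed = 11))
    l <- trim_to_linear_region(sigmoid_agf(ipg = 40, mid = 43,
                                           noise = noise, seed = 12))
    l$amplitude_db <- l$amplitude_db + true_offset
    tol <- if (noise == 0) 0.1 else 0.35
    expect_lt(abs(ipg_offset(s, l) - true_offset), tol)
  }
})

test_that("MPI and PE keep their sign conventions and missingness", {
  expect_identical(compute_mpi(40, 36), 4)
  expect_identical(compute_mpi(36, 36), 0)
  expect_identical(compute_mpi(35, 36), -1)     # negative preserved
  expect_true(is.na(compute_mpi(NA, 36)))
  expect_identical(compute_pe(38, 40), -2)
  expect_identical(compute_pe(40, 40), 0)
  expect_identical(compute_pe(42, 40), 2)
  expect_true(is.na(compute_pe(40, NA)))
  expect_identical(compute_mpi(c(40, 41), c(36, NA)), c(4, NA))
})
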
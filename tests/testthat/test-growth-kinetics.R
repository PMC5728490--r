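test_that("fit_log_od matches the exact Reinsch-form smoothing spline", {
  set.seed(42)
  x <- seq(0, 12, 0.5)
  y <- log2(0.05) + 0.6 * x + rnorm(length(x), 0, 0.05)
  for (p in c(0.2, 0.4, 0.8)) {
    oracle <- reinsch_smooth(x, y, p)
    prof <- fit_log_od(od_series(x, 2^y), smoothing = p)
    at_knots <- prof$fitted_log2_od[match(round(x * 60),
                                          round(prof$grid_times * 60))]
    expect_lt(max(abs(at_knots - oracle$fitted)), 1e-4)
  }
})

test_that("noiseless exponentials are recovered to high accuracy", {
  x <- seq(0, 12, 0.5)
  s <- od_series(x, 0.05 * 2^(0.6 * x))
  prof <- fit_log_od(s, smoothing = 0.4)
  expect_lt(max(abs(prof$fitted_log2_od -
                      (log2(0.05) + 0.6 * prof$grid_times))), 1e-3)
  expect_equal(growth_rate_at(prof, 5), 0.6, tolerance = 0.005 / 0.6)
  # constant OD: flat fit, slope 0 everywhere
  flat <- fit_log_od(od_series(x, rep(0.05, length(x))))
  expect_equal(unname(flat$rates), rep(0, length(flat$rates)),
               tolerance = 1e-10)
})

test_that("rate estimation window and input validation are enforced", {
  x <- seq(0, 12, 0.5)
  prof <- fit_log_od(od_series(x, 0.05 * 2^(0.6 * x)))
  expect_error(growth_rate_at(prof, 0.2), "evaluation window")
  expect_error(growth_rate_at(prof, 12.0), "evaluation window")
  expect_error(od_series(c(0, 1, 1), c(1, 2, 3)), "strictly increasing")
  expect_error(od_series(0:2, c(1, -2, 3)), "positive")
  expect_error(fit_log_od(od_series(0:3 * 1.0, rep(0.05, 4))[1:3, ]),
               "at least 4")
})

test_that("noisy exponential: interior grid slope within 5% of truth", {
  set.seed(7)
  x <- seq(0, 12, 0.5)
  od <- 0.05 * 2^(0.6 * x) + rnorm(length(x), 0, 0.01)
  od[od <= 0] <- 1e-4
  prof <- fit_log_od(od_series(x, od), smoothing = 0.4)
  # interior = densities where the additive OD noise is small relative to
  # the signal (OD >= ~0.4); at very low OD the 0.01 noise is ~20% of the
  # reading and no estimator can do better
  interior <- prof$times >= 5 & prof$times <= 11
  expect_true(all(abs(prof$rates[interior] - 0.6) / 0.6 < 0.05))
  # independent check: least squares on log2 od over the interior
  sel <- x >= 5 & x <= 11
  ls_slope <- unname(coef(lm(log2(od[sel]) ~ x[sel]))[2])
  expect_equal(mean(prof$rates[interior]), ls_slope, tolerance = 0.05)
})

test_that("density-matched normalization annihilates self-reference and
           subtracts the density-matched rate", {
  x <- seq(0, 12, 0.5)
  prof <- fit_log_od(od_series(x, 0.05 * 2^(0.6 * x)))
  self <- normalize_by_reference_density(prof, prof)
  expect_equal(unname(self$normalized_rates),
               rep(0, length(self$times)), tolerance = 1e-10)

  # sample at 0.4 dbl/h vs reference at 0.6 dbl/h at all densities -> -0.2
  samp <- fit_log_od(od_series(x, 0.05 * 2^(0.4 * x)))
  ref <- fit_log_od(od_series(seq(0, 20, 0.5),
                              0.05 * 2^(0.6 * seq(0, 20, 0.5))))
  out <- normalize_by_reference_density(samp, ref)
  expect_equal(unname(out$normalized_rates),
               rep(-0.2, length(out$times)), tolerance = 0.01)
})

test_that("piecewise reference: matching is by density, not by time", {
  # reference grows at 0.6 dbl/h below OD 0.5 and 0.3 above; a sample at
  # OD 0.8 growing at 0.3 dbl/h is density-matched to the slow segment
  t_break <- log2(0.5 / 0.05) / 0.6
  tr <- seq(0, 20, 0.25)
  od_ref <- ifelse(tr <= t_break, 0.05 * 2^(0.6 * tr),
                   0.5 * 2^(0.3 * (tr - t_break)))
  ref <- fit_log_od(od_series(tr, od_ref), smoothing = 0.9999)
  ts <- seq(0, 11, 0.25)
  samp <- fit_log_od(od_series(ts, 0.8 * 2^(0.3 * (ts - 5))))
  out <- suppressWarnings(normalize_by_reference_density(samp, ref))
  mid <- out$times > 3 & out$times < 9   # sample OD near 0.8 there
  expect_true(all(abs(out$normalized_rates[mid]) < 0.02))
})

test_that("sample densities outside the reference range yield NA + warning", {
  x <- seq(0, 12, 0.5)
  samp <- fit_log_od(od_series(x, 0.05 * 2^(0.6 * x)))   # reaches OD 7.3
  ref <- fit_log_od(od_series(seq(0, 4, 0.5),
                              0.05 * 2^(0.6 * seq(0, 4, 0.5))))
  expect_warning(out <- normalize_by_reference_density(samp, ref),
                 "outside the reference OD range")
  expect_true(anyNA(out$normalized_rates))
})

test_that("generation counting is exact log2 arithmetic", {
  expect_identical(count_generations(0.05, 0.05), 0)
  expect_identical(count_generations(0.05, 0.4), 3)
  expect_error(count_generations(-1, 2), "must be in")
  # additivity holds exactly
  set.seed(1)
  for (i in 1:20) {
    abc <- sort(runif(3, 0.01, 10))
    expect_equal(count_generations(abc[1], abc[2]) +
                   count_generations(abc[2], abc[3]),
                 count_generations(abc[1], abc[3]))
  }
})

test_that("serial-transfer generation bookkeeping matches printed cycles", {
  # OD-8.5 stock, 10 ul into 10 ml, grown to OD 4: ~9 generations
  expect_equal(transfer_generations(8.5, 10, 10, 4), 8.88, tolerance = 0.001)
  # OD-9.5 stock, 10 ul into 10 ml, grown to OD 8.5: ~10 generations
  expect_equal(transfer_generations(9.5, 10, 10, 8.5), 9.81,
               tolerance = 0.001)
  # OD-4 stock, 25 ul into 10 ml, grown to OD 9.5: ~10 generations
  expect_equal(transfer_generations(4, 25, 10, 9.5), 9.89, tolerance = 0.001)
  # dilution factor 1 with final = stock: zero generations
  expect_equal(transfer_generations(4, 10000, 10, 4), 0)
})

test_that("rate estimate is sampling-grid independent for exponentials", {
  rates <- sapply(c(0.25, 0.5, 1), function(dt) {
    x <- seq(0, 12, dt)
    growth_rate_at(fit_log_od(od_series(x, 0.05 * 2^(0.55 * x))), 6)
  })
  expect_true(all(abs(rates - 0.55) / 0.55 < 0.01))
})
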
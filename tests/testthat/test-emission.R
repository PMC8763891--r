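test_that("chamber simulator: no source and no background gives zero", {
  s <- simulate_chamber_series(0, volume = 0.294, aer = 0.5, k = 0.1,
                               arc_minutes = 1, duration = 5, dt = 0.1)
  expect_true(all(s$c_in == 0))
})

test_that("chamber simulator approaches the analytic steady state", {
  # arc on for the whole (long) run: C -> (p*AER*c_out + ER/V) / (AER + k)
  er <- 12; V <- 0.3; aer <- 0.4; k <- 0.2; c_out <- 5; p <- 0.8
  s <- simulate_chamber_series(er, volume = V, aer = aer, k = k, p = p,
                               c_out = c_out, arc_minutes = 200,
                               duration = 200, dt = 0.5)
  expect_equal(tail(s$c_in, 1), (p * aer * c_out + er / V) / (aer + k),
               tolerance = 1e-9)
})

test_that("chamber simulator matches an independent stiff ODE integrator", {
  er <- 30; V <- 0.294; aer <- 0.5; k <- 0.1; arc <- 0.5
  s <- simulate_chamber_series(er, volume = V, aer = aer, k = k,
                               arc_minutes = arc, duration = 3, dt = 0.05)
  rhs <- function(t, y, parms) {
    src <- if (t <= arc) er else 0
    list(src / V - (aer + k) * y)
  }
  num <- deSolve::ode(y = 0, times = s$times, func = rhs, parms = NULL,
                      method = "lsoda", rtol = 1e-10, atol = 1e-12)
  scale <- max(s$c_in)
  expect_lt(max(abs(s$c_in - num[, 2])) / scale, 1e-6)
})

test_that("emission estimator round-trips the simulator within 15%", {
  for (er in c(5, 30, 100)) {
    for (aer in c(0.2, 0.5, 1)) {
      for (k in c(0, 0.1)) {
        s <- simulate_chamber_series(er, volume = 0.294, aer = aer, k = k,
                                     arc_minutes = 0.5, duration = 4,
                                     dt = 0.01)
        est <- estimate_emission_rate(s)
        expect_lt(abs(est$er - er) / er, 0.15)
      }
    }
  }
})

test_that("estimator is exactly linear in the concentration trace", {
  s <- simulate_chamber_series(30, volume = 0.294, aer = 0.5, k = 0.1,
                               arc_minutes = 0.5, duration = 3, dt = 0.02)
  e1 <- estimate_emission_rate(s)$er
  s2 <- chamber_series(s$times, 3.7 * s$c_in, s$volume, s$aer, s$k, s$p,
                       s$c_out)
  expect_equal(estimate_emission_rate(s2)$er, 3.7 * e1, tolerance = 1e-12)
})

test_that("round-trip bias shrinks with the sampling resolution", {
  # with a clean trace the estimator is an exact integral identity; the
  # residual bias is the trapezoidal discretization of the mean term and
  # must fall monotonically as the sampling interval shrinks relative to
  # the relaxation time 1/(AER+k)
  bias <- sapply(c(0.4, 0.2, 0.1, 0.05, 0.02, 0.01), function(dt) {
    s <- simulate_chamber_series(30, volume = 0.294, aer = 0.5, k = 0.1,
                                 arc_minutes = 0.5, duration = 3, dt = dt)
    abs(estimate_emission_rate(s)$er - 30) / 30
  })
  expect_true(all(diff(bias) < 0))
})

test_that("degenerate traces are handled as contracted", {
  tt <- seq(0, 2, by = 0.1)
  zero <- chamber_series(tt, rep(0, length(tt)), 0.3, 0.5)
  expect_warning(e <- estimate_emission_rate(zero), "all-zero")
  expect_equal(e$er, 0)
  expect_true(e$zero_trace)

  # unique maximum at t = 0: degenerate
  dec <- chamber_series(tt, exp(-tt), 0.3, 0.5)
  expect_error(estimate_emission_rate(dec), "degenerate")

  # constant trace under the full estimator: ER = V * k * C
  const <- chamber_series(tt, rep(2, length(tt)), 0.3, aer = 0.5, k = 0.1)
  expect_equal(estimate_emission_rate(const, method = "full")$er,
               0.3 * 0.1 * 2, tolerance = 1e-12)
})

test_that("estimates are non-negative for non-negative traces", {
  set.seed(42)
  for (i in 1:20) {
    cc <- cumsum(runif(30))  # rising, peak at the end
    s <- chamber_series(seq_along(cc), cc, runif(1, 0.1, 1),
                        runif(1, 0, 1), runif(1, 0, 0.3))
    expect_gte(estimate_emission_rate(s)$er, 0)
  }
})

test_that("removal-rate fit recovers AER + k from the decay tail", {
  s <- simulate_chamber_series(30, volume = 0.294, aer = 0.5, k = 0.1,
                               arc_minutes = 0.5, duration = 6, dt = 0.02)
  expect_equal(fit_removal_rate(s), 0.6, tolerance = 1e-6)
})

test_that("replicate pooling: mean, CV and condition guards", {
  mk <- function(er) {
    s <- structure(list(er = er, cv = NA_real_, n = 1L, zero_trace = FALSE,
                        method = "simplified", metal = "Fe",
                        process = "FCAW", wire = "KFX71T", current = 220),
                   class = "emission_estimate")
    s
  }
  pooled <- summarize_replicates(list(mk(1), mk(2), mk(3)))
  expect_equal(pooled$er, 2)
  expect_equal(pooled$cv, 0.5)  # SD = 1 with the n-1 denominator
  expect_equal(pooled$n, 3L)

  same <- summarize_replicates(list(mk(10), mk(10), mk(10)))
  expect_equal(same$er, 10)
  expect_equal(same$cv, 0)

  single <- summarize_replicates(list(mk(7)))
  expect_equal(single$er, 7)
  expect_true(is.na(single$cv))

  other <- mk(5); other$metal <- "Mn"
  expect_error(summarize_replicates(list(mk(1), other)), "mix")
})
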
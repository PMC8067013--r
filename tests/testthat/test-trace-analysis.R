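test_that("trace constructor enforces sampling invariants", {
  t <- seq(0, 1e-4, length.out = 100)
  expect_s3_class(blm_trace(t, t, t, mode = "discharge"), "blm_trace")
  expect_error(blm_trace(t[1:10], t[1:10], t[1:10], mode = "discharge"),
               "16 samples")
  expect_error(blm_trace(t, t, t[-1], mode = "discharge"), "equal length")
  expect_error(blm_trace(rev(t), t, t, mode = "discharge"), "increasing")
  t_jit <- t; t_jit[50] <- t_jit[50] + 2e-7
  expect_error(blm_trace(t_jit, t, t, mode = "discharge"), "uniform")
  expect_error(blm_trace(t, t, t, mode = "voltage_controlled"), "slope")
})

test_that("trace CSV round-trips with metadata", {
  tr <- make_step_trace(n = 200, at = 150)
  path <- tempfile(fileext = ".csv")
  write_trace_csv(tr, path)
  back <- read_trace_csv(path)
  expect_equal(back$t, tr$t)
  expect_equal(back$u, tr$u)
  expect_equal(back$i, tr$i)
  expect_identical(back$mode, "voltage_controlled")
  expect_equal(back$slope, tr$slope)
})

test_that("a constructed current step is located exactly", {
  tr <- make_step_trace(n = 1000, at = 800)
  ev <- detect_breakdown_voltage_controlled(tr)
  expect_equal(ev$tbr, tr$t[800])
  expect_equal(ev$Ubr, tr$u[799], tolerance = 1e-9)
})

test_that("a smooth ramp yields no rupture event", {
  n <- 1000
  t <- (seq_len(n) - 1) * 1e-7
  tr <- blm_trace(t, 1e4 * t, 1e-6 + 1e-3 * t, mode = "voltage_controlled",
                  slope = 1e4)
  expect_null(detect_breakdown_voltage_controlled(tr))
})

test_that("detection is invariant to offsets and positive rescaling", {
  tr <- make_step_trace(n = 1000, at = 700)
  ev0 <- detect_breakdown_voltage_controlled(tr)
  shifted <- blm_trace(tr$t, tr$u + 0.3, tr$i + 5e-6,
                       mode = tr$mode, slope = tr$slope)
  scaled <- blm_trace(tr$t, tr$u * 7, tr$i * 7,
                      mode = tr$mode, slope = tr$slope)
  expect_warning(ev1 <- detect_breakdown_voltage_controlled(shifted))
  ev2 <- suppressWarnings(detect_breakdown_voltage_controlled(scaled))
  expect_equal(ev1$tbr, ev0$tbr)
  expect_equal(ev2$tbr, ev0$tbr)
})

test_that("a constructed voltage collapse is located exactly", {
  n <- 1000
  t <- (seq_len(n) - 1) * 1e-4
  u <- 0.05 * t / max(t)
  u[500:n] <- 0
  tr <- blm_trace(t, u, 1e-6 * t, mode = "current_controlled", slope = 1e-6)
  ev <- detect_breakdown_current_controlled(tr)
  expect_equal(ev$tbr, t[500])
  expect_equal(ev$Ubr, u[499], tolerance = 1e-9)
})

test_that("flat noisy voltage yields no rupture event", {
  set.seed(1)
  n <- 2000
  t <- (seq_len(n) - 1) * 1e-4
  tr <- blm_trace(t, 0.2 * (1 + 0.01 * rnorm(n)), 1e-6 * t,
                  mode = "current_controlled", slope = 1e-6)
  expect_null(detect_breakdown_current_controlled(tr))
})

test_that("detection locates simulated ruptures within two samples", {
  cfg <- simulation_config(popc, "voltage_controlled", slopes = fast_slopes,
                           replicates = 15, noise_sigma_u = 0.01,
                           noise_sigma_i = 0.01, seed = 91)
  ens <- generate_ensemble(cfg)
  det <- lapply(ens$traces, detect_breakdown_voltage_controlled)
  expect_true(all(!vapply(det, is.null, TRUE)))
  tbr <- vapply(det, function(e) e$tbr, 0)
  err <- abs(tbr - ens$records$t_star) * cfg$sample_rate
  expect_lte(median(err), 2)
})

test_that("discharge capacitance is recovered from an exact exponential", {
  tr <- make_discharge_trace(tau = 5.48e-6, n = 1000)
  C <- capacitance_from_discharge(tr, R_discharge = 1e5)
  expect_rel(C, 5.48e-11, 1e-6)
})

test_that("discharge capacitance tolerates 1% multiplicative noise", {
  tr <- make_discharge_trace(tau = 5.48e-6, n = 1000, noise = 0.01, seed = 7)
  C <- capacitance_from_discharge(tr, R_discharge = 1e5)
  expect_rel(C, 5.48e-11, 0.02)
})

test_that("non-decaying discharge traces are rejected", {
  n <- 100
  t <- seq(0, 1e-5, length.out = n)
  rising <- blm_trace(t, 0.1 + 1e3 * t, rep(0, n), mode = "discharge")
  expect_error(capacitance_from_discharge(rising, 1e5), "decay")
  tr <- make_discharge_trace(tau = 5.48e-6, n = 1000)
  expect_error(capacitance_from_discharge(tr, -1), "R_discharge")
})
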
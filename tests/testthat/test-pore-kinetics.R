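test_that("pore-area fraction follows the two-phase dielectric model", {
  res <- pore_area_fraction(3.27e-6, 10.4e-6, popc)
  expect_rel(res$fraction, 0.017178, 1e-3)
  expect_equal(res$deltaC, 3.27e-6 * 10.4e-6)
  expect_equal(pore_area_fraction(0, 10.4e-6, popc)$fraction, 0)
  # linear in the rate
  expect_equal(pore_area_fraction(6.54e-6, 10.4e-6, popc)$fraction,
               2 * res$fraction, tolerance = 1e-12)
  expect_error(pore_area_fraction(4, 1, popc), "unphysical")
})

test_that("fraction inversion is an exact algebraic inverse", {
  set.seed(12)
  for (k in 1:20) {
    dCdt <- 10^runif(1, -12, -5)
    tc <- 10^runif(1, -6, -4)
    spec <- sample(default_compositions(), 1)[[1]]
    frac <- pore_area_fraction(dCdt, tc, spec)$fraction
    expect_equal(capacitance_rate_from_fraction(frac, tc, spec), dCdt,
                 tolerance = 1e-13)
  }
  # the tabulated slow-ramp fraction maps into the slow-regime rate band
  slow <- capacitance_rate_from_fraction(4.83e-8, 10.4e-6, popc)
  expect_rel(slow, 9.194e-12, 1e-3)
  expect_true(slow > 1e-12 && slow < 1e-10)
})

test_that("two-phase mosaic capacitance is consistent with the fraction", {
  # partition the bilayer area into pores and lipid patches and compare the
  # mosaic capacitance with the closed-form expression
  set.seed(5)
  pc <- physical_constants()
  for (k in 1:10) {
    spec <- sample(default_compositions(), 1)[[1]]
    n_p <- sample(1:6, 1)
    Api <- runif(n_p) * spec$A * 0.01 / n_p
    Alj <- spec$A - sum(Api)
    C_mosaic <- sum(spec$eps_p * pc$eps0 * Api / spec$D) +
      spec$eps_l * pc$eps0 * Alj / spec$D
    C_closed <- pc$eps0 / spec$D *
      (spec$eps_l * spec$A + sum(Api) * (spec$eps_p - spec$eps_l))
    expect_equal(C_mosaic, C_closed, tolerance = 1e-12)
    # capacitance excess over the intact bilayer recovers the pore area
    deltaC <- C_closed - intact_capacitance(spec)
    frac <- abs(deltaC) * spec$D / (pc$eps0 * (spec$eps_p - spec$eps_l) *
                                      spec$A)
    expect_equal(frac, sum(Api) / spec$A, tolerance = 1e-10)
  }
})

test_that("an exact log-linear law is recovered exactly", {
  U <- c(0.5, 0.6, 0.7, 0.8)
  fit <- fit_pore_kinetics(U, exp(5 * U - 18))
  expect_equal(fit$m, 5, tolerance = 1e-10)
  expect_equal(fit$n, -18, tolerance = 1e-9)
  expect_equal(fit$nu0, exp(-18), tolerance = 1e-9)
})

test_that("kinetic slope converts to pore radius and back", {
  expect_rel(pore_radius(7.788, 298), 0.10099e-9, 1e-4)
  # round trip
  r <- 0.105e-9
  m <- pi * r^2 / (physical_constants()$kB * 298)
  expect_equal(pore_radius(m, 298), r, tolerance = 1e-15)
  expect_error(pore_radius(-1), "positive")
  # m -> 0 gives r -> 0
  expect_lt(pore_radius(1e-12, 298), 1e-15)
  # non-positive slope leaves the radius undefined with a warning
  expect_warning(fit <- fit_pore_kinetics(c(0.5, 0.6, 0.7),
                                          exp(-2 * c(0.5, 0.6, 0.7) - 18)),
                 "radius")
  expect_true(is.na(fit$r))
})

test_that("the kinetic slope is invariant to the inversion time constant", {
  tab <- reference_breakdown_table("POPC")
  vc <- tab[tab$mode == "voltage_controlled", ]
  fits <- lapply(c(1e-6, 10.4e-6, 1e-4), function(tc) {
    dCdt <- capacitance_rate_from_fraction(vc$Awat_frac_percent / 100, tc,
                                           popc)
    fit_pore_kinetics(vc$Ubr_mean_V, dCdt)
  })
  m <- vapply(fits, function(f) f$m, 0)
  expect_equal(m[1], m[2], tolerance = 1e-10)
  expect_equal(m[2], m[3], tolerance = 1e-10)
  # the intercept shifts by exactly -log(tc ratio)
  expect_equal(fits[[1]]$n - fits[[2]]$n, log(10.4e-6 / 1e-6),
               tolerance = 1e-9)
})

test_that("torus width follows the annulus model", {
  expect_rel(torus_width(0.31, 0.6, 117e-6), 16.45e-6, 1e-3)
  expect_equal(torus_width(0.6, 0.6, 117e-6), 0)
  expect_equal(torus_width(0.15, 0.6, 117e-6), 29.25e-6, tolerance = 1e-12)
  expect_error(torus_width(0.7, 0.6, 117e-6), "negative width")
})

test_that("slow-regime breakdown voltages aggregate to unweighted means", {
  expect_rel(mean_breakdown_voltage(c(0.25, 0.12, 0.32, 0.11, 0.26))$mean,
             0.212, 1e-9)
  expect_rel(mean_breakdown_voltage(c(0.27, 0.52, 0.63, 0.43, 0.47))$mean,
             0.464, 1e-9)
  one <- mean_breakdown_voltage(0.3)
  expect_equal(one$mean, 0.3)
  expect_equal(one$sd, 0)
  expect_error(mean_breakdown_voltage(numeric(0)), "empty")
  # list-of-events interface requires current-controlled events
  ev <- breakdown_event(1, 0.3, mode = "current_controlled", slope = 1e-6)
  expect_equal(mean_breakdown_voltage(list(ev))$mean, 0.3)
  ev_v <- breakdown_event(1e-5, 0.5, mode = "voltage_controlled", slope = 5e4)
  expect_error(mean_breakdown_voltage(list(ev_v)), "current_controlled")
})
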
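test_that("identical configurations yield identical ensembles", {
  cfg <- simulation_config(popc, "voltage_controlled",
                           slopes = fast_slopes[c(1, 7)], replicates = 3,
                           seed = 4)
  e1 <- generate_ensemble(cfg)
  e2 <- generate_ensemble(cfg)
  expect_identical(e1$records, e2$records)
  for (k in seq_along(e1$traces)) {
    expect_identical(e1$traces[[k]]$u, e2$traces[[k]]$u)
    expect_identical(e1$traces[[k]]$i, e2$traces[[k]]$i)
  }
  expect_equal(nrow(e1$records), 6)
  # child seeds are distinct across records
  expect_equal(anyDuplicated(e1$records$seed), 0)
})

test_that("threshold rupture stops at the configured pore fraction", {
  frac_crit <- 0.005
  cfg <- simulation_config(popc, "voltage_controlled", slopes = 2e4,
                           replicates = 1, noise_sigma_u = 0,
                           noise_sigma_i = 0,
                           rupture = list(mode = "threshold",
                                          fraction = frac_crit), seed = 1)
  res <- simulate_voltage_controlled(cfg, 2e4)
  pc <- physical_constants()
  frac_star <- res$truth$Cw_star * popc$D /
    (pc$eps0 * (popc$eps_p - popc$eps_l) * popc$A)
  # within one integration step of the threshold
  step <- res$truth$dCwdt_star / cfg$sample_rate * popc$D /
    (pc$eps0 * (popc$eps_p - popc$eps_l) * popc$A)
  expect_gte(frac_star, frac_crit)
  expect_lte(frac_star, frac_crit + step)
})

test_that("the generator satisfies its own kinetic law at rupture", {
  cfg <- simulation_config(popc, "voltage_controlled", slopes = fast_slopes,
                           replicates = 1, noise_sigma_u = 0,
                           noise_sigma_i = 0, seed = 2)
  ens <- generate_ensemble(cfg)
  rec <- ens$records
  expect_false(any(rec$censored))
  expect_equal(log(rec$dCwdt_star), cfg$m_true * rec$U_star + cfg$n_true,
               tolerance = 1e-12)
  # rupture voltage grows with the ramp slope and matches the closed form
  expect_true(all(diff(rec$U_star[order(rec$slope)]) > 0))
  pc <- physical_constants()
  Cw_crit <- 0.005 * pc$eps0 * (popc$eps_p - popc$eps_l) * popc$A / popc$D
  U_pred <- log1p(Cw_crit * cfg$m_true * rec$slope / cfg$nu0_true) /
    cfg$m_true
  one_step <- rec$slope / cfg$sample_rate
  expect_true(all(rec$U_star >= U_pred - 1e-12 &
                    rec$U_star <= U_pred + one_step + 1e-12))
  expect_true(all(rec$U_star > 0.4 & rec$U_star < 0.85))
})

test_that("censoring is flagged when no rupture occurs", {
  cfg <- simulation_config(popc, "voltage_controlled", slopes = 2e4,
                           replicates = 1, nu0_true = 0,
                           rupture = list(mode = "threshold", fraction = 0.5),
                           noise_sigma_u = 0, noise_sigma_i = 0,
                           max_voltage = 0.5, seed = 1)
  res <- simulate_voltage_controlled(cfg, 2e4)
  expect_true(res$truth$censored)
  expect_true(is.na(res$truth$t_star))
})

test_that("current ramp without pores reduces to the RC closed form", {
  cfg <- simulation_config(popc, "current_controlled", slopes = 1e-6,
                           replicates = 1, nu0_true = 0,
                           rupture = list(mode = "threshold", fraction = 0.5),
                           noise_sigma_u = 0, noise_sigma_i = 0,
                           max_voltage = 0.3, seed = 1)
  res <- simulate_current_controlled(cfg, 1e-6)
  u_cf <- voltage_response_current_ramp(1e-6, cfg$R_true, cfg$C0,
                                        res$trace$t[-1])
  expect_lt(max(abs(res$trace$u[-1] - u_cf) / abs(u_cf)), 1e-6)
})

test_that("hazard-mode rupture voltages scatter much more than threshold", {
  base <- list(spec = popc, mode = "current_controlled", slopes = 10e-6,
               replicates = 20, noise_sigma_u = 0, noise_sigma_i = 0,
               seed = 6)
  cfg_h <- do.call(simulation_config, c(base, list(
    rupture = list(mode = "hazard", lambda0 = 0.03))))
  cfg_t <- do.call(simulation_config, c(base, list(
    rupture = list(mode = "threshold", fraction = 1e-7))))
  U_h <- generate_ensemble(cfg_h)$records$U_star
  U_t <- generate_ensemble(cfg_t)$records$U_star
  expect_gt(sd(U_h), 10 * max(sd(U_t), 1e-12))
})

test_that("ensembles round-trip through disk with a manifest", {
  cfg <- simulation_config(popc, "voltage_controlled", slopes = 2e4,
                           replicates = 2, seed = 9)
  ens <- generate_ensemble(cfg)
  dir <- tempfile()
  write_ensemble(ens, dir)
  files <- list.files(dir, pattern = "^trace.*csv$", full.names = TRUE)
  expect_length(files, 2)
  back <- read_trace_csv(files[1])
  expect_equal(back$u, ens$traces[[1]]$u, tolerance = 1e-12)
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  expect_equal(man$config$seed, 9)
  expect_equal(nrow(man$records), 2)
})
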
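# Synthetic ramp-experiment generator. The membrane is an RC element whose
# water-pore capacitance Cw grows at the voltage-dependent rate
# dCw/dt = exp(m*u + n); rupture is deterministic (pore-area threshold or
# strength-duration curve crossing) or stochastic (exponential-in-voltage
# hazard). Instrument noise is multiplicative Gaussian per channel.

#' Simulation configuration
#'
#' @param spec [membrane_spec()] of the simulated bilayer.
#' @param mode `"voltage_controlled"` or `"current_controlled"`.
#' @param slopes Ramp slopes (V/s or A/s according to `mode`).
#' @param replicates Replicates per slope.
#' @param m_true Kinetic slope of the pore-formation rate law, 1/V.
#' @param nu0_true Spontaneous capacitance-change rate `exp(n)`, F/s. Zero
#'   disables pore growth (pure RC membrane).
#' @param R_true Membrane resistance, Ohm.
#' @param C0 Intact membrane capacitance, F; defaults to
#'   [intact_capacitance()] of `spec`.
#' @param alpha Electrostriction coefficient, 1/V^2 (default 0).
#' @param rupture Rupture rule: `list(mode = "threshold", fraction = f)`
#'   ruptures when the pore-area fraction reaches `f`;
#'   `list(mode = "hazard", lambda0 = l)` ruptures stochastically with rate
#'   `lambda0 * exp(m_true * u)`; `list(mode = "sd_curve", a = a, b = b)`
#'   ruptures when the ramp crosses the strength-duration curve
#'   `U = (a + b/t)^(1/4)`. Default: threshold (fraction 0.005) for voltage
#'   ramps, hazard (lambda0 0.03 1/s) for current ramps.
#' @param noise_sigma_u,noise_sigma_i Relative Gaussian noise on the
#'   voltage/current channel (default 0.01).
#' @param sample_rate Samples per second; default 1e7 for voltage ramps
#'   (rupture within tens of microseconds), 1e4 for current ramps (rupture
#'   within seconds).
#' @param max_voltage Simulation stops once the clean voltage would exceed
#'   this value, V (default 1.5); an unruptured trace is flagged censored.
#' @param charging_capacitance `"total"` (default) includes the accumulated
#'   water-pore capacitance in the charging term of the current balance
#'   (full product rule); `"intact"` restricts the charging term to the
#'   intact (electrostricted) capacitance, matching the idealisation under
#'   which the rate extraction is exact.
#' @param seed Integer seed; per-record child seeds are derived from it.
#' @return Object of class `sim_config`.
#' @export
simulation_config <- function(spec,
                              mode = c("voltage_controlled", "current_controlled"),
                              slopes, replicates = 3,
                              m_true = 7.79, nu0_true = 9.1e-9,
                              R_true = 8.7e4, C0 = NULL, alpha = 0,
                              rupture = NULL,
                              noise_sigma_u = 0.01, noise_sigma_i = 0.01,
                              sample_rate = NULL, max_voltage = 1.5,
                              charging_capacitance = c("total", "intact"),
                              seed = 1L) {
  mode <- match.arg(mode)
  charging_capacitance <- match.arg(charging_capacitance)
  validate_membrane_spec(spec)
  if (is.null(C0)) C0 <- intact_capacitance(spec)
  if (is.null(sample_rate))
    sample_rate <- if (mode == "voltage_controlled") 1e7 else 1e4
  if (is.null(rupture))
    rupture <- if (mode == "voltage_controlled")
      list(mode = "threshold", fraction = 0.005)
    else list(mode = "hazard", lambda0 = 0.03)
  stopifnot(all(slopes > 0), replicates >= 1, m_true > 0, nu0_true >= 0,
            R_true > 0, C0 > 0, alpha >= 0, noise_sigma_u >= 0,
            noise_sigma_i >= 0, sample_rate > 0, max_voltage > 0)
  rupture$mode <- match.arg(rupture$mode, c("threshold", "hazard", "sd_curve"))
  if (rupture$mode == "threshold")
    stopifnot(rupture$fraction > 0, rupture$fraction < 1)
  if (rupture$mode == "hazard") stopifnot(rupture$lambda0 > 0)
  if (rupture$mode == "sd_curve") stopifnot(rupture$a > 0, rupture$b > 0)
  structure(
    list(spec = spec, mode = mode, slopes = slopes, replicates = replicates,
         m_true = m_true, nu0_true = nu0_true, n_true = log(nu0_true),
         R_true = R_true, C0 = C0, alpha = alpha, rupture = rupture,
         noise_sigma_u = noise_sigma_u, noise_sigma_i = noise_sigma_i,
         sample_rate = sample_rate, max_voltage = max_voltage,
         charging_capacitance = charging_capacitance, seed = as.integer(seed)),
    class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("<sim_config> %s on %s: %d slopes x %d replicates, rupture = %s, seed = %d\n",
              x$mode, x$spec$name, length(x$slopes), x$replicates,
              x$rupture$mode, x$seed))
  invisible(x)
}

# Deterministic, platform-stable child seed for (slope index, replicate).
child_seed <- function(seed, slope_idx, replicate) {
  as.integer((as.numeric(seed) * 1000003 + slope_idx * 10007 + replicate) %%
               2147483629)
}

.rupture_index <- function(cfg, t, u, frac, dt) {
  switch(cfg$rupture$mode,
    threshold = {
      idx <- which(frac >= cfg$rupture$fraction)
      if (length(idx)) idx[1] else NA_integer_
    },
    hazard = {
      lambda <- cfg$rupture$lambda0 * exp(cfg$m_true * pmax(u, 0))
      p <- 1 - exp(-lambda * dt)
      hit <- which(stats::runif(length(p)) < p)
      if (length(hit)) hit[1] else NA_integer_
    },
    sd_curve = {
      curve <- c(Inf, (cfg$rupture$a + cfg$rupture$b / t[-1])^0.25)
      idx <- which(u >= curve)
      if (length(idx)) idx[1] else NA_integer_
    })
}

# Ramp the resistance down by x1000 over 5 samples after rupture (the
# post-rupture waveform is cosmetic; detection only needs the discontinuity).
.post_rupture_resistance <- function(R, n, idx) {
  Rt <- rep(R, n)
  if (idx <= n) {
    k <- seq(idx, min(n, idx + 4L))
    Rt[k] <- R * 10^(-3 * seq_along(k) / 5)
    if (idx + 5L <= n) Rt[(idx + 5L):n] <- R * 1e-3
  }
  Rt
}

.apply_noise <- function(x, sigma) {
  if (sigma <= 0) return(x)
  x * (1 + sigma * stats::rnorm(length(x)))
}

#' Simulate one voltage-controlled ramp experiment
#'
#' The clean voltage is `u = ku * t`; the water-pore capacitance grows as
#' `dCw/dt = exp(m*u + n)` (integrated in closed form along the ramp); the
#' recorded current follows the charge balance
#' `i = u/R + C_charge * ku + u * dC/dt`, where `C_charge` includes the
#' electrostricted intact capacitance and (by default) the accumulated pore
#' capacitance. After rupture the resistance collapses by three decades
#' over five samples.
#'
#' @param cfg [simulation_config()] with voltage-controlled mode.
#' @param ku Voltage-ramp slope, V/s.
#' @param seed Seed for this record (default `cfg$seed`).
#' @return List with elements `trace` ([blm_trace()]) and `truth` (list:
#'   `t_star`, `U_star`, `dCwdt_star`, `Cw_star`, `censored`, `slope`).
#' @export
simulate_voltage_controlled <- function(cfg, ku, seed = cfg$seed) {
  stopifnot(inherits(cfg, "sim_config"), cfg$mode == "voltage_controlled",
            ku > 0)
  set.seed(seed)
  dt <- 1 / cfg$sample_rate
  n <- max(16L, ceiling(cfg$max_voltage / ku / dt) + 1L)
  t <- (seq_len(n) - 1L) * dt
  u <- ku * t
  # closed-form integral of exp(m*ku*t + n): Cw = exp(n)*(exp(m*ku*t)-1)/(m*ku)
  dCwdt <- exp(cfg$m_true * u + cfg$n_true)
  Cw <- if (cfg$nu0_true > 0)
    cfg$nu0_true * expm1(cfg$m_true * ku * t) / (cfg$m_true * ku)
  else rep(0, n)
  frac <- Cw * .fraction_per_farad(cfg$spec)
  idx <- .rupture_index(cfg, t, u, frac, dt)
  censored <- is.na(idx)
  C_es <- cfg$C0 * (1 + cfg$alpha * u^2)
  C_charge <- if (cfg$charging_capacitance == "total") C_es + Cw else C_es
  dCdt_tot <- dCwdt + 2 * cfg$C0 * cfg$alpha * u * ku
  # the rupture sample itself is still intact; the collapse starts one
  # sample later, so the pre-rupture values can be read at t_star
  Rt <- if (censored) rep(cfg$R_true, n)
        else .post_rupture_resistance(cfg$R_true, n, idx + 1L)
  i <- u / Rt + C_charge * ku + u * dCdt_tot
  keep <- if (censored) n else min(n, idx + max(50L, ceiling(0.05 * idx)))
  keep <- max(keep, 16L)
  trace <- blm_trace(t[1:keep],
                     .apply_noise(u[1:keep], cfg$noise_sigma_u),
                     .apply_noise(i[1:keep], cfg$noise_sigma_i),
                     mode = "voltage_controlled", slope = ku,
                     composition = cfg$spec$name)
  truth <- list(
    t_star = if (censored) NA_real_ else t[idx],
    U_star = if (censored) NA_real_ else u[idx],
    dCwdt_star = if (censored) NA_real_ else dCwdt[idx],
    Cw_star = if (censored) NA_real_ else Cw[idx],
    censored = censored, slope = ku, seed = seed)
  list(trace = trace, truth = truth)
}

#' Simulate one current-controlled ramp experiment
#'
#' Integrates `C(u) du/dt = ki*t - u/R - u*dCw/dt` with
#' `dCw/dt = exp(m*u + n)` using a per-step exponential integrator (exact
#' for the locally linear drive and frozen pore rate), which is stable at
#' the 1e4 /s sampling rate even though R*C is microseconds. Rupture is by
#' hazard (default) or threshold; afterwards the voltage collapses through
#' the three-decade resistance drop.
#'
#' @param cfg [simulation_config()] with current-controlled mode.
#' @param ki Current-ramp slope, A/s.
#' @param seed Seed for this record (default `cfg$seed`).
#' @return As [simulate_voltage_controlled()].
#' @export
simulate_current_controlled <- function(cfg, ki, seed = cfg$seed,
                                        path = NULL) {
  stopifnot(inherits(cfg, "sim_config"), cfg$mode == "current_controlled",
            ki > 0)
  if (is.null(path)) path <- .cc_path(cfg, ki)
  set.seed(seed)
  dt <- 1 / cfg$sample_rate
  idx <- if (cfg$rupture$mode == "hazard") {
    # cumulative-hazard inversion: rupture at the first step whose
    # integrated hazard exceeds a unit-rate exponential deviate
    E <- stats::rexp(1)
    if (E <= path$H[length(path$H)]) findInterval(E, path$H) + 1L
    else NA_integer_
  } else path$rupture_idx
  censored <- is.na(idx)
  truth <- list(
    t_star = if (censored) NA_real_ else path$t[idx],
    U_star = if (censored) NA_real_ else path$u[idx],
    dCwdt_star = if (censored) NA_real_ else path$dCwdt[idx],
    Cw_star = if (censored) NA_real_ else path$Cw[idx],
    censored = censored, slope = ki, seed = seed)
  if (censored) {
    keep <- length(path$t)
    t <- path$t
    u <- path$u
  } else {
    tail_n <- max(50L, ceiling(0.01 * idx))
    keep <- max(idx + tail_n, 16L)
    t <- (seq_len(keep) - 1L) * dt
    u <- numeric(keep)
    m <- min(idx, length(path$u))
    u[1:m] <- path$u[1:m]
    # re-integrate the post-rupture tail with the collapsing resistance
    Rt <- .post_rupture_resistance(cfg$R_true, keep, idx + 1L)
    for (k in idx:(keep - 1L)) {
      g <- 1 / (Rt[k] * cfg$C0)
      s <- ki / cfg$C0
      up0 <- (s / g) * (t[k] - 1 / g)
      up1 <- (s / g) * (t[k + 1L] - 1 / g)
      u[k + 1L] <- up1 + (u[k] - up0) * exp(-g * dt)
    }
  }
  trace <- blm_trace(t,
                     .apply_noise(u, cfg$noise_sigma_u),
                     .apply_noise(ki * t, cfg$noise_sigma_i),
                     mode = "current_controlled", slope = ki,
                     composition = cfg$spec$name)
  list(trace = trace, truth = truth)
}

# Deterministic pre-rupture path of a current-controlled experiment:
# exponential-integrator steps of C(u) du/dt = ki*t - u/R - u*dCw/dt at the
# sample rate. Integration stops at the deterministic rupture point
# (threshold / sd_curve), when the cumulative hazard makes survival
# negligible (hazard), or at max_voltage.
.cc_path <- function(cfg, ki) {
  dt <- 1 / cfg$sample_rate
  t_max <- cfg$max_voltage / (ki * cfg$R_true)
  n <- max(16L, ceiling(t_max / dt) + 1L)
  t <- (seq_len(n) - 1L) * dt
  u <- numeric(n)
  Cw <- numeric(n)
  dCwdt <- numeric(n)
  H <- numeric(n)          # cumulative hazard (hazard mode)
  fpf <- .fraction_per_farad(cfg$spec)
  rup <- cfg$rupture
  hazard <- rup$mode == "hazard"
  total <- cfg$charging_capacitance == "total"
  has_pores <- cfg$nu0_true > 0
  m_ <- cfg$m_true; n_ <- cfg$n_true; R_ <- cfg$R_true; C0 <- cfg$C0
  al <- cfg$alpha
  rupture_idx <- NA_integer_
  k_end <- n
  for (k in seq_len(n - 1L)) {
    dCwdt[k] <- if (has_pores) exp(m_ * u[k] + n_) else 0
    if (hazard) {
      H[k] <- (if (k > 1L) H[k - 1L] else 0) +
        rup$lambda0 * exp(m_ * max(u[k], 0)) * dt
      if (H[k] > 50) { k_end <- k; break }       # survival < exp(-50)
    } else {
      ruptured <- if (rup$mode == "threshold") Cw[k] * fpf >= rup$fraction
                  else k > 1L && u[k] >= (rup$a + rup$b / t[k])^0.25
      if (ruptured) { rupture_idx <- k; k_end <- k; break }
    }
    Cm <- C0 * (1 + al * u[k]^2) + if (total) Cw[k] else 0
    g <- (1 / R_ + dCwdt[k]) / Cm
    s <- ki / Cm
    # exact step of u' + g*u = s*t over [t_k, t_k + dt]
    up0 <- (s / g) * (t[k] - 1 / g)
    up1 <- (s / g) * (t[k + 1L] - 1 / g)
    u[k + 1L] <- up1 + (u[k] - up0) * exp(-g * dt)
    Cw[k + 1L] <- Cw[k] + dCwdt[k] * dt
  }
  if (k_end == n) {
    dCwdt[n] <- if (has_pores) exp(m_ * u[n] + n_) else 0
    if (hazard) H[n] <- H[n - 1L]
  }
  keep <- seq_len(k_end)
  list(t = t[keep], u = u[keep], Cw = Cw[keep], dCwdt = dCwdt[keep],
       H = H[keep], rupture_idx = rupture_idx, complete = k_end == n)
}

#' Simulate a full ensemble (all slopes x replicates)
#'
#' Runs every configured slope/replicate combination with a child seed
#' derived deterministically from `cfg$seed`, so identical configurations
#' produce identical ensembles.
#'
#' @param cfg [simulation_config()].
#' @return Object of class `blm_ensemble`: list with `records` (data frame
#'   of per-record ground truth: slope, replicate, seed, censored, t_star,
#'   U_star, dCwdt_star, Cw_star), `traces` (list of [blm_trace()]) and
#'   `config`.
#' @export
generate_ensemble <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  voltage <- cfg$mode == "voltage_controlled"
  traces <- list()
  rows <- list()
  k <- 0L
  for (si in seq_along(cfg$slopes)) {
    # the pre-rupture path is deterministic: integrate it once per slope
    path <- if (!voltage) .cc_path(cfg, cfg$slopes[si]) else NULL
    for (rep_i in seq_len(cfg$replicates)) {
      k <- k + 1L
      sd_k <- child_seed(cfg$seed, si, rep_i)
      res <- if (voltage) simulate_voltage_controlled(cfg, cfg$slopes[si],
                                                      seed = sd_k)
             else simulate_current_controlled(cfg, cfg$slopes[si],
                                              seed = sd_k, path = path)
      traces[[k]] <- res$trace
      rows[[k]] <- data.frame(
        slope = cfg$slopes[si], replicate = rep_i, seed = sd_k,
        censored = res$truth$censored, t_star = res$truth$t_star,
        U_star = res$truth$U_star, dCwdt_star = res$truth$dCwdt_star,
        Cw_star = res$truth$Cw_star)
    }
  }
  structure(list(records = do.call(rbind, rows), traces = traces,
                 config = cfg),
            class = "blm_ensemble")
}

#' @export
print.blm_ensemble <- function(x, ...) {
  cat(sprintf("<blm_ensemble> %d traces (%s), %d censored\n",
              length(x$traces), x$config$mode, sum(x$records$censored)))
  invisible(x)
}

#' Write an ensemble to disk
#'
#' One trace CSV per record plus a `manifest.json` echoing the
#' configuration and the per-record ground truth.
#'
#' @param ensemble A `blm_ensemble`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_ensemble <- function(ensemble, dir) {
  stopifnot(inherits(ensemble, "blm_ensemble"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(length(ensemble$traces))
  for (k in seq_along(ensemble$traces)) {
    files[k] <- file.path(dir, sprintf("trace_%03d.csv", k))
    write_trace_csv(ensemble$traces[[k]], files[k])
  }
  cfg <- ensemble$config
  manifest <- list(
    config = list(
      composition = cfg$spec$name, mode = cfg$mode, slopes = cfg$slopes,
      replicates = cfg$replicates, m_true = cfg$m_true,
      nu0_true = cfg$nu0_true, R_true = cfg$R_true, C0 = cfg$C0,
      alpha = cfg$alpha, rupture = cfg$rupture,
      noise_sigma_u = cfg$noise_sigma_u, noise_sigma_i = cfg$noise_sigma_i,
      sample_rate = cfg$sample_rate, seed = cfg$seed),
    records = cbind(file = basename(files), ensemble$records))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}
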
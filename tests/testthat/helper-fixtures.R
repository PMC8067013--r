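# Shared fixtures: compositions, the fast-ramp slope grid, and small trace
# builders used across test files.

popc <- default_compositions()[["POPC"]]
pops <- default_compositions()[["POPS"]]
mix  <- default_compositions()[["POPC:POPS"]]

fast_slopes <- c(4800, 5500, 7800, 11500, 16700, 21600, 48100)  # V/s
slow_slopes <- c(0.5, 1, 4, 8, 10) * 1e-6                       # A/s

# exponential discharge transient u(t) = U0 * exp(-t/tau)
make_discharge_trace <- function(tau, U0 = 1, n = 1000, t_end = 5 * tau,
                                 noise = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  t <- seq(0, t_end, length.out = n)
  u <- U0 * exp(-t / tau)
  if (noise > 0) u <- u * (1 + noise * rnorm(n))
  blm_trace(t, u, rep(0, n), mode = "discharge")
}

# clean voltage ramp with a current step injected at sample `at`
make_step_trace <- function(n = 1000, at = 800, ku = 1e4, dt = 1e-7,
                            step_factor = 100) {
  t <- (seq_len(n) - 1) * dt
  u <- ku * t
  i <- 1e-6 + 1e-3 * t
  i[at:n] <- i[at:n] * step_factor
  blm_trace(t, u, i, mode = "voltage_controlled", slope = ku)
}

expect_rel <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / abs(expected), tol)
}
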
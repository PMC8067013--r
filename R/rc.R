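#' Voltage response of an RC membrane to a current ramp
#'
#' Closed-form solution of `C du/dt + u/R = ki * t` with `u(0) = 0`:
#' `u(t) = ki * (R*t - R^2*C + R^2*C * exp(-t/(R*C)))`.
#'
#' @param ki Current-ramp slope, A/s.
#' @param R Membrane resistance, Ohm.
#' @param C Membrane capacitance, F.
#' @param t Time, s (vectorised).
#' @return Voltage, V.
#' @examples
#' voltage_response_current_ramp(1e-6, 1e5, 5e-11, 1)
#' @export
voltage_response_current_ramp <- function(ki, R, C, t) {
  stopifnot(ki > 0, R > 0, C > 0, all(t >= 0))
  tau <- R * C
  ki * (R * t - R * tau + R * tau * exp(-t / tau))
}

#' Membrane resistance from a current-ramp breakdown record
#'
#' For slow current ramps (`R*C` at least ten times smaller than the
#' rupture time) the exponential term of the ramp response is negligible
#' and the response reduces to the quadratic
#' `C*R^2 - tbr*R + u(tbr)/ki = 0`, solved for `R`. The smaller root is the
#' physical one (it satisfies `R*C << tbr`); the larger root would make the
#' neglected exponential term order one.
#'
#' @param C Membrane capacitance, F (measured before the ramp).
#' @param tbr Rupture time, s.
#' @param Ubr Voltage at rupture, V.
#' @param ki Current-ramp slope, A/s.
#' @return Object of class `rc_estimate`: list with `R`, `C`, `tau = R*C`,
#'   `source_tbr`, `valid` (TRUE iff `tau <= tbr/10`), and `R_large` (the
#'   rejected root, for diagnostics).
#' @examples
#' solve_membrane_resistance(5.4825e-11, 5.97, 0.26, 0.5e-6)
#' @export
solve_membrane_resistance <- function(C, tbr, Ubr, ki) {
  stopifnot(C > 0, tbr > 0, Ubr > 0, ki > 0)
  disc <- tbr^2 - 4 * C * Ubr / ki
  if (disc < 0)
    stop("solve_membrane_resistance: negative discriminant (inconsistent record)",
         call. = FALSE)
  R_large <- (tbr + sqrt(disc)) / (2 * C)
  # Vieta form of the smaller root avoids cancellation when R*C << tbr
  R_small <- (Ubr / ki) / (C * R_large)
  tau <- R_small * C
  valid <- tau <= tbr / 10
  if (!valid)
    warning("solve_membrane_resistance: R*C > tbr/10; quadratic approximation invalid")
  structure(list(R = R_small, C = C, tau = tau, source_tbr = tbr,
                 valid = valid, R_large = R_large),
            class = "rc_estimate")
}

#' @export
print.rc_estimate <- function(x, ...) {
  cat(sprintf("<rc_estimate> R = %.4g Ohm, C = %.4g F, tau = %.4g s (%s)\n",
              x$R, x$C, x$tau, if (x$valid) "valid" else "INVALID: tau > tbr/10"))
  invisible(x)
}

#' Rate of capacitance change at the rupture moment
#'
#' Charge balance at rupture during a voltage ramp gives
#' `i(tbr) = ku*tbr/R + C*ku + ku*tbr * dC/dt`, so the capacitance-change
#' rate attributable to water pores is
#' `dC/dt = (i_br - ku*tbr/R - C*ku) / (ku*tbr)`. Electrostrictive thinning
#' is neglected; `C` is the capacitance measured before the ramp.
#'
#' @param i_br Current at rupture, A.
#' @param ku Voltage-ramp slope, V/s.
#' @param tbr Rupture time, s.
#' @param R Membrane resistance, Ohm (from the slow current-ramp estimate).
#' @param C Pre-ramp membrane capacitance, F.
#' @return dC/dt in F/s. A negative value indicates an inconsistent record
#'   (attribute `consistent` is set to FALSE, the value is not clamped).
#' @export
capacitance_rate_at_breakdown <- function(i_br, ku, tbr, R, C) {
  stopifnot(i_br >= 0, ku > 0, tbr > 0, R > 0, C > 0)
  rate <- (i_br - ku * tbr / R - C * ku) / (ku * tbr)
  attr(rate, "consistent") <- rate >= 0
  rate
}
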
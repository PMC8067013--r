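# Dielectric two-phase model: just before rupture the bilayer is a mosaic of
# intact lipid patches (eps_l) and water pores (eps_p), all of thickness D,
# in parallel, so Cbr = eps0/D * (eps_l*A + sum(Api)*(eps_p - eps_l)) and the
# capacitance excess over the intact bilayer is proportional to the pore
# area. Pore appearance is treated as a capacitance *increase* (|dC| used).

.fraction_per_farad <- function(spec) {
  # Awat/A per farad of capacitance excess
  spec$D / (physical_constants()$eps0 * (spec$eps_p - spec$eps_l) * spec$A)
}

#' Fraction of bilayer area occupied by water pores
#'
#' The capacitance excess at rupture is `deltaC = dCdt * tc` (the
#' capacitance-change rate at rupture accumulated over the chronaxie-like
#' time constant of the composition), and the occupied area fraction is
#' `Awat/A = |deltaC| * D / (eps0 * (eps_p - eps_l) * A)`.
#'
#' @param dCdt Capacitance-change rate at rupture, F/s (>= 0).
#' @param tc Strength-duration time constant of the composition, s.
#' @param spec [membrane_spec()].
#' @return Object of class `pore_area_result`: list with `dCdt`, `deltaC`
#'   (F), `fraction` (dimensionless) and `composition`.
#' @examples
#' popc <- membrane_spec("POPC", D = 3.75e-9)
#' pore_area_fraction(3.27e-6, 10.4e-6, popc)$fraction  # ~1.72e-2
#' @export
pore_area_fraction <- function(dCdt, tc, spec) {
  validate_membrane_spec(spec)
  stopifnot(dCdt >= 0, tc > 0)
  deltaC <- dCdt * tc
  fraction <- abs(deltaC) * .fraction_per_farad(spec)
  if (fraction >= 1)
    stop("pore_area_fraction: unphysical pore area (fraction >= 1)", call. = FALSE)
  structure(list(dCdt = dCdt, deltaC = deltaC, fraction = fraction,
                 composition = spec$name),
            class = "pore_area_result")
}

#' @export
print.pore_area_result <- function(x, ...) {
  cat(sprintf("<pore_area_result> %s: dC/dt = %.4g F/s, Awat/A = %.4g %%\n",
              x$composition, x$dCdt, 100 * x$fraction))
  invisible(x)
}

#' Capacitance-change rate from a pore-area fraction
#'
#' Exact algebraic inverse of [pore_area_fraction()]: recovers `dC/dt` from
#' a reported area fraction. Used to re-derive rates from tabulated
#' `Awat/A` columns.
#'
#' @param fraction Pore-area fraction, dimensionless in \[0, 1).
#' @param tc Strength-duration time constant, s.
#' @param spec [membrane_spec()].
#' @return dC/dt, F/s.
#' @export
capacitance_rate_from_fraction <- function(fraction, tc, spec) {
  validate_membrane_spec(spec)
  stopifnot(all(fraction >= 0), all(fraction < 1), tc > 0)
  fraction / (.fraction_per_farad(spec) * tc)
}

#' Fit the log-linear pore-kinetics rate law
#'
#' The capacitance-change rates at rupture under fast voltage ramps depend
#' exponentially on the breakdown voltage: `ln(dC/dt) = m * Ubr + n`
#' (ordinary least squares). In the kinetic picture of membrane failure
#' under fast loading, the slope is `m = pi * r^2 / (kB * T)` with `r` the
#' radius of the water pore governing rupture, and `exp(n)` is the
#' spontaneous rate of capacitance change (water-pore formation) at zero
#' voltage.
#'
#' @param Ubr Breakdown voltages, V (>= 3 records).
#' @param dCdt Capacitance-change rates, F/s (> 0).
#' @param T Absolute temperature, K (default 298).
#' @return Object of class `pk_fit`: list with `m` (1/V), `n` (ln F/s),
#'   `r` (m; `NA` with a warning if `m <= 0`), `nu0 = exp(n)` (F/s),
#'   `r2` and `n_points`.
#' @examples
#' fit_pore_kinetics(c(0.5, 0.6, 0.7), exp(7.7 * c(0.5, 0.6, 0.7) - 18.5))
#' @export
fit_pore_kinetics <- function(Ubr, dCdt, T = 298) {
  if (length(Ubr) < 3 || length(dCdt) != length(Ubr))
    stop("fit_pore_kinetics: need >= 3 (Ubr, dCdt) records", call. = FALSE)
  if (any(dCdt <= 0))
    stop("fit_pore_kinetics: all dCdt must be > 0", call. = FALSE)
  fit <- stats::lm(y ~ x, data = data.frame(x = Ubr, y = log(dCdt)))
  m <- unname(stats::coef(fit)[2])
  n <- unname(stats::coef(fit)[1])
  r <- if (m > 0) pore_radius(m, T) else {
    warning("fit_pore_kinetics: non-positive slope m; pore radius undefined")
    NA_real_
  }
  y <- log(dCdt)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - sum(stats::residuals(fit)^2) / tss else 1
  structure(list(m = m, n = n, r = r, nu0 = exp(n),
                 r2 = r2, n_points = length(Ubr), T = T),
            class = "pk_fit")
}

#' @export
print.pk_fit <- function(x, ...) {
  cat(sprintf(
    "<pk_fit> ln(dC/dt) = m*Ubr + n, %d points (R^2 = %.3f)\n  m = %.3f 1/V, exp(n) = %.3g F/s, r = %s\n",
    x$n_points, x$r2, x$m, x$nu0,
    if (is.na(x$r)) "undefined" else sprintf("%.4f nm", x$r * 1e9)))
  invisible(x)
}

#' Water-pore radius from the kinetic slope
#'
#' Inverts `m = pi * r^2 / (kB * T)`: `r = sqrt(m * kB * T / pi)`.
#'
#' @param m Kinetic slope, 1/V (> 0).
#' @param T Absolute temperature, K.
#' @return Pore radius, m.
#' @examples
#' pore_radius(7.788, 298) * 1e9  # ~0.101 nm
#' @export
pore_radius <- function(m, T = 298) {
  if (!(m > 0)) stop("pore_radius: slope m must be positive", call. = FALSE)
  stopifnot(T > 0)
  sqrt(m * physical_constants()$kB * T / pi)
}

#' Width of the solvent torus around the bilayer
#'
#' A measured specific capacitance below the reference value for a fully
#' bilayer-covered aperture indicates that an annulus (torus) of bulk
#' solvent rings the hole. The annulus model takes the true bilayer
#' diameter as `d_eff = d * sqrt(c_meas / c_ref)` and returns the annulus
#' width `(d - d_eff) / 2`.
#'
#' @param c_meas Measured specific capacitance (any unit, same as `c_ref`).
#' @param c_ref Reference specific capacitance of a torus-free bilayer.
#' @param d Aperture diameter, m.
#' @return Torus width, m.
#' @examples
#' torus_width(0.31, 0.6, 117e-6) * 1e6  # ~16.4 um
#' @export
torus_width <- function(c_meas, c_ref, d) {
  stopifnot(c_meas > 0, c_ref > 0, d > 0)
  if (c_meas > c_ref)
    stop("torus_width: c_meas > c_ref implies negative width", call. = FALSE)
  (d - d * sqrt(c_meas / c_ref)) / 2
}

#' Mean breakdown voltage of slow (current-ramp) experiments
#'
#' Under slow voltage build-up the breakdown voltage no longer depends on
#' the ramp slope, so a single unweighted mean (and standard deviation)
#' over the per-slope group means (or raw events) summarises each
#' composition.
#'
#' @param Ubr Breakdown voltages, V (either per-slope group means or raw
#'   per-experiment values), or a list of [breakdown_event()] objects.
#' @return Named list with `mean` and `sd` (V; `sd` is 0 for one value).
#' @examples
#' mean_breakdown_voltage(c(0.25, 0.12, 0.32, 0.11, 0.26))
#' @export
mean_breakdown_voltage <- function(Ubr) {
  if (is.list(Ubr)) {
    if (!all(vapply(Ubr, inherits, logical(1), "breakdown_event")))
      stop("mean_breakdown_voltage: list input must be breakdown_event objects",
           call. = FALSE)
    if (!all(vapply(Ubr, function(e) e$mode, "") == "current_controlled"))
      stop("mean_breakdown_voltage: events must be current_controlled", call. = FALSE)
    Ubr <- vapply(Ubr, function(e) e$Ubr, 0)
  }
  if (length(Ubr) < 1) stop("mean_breakdown_voltage: empty input", call. = FALSE)
  list(mean = mean(Ubr), sd = if (length(Ubr) > 1) stats::sd(Ubr) else 0)
}
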
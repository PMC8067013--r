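# Orchestration: chains detection -> resistance estimation -> rate of
# capacitance change -> strength-duration fit -> pore-kinetics fit ->
# area-fraction model, for simulated trace ensembles, for record tables,
# and for the bundled reference tables.

.detect_all <- function(traces, window, k_sigma) {
  events <- list()
  n_failed <- 0L
  for (tr in traces) {
    ev <- tryCatch(
      if (tr$mode == "voltage_controlled")
        detect_breakdown_voltage_controlled(tr, window, k_sigma)
      else detect_breakdown_current_controlled(tr, window, k_sigma),
      error = function(e) NULL)
    if (is.null(ev)) n_failed <- n_failed + 1L else events[[length(events) + 1L]] <- ev
  }
  if (n_failed > 0L)
    warning(sprintf("breakdown detection failed on %d of %d traces",
                    n_failed, length(traces)))
  list(events = events, n_failed = n_failed)
}

# Self-consistent correction of the naive rate extraction for the water-pore
# capacitance accumulated before rupture. Under the exponential rate law the
# accumulated pore capacitance is Cw = (dC/dt - exp(n)) / (m * ku), which the
# naive inversion (charging term = C0 only) misattributes to the pore term:
# dCdt_naive = dCdt + Cw * ku / Ubr. Given current (m, n) estimates this is
# inverted in closed form and the kinetic fit re-run to a fixed point.
.correct_pore_charging <- function(Ubr, dCdt_naive, T, max_iter = 100,
                                   tol = 1e-12) {
  dCdt <- dCdt_naive
  fit <- fit_pore_kinetics(Ubr, dCdt, T = T)
  for (it in seq_len(max_iter)) {
    dCdt_new <- (dCdt_naive + exp(fit$n) / (fit$m * Ubr)) /
      (1 + 1 / (fit$m * Ubr))
    ok <- dCdt_new > 0
    if (!all(ok)) dCdt_new[!ok] <- dCdt_naive[!ok]
    fit_new <- fit_pore_kinetics(Ubr, dCdt_new, T = T)
    delta <- abs(fit_new$m - fit$m) / abs(fit$m)
    fit <- fit_new
    dCdt <- dCdt_new
    if (delta < tol) break
  }
  list(fit = fit, dCdt = dCdt)
}

#' Analyse a voltage-controlled trace ensemble
#'
#' Chains breakdown detection, the charge-balance extraction of the
#' capacitance-change rate at rupture, the strength-duration fit on
#' per-slope group means and the log-linear pore-kinetics fit.
#'
#' @param traces List of voltage-controlled [blm_trace()] objects.
#' @param spec [membrane_spec()] of the preparation.
#' @param R Membrane resistance, Ohm (from the slow current-ramp estimate).
#' @param C0 Pre-ramp membrane capacitance, F.
#' @param window,k_sigma Detection parameters, see
#'   [detect_breakdown_voltage_controlled()].
#' @param group `"slope"` (default) fits kinetics on per-slope group
#'   records (mean Ubr, geometric-mean rate); `"record"` fits on raw
#'   per-trace records.
#' @param correct_pore_capacitance If `TRUE` (default), apply the
#'   self-consistent correction for the pore capacitance accumulated
#'   before rupture, which the naive extraction misattributes to the pore
#'   current term.
#' @return List with `events` (data frame), `dCdt` (per-record rates,
#'   naive), `sd_fit`, `pk_fit`, `n_failed`.
#' @export
analyze_voltage_ensemble <- function(traces, spec, R, C0, window = 50,
                                     k_sigma = 8,
                                     group = c("slope", "record"),
                                     correct_pore_capacitance = TRUE) {
  group <- match.arg(group)
  validate_membrane_spec(spec)
  det <- .detect_all(traces, window, k_sigma)
  if (length(det$events) == 0L)
    stop("analyze_voltage_ensemble: no usable breakdown events", call. = FALSE)
  ev <- events_to_frame(det$events)
  # Ubr and i_br are read one sample before the detected jump; the
  # voltage-consistent rupture time Ubr/ku refers them to the same instant
  # (ramp consistency with tbr is asserted to 5% by breakdown_event)
  ev$dCdt <- mapply(function(ib, ku, ub)
    as.numeric(capacitance_rate_at_breakdown(ib, ku, ub / ku, R, C0)),
    ev$ibr_A, ev$slope, ev$Ubr_V)
  grp <- split(ev, ev$slope)
  means <- data.frame(
    slope = as.numeric(names(grp)),
    tbr = vapply(grp, function(g) mean(g$tbr_s), 0),
    Ubr = vapply(grp, function(g) mean(g$Ubr_V), 0),
    dCdt = vapply(grp, function(g) exp(mean(log(pmax(g$dCdt, 1e-300)))), 0),
    n = vapply(grp, nrow, 0L))
  sd_fit <- fit_strength_duration(means$tbr, means$Ubr)
  if (group == "slope") {
    Ubr_fit <- means$Ubr
    dCdt_fit <- means$dCdt
  } else {
    keep <- ev$dCdt > 0
    Ubr_fit <- ev$Ubr_V[keep]
    dCdt_fit <- ev$dCdt[keep]
  }
  if (any(dCdt_fit <= 0))
    stop("analyze_voltage_ensemble: non-positive extracted rates", call. = FALSE)
  pk <- if (correct_pore_capacitance)
    .correct_pore_charging(Ubr_fit, dCdt_fit, T = spec$T)$fit
  else fit_pore_kinetics(Ubr_fit, dCdt_fit, T = spec$T)
  list(events = ev, group_means = means, sd_fit = sd_fit, pk_fit = pk,
       n_failed = det$n_failed, R = R, C0 = C0)
}

#' Analyse a current-controlled trace ensemble
#'
#' Detects the voltage collapse in each trace, solves the ramp-response
#' quadratic for the membrane resistance per record, and summarises the
#' slow-regime breakdown voltage (unweighted mean over per-slope means).
#'
#' @param traces List of current-controlled [blm_trace()] objects.
#' @param C Membrane capacitance, F (measured before the ramp).
#' @param window,k_sigma Detection parameters.
#' @return List with `events`, `R_records` (per-record `rc_estimate`
#'   results as a data frame), `R_pooled` (mean over valid records),
#'   `Ubr_summary` (list mean/sd), `n_failed`.
#' @export
analyze_current_ensemble <- function(traces, C, window = 50, k_sigma = 8) {
  det <- .detect_all(traces, window, k_sigma)
  if (length(det$events) == 0L)
    stop("analyze_current_ensemble: no usable breakdown events", call. = FALSE)
  ev <- events_to_frame(det$events)
  rc <- lapply(seq_len(nrow(ev)), function(k)
    tryCatch(solve_membrane_resistance(C, ev$tbr_s[k], ev$Ubr_V[k],
                                       ev$slope[k]),
             error = function(e) NULL, warning = function(w) NULL))
  keep <- !vapply(rc, is.null, TRUE)
  R_records <- if (any(keep))
    data.frame(slope = ev$slope[keep],
               R = vapply(rc[keep], function(x) x$R, 0),
               tau = vapply(rc[keep], function(x) x$tau, 0),
               valid = vapply(rc[keep], function(x) x$valid, TRUE))
  else data.frame(slope = numeric(), R = numeric(), tau = numeric(),
                  valid = logical())
  valid_R <- R_records$R[R_records$valid]
  grp_means <- vapply(split(ev$Ubr_V, ev$slope), mean, 0)
  list(events = ev, R_records = R_records,
       R_pooled = if (length(valid_R)) mean(valid_R) else NA_real_,
       Ubr_summary = mean_breakdown_voltage(unname(grp_means)),
       n_failed = det$n_failed)
}

#' Analyse a breakdown-record table
#'
#' Record-level path (no raw traces): per composition, estimates the
#' membrane resistance from the slowest current-ramp records, extracts the
#' capacitance-change rate of every voltage-ramp record from the charge
#' balance, and runs the strength-duration and pore-kinetics fits.
#'
#' @param records data.frame with columns `composition`, `mode`, `slope`,
#'   `tbr_s`, `Ubr_V`, `ibr_A` (`ibr_A` may be `NA` for current-controlled
#'   rows).
#' @param specs Named list of [membrane_spec()] (default
#'   [default_compositions()]).
#' @param C Named vector of pre-ramp capacitances, F, per composition;
#'   default derives them from the bundled discharge-method specific
#'   capacitances.
#' @return Named list (per composition) of analysis results; failures on
#'   individual compositions are reported as warnings, not errors.
#' @export
analyze_records <- function(records, specs = default_compositions(), C = NULL) {
  need <- c("composition", "mode", "slope", "tbr_s", "Ubr_V")
  if (!all(need %in% names(records)))
    stop("analyze_records: missing required columns", call. = FALSE)
  if (is.null(C)) {
    cap <- reference_capacitance_table()
    cap <- cap[cap$method == "discharge", ]
    C <- stats::setNames(cap$cblm_uF_cm2 * 1e-2 *
                           vapply(cap$composition,
                                  function(x) specs[[x]]$A, 0),
                         cap$composition)
  }
  out <- list()
  for (comp in unique(records$composition)) {
    res <- tryCatch({
      rec <- records[records$composition == comp, ]
      spec <- specs[[comp]]
      if (is.null(spec)) stop("unknown composition: ", comp)
      cc <- rec[rec$mode == "current_controlled", ]
      vc <- rec[rec$mode == "voltage_controlled", ]
      R_pooled <- NA_real_
      if (nrow(cc)) {
        slow <- cc[cc$slope == min(cc$slope), ]
        Rs <- vapply(seq_len(nrow(slow)), function(k)
          solve_membrane_resistance(C[[comp]], slow$tbr_s[k], slow$Ubr_V[k],
                                    slow$slope[k])$R, 0)
        R_pooled <- mean(Rs)
      }
      sd_fit <- NULL
      pk_fit <- NULL
      if (nrow(vc) >= 3) {
        sd_fit <- fit_strength_duration(vc$tbr_s, vc$Ubr_V)
        if (!is.na(R_pooled) && all(is.finite(vc$ibr_A))) {
          dCdt <- mapply(function(ib, ku, tb)
            as.numeric(capacitance_rate_at_breakdown(ib, ku, tb, R_pooled,
                                                     C[[comp]])),
            vc$ibr_A, vc$slope, vc$tbr_s)
          if (all(dCdt > 0))
            pk_fit <- fit_pore_kinetics(vc$Ubr_V, dCdt, T = spec$T)
        }
      }
      list(composition = comp, R_pooled = R_pooled, sd_fit = sd_fit,
           pk_fit = pk_fit,
           Ubr_slow = if (nrow(cc))
             mean_breakdown_voltage(vapply(split(cc$Ubr_V, cc$slope), mean, 0))
           else NULL)
    }, error = function(e) {
      warning(sprintf("analyze_records: composition %s skipped (%s)",
                      comp, conditionMessage(e)))
      NULL
    })
    out[[comp]] <- res
  }
  if (all(vapply(out, is.null, TRUE)))
    stop("analyze_records: no usable records", call. = FALSE)
  out
}

#' Full analysis of the bundled reference tables
#'
#' Reproduces the headline quantities of the reference experiments from the
#' bundled per-slope summary tables: per composition, the strength-duration
#' fit (minimal breakdown voltage and chronaxie-like time constant) on the
#' seven voltage-ramp group means; the inversion of the tabulated pore-area
#' fractions back to capacitance-change rates using the fitted time
#' constant; the log-linear pore-kinetics fit giving the water-pore radius
#' and the spontaneous rate; the unweighted slow-regime mean breakdown
#' voltage; the membrane-resistance estimate from the slowest current ramp;
#' and the solvent-torus width from the measured specific capacitance.
#'
#' @param compositions Compositions to analyse (default all three).
#' @param c_ref_uF_cm2 Reference torus-free specific capacitance, uF/cm^2
#'   (default 0.6).
#' @return Object of class `blm_report`: per-composition results plus a
#'   provenance block (package version, parameters).
#' @examples
#' \donttest{
#' rep <- reference_report("POPC")
#' rep$compositions$POPC$pore_radius_nm
#' }
#' @export
reference_report <- function(compositions = c("POPC", "POPS", "POPC:POPS"),
                             c_ref_uF_cm2 = 0.6) {
  specs <- default_compositions()
  compositions <- match.arg(compositions, several.ok = TRUE)
  cap <- reference_capacitance_table()
  out <- list()
  for (comp in compositions) {
    spec <- specs[[comp]]
    tab <- reference_breakdown_table(comp)
    vc <- tab[tab$mode == "voltage_controlled", ]
    cc <- tab[tab$mode == "current_controlled", ]
    sd_fit <- fit_strength_duration(vc$tbr_mean_s, vc$Ubr_mean_V)
    dCdt <- capacitance_rate_from_fraction(vc$Awat_frac_percent / 100,
                                           sd_fit$tc, spec)
    pk_fit <- fit_pore_kinetics(vc$Ubr_mean_V, dCdt, T = spec$T)
    dCdt_slow <- capacitance_rate_from_fraction(cc$Awat_frac_percent / 100,
                                                sd_fit$tc, spec)
    UbrI <- mean_breakdown_voltage(cc$Ubr_mean_V)
    cblm <- cap$cblm_uF_cm2[cap$composition == comp & cap$method == "discharge"]
    C_meas <- cblm * 1e-2 * spec$A          # uF/cm^2 -> F/m^2 -> F
    slow <- cc[cc$slope == min(cc$slope), ]
    rc <- solve_membrane_resistance(C_meas, slow$tbr_mean_s, slow$Ubr_mean_V,
                                    slow$slope)
    out[[comp]] <- list(
      composition = comp,
      sd_fit = sd_fit,
      Ubrmin_V = sd_fit$Ubrmin,
      tc_us = sd_fit$tc * 1e6,
      pk_fit = pk_fit,
      pore_radius_nm = pk_fit$r * 1e9,
      spontaneous_rate_F_per_s = pk_fit$nu0,
      dCdt_fast_F_per_s = dCdt,
      dCdt_slow_F_per_s = dCdt_slow,
      UbrI_mean_V = UbrI$mean,
      UbrI_sd_V = UbrI$sd,
      cblm_discharge_uF_cm2 = cblm,
      C_meas_F = C_meas,
      R_slow_ramp_ohm = rc$R)
  }
  mix_cblm <- cap$cblm_uF_cm2[cap$composition == "POPC:POPS" &
                                cap$method == "discharge"]
  torus_um <- torus_width(mix_cblm, c_ref_uF_cm2, specs[["POPC:POPS"]]$d) * 1e6
  structure(list(
    compositions = out,
    torus_width_um = torus_um,
    provenance = list(
      package = "blmpore",
      version = as.character(utils::packageVersion("blmpore")),
      c_ref_uF_cm2 = c_ref_uF_cm2,
      r_version = as.character(getRversion()))),
    class = "blm_report")
}

#' @export
print.blm_report <- function(x, ...) {
  cat("<blm_report>\n")
  for (res in x$compositions) {
    cat(sprintf(
      "  %-9s Ubrmin = %.3f V, tc = %.1f us, r = %.4f nm, exp(n) = %.2e F/s, UbrI = %.2f +/- %.2f V\n",
      res$composition, res$Ubrmin_V, res$tc_us, res$pore_radius_nm,
      res$spontaneous_rate_F_per_s, res$UbrI_mean_V, res$UbrI_sd_V))
  }
  cat(sprintf("  torus width (POPC:POPS vs %.1f uF/cm^2): %.1f um\n",
              x$provenance$c_ref_uF_cm2, x$torus_width_um))
  invisible(x)
}

#' Write an analysis report as JSON
#'
#' @param report A `blm_report` (or any list-like report).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(path)
}
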
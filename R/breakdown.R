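#' Breakdown event record
#'
#' @param tbr Rupture time, s.
#' @param Ubr Breakdown voltage, V.
#' @param i_br Current at rupture, A (voltage-controlled mode only).
#' @param mode Acquisition mode.
#' @param slope Ramp slope (V/s or A/s).
#' @param composition Composition label or [membrane_spec()].
#' @return Object of class `breakdown_event`.
#' @export
breakdown_event <- function(tbr, Ubr, i_br = NA_real_, mode, slope,
                            composition = NULL) {
  ev <- structure(
    list(tbr = tbr, Ubr = Ubr, i_br = i_br, mode = mode, slope = slope,
         composition = composition),
    class = "breakdown_event")
  if (!(is.finite(ev$tbr) && ev$tbr > 0 && is.finite(ev$Ubr) && ev$Ubr > 0))
    stop("breakdown_event: tbr and Ubr must be positive", call. = FALSE)
  if (identical(mode, "voltage_controlled") &&
      abs(Ubr - slope * tbr) / Ubr > 0.05)
    warning("breakdown_event: Ubr deviates from ku*tbr by more than 5%")
  ev
}

#' @export
print.breakdown_event <- function(x, ...) {
  cat(sprintf("<breakdown_event> tbr = %.4g s, Ubr = %.4g V (%s)\n",
              x$tbr, x$Ubr, x$mode))
  invisible(x)
}

#' Convert breakdown events to a data frame
#'
#' @param events List of [breakdown_event()] objects.
#' @return data.frame with columns
#'   `composition,mode,slope,tbr_s,Ubr_V,ibr_A`.
#' @export
events_to_frame <- function(events) {
  if (inherits(events, "breakdown_event")) events <- list(events)
  do.call(rbind, lapply(events, function(e) {
    comp <- if (inherits(e$composition, "membrane_spec")) e$composition$name
            else if (is.null(e$composition)) NA_character_ else as.character(e$composition)
    data.frame(composition = comp, mode = e$mode, slope = e$slope,
               tbr_s = e$tbr, Ubr_V = e$Ubr, ibr_A = e$i_br)
  }))
}

# Local-polynomial estimate of a channel's value at sample `idx`, fitted on
# the `w` samples ending there. Averages instrument noise down by ~sqrt(w)
# while the quadratic term absorbs the curvature of a growing pore current.
.endpoint_estimate <- function(y, t, idx, w, degree = 2L) {
  w <- min(w, idx)
  if (w < degree + 2L) return(y[idx])
  k <- (idx - w + 1L):idx
  ts <- (t[k] - t[idx]) / (t[idx] - t[k[1]] + .Machine$double.xmin)
  X <- stats::poly(ts, degree = degree, raw = TRUE)
  unname(stats::coef(stats::lm.fit(cbind(1, X), y[k]))[1])
}

# Robust discontinuity detector on forward increments dx. The test runs on
# the second differences c2 = diff(dx): a smoothly accelerating signal (an
# exponentially growing pore current, say) keeps |c2| at the local
# curvature scale, while a rupture jump exceeds it by orders of magnitude.
# A candidate must beat BOTH the noise criterion (k_sigma times the
# MAD-based spread of the preceding window) and the magnitude criterion
# (4 times the local |c2| scale, so noise-free smooth growth, whose robust
# spread collapses to zero, cannot fire). Running medians are C-level; the
# centered windows are shifted back so each reference window precedes the
# candidate. Returns the index (into dx) of the anomalous increment.
.first_excursion <- function(dx, window, k_sigma) {
  c2 <- diff(dx)
  n <- length(c2)
  if (n <= window + 1L) return(NA_integer_)
  w2 <- 2L * (window %/% 2L) + 1L      # odd centered width ~ window
  half <- (w2 - 1L) %/% 2L
  med <- stats::runmed(c2, w2, endrule = "median")
  spr <- stats::runmed(abs(c2 - med), w2, endrule = "median") * 1.4826
  absmed <- stats::runmed(abs(c2), w2, endrule = "median")
  js <- seq.int(window + 1L, n)
  ref <- js - half - 1L                # centered window fully before js
  excess <- c2[js] - med[ref]
  flo <- 1e-9 * max(abs(dx), .Machine$double.xmin)
  thr <- pmax(k_sigma * spr[ref], 4 * absmed[ref], flo)
  for (h in which(excess > thr)) {
    j <- js[h] + 1L                    # anomalous increment in dx
    # persistence: a rupture shifts the level for good, a lone noise spike
    # reverses on the next sample and is rejected
    jend <- min(j + 4L, length(dx))
    L <- jend - j + 1L
    w <- dx[(j - window):(j - 1L)]
    sp <- stats::mad(w)
    base <- sum(dx[j:jend]) - L * stats::median(w)
    if (base > max(k_sigma * sqrt(L) * max(sp, flo),
                   2 * L * max(stats::median(abs(w)), flo)))
      return(j)
  }
  NA_integer_
}

#' Detect the breakdown event in a voltage-controlled ramp trace
#'
#' Rupture is a sudden increase in transmembrane current. The detector flags
#' the first sample whose forward current increment exceeds `k_sigma` times
#' the median-absolute-deviation spread of the increments in the preceding
#' `window` samples. The breakdown voltage is read from the voltage channel
#' at the sample immediately before the detected index, so the post-rupture
#' transient does not contaminate it.
#'
#' @param trace A [blm_trace()] in voltage-controlled mode.
#' @param window Number of preceding increments forming the reference
#'   spread (default 50).
#' @param k_sigma Detection threshold in MAD units (default 8).
#' @param est_window_u Samples used by the local-polynomial endpoint
#'   estimate of the breakdown voltage (default 200).
#' @param est_window_i Samples used for the current at rupture; default
#'   (`NULL`) adapts to the ramp slope so the window spans a fixed
#'   fraction of an e-fold of a kinetically growing pore current.
#' @return A [breakdown_event()], or `NULL` if no rupture is found.
#' @export
detect_breakdown_voltage_controlled <- function(trace, window = 50, k_sigma = 8,
                                                est_window_u = 200,
                                                est_window_i = NULL) {
  validate_blm_trace(trace)
  if (trace$mode != "voltage_controlled")
    stop("detect_breakdown_voltage_controlled: trace mode mismatch", call. = FALSE)
  di <- diff(trace$i)
  j <- .first_excursion(di, window, k_sigma)
  if (is.na(j)) return(NULL)
  idx <- j + 1L                        # sample index of the jump
  if (is.null(est_window_i)) {
    dt <- trace$t[2] - trace$t[1]
    # ~0.7 e-folds of exponential pore-current growth at a nominal kinetic
    # slope of 8 / V, so the quadratic fit sees the same curvature at every
    # ramp slope
    est_window_i <- max(8, round(0.7 / (8 * trace$slope * dt)))
  }
  # Ubr and i_br are estimated at the sample immediately before the jump so
  # the post-rupture transient contaminates neither.
  breakdown_event(
    tbr = trace$t[idx],
    Ubr = .endpoint_estimate(trace$u, trace$t, idx - 1L, est_window_u),
    i_br = .endpoint_estimate(trace$i, trace$t, idx - 1L, est_window_i),
    mode = trace$mode, slope = trace$slope, composition = trace$composition)
}

#' Detect the breakdown event in a current-controlled ramp trace
#'
#' Rupture is a sudden drop of the transmembrane voltage. The breakdown
#' voltage is the maximum voltage reached up to (and excluding) the drop.
#'
#' @inheritParams detect_breakdown_voltage_controlled
#' @param trace A [blm_trace()] in current-controlled mode.
#' @param est_window Samples used by the local-polynomial estimate of the
#'   breakdown voltage just before the collapse (default 200). The voltage
#'   rises monotonically up to rupture, so its maximum is its value there;
#'   the local fit reads it without the upward bias a maximum over noisy
#'   samples would have.
#' @return A [breakdown_event()], or `NULL` if no rupture is found.
#' @export
detect_breakdown_current_controlled <- function(trace, window = 50, k_sigma = 8,
                                                est_window = 200) {
  validate_blm_trace(trace)
  if (trace$mode != "current_controlled")
    stop("detect_breakdown_current_controlled: trace mode mismatch", call. = FALSE)
  du <- -diff(trace$u)                 # voltage decrements
  j <- .first_excursion(du, window, k_sigma)
  if (is.na(j)) return(NULL)
  idx <- j + 1L
  breakdown_event(
    tbr = trace$t[idx],
    Ubr = .endpoint_estimate(trace$u, trace$t, idx - 1L, est_window),
    mode = trace$mode, slope = trace$slope,
    composition = trace$composition)
}

#' Capacitance from a discharge transient
#'
#' Fits `u(t) = U0 * exp(-t / tau)` by least squares on `log(u)` over the
#' samples where the voltage still exceeds 5% of its initial value, and
#' returns `tau / R_discharge`.
#'
#' @param trace A [blm_trace()] in discharge mode; voltage must decay
#'   towards zero.
#' @param R_discharge Known resistance of the discharge path, Ohm.
#' @return Capacitance, F.
#' @export
capacitance_from_discharge <- function(trace, R_discharge) {
  validate_blm_trace(trace)
  if (trace$mode != "discharge")
    stop("capacitance_from_discharge: trace mode must be 'discharge'", call. = FALSE)
  stopifnot(R_discharge > 0)
  u0 <- trace$u[1]
  if (!(u0 > 0) || stats::median(diff(trace$u)) >= 0)
    stop("capacitance_from_discharge: trace does not decay", call. = FALSE)
  keep <- trace$u > 0.05 * u0 & trace$u > 0
  if (sum(keep) < 8)
    stop("capacitance_from_discharge: fewer than 8 usable samples", call. = FALSE)
  fit <- stats::lm(log(u) ~ t, data = data.frame(t = trace$t[keep],
                                                 u = trace$u[keep]))
  slope <- unname(stats::coef(fit)[2])
  if (slope >= 0)
    stop("capacitance_from_discharge: fitted decay rate is non-negative", call. = FALSE)
  tau <- -1 / slope
  tau / R_discharge
}
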
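#' Fit the two-parameter strength-duration curve
#'
#' Fits the viscoelastic strength-duration law `U^4 = a + b/t` to breakdown
#' points `(tbr, Ubr)`: ordinary least squares of `Ubr^4` on `1/tbr`. The
#' asymptote `a^(1/4)` is the minimal breakdown voltage `Ubrmin` (the
#' rheobase analogue) and `tc = b/(15*a)` is the chronaxie-like time at
#' which a stimulus of twice `Ubrmin` ruptures the bilayer (since
#' `2^4 = 16 = 1 + 15`).
#'
#' @param tbr Rupture times, s (>= 3 points, at least two distinct).
#' @param Ubr Breakdown voltages, V.
#' @param weights Optional non-negative weights (e.g. replicate counts);
#'   default unweighted.
#' @param refine If `TRUE`, follow the linearised fit with a nonlinear
#'   least-squares refinement minimising residuals in U space
#'   (Levenberg-Marquardt, needs the minpack.lm package). Experimental;
#'   default `FALSE`.
#' @return Object of class `sd_fit`: list with `a` (V^4), `b` (V^4 s),
#'   `Ubrmin` (V), `tc` (s), `rss` (residual sum of squares in U^4 space)
#'   and `n_points`.
#' @examples
#' fit <- fit_strength_duration(c(20e-6, 50e-6, 100e-6), c(0.7, 0.55, 0.5))
#' fit$Ubrmin
#' @export
fit_strength_duration <- function(tbr, Ubr, weights = NULL, refine = FALSE) {
  if (length(tbr) < 3 || length(Ubr) != length(tbr))
    stop("fit_strength_duration: need >= 3 (tbr, Ubr) points", call. = FALSE)
  if (any(tbr <= 0) || any(Ubr <= 0))
    stop("fit_strength_duration: all points must be positive", call. = FALSE)
  if (length(unique(tbr)) < 2)
    stop("fit_strength_duration: need at least two distinct tbr", call. = FALSE)
  df <- data.frame(x = 1 / tbr, y = Ubr^4)
  fit <- if (is.null(weights)) stats::lm(y ~ x, data = df)
         else stats::lm(y ~ x, data = df, weights = weights)
  a <- unname(stats::coef(fit)[1])
  b <- unname(stats::coef(fit)[2])
  if (refine) {
    if (!requireNamespace("minpack.lm", quietly = TRUE))
      stop("fit_strength_duration: refine = TRUE needs minpack.lm", call. = FALSE)
    nl <- minpack.lm::nlsLM(Ubr ~ (a + b / tbr)^0.25,
                            data = data.frame(tbr = tbr, Ubr = Ubr),
                            start = list(a = a, b = b))
    a <- unname(stats::coef(nl)["a"])
    b <- unname(stats::coef(nl)["b"])
  }
  if (!(a > 0) || !(b > 0))
    stop("fit_strength_duration: no physical asymptote (a or b <= 0)", call. = FALSE)
  structure(list(a = a, b = b, Ubrmin = a^0.25, tc = b / (15 * a),
                 rss = sum((Ubr^4 - (a + b / tbr))^2),
                 n_points = length(tbr)),
            class = "sd_fit")
}

#' @export
print.sd_fit <- function(x, ...) {
  cat(sprintf(
    "<sd_fit> U^4 = a + b/t, %d points\n  a = %.4g V^4, b = %.4g V^4 s\n  Ubrmin = %.3f V, tc = %.3g us\n",
    x$n_points, x$a, x$b, x$Ubrmin, x$tc * 1e6))
  invisible(x)
}

#' Predicted breakdown voltage at a given rupture time
#'
#' Evaluates the fitted strength-duration curve `U(t) = (a + b/t)^(1/4)`;
#' strictly decreasing in `t`, with limit `Ubrmin` as `t -> Inf`.
#'
#' @param object An `sd_fit`.
#' @param t Rupture time(s), s (> 0).
#' @param ... Unused.
#' @return Predicted breakdown voltage(s), V.
#' @export
predict.sd_fit <- function(object, t, ...) {
  stopifnot(all(t > 0))
  (object$a + object$b / t)^0.25
}
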
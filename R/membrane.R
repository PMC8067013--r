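#' Membrane composition specification
#'
#' Bundles the composition-specific physical parameters of a planar lipid
#' bilayer: thickness, dielectric constants of the lipid phase and of water
#' pores, aperture (hole) geometry and temperature. All fields are SI.
#'
#' @param name Composition label, e.g. `"POPC"`.
#' @param D Bilayer thickness (head-to-head distance), m. Must lie in
#'   \[2e-9, 6e-9\] m — the physically plausible range for a lipid bilayer.
#' @param eps_l Relative permittivity of the lipid phase (dimensionless,
#'   default 2).
#' @param eps_p Relative permittivity of water pores (dimensionless,
#'   default 80). Must exceed `eps_l`.
#' @param A Bilayer (hole) area, m^2. Default corresponds to the 117 um
#'   aperture used in the reference experiments.
#' @param d Hole diameter, m. `A` must agree with `pi*d^2/4` within 1%.
#' @param T Absolute temperature, K (default 298).
#' @return An object of class `membrane_spec` (a named list).
#' @examples
#' popc <- membrane_spec("POPC", D = 3.75e-9)
#' intact_capacitance(popc)
#' @export
membrane_spec <- function(name, D, eps_l = 2, eps_p = 80,
                          A = 1.075e-8, d = 117e-6, T = 298) {
  spec <- structure(
    list(name = as.character(name), D = D, eps_l = eps_l, eps_p = eps_p,
         A = A, d = d, T = T),
    class = "membrane_spec")
  validate_membrane_spec(spec)
  spec
}

validate_membrane_spec <- function(spec) {
  stopifnot(inherits(spec, "membrane_spec"))
  with(spec, {
    if (!(eps_p > eps_l && eps_l > 0))
      stop("membrane_spec: need eps_p > eps_l > 0", call. = FALSE)
    if (!(D >= 2e-9 && D <= 6e-9))
      stop("membrane_spec: thickness D outside [2, 6] nm; supply SI metres",
           call. = FALSE)
    if (!(T > 0)) stop("membrane_spec: temperature must be positive", call. = FALSE)
    if (!(A > 0 && d > 0)) stop("membrane_spec: A and d must be positive", call. = FALSE)
    if (abs(A - pi * d^2 / 4) / A >= 0.01)
      stop("membrane_spec: area A inconsistent with diameter d (> 1%)", call. = FALSE)
  })
  invisible(spec)
}

#' @export
print.membrane_spec <- function(x, ...) {
  cat(sprintf("<membrane_spec> %s\n", x$name))
  cat(sprintf("  D = %.3g nm, eps_l = %g, eps_p = %g\n",
              x$D * 1e9, x$eps_l, x$eps_p))
  cat(sprintf("  hole: d = %.1f um, A = %.4g m^2; T = %g K\n",
              x$d * 1e6, x$A, x$T))
  invisible(x)
}

#' Default bilayer compositions
#'
#' Registry of the three compositions used in the bundled reference
#' experiments: POPC, POPS and a 1:1 POPC:POPS mixture, with head-to-head
#' thicknesses of 3.75, 4.32 and 4.00 nm taken from molecular-dynamics
#' electron-density profiles, a 117 um aperture and room temperature.
#'
#' @return Named list of [membrane_spec()] objects
#'   (`POPC`, `POPS`, `POPC:POPS`).
#' @examples
#' names(default_compositions())
#' @export
default_compositions <- function() {
  list(
    "POPC"      = membrane_spec("POPC",      D = 3.75e-9),
    "POPS"      = membrane_spec("POPS",      D = 4.32e-9),
    "POPC:POPS" = membrane_spec("POPC:POPS", D = 4.00e-9)
  )
}

#' Read or write a composition registry as YAML
#'
#' The registry file holds one section per composition under a top-level
#' `compositions` key, with keys `D_nm`, `eps_l`, `eps_p`, `area_m2`,
#' `diameter_um`, `T_K` (thickness in nm and diameter in um for human
#' readability; everything is converted to SI on read).
#'
#' @param path File path.
#' @param specs Named list of [membrane_spec()] objects (for writing).
#' @return `read_compositions()` returns a named list of `membrane_spec`;
#'   `write_compositions()` returns `path` invisibly.
#' @export
read_compositions <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$compositions))
    stop("composition registry: missing 'compositions' key", call. = FALSE)
  out <- lapply(names(cfg$compositions), function(nm) {
    s <- cfg$compositions[[nm]]
    for (key in c("D_nm", "eps_l", "eps_p", "area_m2", "diameter_um", "T_K"))
      if (is.null(s[[key]]))
        stop(sprintf("composition '%s': missing key '%s'", nm, key), call. = FALSE)
    membrane_spec(nm, D = s$D_nm * 1e-9, eps_l = s$eps_l, eps_p = s$eps_p,
                  A = s$area_m2, d = s$diameter_um * 1e-6, T = s$T_K)
  })
  names(out) <- names(cfg$compositions)
  out
}

#' @rdname read_compositions
#' @export
write_compositions <- function(specs, path) {
  comps <- lapply(specs, function(s)
    list(D_nm = s$D * 1e9, eps_l = s$eps_l, eps_p = s$eps_p,
         area_m2 = s$A, diameter_um = s$d * 1e6, T_K = s$T))
  yaml::write_yaml(list(compositions = comps), path)
  invisible(path)
}

#' Capacitance of the intact bilayer
#'
#' Parallel-plate capacitance of the unperturbed bilayer,
#' `C = eps_l * eps0 * A / D`.
#'
#' @param spec A [membrane_spec()].
#' @return Capacitance in farads.
#' @examples
#' intact_capacitance(membrane_spec("POPC", D = 3.75e-9))
#' @export
intact_capacitance <- function(spec) {
  validate_membrane_spec(spec)
  spec$eps_l * physical_constants()$eps0 * spec$A / spec$D
}

#' Specific capacitance (capacitance per unit area)
#'
#' @param C Capacitance, F. Must be positive.
#' @param A Area, m^2. Must be positive.
#' @param units `"si"` for F/m^2 or `"uF_cm2"` for the conventional
#'   uF/cm^2 reporting unit (1 F/m^2 = 100 uF/cm^2).
#' @return Specific capacitance in the requested unit.
#' @examples
#' specific_capacitance(5.4825e-11, 1.075e-8, units = "uF_cm2")  # 0.51
#' @export
specific_capacitance <- function(C, A, units = c("si", "uF_cm2")) {
  units <- match.arg(units)
  if (!(is.numeric(C) && all(C > 0))) stop("specific_capacitance: C must be > 0", call. = FALSE)
  if (!(is.numeric(A) && all(A > 0))) stop("specific_capacitance: A must be > 0", call. = FALSE)
  out <- C / A
  if (units == "uF_cm2") out <- out * 100
  out
}

#' Electrostrictive capacitance increase
#'
#' Voltage-driven thinning increases the bilayer capacitance quadratically:
#' `C(U) = C0 * (1 + alpha * U^2)`. Reported proportionality coefficients
#' are around 0.02 per V^2.
#'
#' @param C0 Zero-voltage capacitance, F.
#' @param alpha Electrostriction coefficient, 1/V^2 (>= 0).
#' @param U Transmembrane voltage, V (vectorised).
#' @return Capacitance at voltage `U`, F.
#' @examples
#' electrostriction_capacitance(1, 0.02, 1)  # 1.02
#' @export
electrostriction_capacitance <- function(C0, alpha, U) {
  stopifnot(C0 > 0, alpha >= 0)
  C0 * (1 + alpha * U^2)
}
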
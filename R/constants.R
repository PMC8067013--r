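#' Physical constants used throughout the package
#'
#' Returns the two fundamental constants the capacitance and pore-kinetics
#' relations depend on, in SI units.
#'
#' @return A named list with elements:
#' \describe{
#'   \item{eps0}{Vacuum permittivity, 8.854e-12 F/m.}
#'   \item{kB}{Boltzmann constant, 1.380649e-23 J/K.}
#' }
#' @examples
#' physical_constants()$eps0
#' @export
physical_constants <- function() {
  list(eps0 = 8.854e-12, kB = 1.380649e-23)
}
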
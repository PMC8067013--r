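# Bundled reference measurement tables: published group summaries of
# voltage-ramp and current-ramp breakdown experiments on POPC, POPS and
# POPC:POPS (1:1) planar lipid bilayers across a 117 um aperture, plus the
# specific-capacitance survey of the same bilayers (discharge and
# capacitance-to-period methods). Slopes are SI (V/s or A/s), times in
# seconds, area fractions in percent.

.ref_file <- function(name) {
  path <- system.file("extdata", name, package = "blmpore")
  if (!nzchar(path)) stop("reference table not found: ", name, call. = FALSE)
  path
}

#' Bundled specific-capacitance measurements
#'
#' @return data.frame with columns `composition`, `method`
#'   (`discharge`/`period_converter`), `cblm_uF_cm2`, `cblm_sd_uF_cm2`, `n`.
#' @examples
#' reference_capacitance_table()
#' @export
reference_capacitance_table <- function() {
  utils::read.csv(.ref_file("specific_capacitance.csv"))
}

#' Bundled breakdown summary tables
#'
#' Per-slope group means of the breakdown voltage, rupture time and
#' water-pore area fraction for one composition, for both fast
#' (voltage-controlled, slopes 4.8--48.1 kV/s) and slow
#' (current-controlled, slopes 0.5--10 uA/s) ramps.
#'
#' @param composition `"POPC"`, `"POPS"` or `"POPC:POPS"`.
#' @return data.frame with columns `composition`, `mode`, `slope` (V/s or
#'   A/s), `N`, `Ubr_mean_V`, `Ubr_sd_V`, `tbr_mean_s`, `tbr_sd_s`,
#'   `Awat_frac_percent`.
#' @examples
#' head(reference_breakdown_table("POPC"))
#' @export
reference_breakdown_table <- function(composition = c("POPC", "POPS", "POPC:POPS")) {
  composition <- match.arg(composition)
  file <- switch(composition,
                 "POPC" = "breakdown_popc.csv",
                 "POPS" = "breakdown_pops.csv",
                 "POPC:POPS" = "breakdown_popc_pops.csv")
  utils::read.csv(.ref_file(file))
}
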
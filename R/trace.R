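#' Ramp-experiment trace
#'
#' Container for one recorded or simulated electrical trace: sample times,
#' transmembrane voltage and current, acquisition mode and ramp slope.
#'
#' @param t Sample times, s. Strictly increasing, uniform step (within 1 ppm
#'   relative), at least 16 samples.
#' @param u Transmembrane voltage samples, V.
#' @param i Transmembrane current samples, A.
#' @param mode One of `"voltage_controlled"`, `"current_controlled"`,
#'   `"discharge"`.
#' @param slope Ramp slope: V/s in voltage-controlled mode, A/s in
#'   current-controlled mode; `NA` for discharge transients.
#' @param composition Composition label or a [membrane_spec()].
#' @return Object of class `blm_trace`.
#' @export
blm_trace <- function(t, u, i,
                      mode = c("voltage_controlled", "current_controlled",
                               "discharge"),
                      slope = NA_real_, composition = NULL) {
  mode <- match.arg(mode)
  tr <- structure(
    list(t = as.numeric(t), u = as.numeric(u), i = as.numeric(i),
         mode = mode, slope = slope, composition = composition),
    class = "blm_trace")
  validate_blm_trace(tr)
  tr
}

validate_blm_trace <- function(tr) {
  stopifnot(inherits(tr, "blm_trace"))
  n <- length(tr$t)
  if (n < 16) stop("blm_trace: need at least 16 samples", call. = FALSE)
  if (length(tr$u) != n || length(tr$i) != n)
    stop("blm_trace: t, u, i must have equal length", call. = FALSE)
  dt <- diff(tr$t)
  if (any(dt <= 0)) stop("blm_trace: t must be strictly increasing", call. = FALSE)
  if ((max(dt) - min(dt)) / mean(dt) > 1e-6)
    stop("blm_trace: sampling step not uniform within 1 ppm", call. = FALSE)
  if (tr$mode != "discharge" && !is.finite(tr$slope))
    stop("blm_trace: ramp traces need a finite slope", call. = FALSE)
  invisible(tr)
}

#' @export
print.blm_trace <- function(x, ...) {
  comp <- if (inherits(x$composition, "membrane_spec")) x$composition$name
          else if (is.null(x$composition)) "?" else as.character(x$composition)
  cat(sprintf("<blm_trace> %s, %s, %d samples over %.3g s",
              comp, x$mode, length(x$t), max(x$t) - min(x$t)))
  if (is.finite(x$slope)) cat(sprintf(", slope = %.4g", x$slope))
  cat("\n")
  invisible(x)
}

#' Read / write a trace CSV
#'
#' One trace per file. Columns `time_s,voltage_V,current_A`; metadata
#' (`mode`, `slope`, `composition`) carried as `# key=value` comment lines
#' before the header.
#'
#' @param path File path.
#' @param trace A [blm_trace()] (for writing).
#' @return `read_trace_csv()` returns a `blm_trace`;
#'   `write_trace_csv()` returns `path` invisibly.
#' @export
read_trace_csv <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ml in meta_lines) {
    kv <- strsplit(sub("^#\\s*", "", ml), "=", fixed = TRUE)[[1]]
    if (length(kv) == 2) meta[[trimws(kv[1])]] <- trimws(kv[2])
  }
  df <- utils::read.csv(text = lines[!startsWith(lines, "#")])
  need <- c("time_s", "voltage_V", "current_A")
  if (!all(need %in% names(df)))
    stop("trace CSV: expected columns time_s,voltage_V,current_A", call. = FALSE)
  blm_trace(df$time_s, df$voltage_V, df$current_A,
            mode = meta$mode %||% "voltage_controlled",
            slope = suppressWarnings(as.numeric(meta$slope %||% NA)),
            composition = meta$composition)
}

#' @rdname read_trace_csv
#' @export
write_trace_csv <- function(trace, path) {
  validate_blm_trace(trace)
  comp <- if (inherits(trace$composition, "membrane_spec"))
    trace$composition$name else trace$composition
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# mode=%s", trace$mode), con)
  if (is.finite(trace$slope)) writeLines(sprintf("# slope=%.15g", trace$slope), con)
  if (!is.null(comp)) writeLines(sprintf("# composition=%s", comp), con)
  utils::write.csv(
    data.frame(time_s = trace$t, voltage_V = trace$u, current_A = trace$i),
    con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
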
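#' Uniformly sampled action-potential trace
#'
#' Bundles a time grid (ms) and a voltage series (mV) into a validated
#' `ap_trace` object, the common currency of the package. The grid must be
#' strictly increasing with constant spacing; relative spacing jitter above
#' `1e-9` is rejected because the phase-extraction math assumes a uniform grid.
#'
#' @param t Numeric vector of sample times in milliseconds, length >= 2.
#' @param v Numeric vector of voltages in millivolts, same length as `t`.
#' @param meta Optional free-form label or provenance list.
#' @return An object of class `ap_trace`: a list with elements `t`, `v`,
#'   `dt` (sample spacing, ms) and `meta`.
#' @examples
#' tr <- ap_trace(t = seq(0, 10, by = 0.5), v = sin(seq(0, 10, by = 0.5)))
#' tr
#' @export
ap_trace <- function(t, v, meta = NULL) {
  t <- as.numeric(t)
  v <- as.numeric(v)
  if (length(t) < 2L || length(t) != length(v))
    stop("'t' and 'v' must have equal length >= 2")
  if (!all(is.finite(t))) stop("non-finite time values")
  if (!all(is.finite(v))) stop("non-finite voltage values")
  dts <- diff(t)
  if (any(dts <= 0)) stop("time grid must be strictly increasing")
  dt <- (t[length(t)] - t[1L]) / (length(t) - 1L)
  if (max(abs(dts - dt)) > 1e-9 * max(dt, abs(t[length(t)])))
    stop("time grid is not uniform (relative jitter exceeds 1e-9)")
  structure(list(t = t, v = v, dt = dt, meta = meta), class = "ap_trace")
}

#' @export
print.ap_trace <- function(x, ...) {
  cat(sprintf("<ap_trace> %d samples, dt = %g ms, span [%g, %g] ms\n",
              length(x$t), x$dt, x$t[1L], x$t[length(x$t)]))
  cat(sprintf("  voltage range [%.4g, %.4g] mV", min(x$v), max(x$v)))
  if (!is.null(x$meta)) cat("  (", format(x$meta)[1L], ")", sep = "")
  cat("\n")
  invisible(x)
}

#' @export
plot.ap_trace <- function(x, ..., xlab = "time (ms)", ylab = "voltage (mV)",
                          type = "l") {
  graphics::plot(x$t, x$v, type = type, xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

#' @export
length.ap_trace <- function(x) length(x$t)

#' Read an action-potential trace from a delimited text file
#'
#' Expects at least two numeric columns (time, voltage); a header line is
#' detected and skipped automatically. The time column must form a strictly
#' increasing uniform grid.
#'
#' @param path Path to a CSV/TSV file.
#' @param time_unit Unit of the stored time column; `"ms"` (default) or `"s"`
#'   (converted to ms on read).
#' @param voltage_column Index of the voltage column (default 2).
#' @param sep Field separator; `""` lets [utils::read.table()] sniff
#'   whitespace, use `","` for CSV. Default tries comma, then whitespace.
#' @return An [ap_trace()].
#' @export
read_ap_trace <- function(path, time_unit = c("ms", "s"), voltage_column = 2L,
                          sep = NULL) {
  time_unit <- match.arg(time_unit)
  first <- readLines(path, n = 1L)
  if (is.null(sep)) sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
  has_header <- {
    fields <- strsplit(first, if (nzchar(sep)) sep else "[ \t]+")[[1L]]
    fields <- fields[nzchar(fields)]
    suppressWarnings(any(is.na(as.numeric(fields))))
  }
  dat <- utils::read.table(path, header = has_header, sep = sep)
  if (nrow(dat) < 2L) stop("fewer than 2 data rows in ", path)
  if (ncol(dat) < voltage_column) stop("file has no column ", voltage_column)
  t <- suppressWarnings(as.numeric(dat[[1L]]))
  v <- suppressWarnings(as.numeric(dat[[voltage_column]]))
  if (anyNA(t) || anyNA(v)) stop("non-numeric cells in ", path)
  if (time_unit == "s") t <- t * 1000
  ap_trace(t, v, meta = basename(path))
}

#' Write an action-potential trace to a delimited text file
#'
#' Emits two comma-separated columns (time in ms, voltage in mV) at full
#' double precision, so `read_ap_trace(write_ap_trace(x))` round-trips the
#' numerics exactly.
#'
#' @param trace An [ap_trace()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ap_trace <- function(trace, path) {
  stopifnot(inherits(trace, "ap_trace"))
  lines <- paste(format(trace$t, digits = 17, trim = TRUE, scientific = FALSE),
                 format(trace$v, digits = 17, trim = TRUE),
                 sep = ",")
  writeLines(c("t_ms,v_mV", lines), path)
  invisible(path)
}
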
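#' Convert a millisecond grid to seconds
#'
#' All trigonometric math in the FM transform uses seconds and rad/s; traces
#' are stored in milliseconds. This helper is the single conversion chokepoint.
#'
#' @param t_ms Numeric vector of times in milliseconds.
#' @return Times in seconds.
#' @export
ms_to_s <- function(t_ms) t_ms / 1000

#' Normalize a trace to the unit amplitude range
#'
#' Maps the voltage onto `[-1, 1]` with `offset = (max + min)/2` and amplitude
#' `C = (max - min)/2`, the invertible carrier scaling of the FM model.
#'
#' @param trace An [ap_trace()].
#' @return A list of class `fm_normalized` with elements `y` (normalized
#'   series), `C` (mV), `offset` (mV), `t` (ms grid) and `meta`.
#' @export
normalize_trace <- function(trace) {
  stopifnot(inherits(trace, "ap_trace"))
  vmax <- max(trace$v); vmin <- min(trace$v)
  if (vmax <= vmin) stop("degenerate range: constant trace cannot be normalized")
  offset <- (vmax + vmin) / 2
  C <- (vmax - vmin) / 2
  structure(list(y = (trace$v - offset) / C, C = C, offset = offset,
                 t = trace$t, meta = trace$meta), class = "fm_normalized")
}

# continuous arcsine branch path: theta with sin(theta) = y, built greedily.
# Candidates at each sample are asin(y) + 2*pi*k and pi - asin(y) + 2*pi*k;
# the one nearest the constant-angular-velocity prediction
# 2*theta[i-1] - theta[i-2] wins. Plain nearest-to-previous systematically
# reflects at every crest (the reflected branch is always the closer one
# there); extrapolating the velocity carries the path through extrema.
unwrap_asin <- function(y, ref_theta = NULL) {
  base <- asin(pmin(1, pmax(-1, y)))
  K <- length(y)
  theta <- numeric(K)
  theta[1L] <- base[1L]
  two_pi <- 2 * pi
  for (i in 2:K) {
    prev <- theta[i - 1L]
    pred <- if (!is.null(ref_theta)) ref_theta[i]
    else if (i > 2L) 2 * prev - theta[i - 2L]
    else prev
    c1 <- base[i] + two_pi * round((pred - base[i]) / two_pi)
    alt <- pi - base[i]
    c2 <- alt + two_pi * round((pred - alt) / two_pi)
    theta[i] <- if (abs(c1 - pred) <= abs(c2 - pred)) c1 else c2
  }
  theta
}

#' Extract the varying phase of a normalized trace
#'
#' Inverts the carrier sine sample-by-sample: the principal arcsine of the
#' normalized voltage is branch-corrected so the total phase is continuous,
#' then the carrier ramp `omega * t` and the constant phase `phi0` are
#' subtracted. The result satisfies
#' `sin(omega * t + phi0 + phi_t(t)) == y` at every sample, so extraction
#' followed by reconstruction is exact.
#'
#' @param norm A normalized trace from [normalize_trace()].
#' @param omega Carrier angular frequency in rad/s. Default `NULL` uses one
#'   carrier period per trace duration, `2 * pi / duration_s`.
#' @param phi0 Constant carrier phase in radians. Default `NULL` uses
#'   `asin(y[1])`, which anchors the varying phase at zero at the first sample
#'   and keeps the frequency-modulating factor bounded near the grid origin.
#' @param tol Tolerance on `|y| <= 1` before a domain error is raised.
#' @param ref_phase Optional `fm_phase` of a kindred trace on the same grid:
#'   its phase increments anchor the branch decisions, so that families of
#'   related traces resolve arcsine ambiguities consistently (used by
#'   [fit_family()] across blockade levels).
#' @return A list of class `fm_phase` with `phi_t` (radians), `phi0`, `omega`
#'   (rad/s) and `t` (ms grid).
#' @export
extract_phase <- function(norm, omega = NULL, phi0 = NULL, tol = 1e-9,
                          ref_phase = NULL) {
  stopifnot(inherits(norm, "fm_normalized"))
  if (max(abs(norm$y)) > 1 + tol)
    stop("normalized series exceeds [-1, 1]: broken normalization")
  t_s <- ms_to_s(norm$t - norm$t[1L])
  dur <- t_s[length(t_s)]
  if (is.null(omega)) omega <- 2 * pi / dur
  ref_theta <- if (!is.null(ref_phase)) {
    stopifnot(inherits(ref_phase, "fm_phase"),
              length(ref_phase$phi_t) == length(t_s))
    ref_phase$phi_t + ref_phase$omega * t_s + ref_phase$phi0
  }
  theta <- unwrap_asin(norm$y, ref_theta)
  if (is.null(phi0)) phi0 <- theta[1L]
  structure(list(phi_t = theta - omega * t_s - phi0, phi0 = phi0,
                 omega = omega, t = norm$t), class = "fm_phase")
}

#' Convert a phase profile to a frequency-modulating profile
#'
#' Applies the defining relation `delta_w(t) = phi_t(t) / t` (time in
#' seconds). The `t = 0` sample is filled with its right neighbor, the
#' one-sided limit of the quotient.
#'
#' @param phase An `fm_phase` from [extract_phase()].
#' @param C,offset Carrier amplitude and offset (mV) to carry along, so the
#'   profile alone reconstructs the trace.
#' @return A list of class `fm_profile` with `delta_w` (rad/s), `omega`, `C`,
#'   `offset`, `phi0` and `t` (ms grid).
#' @export
phase_to_deltaw <- function(phase, C = 1, offset = 0) {
  stopifnot(inherits(phase, "fm_phase"))
  t_s <- ms_to_s(phase$t - phase$t[1L])
  dw <- phase$phi_t / t_s
  zero <- t_s == 0
  if (any(zero)) {
    first_pos <- which(!zero)[1L]
    dw[zero] <- dw[first_pos]
  }
  structure(list(delta_w = dw, omega = phase$omega, C = C, offset = offset,
                 phi0 = phase$phi0, t = phase$t), class = "fm_profile")
}

#' Extract the full FM profile from a trace
#'
#' Convenience pipeline: [normalize_trace()], [extract_phase()],
#' [phase_to_deltaw()]. The returned profile is an exact re-parameterization
#' of the input: [fm_reconstruct()] reproduces the trace to floating-point
#' accuracy.
#'
#' @inheritParams extract_phase
#' @param trace An [ap_trace()].
#' @return An `fm_profile` (see [phase_to_deltaw()]).
#' @examples
#' tr <- simulate_fhn(fhn_params(duration = 40), stim_time = 0)
#' prof <- fm_extract(tr)
#' max(abs(fm_reconstruct(prof)$v - tr$v))   # ~1e-15
#' @export
fm_extract <- function(trace, omega = NULL, phi0 = NULL) {
  norm <- normalize_trace(trace)
  phase <- extract_phase(norm, omega = omega, phi0 = phi0)
  phase_to_deltaw(phase, C = norm$C, offset = norm$offset)
}

#' @export
print.fm_profile <- function(x, ...) {
  cat(sprintf(
    "<fm_profile> %d samples, omega = %.6g rad/s, C = %.6g mV, offset = %.6g mV, phi0 = %.6g rad\n",
    length(x$t), x$omega, x$C, x$offset, x$phi0))
  cat(sprintf("  delta_w range [%.6g, %.6g] rad/s\n",
              min(x$delta_w), max(x$delta_w)))
  invisible(x)
}

#' @export
plot.fm_profile <- function(x, ...,
                            xlab = "time (ms)", ylab = "delta_w (rad/s)") {
  graphics::plot(x$t, x$delta_w, type = "l", xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

#' Reconstruct an action potential from an FM profile
#'
#' Evaluates the literal instantaneous-frequency form
#' `v(t) = C * sin((omega + delta_w(t)) * t + phi0) + offset` (time in
#' seconds) on the profile's grid. If `pwl` is supplied, its evaluation on the
#' grid replaces the dense `delta_w` samples, which is how a compressed
#' piecewise-linear profile is played back.
#'
#' @param profile An `fm_profile`.
#' @param pwl Optional [pwl_fit()] result or `pwl` object defined on the
#'   grid's time domain in seconds.
#' @return An [ap_trace()].
#' @export
fm_reconstruct <- function(profile, pwl = NULL) {
  stopifnot(inherits(profile, "fm_profile"))
  t_s <- ms_to_s(profile$t - profile$t[1L])
  dw <- if (is.null(pwl)) profile$delta_w else predict(pwl, t_s)
  v <- profile$C * sin((profile$omega + dw) * t_s + profile$phi0) +
    profile$offset
  ap_trace(profile$t, v, meta = "fm reconstruction")
}

#' Serialize or load an FM profile
#'
#' The dense profile is written as a two-column CSV (time ms, delta_w rad/s)
#' with the carrier constants in a JSON side-car file `<path>.json`.
#'
#' @param profile An `fm_profile`.
#' @param path CSV path; the JSON header is written next to it.
#' @return `path` invisibly for the writer; an `fm_profile` for the reader.
#' @export
write_fm_profile <- function(profile, path) {
  stopifnot(inherits(profile, "fm_profile"))
  lines <- paste(format(profile$t, digits = 17, trim = TRUE, scientific = FALSE),
                 format(profile$delta_w, digits = 17, trim = TRUE), sep = ",")
  writeLines(c("t_ms,delta_w", lines), path)
  jsonlite::write_json(
    list(omega = profile$omega, C = profile$C, offset = profile$offset,
         phi0 = profile$phi0),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_fm_profile
#' @export
read_fm_profile <- function(path) {
  dat <- utils::read.csv(path)
  hdr <- jsonlite::read_json(paste0(path, ".json"))
  structure(list(delta_w = dat[[2L]], omega = hdr$omega, C = hdr$C,
                 offset = hdr$offset, phi0 = hdr$phi0, t = dat[[1L]]),
            class = "fm_profile")
}
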
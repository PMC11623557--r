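#' Configuration of a two-state playback cell
#'
#' The FM cell is a two-state automaton: at rest (state 1) it outputs the
#' resting voltage; when the sensed input reaches the threshold it switches to
#' the generation state (state 2) and plays its stored waveform for exactly
#' `k` samples, ignoring further stimuli, then returns to rest. The waveform
#' is the FM-reconstructed action potential held as a playback table.
#'
#' @param waveform An [ap_trace()] to play back (its grid defines the cell's
#'   sample clock).
#' @param v_rest Resting voltage (mV); default: the waveform's first sample.
#' @param v_th Threshold voltage (mV); default: `v_rest` plus 10 percent of
#'   the waveform amplitude.
#' @param delta_rest Frequency-modulating factor at rest (rad/s), carried for
#'   completeness; playback uses the precomputed waveform table.
#' @return A list of class `fm_cell` with `waveform` (numeric), `dt`, `k`,
#'   `v_rest`, `v_th`, `delta_rest`.
#' @export
fm_cell <- function(waveform, v_rest = NULL, v_th = NULL, delta_rest = 0) {
  stopifnot(inherits(waveform, "ap_trace"))
  w <- waveform$v
  if (is.null(v_rest)) v_rest <- w[1L]
  if (is.null(v_th)) v_th <- v_rest + 0.1 * (max(w) - min(w))
  if (v_rest > v_th) stop("'v_rest' must not exceed 'v_th'")
  structure(list(waveform = w, dt = waveform$dt, k = length(w),
                 v_rest = v_rest, v_th = v_th, delta_rest = delta_rest),
            class = "fm_cell")
}

#' @export
print.fm_cell <- function(x, ...) {
  cat(sprintf(
    "<fm_cell> k = %d playback samples at dt = %g ms; v_rest = %.4g mV, v_th = %.4g mV\n",
    x$k, x$dt, x$v_rest, x$v_th))
  invisible(x)
}

#' Fresh resting state for a playback cell
#' @return A list with `S = 1` and playback index `idx = 0`.
#' @export
cell_state <- function() list(S = 1L, idx = 0L)

#' Advance a playback cell by one sample
#'
#' At rest, an input below threshold keeps the cell at the resting voltage; an
#' input at or above threshold starts playback at the first waveform sample.
#' During playback the cell emits the stored waveform sample by sample and
#' ignores its input entirely (absolute refractoriness by construction); when
#' the last sample has been emitted the cell is at rest again on the next
#' step.
#'
#' @param cfg An [fm_cell()].
#' @param state A state list from [cell_state()] or a previous call.
#' @param v_in Sensed input voltage (mV): external stimulus or
#'   diffusion-perturbed membrane voltage.
#' @return A list `(state, v_out)`.
#' @export
step_cell <- function(cfg, state, v_in) {
  if (state$S == 1L) {
    if (v_in >= cfg$v_th) {
      state$S <- 2L
      state$idx <- 1L
      v_out <- cfg$waveform[1L]
      if (cfg$k == 1L) { state$S <- 1L; state$idx <- 0L }
      return(list(state = state, v_out = v_out))
    }
    return(list(state = state, v_out = cfg$v_rest))
  }
  v_out <- cfg$waveform[state$idx + 1L]
  state$idx <- state$idx + 1L
  if (state$idx >= cfg$k) { state$S <- 1L; state$idx <- 0L }
  list(state = state, v_out = v_out)
}

#' Run a playback cell against a stimulus schedule
#'
#' Steps the cell on its waveform sample clock for `duration` ms. Stimuli are
#' `(time_ms, amplitude_mV)` rows; each is snapped to the nearest sample and
#' presented as the cell input for that single sample (the input is the
#' resting voltage otherwise).
#'
#' @param cfg An [fm_cell()].
#' @param stim Two-column matrix or data.frame of stimulus times (ms) and
#'   amplitudes (mV), sorted by time. May be empty.
#' @param duration Total run length (ms).
#' @return A list of class `fm_cell_run`: `t` (ms), `v_out`, `S` (state
#'   trace).
#' @export
run_cell <- function(cfg, stim = NULL, duration) {
  n <- floor(duration / cfg$dt) + 1L
  t <- (seq_len(n) - 1L) * cfg$dt
  v_in <- rep(cfg$v_rest, n)
  if (!is.null(stim) && NROW(stim) > 0L) {
    stim <- as.matrix(stim)
    idx <- pmin(pmax(round(stim[, 1L] / cfg$dt) + 1L, 1L), n)
    v_in[idx] <- stim[, 2L]
  }
  v_out <- numeric(n)
  S <- integer(n)
  st <- cell_state()
  for (i in seq_len(n)) {
    # S is reported for the emitted sample: 2 while the waveform is playing
    S[i] <- if (st$S == 2L || v_in[i] >= cfg$v_th) 2L else 1L
    res <- step_cell(cfg, st, v_in[i])
    st <- res$state
    v_out[i] <- res$v_out
  }
  structure(list(t = t, v_out = v_out, S = S), class = "fm_cell_run")
}

#' @export
plot.fm_cell_run <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$t, x$v_out, type = "l", xlab = "time (ms)",
                 ylab = "V_out (mV)", ...)
  graphics::plot(x$t, x$S, type = "s", xlab = "time (ms)", ylab = "state S",
                 yaxt = "n")
  graphics::axis(2, at = c(1, 2))
  invisible(x)
}
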
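#' Deterministic analytic test signals
#'
#' Generates the modulating-signal shapes used to exercise the piecewise
#' fitter: a sine of given angular frequency and amplitude, a trapezoid
#' (rise, plateau, fall; zero plateau width gives a triangle), and a
#' ramp-step profile (step up, step down, slow ramp, constant tail).
#'
#' @param kind `"sine"`, `"trapezoid"` or `"ramp-step"`.
#' @param omega Sine angular frequency (rad/s).
#' @param amplitude Sine amplitude (mV).
#' @param periods Number of sine periods in the window.
#' @param plateau Fraction of the window occupied by the trapezoid plateau.
#' @param n_samples Number of samples. For the sine the grid is
#'   endpoint-exclusive, `t_i = (i-1) * periods * P / n`, so the window covers
#'   an exact integer number of periods for Fourier analysis.
#' @param duration Window length in seconds for the non-sine kinds.
#' @return A list with elements `t` (seconds) and `y`.
#' @examples
#' s <- make_test_signal("sine", omega = 2.0102, amplitude = 42.5175)
#' max(abs(s$y))   # ~42.5175
#' @export
make_test_signal <- function(kind = c("sine", "trapezoid", "ramp-step"),
                             omega = 2.0102, amplitude = 42.5175,
                             periods = 1L, plateau = 0.3,
                             n_samples = 12000L, duration = 1) {
  kind <- match.arg(kind)
  K <- as.integer(n_samples)
  if (kind == "sine") {
    span <- periods * 2 * pi / omega
    t <- (0:(K - 1L)) * span / K
    return(list(t = t, y = amplitude * sin(omega * t)))
  }
  t <- seq(0, duration, length.out = K)
  if (kind == "trapezoid") {
    stopifnot(plateau >= 0, plateau < 1)
    rise <- (1 - plateau) / 2
    y <- amplitude * pmin(t / (rise * duration),
                          1,
                          (duration - t) / (rise * duration))
    y <- pmax(y, 0)
    return(list(t = t, y = y))
  }
  # ramp-step: positive step, negative step, slow negative ramp, constant
  frac <- t / duration
  y <- ifelse(frac < 0.25, amplitude,
       ifelse(frac < 0.5, -amplitude / 2,
       ifelse(frac < 0.85,
              -amplitude / 2 - (frac - 0.5) / 0.35 * amplitude / 4,
              -amplitude / 10)))
  list(t = t, y = y)
}

#' Synthetic action-potential family over a blockade parameter
#'
#' Emulates the phenomenology of a channel-blockade study on a pacemaker-like
#' cell: a family of smooth AP traces on a common grid whose action-potential
#' duration follows `apd_law(ifb)` for blockade levels equally spaced in
#' `[0, 1]`. Each trace has a fast sigmoidal upstroke of fixed width, a gently
#' decaying plateau, a sigmoidal repolarization whose timing carries the APD
#' dependence, and optionally a pacemaker-like diastolic depolarization ramp
#' after repolarization (the SAN-like mode; it also keeps the phase of the FM
#' transform identifiable along the whole window). Gaussian voltage noise of
#' standard deviation `noise_sigma` is added independently per sample,
#' deterministically per `seed`.
#'
#' @param n_levels Number of blockade levels (>= 3), equally spaced on
#'   `[0, 1]`.
#' @param apd_law Function mapping blockade in `[0, 1]` to APD in ms.
#' @param noise_sigma Gaussian noise SD in mV (0 for noiseless traces).
#' @param seed Integer RNG seed.
#' @param duration,dt Common time grid (ms).
#' @param v_rest,v_peak Resting and peak voltage (mV).
#' @param upstroke_time,upstroke_width Upstroke midpoint and sigmoid width
#'   (ms).
#' @param repol_width Repolarization sigmoid width (ms), fixed across levels
#'   so the measured APD90 tracks `apd_law` up to a constant offset.
#' @param diastolic_depol Millivolts of linear diastolic depolarization
#'   accumulated between the end of repolarization and the window end
#'   (0 disables; use ~12 mV for a SAN-like family).
#' @return A list of `n_levels` elements, each `list(ifb =, trace =)` with an
#'   [ap_trace()].
#' @export
make_synthetic_ap_family <- function(n_levels = 11L,
                                     apd_law = function(b) 300 - 100 * b,
                                     noise_sigma = 0, seed = 1L,
                                     duration = 400, dt = 0.5,
                                     v_rest = -65, v_peak = 25,
                                     upstroke_time = 5, upstroke_width = 1,
                                     repol_width = 8, diastolic_depol = 0) {
  n_levels <- as.integer(n_levels)
  if (n_levels < 3L) stop("need at least 3 blockade levels")
  t <- seq(0, duration, by = dt)
  b_values <- seq(0, 1, length.out = n_levels)
  amp <- v_peak - v_rest
  rng_state <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(rng_state))
    assign(".Random.seed", rng_state, globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  lapply(b_values, function(b) {
    v <- ap_pulse(t, apd_law(b), v_rest, amp, upstroke_time, upstroke_width,
                  repol_width, diastolic_depol)
    if (noise_sigma > 0) v <- v + stats::rnorm(length(t), sd = noise_sigma)
    list(ifb = b, trace = ap_trace(t, v, meta = sprintf("synthetic ifb=%g", b)))
  })
}

# smooth AP-like pulse: sigmoidal upstroke, decaying plateau, sigmoidal
# repolarization at upstroke_time + apd, optional post-repolarization
# diastolic depolarization ramp
ap_pulse <- function(t, apd, v_rest, amp, upstroke_time, upstroke_width,
                     repol_width, diastolic_depol = 0) {
  up <- stats::plogis((t - upstroke_time) / upstroke_width)
  down <- stats::plogis((upstroke_time + apd - t) / repol_width)
  shape <- up * down * (1 - 0.15 * pmin(pmax(t - upstroke_time, 0) / apd, 1))
  v <- v_rest + amp * shape
  if (diastolic_depol != 0) {
    ramp_start <- upstroke_time + apd + 3 * repol_width
    span <- max(max(t) - ramp_start, 1e-6)
    v <- v + diastolic_depol * pmax(t - ramp_start, 0) / span
  }
  v
}

#' Synthetic coefficient family with known piecewise-linear laws
#'
#' Builds the ground truth for coefficient-law recovery directly in
#' coefficient space: an `fm_family` object whose slope trajectories
#' `A_i(b)`, first-segment intercept, carrier frequency and phase follow
#' known continuous piecewise-linear (PL3-type) laws of the blockade
#' parameter, plus Gaussian noise of standard deviation `noise_sigma`
#' (rad/s) on every coefficient. [fit_fittype()] applied to this family
#' should recover the per-piece slopes and knots, which is the oracle the
#' recovery tests use.
#'
#' The base coefficients come from compressing a pacemaker-like action
#' potential (diastolic ramp included), so their magnitudes are those of a
#' realistic modulating profile.
#'
#' @param n_levels Number of equally spaced blockade levels.
#' @param n_segments Segments of the underlying profile.
#' @param knots Interior knots of the coefficient laws, inside (0, 1).
#' @param slopes Relative slopes of the law pieces (length `length(knots) +
#'   1`); the shared law shape `g(b)` is continuous with `g(0) = 0`.
#' @param law_scale Per-coefficient modulation amplitudes are drawn
#'   uniformly in `[law_scale/2, law_scale]` with random sign
#'   (deterministic per seed).
#' @param noise_sigma Gaussian noise SD added to each coefficient (rad/s).
#' @param seed Integer RNG seed.
#' @param base_apd Base action-potential duration (ms).
#' @return A list with `family` (an `fm_family` whose `A_matrix`,
#'   `b1_values`, `omega_values`, `phi0_values` follow the laws), `truth`
#'   (base coefficients `A0`/`b1`, law amplitudes `s`, `knots`, piece
#'   `slopes`, and the law shape `g`), and the base `fm_profile`.
#' @export
make_coefficient_family <- function(n_levels = 11L, n_segments = 12L,
                                    knots = c(0.3, 0.7),
                                    slopes = c(0.4, 1.6, 0.8),
                                    law_scale = 0.2, noise_sigma = 0.5,
                                    seed = 1L, base_apd = 300) {
  t <- seq(0, 400, by = 0.5)
  v <- ap_pulse(t, base_apd, v_rest = -65, amp = 90, upstroke_time = 5,
                upstroke_width = 1, repol_width = 8, diastolic_depol = 12)
  base <- ap_trace(t, v, meta = "coefficient-family base")
  prof <- fm_extract(base)
  t_s <- ms_to_s(prof$t)
  fit <- pwl_fit(t_s, prof$delta_w, n_segments = n_segments,
                 free_intercept = TRUE, restarts = 4L, seed = 0L)
  rng_state <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(rng_state))
    assign(".Random.seed", rng_state, globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  s_amp <- stats::runif(n_segments + 1L, law_scale / 2, law_scale) *
    sample(c(-1, 1), n_segments + 1L, replace = TRUE)
  g <- function(b) {
    br <- c(0, knots, 1)
    seg <- pmin(findInterval(b, br, rightmost.closed = TRUE), length(slopes))
    base_v <- c(0, cumsum(slopes * diff(br)))
    base_v[seg] + slopes[seg] * (b - br[seg])
  }
  b_values <- seq(0, 1, length.out = n_levels)
  A0 <- fit$pwl$slopes
  b10 <- fit$pwl$b1
  gb <- vapply(b_values, g, numeric(1))
  A_matrix <- (A0 %o% rep(1, n_levels)) * (1 + s_amp[-1L] %o% gb)
  b1_values <- b10 * (1 + s_amp[1L] * gb)
  if (noise_sigma > 0) {
    A_matrix <- A_matrix + stats::rnorm(length(A_matrix), sd = noise_sigma)
    b1_values <- b1_values + stats::rnorm(n_levels, sd = noise_sigma)
  }
  family <- structure(list(
    b_values = b_values, shared_T = fit$pwl$breaks, A_matrix = A_matrix,
    b1_values = b1_values, omega_values = rep(prof$omega, n_levels),
    phi0_values = rep(prof$phi0, n_levels), C = prof$C,
    offset = prof$offset, t = prof$t, n_segments = n_segments,
    metrics = NULL, ref_fit = fit), class = "fm_family")
  list(family = family,
       truth = list(shared_T = fit$pwl$breaks, A0 = A0, b1 = b10,
                    s = s_amp, knots = knots, slopes = slopes, g = g),
       base_profile = prof)
}

#' Action-potential duration at 90 percent repolarization
#'
#' APD90 measured between the upward and final downward crossings of the
#' voltage level 90 percent of the way from peak back to rest (rest taken as
#' the first sample), with linear interpolation between samples.
#'
#' @param trace An [ap_trace()].
#' @return APD90 in ms (`NA` if the trace never crosses the level).
#' @export
apd90 <- function(trace) {
  stopifnot(inherits(trace, "ap_trace"))
  v <- trace$v; t <- trace$t
  rest <- v[1L]; peak <- max(v)
  if (peak <= rest) return(NA_real_)
  level <- peak - 0.9 * (peak - rest)
  above <- v > level
  cross_up <- which(!above[-length(v)] & above[-1L])
  cross_dn <- which(above[-length(v)] & !above[-1L])
  if (!length(cross_up) || !length(cross_dn)) return(NA_real_)
  interp <- function(i) t[i] + (level - v[i]) / (v[i + 1L] - v[i]) *
    (t[i + 1L] - t[i])
  interp(max(cross_dn)) - interp(min(cross_up))
}
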
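#' Parameter sets for the reference cell models
#'
#' The package ships two small excitable-cell models used to generate
#' ground-truth traces for the FM pipeline: the two-variable FitzHugh-Nagumo
#' (FHN) model and the three-variable Fenton-Karma (FK) ventricular model.
#' Defaults are chosen so the FHN pulse lasts roughly 40 ms and the FK action
#' potential roughly 300 ms; every constant is overridable.
#'
#' For FHN the equations are dv/dt = c (v - v^3/3 - u + I) and
#' du/dt = c eps (v + a - b u), with `c = time_scale` converting the
#' dimensionless model clock to milliseconds.
#'
#' @param a,b,eps Dimensionless FHN constants.
#' @param time_scale Rate factor (1/ms) applied to both FHN equations.
#' @param I_stim Stimulus magnitude added to dv/dt during the stimulus pulse.
#' @param stim_dur Stimulus pulse width (ms).
#' @param dt Integrator step (ms).
#' @param duration Total simulated time (ms).
#' @return A named list of model constants.
#' @export
fhn_params <- function(a = 0.7, b = 0.8, eps = 0.08, time_scale = 1,
                       I_stim = 1.5, stim_dur = 1, dt = 0.01, duration = 40) {
  stopifnot(dt > 0, duration >= dt, stim_dur > 0)
  list(a = a, b = b, eps = eps, time_scale = time_scale, I_stim = I_stim,
       stim_dur = stim_dur, dt = dt, duration = duration)
}

#' @rdname fhn_params
#' @param tau_vp,tau_vm1,tau_vm2,tau_wp,tau_wm,tau_d,tau_0,tau_r,tau_si Time
#'   constants of the three-variable model (ms).
#' @param k_si,u_csi,u_c,u_v Gate steepness and threshold constants
#'   (dimensionless).
#' @export
fk_params <- function(tau_vp = 3.33, tau_vm1 = 1250, tau_vm2 = 19.6,
                      tau_wp = 870, tau_wm = 41, tau_d = 0.25, tau_0 = 12.5,
                      tau_r = 33.33, tau_si = 29, k_si = 10, u_csi = 0.85,
                      u_c = 0.13, u_v = 0.04, I_stim = 0.3, stim_dur = 1,
                      dt = 0.01, duration = 300) {
  taus <- c(tau_vp, tau_vm1, tau_vm2, tau_wp, tau_wm, tau_d, tau_0, tau_r,
            tau_si)
  stopifnot(all(taus > 0), dt > 0, duration >= dt, stim_dur > 0)
  list(tau_vp = tau_vp, tau_vm1 = tau_vm1, tau_vm2 = tau_vm2, tau_wp = tau_wp,
       tau_wm = tau_wm, tau_d = tau_d, tau_0 = tau_0, tau_r = tau_r,
       tau_si = tau_si, k_si = k_si, u_csi = u_csi, u_c = u_c, u_v = u_v,
       I_stim = I_stim, stim_dur = stim_dur, dt = dt, duration = duration)
}

# fixed-step RK4 drive shared by both models; errors at the first non-finite
# state so integrator blow-ups are reported with the time they occur
run_rk4 <- function(y0, times, derivs, parms) {
  out <- deSolve::ode(y = y0, times = times, func = derivs, parms = parms,
                      method = "rk4")
  bad <- !stats::complete.cases(out) | !apply(is.finite(out), 1L, all)
  if (any(bad))
    stop(sprintf("integration failure: non-finite state at t = %g ms",
                 times[which(bad)[1L]]))
  out
}

#' Simulate the FitzHugh-Nagumo reference model
#'
#' Fixed-step RK4 integration from the resting fixed point, with a single
#' suprathreshold current pulse at `stim_time`. The excitation variable is
#' returned as the trace voltage.
#'
#' @param params A list from [fhn_params()].
#' @param stim_time Stimulus onset (ms); use `Inf` (or a negative `I_stim`
#'   window outside the run) for an unstimulated run.
#' @return An [ap_trace()] of the excitation variable (dimensionless units
#'   stored in the voltage slot; the FM normalization makes the scale moot).
#' @examples
#' tr <- simulate_fhn(fhn_params(duration = 60), stim_time = 0)
#' @export
simulate_fhn <- function(params = fhn_params(), stim_time = 0) {
  p <- params
  # resting fixed point: v - v^3/3 - (v + a)/b = 0
  g <- function(v) v - v^3 / 3 - (v + p$a) / p$b
  v0 <- stats::uniroot(g, c(-3, 0), tol = 1e-12)$root
  u0 <- (v0 + p$a) / p$b
  times <- seq(0, p$duration, by = p$dt)
  # raised-cosine stimulus pulse: smooth in t, so the fixed-step integrator
  # keeps its full convergence order across the stimulus window
  derivs <- function(t, y, parms) {
    I <- if (t >= stim_time && t < stim_time + p$stim_dur)
      p$I_stim * 0.5 * (1 - cos(2 * pi * (t - stim_time) / p$stim_dur))
    else 0
    dv <- p$time_scale * (y[1L] - y[1L]^3 / 3 - y[2L] + I)
    du <- p$time_scale * p$eps * (y[1L] + p$a - p$b * y[2L])
    list(c(dv, du))
  }
  out <- run_rk4(c(v = v0, u = u0), times, derivs, NULL)
  ap_trace(out[, "time"], out[, "v"], meta = "FHN")
}

#' Simulate the Fenton-Karma three-variable reference model
#'
#' Fixed-step RK4 integration of the transmembrane potential `u` and gates
#' `v`, `w` from rest, with one stimulus pulse at `stim_time`.
#'
#' @inheritParams simulate_fhn
#' @param params A list from [fk_params()].
#' @return An [ap_trace()] of `u` (dimensionless, 0 at rest).
#' @export
simulate_fk <- function(params = fk_params(), stim_time = 0) {
  p <- params
  H <- function(x) as.numeric(x > 0)
  times <- seq(0, p$duration, by = p$dt)
  derivs <- function(t, y, parms) {
    u <- y[1L]; v <- y[2L]; w <- y[3L]
    Iext <- if (t >= stim_time && t < stim_time + p$stim_dur) p$I_stim else 0
    hu <- H(u - p$u_c)
    J_fi <- -v / p$tau_d * hu * (1 - u) * (u - p$u_c)
    J_so <- u / p$tau_0 * (1 - hu) + hu / p$tau_r
    J_si <- -w / (2 * p$tau_si) * (1 + tanh(p$k_si * (u - p$u_csi)))
    tau_vm <- if (u > p$u_v) p$tau_vm1 else p$tau_vm2
    dv <- (1 - hu) * (1 - v) / tau_vm - hu * v / p$tau_vp
    dw <- (1 - hu) * (1 - w) / p$tau_wm - hu * w / p$tau_wp
    list(c(-(J_fi + J_so + J_si) + Iext, dv, dw))
  }
  out <- run_rk4(c(u = 0, v = 1, w = 1), times, derivs, NULL)
  ap_trace(out[, "time"], out[, "u"], meta = "FK")
}
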
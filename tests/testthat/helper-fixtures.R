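# shared fixtures, computed once per test run and cached

fhn_fixture_env <- new.env(parent = emptyenv())

# canonical FHN pipeline: trace -> profile -> 31-segment compressed fit ->
# reconstructed playback waveform -> tissue-ready cell at dt = 0.1 ms
fhn_fixture <- function() {
  if (is.null(fhn_fixture_env$fx)) {
    trace <- simulate_fhn(fhn_params(), stim_time = 0)
    prof <- fm_extract(trace)
    fit <- suppressWarnings(
      pwl_fit(ms_to_s(prof$t), prof$delta_w, n_segments = 31,
              restarts = 8, seed = 0, free_intercept = TRUE))
    wave <- fm_reconstruct(prof, pwl = fit$pwl)
    # affine rescale of the dimensionless excitation variable to a mV-like
    # range before building the playback cell (the tissue layer's clamp and
    # threshold defaults are millivolt-scaled)
    wave_mv <- ap_trace(wave$t, -85 + (wave$v - min(wave$v)) /
                          diff(range(wave$v)) * 120)
    cell <- fm_cell(resample_trace(wave_mv, 0.1))
    fhn_fixture_env$fx <- list(trace = trace, prof = prof, fit = fit,
                               wave = wave, cell = cell)
  }
  fhn_fixture_env$fx
}

# minimum coupling constant for the fixture cell (bisection on a 2-cell chain)
fhn_dmin <- function() {
  if (is.null(fhn_fixture_env$dmin))
    fhn_fixture_env$dmin <- find_dmin(fhn_fixture()$cell, dt = 0.1,
                                      D_bracket = c(1e-4, 1), tol = 1e-6)
  fhn_fixture_env$dmin
}

# smooth random trace: a few low-frequency Fourier terms on [0, 100] ms
random_smooth_trace <- function(seed, K = 200) {
  set.seed(seed)
  t <- seq(0, 100, length.out = K)
  x <- t / max(t)
  v <- rnorm(1, 0, 20)
  for (h in 1:3)
    v <- v + rnorm(1, 0, 30 / h) * sin(2 * pi * h * x + runif(1, 0, 2 * pi))
  ap_trace(t, v, meta = sprintf("random smooth %d", seed))
}

# exhaustive breakpoint-grid least-squares SSE oracle: interior breakpoints
# restricted to sample locations, continuity enforced by the same overlap
# design, first segment through the origin
grid_oracle_sse <- function(x, y, n_segments) {
  K <- length(x)
  interior <- 2:(K - 1)
  combos <- utils::combn(interior, n_segments - 1, simplify = FALSE)
  best <- Inf
  for (cc in combos) {
    M <- fmcell:::pwl_design(x, x[cc], x[1], x[K])
    co <- qr.coef(qr(M), y)
    co[is.na(co)] <- 0
    sse <- sum((y - drop(M %*% co))^2)
    if (sse < best) best <- sse
  }
  best
}

# direct per-segment evaluation of the lookup-table form (independent oracle
# for predict.pwl): find the segment by scanning, apply A_i * x + B_i
pwl_direct_eval <- function(p, x) {
  Tall <- c(p$x0, p$breaks)
  B <- fmcell:::pwl_intercepts(p)
  vapply(x, function(xx) {
    seg <- max(1L, min(p$n, findInterval(xx, Tall, left.open = TRUE,
                                         rightmost.closed = TRUE)))
    p$slopes[seg] * xx + B[seg]
  }, numeric(1))
}
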
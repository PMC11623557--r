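#' Configure a 1-D or 2-D lattice of coupled playback cells
#'
#' Cells sit on a `1 x M` chain or an `N x N` grid and sense
#' `V_in = V + D * L(V)`, where `L` is the discrete Laplacian with unit mesh
#' (`v_{j+1} - 2 v_j + v_{j-1}` in 1-D;
#' `v_{i+1,j} + v_{i-1,j} - 4 v_{i,j} + v_{i,j+1} + v_{i,j-1}` in 2-D) and
#' no-flux boundaries (a missing neighbor contributes the cell's own value).
#' The diffusion term serves to trigger each cell's state controller; during
#' playback a cell's emitted voltage is its stored waveform, which keeps the
#' played AP shape invariant across tissue sizes. Cells are numbered
#' row-major: cell 1 top-left, cell `N^2` bottom-right.
#'
#' Cells under the dysfunction mask never fire and hold a clamped sub-resting
#' voltage that enters their neighbors' Laplacians, so wavefronts must route
#' around them.
#'
#' @param shape Integer vector: `c(1, M)` for a chain or `c(N, N)` for a
#'   grid.
#' @param D Diffusion constant (dimensionless, unit mesh), >= 0.
#' @param dt Tissue step time (ms). The cell waveform is resampled to this
#'   step at configuration time if its native grid differs.
#' @param cell An [fm_cell()] (its waveform should be on the tissue `dt`, or
#'   supply `waveform` as an [ap_trace()] instead).
#' @param waveform Alternative to `cell`: an [ap_trace()] from which an
#'   [fm_cell()] is built after resampling to `dt`.
#' @param stim_cells Integer ids of cells stimulated at `stim_time`.
#' @param stim_time Stimulus time (ms), snapped to the nearest step.
#' @param v_sti Stimulus voltage (mV), default the cell threshold.
#' @param dysfunction_mask Logical vector over cells (row-major), or `NULL`.
#' @param clamp Voltage held by dysfunctional cells; default
#'   `v_rest - 5` mV.
#' @return A list of class `fm_tissue_config`.
#' @export
tissue_config <- function(shape, D, dt, cell = NULL, waveform = NULL,
                          stim_cells = 1L, stim_time = 0, v_sti = NULL,
                          dysfunction_mask = NULL, clamp = NULL) {
  shape <- as.integer(shape)
  if (length(shape) != 2L || any(shape < 1L))
    stop("'shape' must be c(1, M) or c(N, N)")
  if (shape[1L] != 1L && shape[1L] != shape[2L])
    stop("only 1 x M chains and N x N grids are supported")
  if (D < 0) stop("'D' must be >= 0")
  if (dt <= 0) stop("'dt' must be > 0")
  if (is.null(cell)) {
    if (is.null(waveform)) stop("supply 'cell' or 'waveform'")
    cell <- fm_cell(resample_trace(waveform, dt))
  } else if (abs(cell$dt - dt) > 1e-9) {
    cell <- fm_cell(resample_trace(
      ap_trace((seq_along(cell$waveform) - 1L) * cell$dt, cell$waveform), dt),
      v_rest = cell$v_rest, v_th = cell$v_th, delta_rest = cell$delta_rest)
  }
  ncell <- prod(shape)
  stim_cells <- as.integer(stim_cells)
  if (any(stim_cells < 1L | stim_cells > ncell)) stop("stimulated cell outside lattice")
  if (is.null(dysfunction_mask)) dysfunction_mask <- rep(FALSE, ncell)
  if (length(dysfunction_mask) != ncell) stop("mask shape must match lattice")
  if (any(dysfunction_mask[stim_cells]))
    stop("dysfunction region covers a stimulated cell")
  if (is.null(v_sti)) v_sti <- cell$v_th
  if (v_sti < cell$v_th) stop("'v_sti' must reach the threshold")
  if (is.null(clamp)) clamp <- cell$v_rest - 5
  if (clamp >= cell$v_rest) stop("'clamp' must be below the resting voltage")
  structure(list(shape = shape, D = D, dt = dt, cell = cell,
                 stim_cells = stim_cells, stim_time = stim_time,
                 v_sti = v_sti, mask = as.logical(dysfunction_mask),
                 clamp = clamp),
            class = "fm_tissue_config")
}

#' Resample a trace onto a coarser or finer uniform grid
#'
#' Linear interpolation onto `seq(t[1], t[K], by = dt)`; used to match a
#' high-resolution playback waveform to the tissue step time.
#'
#' @param trace An [ap_trace()].
#' @param dt Target spacing (ms).
#' @return An [ap_trace()].
#' @export
resample_trace <- function(trace, dt) {
  stopifnot(inherits(trace, "ap_trace"))
  if (abs(dt - trace$dt) < 1e-12) return(trace)
  tt <- seq(trace$t[1L], trace$t[length(trace$t)], by = dt)
  ap_trace(tt, stats::approx(trace$t, trace$v, xout = tt)$y, meta = trace$meta)
}

# neighbor index table with no-flux boundaries (missing neighbor = self)
neighbor_index <- function(shape) {
  nr <- shape[1L]; nc <- shape[2L]
  ncell <- nr * nc
  id <- seq_len(ncell)
  r <- (id - 1L) %/% nc + 1L
  c <- (id - 1L) %% nc + 1L
  left <- ifelse(c > 1L, id - 1L, id)
  right <- ifelse(c < nc, id + 1L, id)
  if (nr == 1L) return(cbind(left, right))
  up <- ifelse(r > 1L, id - nc, id)
  down <- ifelse(r < nr, id + nc, id)
  cbind(left, right, up, down)
}

#' Simulate a tissue of coupled playback cells
#'
#' Synchronous update on the tissue clock: each step, every cell senses its
#' diffusion-perturbed voltage, the state controllers advance, and the
#' emitted voltages form the next field. Stimulated cells receive `v_sti` as
#' input at the step nearest `stim_time`. The run is fully deterministic.
#'
#' @param cfg An [tissue_config()].
#' @param duration Simulated time (ms).
#' @return An object of class `fm_tissue_sim`: `field` (time-by-cell matrix
#'   of emitted voltages, cells in row-major id order), `t` (ms), and the
#'   configuration.
#' @export
simulate_tissue <- function(cfg, duration) {
  stopifnot(inherits(cfg, "fm_tissue_config"))
  ncell <- prod(cfg$shape)
  nb <- neighbor_index(cfg$shape)
  deg <- ncol(nb)
  w <- cfg$cell$waveform
  k <- cfg$cell$k
  v_rest <- cfg$cell$v_rest
  v_th <- cfg$cell$v_th
  n_steps <- floor(duration / cfg$dt) + 1L
  stim_step <- round(cfg$stim_time / cfg$dt) + 1L
  V <- rep(v_rest, ncell)
  V[cfg$mask] <- cfg$clamp
  S <- rep(1L, ncell)
  idx <- integer(ncell)
  field <- matrix(NA_real_, n_steps, ncell)
  live <- !cfg$mask
  for (step in seq_len(n_steps)) {
    lap <- V[nb[, 1L]] + V[nb[, 2L]] - deg * V
    if (deg == 4L) lap <- lap + V[nb[, 3L]] + V[nb[, 4L]]
    v_in <- V + cfg$D * lap
    if (any(!is.finite(v_in)))
      stop(sprintf("unstable coupling: non-finite input at step %d (t = %g ms)",
                   step, (step - 1L) * cfg$dt))
    if (step == stim_step) v_in[cfg$stim_cells] <- cfg$v_sti
    playing <- S == 2L
    trigger <- !playing & live & v_in >= v_th
    V <- rep(v_rest, ncell)
    V[cfg$mask] <- cfg$clamp
    if (any(playing)) {
      V[playing] <- w[idx[playing] + 1L]
      idx[playing] <- idx[playing] + 1L
      done <- playing & idx >= k
      S[done] <- 1L
      idx[done] <- 0L
    }
    if (any(trigger)) {
      V[trigger] <- w[1L]
      if (k > 1L) {
        S[trigger] <- 2L
        idx[trigger] <- 1L
      }
    }
    field[step, ] <- V
  }
  structure(list(field = field, t = (seq_len(n_steps) - 1L) * cfg$dt,
                 cfg = cfg),
            class = "fm_tissue_sim")
}

#' @export
print.fm_tissue_sim <- function(x, ...) {
  cat(sprintf("<fm_tissue_sim> %d x %d lattice, %d steps of %g ms, D = %g\n",
              x$cfg$shape[1L], x$cfg$shape[2L], length(x$t), x$cfg$dt,
              x$cfg$D))
  invisible(x)
}

# first time each cell attains its maximum; NA when the cell never fires
peak_times <- function(sim) {
  v_rest <- sim$cfg$cell$v_rest
  tol <- 1e-9 * max(1, abs(v_rest))
  apply_peaks <- function(col) {
    m <- max(col)
    if (m <= v_rest + tol) return(NA_real_)
    sim$t[which.max(col)]
  }
  vapply(seq_len(ncol(sim$field)), function(j) apply_peaks(sim$field[, j]),
         numeric(1))
}

#' Wavefront-timing metrics of a tissue run
#'
#' Peak time of a cell is the first sample attaining its voltage maximum.
#' `Tp1`, `Tpmid`, `TpNN` are the peak times at cell 1, the central cell
#' `(ncell + 1) / 2` and cell `ncell`; `T_mc1 = |Tp1 - Tpmid|` and
#' `T_mNN = |TpNN - Tpmid|`. `T_adj` is the lag between the stimulated
#' cell(s) and their non-stimulated orthogonal neighbors; it is verified to
#' be identical (within `dt / 2`) across those neighbors before being
#' reported. A probed cell that never fires yields `NA` for its metrics.
#'
#' @param sim An `fm_tissue_sim` from [simulate_tissue()].
#' @return A list of class `fm_wavefront_metrics` with `Tp1`, `Tpmid`,
#'   `TpNN`, `T_mc1`, `T_mNN`, `T_adj` (all ms) and the per-cell peak-time
#'   vector `Tp`.
#' @export
wavefront_metrics <- function(sim) {
  stopifnot(inherits(sim, "fm_tissue_sim"))
  Tp <- peak_times(sim)
  ncell <- length(Tp)
  mid <- (ncell + 1L) %/% 2L
  Tp1 <- Tp[1L]; Tpmid <- Tp[mid]; TpNN <- Tp[ncell]
  nb <- neighbor_index(sim$cfg$shape)
  stim <- sim$cfg$stim_cells
  lags <- numeric(0)
  for (s in stim) {
    nbs <- setdiff(unique(nb[s, ]), c(s, stim))
    nbs <- nbs[!sim$cfg$mask[nbs]]
    lags <- c(lags, abs(Tp[s] - Tp[nbs]))
  }
  lags <- lags[!is.na(lags)]
  T_adj <- if (!length(lags)) NA_real_ else {
    if (diff(range(lags)) > sim$cfg$dt / 2 + 1e-9)
      stop("adjacent peak-time lags differ across orthogonal neighbors")
    lags[1L]
  }
  structure(list(Tp1 = Tp1, Tpmid = Tpmid, TpNN = TpNN,
                 T_mc1 = abs(Tp1 - Tpmid), T_mNN = abs(TpNN - Tpmid),
                 T_adj = T_adj, Tp = Tp),
            class = "fm_wavefront_metrics")
}

#' @export
print.fm_wavefront_metrics <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "-" else sprintf("%.4f", v)
  cat(sprintf(
    "Tp1 = %s, Tpmid = %s, TpNN = %s, T_mc1 = %s, T_mNN = %s, T_adj = %s (ms)\n",
    fmt(x$Tp1), fmt(x$Tpmid), fmt(x$TpNN), fmt(x$T_mc1), fmt(x$T_mNN),
    fmt(x$T_adj)))
  invisible(x)
}

#' Export wavefront metrics as a one-row data frame
#'
#' Column order mirrors the timing tables of the tissue experiments.
#'
#' @param metrics An `fm_wavefront_metrics`.
#' @return A one-row `data.frame`.
#' @export
metrics_row <- function(metrics) {
  data.frame(Tp1 = metrics$Tp1, Tpmid = metrics$Tpmid, TpNN = metrics$TpNN,
             T_mc1 = metrics$T_mc1, T_mNN = metrics$T_mNN,
             T_adj = metrics$T_adj)
}

#' Minimum diffusion constant supporting propagation
#'
#' Bisection on the two-cell propagation predicate: a 1 x 2 chain is
#' stimulated at cell 1 and propagation means cell 2 fires within the run.
#' The bracket must straddle the switch point (low end fails, high end
#' propagates).
#'
#' @param cell An [fm_cell()] on the tissue step (or any step; it is
#'   resampled).
#' @param dt Tissue step time (ms).
#' @param D_bracket Length-2 bracket `c(low, high)`.
#' @param tol Absolute tolerance on the returned value.
#' @param duration Run length (ms); default twice the waveform length.
#' @return `D_min`, the smallest bracketed value at which propagation occurs
#'   (to within `tol`).
#' @export
find_dmin <- function(cell, dt, D_bracket, tol = 1e-6, duration = NULL) {
  stopifnot(length(D_bracket) == 2L, D_bracket[1L] < D_bracket[2L])
  if (is.null(duration)) duration <- 2 * cell$k * dt
  propagates <- function(D) {
    cfg <- tissue_config(c(1L, 2L), D = D, dt = dt, cell = cell,
                         stim_cells = 1L, stim_time = 0)
    sim <- simulate_tissue(cfg, duration)
    max(sim$field[, 2L]) > cfg$cell$v_rest + 1e-9
  }
  lo <- D_bracket[1L]; hi <- D_bracket[2L]
  if (propagates(lo)) stop("bracket invalid: low end already propagates")
  if (!propagates(hi)) stop("bracket invalid: high end does not propagate")
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (propagates(mid)) hi <- mid else lo <- mid
  }
  hi
}

#' Mark a lattice region as dysfunctional
#'
#' Returns a copy of the configuration whose masked cells never fire and hold
#' a sub-resting clamp voltage (default `v_rest - 5` mV) that their neighbors
#' sense through the Laplacian.
#'
#' @param cfg An [tissue_config()].
#' @param cells Integer ids (row-major) of the cells to mask, or a logical
#'   vector over the lattice.
#' @return The modified `fm_tissue_config`.
#' @export
apply_dysfunction <- function(cfg, cells) {
  stopifnot(inherits(cfg, "fm_tissue_config"))
  ncell <- prod(cfg$shape)
  mask <- cfg$mask
  if (is.logical(cells)) {
    if (length(cells) != ncell) stop("logical mask must match lattice size")
    mask <- mask | cells
  } else {
    cells <- as.integer(cells)
    if (any(cells < 1L | cells > ncell)) stop("region outside lattice")
    mask[cells] <- TRUE
  }
  if (any(mask[cfg$stim_cells]))
    stop("dysfunction region covers a stimulated cell")
  cfg$mask <- mask
  cfg
}

#' Row-major cell ids of a rectangular block
#'
#' Convenience for building lesion strips: all cells with row in `rows` and
#' column in `cols` of an `N x N` lattice (row-major numbering, cell 1
#' top-left).
#'
#' @param shape Lattice shape, as in [tissue_config()].
#' @param rows,cols Integer ranges.
#' @return Integer cell ids.
#' @export
block_cells <- function(shape, rows, cols) {
  nc <- shape[2L]
  as.integer(outer((rows - 1L) * nc, cols, "+"))
}
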
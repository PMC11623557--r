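#' Fit a shared-breakpoint coefficient family over blockade levels
#'
#' Extracts the frequency-modulating profile of every trace in a blockade
#' family on a common grid and compresses each into the same n-segment
#' piecewise-linear form: the breakpoints are optimized once on the reference
#' (lowest-blockade) level and then frozen, so that for every other level only
#' the segment slopes are re-estimated (a linear least-squares solve). This
#' makes each slope a single-valued trajectory `A_i(b)` over blockade, the
#' structure the fit-type equations model.
#'
#' The carrier amplitude and offset are shared across the family (taken from
#' the pooled voltage range); the carrier frequency and constant phase are
#' extracted per level and carried as additional targets.
#'
#' @param traces A list of `list(ifb =, trace =)` pairs (>= 3 levels), as
#'   produced by [make_synthetic_ap_family()]. Blockade values must lie in
#'   `[0, 1]`. Traces on different grids are linearly resampled onto the
#'   reference grid; disjoint time ranges are an error.
#' @param n_segments Number of piecewise-linear segments.
#' @param omega Carrier frequency (rad/s) shared by all levels; default one
#'   carrier period per trace duration.
#' @param restarts,seed Passed to [pwl_fit()] for the reference-level fit.
#' @param breaks Optional known breakpoint vector (seconds, last value the
#'   domain end) to use instead of fitting the reference level, e.g. when the
#'   true breakpoints of a synthetic family are known.
#' @return An object of class `fm_family`: `b_values`, `shared_T` (breakpoint
#'   vector, seconds), `A_matrix` (n x levels slope matrix), `omega_values`,
#'   `b1_values` (first-segment intercepts), `phi0_values`, carrier
#'   `C`/`offset`, common grid `t` (ms), per-level delta-w fit metrics, and
#'   the reference [pwl_fit()]. Slopes are fitted with a free first-segment
#'   intercept because the modulating factor need not vanish at the grid
#'   origin.
#' @export
fit_family <- function(traces, n_segments, omega = NULL, restarts = 8L,
                       seed = 0L, breaks = NULL) {
  if (length(traces) < 3L) stop("need at least 3 blockade levels")
  b <- vapply(traces, function(x) x$ifb, numeric(1))
  if (any(b < 0 | b > 1)) stop("blockade values must lie in [0, 1]")
  ord <- order(b)
  traces <- traces[ord]; b <- b[ord]
  if (any(diff(b) <= 0)) stop("blockade values must be distinct")

  ref <- traces[[1L]]$trace
  t_ref <- ref$t
  vs <- lapply(traces, function(x) {
    tr <- x$trace
    if (length(tr$t) == length(t_ref) && max(abs(tr$t - t_ref)) < 1e-9)
      return(tr$v)
    if (tr$t[1L] > t_ref[1L] + 1e-9 ||
        tr$t[length(tr$t)] < t_ref[length(t_ref)] - 1e-9)
      stop("trace time ranges do not cover the reference grid")
    stats::approx(tr$t, tr$v, xout = t_ref)$y
  })

  gmax <- max(vapply(vs, max, numeric(1)))
  gmin <- min(vapply(vs, min, numeric(1)))
  C <- (gmax - gmin) / 2; offset <- (gmax + gmin) / 2
  t_s <- ms_to_s(t_ref - t_ref[1L])
  if (is.null(omega)) omega <- 2 * pi / t_s[length(t_s)]

  ref_phase <- NULL
  profiles <- lapply(vs, function(v) {
    norm <- structure(list(y = (v - offset) / C, C = C, offset = offset,
                           t = t_ref, meta = NULL), class = "fm_normalized")
    phase <- extract_phase(norm, omega = omega, ref_phase = ref_phase)
    # anchor every level's branch decisions to the reference level's path,
    # so arcsine ambiguities resolve consistently across the family
    if (is.null(ref_phase)) ref_phase <<- phase
    list(dw = phase_to_deltaw(phase, C = C, offset = offset)$delta_w,
         phi0 = phase$phi0)
  })

  if (is.null(breaks)) {
    ref_fit <- pwl_fit(t_s, profiles[[1L]]$dw, n_segments = n_segments,
                       restarts = restarts, seed = seed, free_intercept = TRUE)
    shared_T <- ref_fit$pwl$breaks
  } else {
    if (length(breaks) != n_segments)
      stop("'breaks' must have length n_segments (last value = domain end)")
    ref_fit <- NULL
    shared_T <- as.numeric(breaks)
  }
  inner <- shared_T[-n_segments]
  M <- cbind(1, pwl_design(t_s, inner, t_s[1L], t_s[length(t_s)]))
  qrM <- qr(M)
  co <- vapply(profiles, function(p) {
    cc <- qr.coef(qrM, p$dw)
    cc[is.na(cc)] <- 0
    cc
  }, numeric(n_segments + 1L))
  metrics <- lapply(seq_along(profiles), function(j)
    fit_metrics(profiles[[j]]$dw, drop(M %*% co[, j])))
  structure(list(b_values = b, shared_T = shared_T,
                 A_matrix = co[-1L, , drop = FALSE],
                 b1_values = co[1L, ],
                 omega_values = rep(omega, length(b)),
                 phi0_values = vapply(profiles, `[[`, numeric(1), "phi0"),
                 C = C, offset = offset, t = t_ref,
                 n_segments = n_segments, metrics = metrics,
                 ref_fit = ref_fit),
            class = "fm_family")
}

#' @export
print.fm_family <- function(x, ...) {
  cat(sprintf(
    "<fm_family> %d blockade levels, %d shared segments, grid of %d samples\n",
    length(x$b_values), x$n_segments, length(x$t)))
  r2 <- vapply(x$metrics, `[[`, numeric(1), "r2")
  cat(sprintf("  per-level delta_w R^2: [%.4f, %.4f]\n", min(r2), max(r2)))
  invisible(x)
}

# all contiguous partitions of L ordered points into k groups of >= 2
partitions_k <- function(L, k) {
  if (k == 1L) return(list(integer(0)))
  cuts <- utils::combn(L - 1L, k - 1L, simplify = FALSE)
  Filter(function(cc) all(diff(c(0L, cc, L)) >= 2L), cuts)
}

# piecewise-linear (independent pieces) regression of z on b with free knots,
# by exhaustive search over data-gap partitions with per-piece OLS
fit_pl_target <- function(b, z, pieces) {
  L <- length(b)
  parts <- partitions_k(L, pieces)
  if (!length(parts))
    stop("too few levels for ", pieces, " pieces (need >= 2 per piece)")
  best <- NULL
  for (cc in parts) {
    bounds <- c(0L, cc, L)
    sse <- 0; cf <- matrix(0, pieces, 2L)
    for (j in seq_len(pieces)) {
      idx <- (bounds[j] + 1L):bounds[j + 1L]
      fit <- stats::lm.fit(cbind(1, b[idx]), z[idx])
      cf[j, ] <- ifelse(is.na(fit$coefficients), 0, fit$coefficients)
      sse <- sse + sum(fit$residuals^2)
    }
    if (is.null(best) || sse < best$sse) best <- list(cuts = cc, sse = sse,
                                                     coef = cf)
  }
  # knot between pieces j, j+1: fitted-line intersection when it falls near
  # the separating data gap (within one level on either side, where a
  # continuous law's knot must lie), else the gap midpoint
  knots <- vapply(seq_len(pieces - 1L), function(j) {
    lo <- b[best$cuts[j]]; hi <- b[best$cuts[j] + 1L]
    wide_lo <- b[max(best$cuts[j] - 1L, 1L)]
    wide_hi <- b[min(best$cuts[j] + 2L, L)]
    d_slope <- best$coef[j, 2L] - best$coef[j + 1L, 2L]
    if (abs(d_slope) > 1e-12) {
      r <- (best$coef[j + 1L, 1L] - best$coef[j, 1L]) / d_slope
      if (r >= wide_lo && r <= wide_hi) return(r)
    }
    (lo + hi) / 2
  }, numeric(1))
  if (length(knots) > 1L && is.unsorted(knots, strictly = TRUE))
    knots <- vapply(seq_len(pieces - 1L), function(j)
      (b[best$cuts[j]] + b[best$cuts[j] + 1L]) / 2, numeric(1))
  list(knots = knots, p0 = best$coef[, 1L], p1 = best$coef[, 2L],
       sse = best$sse)
}

eval_pl_target <- function(target, ifb) {
  j <- findInterval(ifb, c(0, target$knots, 1), rightmost.closed = TRUE)
  target$p0[j] + target$p1[j] * ifb
}

#' Fit PL3/PL4/PL5 fit-type equations to a coefficient family
#'
#' Models every slope trajectory `A_i(b)`, the carrier frequency `omega(b)`
#' and the constant phase `phi0(b)` as a piecewise-linear function of the
#' blockade parameter with 3, 4 or 5 independent linear pieces and free
#' interior knots. Knot placement is solved exactly by exhaustive search over
#' contiguous partitions of the levels (each piece needs at least two
#' levels), with ordinary least squares inside each piece; the reported knot
#' is the intersection of adjacent fitted lines when it falls in the
#' separating gap of levels.
#'
#' @param family An `fm_family` from [fit_family()].
#' @param kind `"PL3"`, `"PL4"` or `"PL5"`.
#' @return An object of class `fm_fittype` with one fitted target per slope
#'   plus the first-segment intercept `b1`, `omega` and `phi0`, and the
#'   family's carrier and grid metadata.
#' @export
fit_fittype <- function(family, kind = c("PL3", "PL4", "PL5")) {
  stopifnot(inherits(family, "fm_family"))
  kind <- match.arg(kind)
  pieces <- as.integer(substring(kind, 3L))
  b <- family$b_values
  targets <- lapply(seq_len(family$n_segments), function(i)
    fit_pl_target(b, family$A_matrix[i, ], pieces))
  names(targets) <- paste0("A", seq_len(family$n_segments))
  targets$b1 <- fit_pl_target(b, family$b1_values, pieces)
  targets$omega <- fit_pl_target(b, family$omega_values, pieces)
  targets$phi0 <- fit_pl_target(b, family$phi0_values, pieces)
  structure(list(kind = kind, pieces = pieces, targets = targets,
                 shared_T = family$shared_T, C = family$C,
                 offset = family$offset, t = family$t,
                 n_segments = family$n_segments),
            class = "fm_fittype")
}

#' @export
print.fm_fittype <- function(x, ...) {
  cat(sprintf("<fm_fittype> %s: %d pieces per target, %d slope targets + omega + phi0\n",
              x$kind, x$pieces, x$n_segments))
  invisible(x)
}

#' Total SSE of a fit-type model over its training levels
#' @param object An `fm_fittype`.
#' @param ... Unused.
#' @export
deviance.fm_fittype <- function(object, ...)
  sum(vapply(object$targets, `[[`, numeric(1), "sse"))

#' Reconstruct an action potential at an arbitrary blockade level
#'
#' Evaluates every fit-type target at `ifb`, assembles the shared-breakpoint
#' piecewise-linear modulating profile, and plays it through the FM carrier.
#'
#' @param model An `fm_fittype` from [fit_fittype()].
#' @param ifb Blockade level in `[0, 1]`.
#' @param carrier Optional `list(C =, offset =, phi0 =)` overriding the
#'   family carrier (phi0 `NULL` keeps the fit-type prediction).
#' @return A list with `trace` (the reconstructed [ap_trace()]), `profile`
#'   (the `fm_profile` played) and `pwl` (the assembled [pwl()]).
#' @export
predict_ap <- function(model, ifb, carrier = NULL) {
  stopifnot(inherits(model, "fm_fittype"))
  if (length(ifb) != 1L || ifb < 0 || ifb > 1)
    stop("'ifb' must be a single value in [0, 1]")
  A <- vapply(seq_len(model$n_segments), function(i)
    eval_pl_target(model$targets[[i]], ifb), numeric(1))
  b1 <- eval_pl_target(model$targets$b1, ifb)
  omega <- eval_pl_target(model$targets$omega, ifb)
  phi0 <- eval_pl_target(model$targets$phi0, ifb)
  C <- model$C; offset <- model$offset
  if (!is.null(carrier)) {
    C <- carrier$C %||% C
    offset <- carrier$offset %||% offset
    phi0 <- carrier$phi0 %||% phi0
  }
  p <- pwl(breaks = model$shared_T, slopes = A, b1 = b1, x0 = 0)
  t_s <- ms_to_s(model$t - model$t[1L])
  dw <- predict(p, t_s)
  profile <- structure(list(delta_w = dw, omega = omega, C = C,
                            offset = offset, phi0 = phi0, t = model$t),
                       class = "fm_profile")
  list(trace = fm_reconstruct(profile), profile = profile, pwl = p)
}

#' @export
predict.fm_fittype <- function(object, newdata, ...) {
  predict_ap(object, ifb = newdata, ...)$trace
}
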
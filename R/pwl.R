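#' Continuous piecewise-linear function
#'
#' Represents `f(x) = b1 + sum_i A_i * l_i(x)` where `l_i(x)` is the length of
#' the overlap of `[x0, x]` with segment `i`. Continuity at every breakpoint
#' holds by construction, which is exactly the intercept recurrence
#' `B_{i+1} = A_i T_i + B_i` of the lookup-table form.
#'
#' @param breaks Breakpoint locations `T_1 < ... < T_n`; `T_n` is the domain
#'   end.
#' @param slopes Segment slopes `A_1 ... A_n`, same length as `breaks`.
#' @param b1 Intercept of the first segment (default 0: the first segment
#'   passes through the origin).
#' @param x0 Domain start (default 0).
#' @return An object of class `pwl`.
#' @examples
#' f <- pwl(breaks = c(5, 10), slopes = c(1, -1))
#' predict(f, c(0, 5, 7))   # 0 5 3
#' @export
pwl <- function(breaks, slopes, b1 = 0, x0 = 0) {
  breaks <- as.numeric(breaks); slopes <- as.numeric(slopes)
  n <- length(breaks)
  if (n < 1L || length(slopes) != n)
    stop("'breaks' and 'slopes' must have equal length >= 1")
  if (any(diff(c(x0, breaks)) <= 0))
    stop("breakpoints must be strictly increasing and exceed 'x0'")
  structure(list(breaks = breaks, slopes = slopes, b1 = b1, x0 = x0, n = n),
            class = "pwl")
}

# segment intercepts B_i via the continuity recurrence
pwl_intercepts <- function(object) {
  Tprev <- c(object$x0, object$breaks[-object$n])
  # value at the left end of each segment
  left_val <- object$b1 +
    c(0, cumsum(object$slopes[-object$n] * diff(c(object$x0, object$breaks)))[
      seq_len(object$n - 1L)])
  left_val - object$slopes * Tprev
}

# design matrix of per-segment overlap lengths; slopes enter linearly
pwl_design <- function(x, inner, x0, xend) {
  Tall <- c(x0, inner, xend)
  g <- diff(Tall)
  M <- outer(x, Tall[-length(Tall)], "-")
  M[M < 0] <- 0
  M <- pmin(M, matrix(g, length(x), length(g), byrow = TRUE))
  M
}

#' Evaluate a piecewise-linear function
#'
#' @param object A [pwl()] object (or a [pwl_fit()], whose fitted function is
#'   used).
#' @param newdata Numeric vector of evaluation points within
#'   `[x0, T_n]`; values outside the domain raise an extrapolation error.
#' @param tol Domain tolerance.
#' @param ... Unused.
#' @return Numeric vector of function values.
#' @export
predict.pwl <- function(object, newdata, tol = 1e-8, ...) {
  x <- as.numeric(newdata)
  rng <- c(object$x0, object$breaks[object$n])
  span <- diff(rng)
  if (any(x < rng[1L] - tol * span | x > rng[2L] + tol * span))
    stop("evaluation outside the piecewise-linear domain [",
         rng[1L], ", ", rng[2L], "]")
  M <- pwl_design(x, object$breaks[-object$n], object$x0,
                  object$breaks[object$n])
  drop(M %*% object$slopes) + object$b1
}

#' @export
print.pwl <- function(x, ...) {
  cat(sprintf("<pwl> %d segments on [%g, %g], b1 = %g\n",
              x$n, x$x0, x$breaks[x$n], x$b1))
  invisible(x)
}

#' Goodness-of-fit metrics
#'
#' Sum of squared errors `SSE = sum((y - yhat)^2)`, root mean squared error
#' `RMSE = sqrt(SSE / K)` and coefficient of determination
#' `R^2 = 1 - SSE / sum((y - mean(y))^2)`.
#'
#' @param y Observed values.
#' @param y_hat Fitted values, same length.
#' @return A list of class `fm_metrics` with `sse`, `rmse`, `r2` and
#'   `r2_defined` (`FALSE` when `y` has zero variance with nonzero SSE, in
#'   which case `r2` is `NA`).
#' @export
fit_metrics <- function(y, y_hat) {
  if (length(y) != length(y_hat)) stop("length mismatch")
  sse <- sum((y - y_hat)^2)
  sst <- sum((y - mean(y))^2)
  r2_defined <- sst > 0 || sse == 0
  r2 <- if (sst > 0) 1 - sse / sst else if (sse == 0) 1 else NA_real_
  structure(list(sse = sse, rmse = sqrt(sse / length(y)), r2 = r2,
                 r2_defined = r2_defined),
            class = "fm_metrics")
}

#' @export
print.fm_metrics <- function(x, ...) {
  cat(sprintf("SSE = %.6g, RMSE = %.6g, R^2 = %.6g\n", x$sse, x$rmse, x$r2))
  invisible(x)
}

#' Total harmonic distortion of a sampled signal
#'
#' Discrete Fourier magnitudes are taken at exact multiples of the fundamental
#' over a window covering an integer number of fundamental periods (the
#' integer-period requirement avoids spectral leakage corrupting the harmonic
#' magnitudes). The square-root convention is used:
#' `THD = sqrt(sum_k V_k^2) / V_1` over harmonics `k = 2..N` below Nyquist.
#'
#' @param y Uniformly sampled signal.
#' @param dt Sample spacing in seconds.
#' @param fundamental_omega Fundamental angular frequency in rad/s.
#' @param tol Tolerance on integer period coverage (in periods).
#' @return THD (dimensionless, >= 0).
#' @examples
#' t <- (0:9999) * (2 * pi / 10000)
#' thd(sin(t), t[2], 1)          # ~0 for a pure sine
#' @export
thd <- function(y, dt, fundamental_omega, tol = 1e-6) {
  K <- length(y)
  period <- 2 * pi / fundamental_omega
  m <- K * dt / period
  if (abs(m - round(m)) > tol)
    stop(sprintf(
      "window covers %.8g fundamental periods; an integer count is required",
      m))
  m <- as.integer(round(m))
  spec <- abs(stats::fft(y))
  k_max <- floor((K / 2 - 1) / m)        # highest harmonic below Nyquist
  if (k_max < 1L) stop("no resolvable fundamental below Nyquist")
  Vk <- spec[seq_len(k_max) * m + 1L]    # bin k*m holds harmonic k
  if (Vk[1L] == 0) stop("zero fundamental component")
  sqrt(sum(Vk[-1L]^2)) / Vk[1L]
}

# curvature-weighted interior breakpoints: quantiles of |second difference|
curvature_breaks <- function(x, y, n) {
  if (n < 2L) return(numeric(0))
  w <- abs(diff(y, differences = 2L))
  w <- w + max(w, .Machine$double.eps) * 1e-3   # keep mass everywhere
  cw <- cumsum(w) / sum(w)
  idx <- vapply(seq_len(n - 1L) / n,
                function(q) which(cw >= q)[1L] + 1L, integer(1L))
  sort(unique(x[pmin(pmax(idx, 2L), length(x) - 1L)]))
}

# interior breakpoints at quantiles of |first difference| mass
slope_breaks <- function(x, y, n) {
  if (n < 2L) return(numeric(0))
  w <- abs(diff(y))
  w <- w + max(w, .Machine$double.eps) * 1e-3
  cw <- cumsum(w) / sum(w)
  idx <- vapply(seq_len(n - 1L) / n,
                function(q) which(cw >= q)[1L] + 1L, integer(1L))
  sort(unique(x[pmin(pmax(idx, 2L), length(x) - 1L)]))
}

# greedy knot insertion: repeatedly add a breakpoint at the location of the
# largest absolute residual of the current least-squares fit
greedy_breaks <- function(x, y, n, x0, xend, solve_slopes) {
  if (n < 2L) return(numeric(0))
  Tin <- numeric(0)
  for (m in seq_len(n - 1L)) {
    M <- pwl_design(x, Tin, x0, xend)
    r <- abs(y - solve_slopes(M, y)$fitted)
    r[c(1L, length(r))] <- 0
    # exclude samples already adjacent to a breakpoint
    if (length(Tin)) {
      near <- vapply(x, function(xx) min(abs(xx - Tin)), numeric(1))
      r[near < (xend - x0) * 1e-6] <- 0
    }
    cand <- x[which.max(r)]
    if (cand <= x0 || cand >= xend || any(cand == Tin)) break
    Tin <- sort(c(Tin, cand))
  }
  Tin
}

softmax_gaps <- function(u, span) {
  e <- exp(u - max(u)) + 1e-12
  span * e / sum(e)
}

#' Fit a continuous piecewise-linear function with free breakpoints
#'
#' Least-squares segmented regression: both the interior breakpoints and the
#' segment slopes are free, continuity is enforced by construction, and the
#' first segment passes through the origin unless `free_intercept = TRUE`.
#' Because the model is linear in the slopes for fixed breakpoints, slopes are
#' profiled out by linear least squares and only the breakpoint positions
#' (under a strict-ordering log-gap parameterization) are optimized
#' numerically, by multi-start local search ([stats::nlminb()]). Starts are
#' equally spaced breakpoints, curvature-weighted breakpoints, the optional
#' warm start `init`, and seeded random perturbations; the best SSE wins, with
#' ties (within `1e-12`) broken toward the lexicographically smaller
#' breakpoint vector. The result is deterministic for a given `seed`.
#'
#' For long signals the breakpoint search runs on a thinned subgrid of at most
#' `opt_points` samples; slopes and all reported metrics are then recomputed
#' on the full grid.
#'
#' @param x Sample locations, strictly increasing (a uniform grid in typical
#'   use; the domain is `[x[1], x[K]]`).
#' @param y Signal values, same length as `x` (`K > 2 * n_segments`).
#' @param n_segments Number of linear segments `n >= 1`.
#' @param restarts Number of multi-start local optimizations (default 8).
#' @param seed Integer seed for the random restarts (default 0).
#' @param free_intercept If `TRUE` the first segment has a free intercept
#'   instead of passing through the origin.
#' @param init Optional warm start: a `pwl`/`pwl_fit` or a numeric vector of
#'   interior breakpoints added to the start list (used e.g. to seed an
#'   `n + 1`-segment fit with an `n`-segment solution).
#' @param opt_points Maximum samples used during breakpoint search.
#' @param control Passed to [stats::nlminb()].
#' @return An object of class `pwl_fit`: list with the fitted `pwl`, `metrics`
#'   ([fit_metrics()] on the full grid), `fitted`, `x`, `y` and call details.
#' @examples
#' x <- seq(0, 10, length.out = 201)
#' y <- ifelse(x <= 5, x, 10 - x)
#' fit <- pwl_fit(x, y, n_segments = 2)
#' coef(fit)
#' @export
pwl_fit <- function(x, y, n_segments, restarts = 8L, seed = 0L,
                    free_intercept = FALSE, init = NULL, opt_points = 4000L,
                    control = list(iter.max = 400L, eval.max = 2000L)) {
  x <- as.numeric(x); y <- as.numeric(y)
  K <- length(x)
  n <- as.integer(n_segments)
  if (n < 1L) stop("'n_segments' must be >= 1")
  if (K != length(y)) stop("'x' and 'y' must have equal length")
  if (K <= 2L * n)
    stop("infeasible segment count: need more than 2 * n_segments samples")
  if (any(diff(x) <= 0)) stop("'x' must be strictly increasing")
  x0 <- x[1L]; xend <- x[K]; span <- xend - x0

  solve_slopes <- function(M, yy) {
    if (free_intercept) M <- cbind(1, M)
    co <- qr.coef(qr(M), yy)
    co[is.na(co)] <- 0
    list(coef = co, fitted = drop(M %*% co))
  }
  sse_of <- function(inner, xx, yy) {
    M <- pwl_design(xx, inner, x0, xend)
    sum((yy - solve_slopes(M, yy)$fitted)^2)
  }

  # thinned subgrid for the breakpoint search
  if (K > opt_points) {
    idx <- unique(round(seq(1L, K, length.out = opt_points)))
    xs <- x[idx]; ys <- y[idx]
  } else {
    xs <- x; ys <- y
  }

  gaps_to_u <- function(Tin) log(pmax(diff(c(x0, Tin, xend)), 1e-10 * span))
  u_to_inner <- function(u) {
    g <- softmax_gaps(u, span)
    x0 + cumsum(g)[-n]
  }
  objective <- function(u) sse_of(u_to_inner(u), xs, ys)

  # objective + analytic gradient on the search grid, with shared evaluation.
  # Slopes are the least-squares minimizers for given breakpoints, so by the
  # envelope theorem dSSE/dT_j = -2 (A_j - A_{j+1}) * sum_{x_i > T_j} r_i,
  # which the softmax chain rule maps onto the log-gap parameters.
  cache <- new.env(parent = emptyenv())
  cache$u <- NULL
  eval_cached <- function(u) {
    if (!is.null(cache$u) && identical(u, cache$u)) return(invisible(NULL))
    g <- softmax_gaps(u, span)
    Tin <- x0 + cumsum(g)[-n]
    M <- pwl_design(xs, Tin, x0, xend)
    sol <- solve_slopes(M, ys)
    A <- if (free_intercept) sol$coef[-1L] else sol$coef
    r <- ys - sol$fitted
    cache$u <- u; cache$g <- g; cache$Tin <- Tin; cache$A <- A
    cache$r <- r; cache$sse <- sum(r^2)
    invisible(NULL)
  }
  obj_fn <- function(u) { eval_cached(u); cache$sse }
  grad_fn <- function(u) {
    eval_cached(u)
    tail_r <- rev(cumsum(rev(cache$r)))               # sum of r over x > T_j
    pos <- findInterval(cache$Tin, xs)
    S <- ifelse(pos + 1L <= length(xs), tail_r[pmin(pos + 1L, length(xs))], 0)
    gradT <- -2 * (cache$A[-n] - cache$A[-1L]) * S    # length n - 1
    ck <- (cache$Tin - x0) / span
    tailG <- rev(cumsum(rev(c(gradT, 0))))            # sum_{k >= m} gradT_k
    cache$g * (tailG - sum(gradT * ck))
  }

  starts <- list(rep(0, n))                      # equal spacing
  cb <- curvature_breaks(xs, ys, n)
  if (length(cb) == n - 1L) starts <- c(starts, list(gaps_to_u(cb)))
  sb <- slope_breaks(xs, ys, n)
  if (length(sb) == n - 1L) starts <- c(starts, list(gaps_to_u(sb)))
  gb <- greedy_breaks(xs, ys, n, x0, xend, solve_slopes)
  if (length(gb) == n - 1L) starts <- c(starts, list(gaps_to_u(gb)))
  if (!is.null(init)) {
    if (inherits(init, "pwl_fit")) init <- init$pwl
    Tin <- if (inherits(init, "pwl")) init$breaks[-init$n] else as.numeric(init)
    Tin <- sort(Tin[Tin > x0 & Tin < xend])
    if (length(Tin) > n - 1L) Tin <- Tin[seq_len(n - 1L)]
    while (length(Tin) < n - 1L) {               # split the widest gap
      gaps <- diff(c(x0, Tin, xend))
      j <- which.max(gaps)
      newb <- c(x0, Tin, xend)[j] + gaps[j] / 2
      Tin <- sort(c(Tin, newb))
    }
    starts <- c(starts, list(gaps_to_u(Tin)))
  }
  if (!is.null(seed)) {
    rng_state <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(rng_state))
      assign(".Random.seed", rng_state, globalenv())
      else if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv()), add = TRUE)
    set.seed(as.integer(seed))
  }
  while (length(starts) < restarts)
    starts <- c(starts, list(stats::rnorm(n, sd = 0.8)))
  starts <- starts[seq_len(min(length(starts), max(restarts, length(starts))))]

  best <- NULL
  converged <- TRUE
  for (u0 in starts) {
    opt <- stats::nlminb(u0, obj_fn, gradient = grad_fn, control = control)
    if (grepl("limit", opt$message %||% "", fixed = TRUE)) converged <- FALSE
    cand <- list(inner = sort(u_to_inner(opt$par)), sse = opt$objective)
    take <- is.null(best) || cand$sse < best$sse - 1e-12
    if (!take && abs(cand$sse - best$sse) <= 1e-12) {
      d <- which(cand$inner != best$inner)           # lexicographic tie-break
      take <- length(d) > 0L && cand$inner[d[1L]] < best$inner[d[1L]]
    }
    if (take) best <- cand
  }
  if (!converged)
    warning("one or more restarts did not converge; best solution returned")

  # final slopes + metrics on the full grid
  M <- pwl_design(x, best$inner, x0, xend)
  sol <- solve_slopes(M, y)
  if (free_intercept) {
    b1 <- sol$coef[1L]; A <- sol$coef[-1L]
  } else {
    b1 <- 0; A <- sol$coef
  }
  fitted <- sol$fitted
  model <- pwl(breaks = c(best$inner, xend), slopes = A, b1 = b1, x0 = x0)
  structure(list(pwl = model, metrics = fit_metrics(y, fitted),
                 fitted = fitted, x = x, y = y, n_segments = n,
                 restarts = length(starts), seed = seed,
                 free_intercept = free_intercept),
            class = "pwl_fit")
}

#' @export
print.pwl_fit <- function(x, ...) {
  cat(sprintf("Piecewise-linear least-squares fit: %d segments, %d samples\n",
              x$n_segments, length(x$x)))
  print(x$metrics)
  invisible(x)
}

#' @export
summary.pwl_fit <- function(object, ...) {
  cat(sprintf(
    "Piecewise-linear fit with free breakpoints\n  segments: %d\n  samples:  %d\n  restarts: %d (seed %s)\n",
    object$n_segments, length(object$x), object$restarts,
    format(object$seed)))
  print(object$metrics)
  cat("\nSegment table:\n")
  print(coef(object), digits = 6)
  invisible(object)
}

#' @export
coef.pwl_fit <- function(object, ...) {
  p <- object$pwl
  data.frame(segment = seq_len(p$n),
             T_start = c(p$x0, p$breaks[-p$n]),
             T_end = p$breaks,
             A = p$slopes,
             B = pwl_intercepts(p))
}

#' @export
predict.pwl_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  predict(object$pwl, newdata, ...)
}

#' @export
fitted.pwl_fit <- function(object, ...) object$fitted

#' @export
residuals.pwl_fit <- function(object, ...) object$y - object$fitted

#' @export
plot.pwl_fit <- function(x, ..., xlab = "x", ylab = "y") {
  graphics::plot(x$x, x$y, type = "l", col = "grey50", xlab = xlab,
                 ylab = ylab, ...)
  graphics::lines(x$x, x$fitted, col = "red3")
  graphics::abline(v = x$pwl$breaks[-x$pwl$n], lty = 3, col = "grey70")
  invisible(x)
}

#' Export or import a piecewise-linear coefficient lookup table
#'
#' Writes the segment table (segment, T_start, T_end, A, B) as CSV with a JSON
#' side-car carrying `n`, `b1` and `x0`, mirroring the coefficient LUT used
#' for waveform playback hardware.
#'
#' @param object A `pwl` or `pwl_fit`.
#' @param path CSV path; metadata goes to `<path>.json`.
#' @return `path` invisibly for the writer; a `pwl` for the reader.
#' @export
write_pwl_lut <- function(object, path) {
  if (inherits(object, "pwl_fit")) object <- object$pwl
  stopifnot(inherits(object, "pwl"))
  tab <- data.frame(segment = seq_len(object$n),
                    T_start = c(object$x0, object$breaks[-object$n]),
                    T_end = object$breaks,
                    A = object$slopes,
                    B = pwl_intercepts(object))
  utils::write.csv(format(tab, digits = 17), path, row.names = FALSE,
                   quote = FALSE)
  jsonlite::write_json(list(n = object$n, b1 = object$b1, x0 = object$x0),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_pwl_lut
#' @export
read_pwl_lut <- function(path) {
  tab <- utils::read.csv(path)
  hdr <- jsonlite::read_json(paste0(path, ".json"))
  pwl(breaks = tab$T_end, slopes = tab$A, b1 = hdr$b1, x0 = hdr$x0)
}
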
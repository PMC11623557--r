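test_that("piecewise-linear evaluation matches the lookup-table form", {
  f1 <- pwl(breaks = 10, slopes = 2)
  expect_equal(predict(f1, 3), 6)

  f2 <- pwl(breaks = c(5, 10), slopes = c(1, -1))
  expect_equal(predict(f2, c(5, 7)), c(5, 3))

  # random functions against the direct per-segment formula
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(2:6, 1)
    p <- pwl(breaks = sort(runif(n, 0.1, 10)), slopes = rnorm(n),
             b1 = rnorm(1))
    x <- runif(1000, 0, max(p$breaks))
    expect_lt(max(abs(predict(p, x) - pwl_direct_eval(p, x))), 1e-12)
  }

  expect_error(predict(f2, 11), "outside")
  expect_error(pwl(breaks = c(5, 5), slopes = c(1, 2)), "strictly increasing")
})

test_that("an exactly representable signal is recovered to machine precision", {
  x <- seq(0, 10, length.out = 201)
  y <- ifelse(x <= 5, x, 10 - x)
  fit <- suppressWarnings(pwl_fit(x, y, n_segments = 2))
  expect_lt(fit$metrics$sse, 1e-16 * length(x))
  expect_equal(fit$pwl$slopes, c(1, -1), tolerance = 1e-6)
  expect_equal(fit$pwl$breaks[1], 5, tolerance = 1e-4)
})

test_that("fits are continuous at every breakpoint", {
  fx <- fhn_fixture()
  co <- coef(fx$fit)
  inner <- seq_len(nrow(co) - 1)
  left <- co$A[inner] * co$T_end[inner] + co$B[inner]
  right <- co$A[inner + 1] * co$T_end[inner] + co$B[inner + 1]
  # relative to the size of the terms being cancelled
  scale <- max(abs(co$A * co$T_end))
  expect_lt(max(abs(left - right)), 1e-10 * scale)
})

test_that("fitting is deterministic for a fixed seed", {
  set.seed(99)
  x <- seq(0, 1, length.out = 120)
  y <- sin(6 * x) + 0.05 * rnorm(120)
  f1 <- suppressWarnings(pwl_fit(x, y, 3, seed = 7))
  f2 <- suppressWarnings(pwl_fit(x, y, 3, seed = 7))
  expect_identical(f1$pwl$breaks, f2$pwl$breaks)
  expect_identical(f1$metrics$sse, f2$metrics$sse)
})

test_that("adding a segment never hurts when warm-started", {
  x <- seq(0, 2, length.out = 300)
  y <- exp(-x) * sin(8 * x)
  prev <- suppressWarnings(pwl_fit(x, y, 3, seed = 0))
  for (n in 4:6) {
    nxt <- suppressWarnings(pwl_fit(x, y, n, seed = 0, init = prev))
    expect_lte(nxt$metrics$sse, prev$metrics$sse + 1e-12)
    prev <- nxt
  }
})

test_that("the optimizer is at least as good as exhaustive grid search", {
  # small-signal oracle equivalence on a couple of representative cases;
  # the full 20-signal sweep runs in the acceptance suite
  for (seed in c(1, 2)) {
    set.seed(seed)
    K <- 40
    x <- seq(0, 1, length.out = K)
    y <- sin(3 * x) + 0.3 * x^2 + 0.02 * rnorm(K)
    fit <- suppressWarnings(pwl_fit(x, y, 2, seed = 0))
    expect_lte(fit$metrics$sse, grid_oracle_sse(x, y, 2) + 1e-10)
  }
})

test_that("infeasible segment counts are rejected", {
  expect_error(pwl_fit(seq_len(5), rnorm(5), 3), "infeasible")
  expect_error(pwl_fit(seq_len(10), rnorm(10), 0), ">= 1")
})

test_that("goodness metrics follow their definitions", {
  m <- fit_metrics(c(0, 1, 2), c(0, 1, 3))
  expect_equal(m$sse, 1)
  expect_equal(m$rmse, sqrt(1 / 3))
  expect_equal(m$r2, 0.5)

  m2 <- fit_metrics(1:5, 1:5)
  expect_equal(c(m2$sse, m2$rmse, m2$r2), c(0, 0, 1))

  m3 <- fit_metrics(rep(2, 4), c(2, 2, 2, 3))
  expect_false(m3$r2_defined)
  expect_true(is.na(m3$r2))
})

test_that("harmonic distortion matches closed-form references", {
  K <- 10000
  P <- 2 * pi
  t <- (0:(K - 1)) * P / K
  expect_lt(thd(sin(t), t[2], 1), 1e-10)

  # symmetric triangle wave: V_k ~ 1/k^2 over odd k, THD = sqrt(pi^4/96 - 1)
  tri <- 2 / pi * asin(sin(t))
  expect_equal(thd(tri, t[2], 1), sqrt(pi^4 / 96 - 1), tolerance = 1e-4)

  expect_error(thd(sin(t[1:9000]), t[2], 1), "integer")
})

test_that("coefficient lookup tables round-trip through files", {
  fx <- fhn_fixture()
  path <- withr::local_tempfile(fileext = ".csv")
  write_pwl_lut(fx$fit, path)
  back <- read_pwl_lut(path)
  x <- seq(0, max(back$breaks), length.out = 500)
  expect_lt(max(abs(predict(back, x) - predict(fx$fit$pwl, x))), 1e-8)
  tab <- utils::read.csv(path)
  expect_identical(names(tab), c("segment", "T_start", "T_end", "A", "B"))
})

test_that("model methods expose the fit consistently", {
  x <- seq(0, 10, length.out = 101)
  y <- ifelse(x <= 4, 2 * x, 8 - (x - 4))
  fit <- suppressWarnings(pwl_fit(x, y, 2))
  expect_s3_class(fit, "pwl_fit")
  expect_equal(fitted(fit), predict(fit))
  expect_equal(residuals(fit), y - fitted(fit))
  co <- coef(fit)
  expect_equal(nrow(co), 2)
  # continuity recurrence: B_2 = A_1 T_1 + B_1
  expect_equal(co$B[2], (co$A[1] - co$A[2]) * co$T_end[1] + co$B[1],
               tolerance = 1e-8)
  expect_output(print(fit), "Piecewise-linear")
  expect_output(summary(fit), "Segment table")
})
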
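test_that("normalization is the forced affine map and inverts exactly", {
  tr <- ap_trace(seq(0, 10, by = 0.1), seq(-85, 35, length.out = 101))
  nm <- normalize_trace(tr)
  expect_equal(nm$C, 60)
  expect_equal(nm$offset, -25)
  expect_true(all(abs(nm$y) <= 1 + 1e-12))

  # already-normalized input is a fixed point
  tr2 <- ap_trace(seq(0, 10, by = 0.1), sin(seq(0, 2 * pi, length.out = 101)))
  nm2 <- normalize_trace(tr2)
  expect_equal(nm2$C, 1, tolerance = 1e-12)
  expect_equal(nm2$offset, 0, tolerance = 1e-12)

  # random trace denormalizes exactly
  tr3 <- random_smooth_trace(4)
  nm3 <- normalize_trace(tr3)
  expect_lt(max(abs(nm3$C * nm3$y + nm3$offset - tr3$v)), 1e-9)

  expect_error(normalize_trace(ap_trace(c(0, 1, 2), c(5, 5, 5))),
               "degenerate")
})

test_that("phase extraction satisfies the carrier identities", {
  t_ms <- seq(0, 2000, by = 0.5)
  t_s <- ms_to_s(t_ms)
  omega <- 2 * pi
  phi <- 0.3
  nm <- normalize_trace(ap_trace(t_ms, sin(omega * t_s + phi)))
  ph <- extract_phase(nm, omega = omega, phi0 = phi)
  # the varying phase vanishes up to arcsine conditioning at the crests
  expect_lt(sqrt(mean(ph$phi_t^2)), 1e-3)
  expect_lt(max(abs(ph$phi_t)), 0.01)

  # doubled carrier frequency: phi_t(t) = omega * t
  nm2 <- normalize_trace(ap_trace(t_ms, sin(2 * omega * t_s + phi)))
  ph2 <- extract_phase(nm2, omega = omega, phi0 = phi)
  expect_lt(sqrt(mean((ph2$phi_t - omega * t_s)^2)), 1e-3)
  expect_lt(max(abs(ph2$phi_t - omega * t_s)), 0.01)

  # out-of-range normalized values are a domain error
  nm$y[5] <- 1.01
  expect_error(extract_phase(nm, omega = omega), "broken normalization")
})

test_that("the modulation identity holds sample-wise", {
  fx <- fhn_fixture()
  prof <- fx$prof
  t_s <- ms_to_s(prof$t)
  nm <- normalize_trace(fx$trace)
  ph <- extract_phase(nm)
  lhs <- sin((ph$omega + prof$delta_w) * t_s + prof$phi0)
  rhs <- sin(ph$omega * t_s + prof$phi0 + ph$phi_t)
  expect_lt(max(abs(lhs - rhs)), 1e-12)
})

test_that("phase-to-modulation handles the origin and constants", {
  t_ms <- seq(0, 100, by = 0.5)
  ph <- structure(list(phi_t = rep(0, length(t_ms)), phi0 = 0, omega = 10,
                       t = t_ms), class = "fm_phase")
  expect_true(all(phase_to_deltaw(ph)$delta_w == 0))

  ph$phi_t <- 10 * ms_to_s(t_ms)
  dw <- phase_to_deltaw(ph)$delta_w
  expect_lt(max(abs(dw - 10)), 1e-9)
})

test_that("extract -> reconstruct is exact for arbitrary finite traces", {
  for (seed in c(1, 2, 3)) {
    tr <- random_smooth_trace(seed)
    rec <- fm_reconstruct(fm_extract(tr))
    expect_lt(fit_metrics(tr$v, rec$v)$rmse, 1e-8)
  }
  fx <- fhn_fixture()
  rec <- fm_reconstruct(fx$prof)
  expect_lt(fit_metrics(fx$trace$v, rec$v)$rmse, 1e-8)
})

test_that("a zero modulation profile reconstructs the bare carrier", {
  t_ms <- seq(0, 1000, by = 1)
  prof <- structure(list(delta_w = rep(0, length(t_ms)), omega = 2 * pi,
                         C = 3, offset = -1, phi0 = 0.2, t = t_ms),
                    class = "fm_profile")
  rec <- fm_reconstruct(prof)
  expect_equal(rec$v, 3 * sin(2 * pi * ms_to_s(t_ms) + 0.2) - 1,
               tolerance = 1e-12)
})

test_that("modulation profiles serialize and load", {
  fx <- fhn_fixture()
  path <- withr::local_tempfile(fileext = ".csv")
  write_fm_profile(fx$prof, path)
  back <- read_fm_profile(path)
  expect_equal(back$omega, fx$prof$omega)
  expect_equal(back$C, fx$prof$C)
  expect_equal(back$delta_w, fx$prof$delta_w)
  rec <- fm_reconstruct(back)
  expect_lt(fit_metrics(fx$trace$v, rec$v)$rmse, 1e-8)
})
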
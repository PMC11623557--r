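# shared SAN-like fixture family for the parameterization tests
san_family <- local({
  env <- new.env()
  function() {
    if (is.null(env$fam))
      env$fam <- make_synthetic_ap_family(
        n_levels = 11, apd_law = function(b) 280 - 60 * b,
        diastolic_depol = 12, upstroke_width = 2, repol_width = 14,
        noise_sigma = 0)
    env$fam
  }
})

test_that("identical traces give constant coefficient trajectories", {
  fam <- make_synthetic_ap_family(n_levels = 4, noise_sigma = 0,
                                  apd_law = function(b) 250,
                                  diastolic_depol = 12)
  ff <- suppressWarnings(fit_family(fam, n_segments = 10, restarts = 2))
  expect_lt(max(apply(ff$A_matrix, 1, function(r) diff(range(r)))),
            1e-6 * max(abs(ff$A_matrix)))
})

test_that("blockade family input is validated", {
  fam <- make_synthetic_ap_family(n_levels = 4, noise_sigma = 0)
  expect_error(fit_family(fam[1:2], 5), "at least 3")
  bad <- fam
  bad[[2]]$ifb <- bad[[1]]$ifb
  expect_error(fit_family(bad, 5), "distinct")
})

test_that("known coefficient laws are recovered from a noisy family", {
  cf <- make_coefficient_family()
  ft <- fit_fittype(cf$family, "PL3")
  # per-piece true slopes: A0_i * s_i * g'_j
  true_p1 <- outer(cf$truth$A0 * cf$truth$s[-1], cf$truth$slopes)
  rec_p1 <- t(vapply(seq_len(cf$family$n_segments),
                     function(i) ft$targets[[i]]$p1,
                     numeric(length(cf$truth$slopes))))
  informative <- abs(true_p1) > 0.05 * max(abs(true_p1))
  rel <- abs(rec_p1 - true_p1) / abs(true_p1)
  expect_lt(max(rel[informative]), 0.10)
})

test_that("exactly piecewise-linear laws give exact knots", {
  cf <- make_coefficient_family(noise_sigma = 0)
  ft <- fit_fittype(cf$family, "PL3")
  strong <- which(abs(cf$truth$s[-1]) > 0.1)
  kn <- vapply(strong, function(i) ft$targets[[i]]$knots, numeric(2))
  expect_lt(max(abs(kn[1, ] - 0.3)), 0.02 + 1e-9)
  expect_lt(max(abs(kn[2, ] - 0.7)), 0.02 + 1e-9)
})

test_that("constant targets fit exactly with zero slopes", {
  b <- seq(0, 1, length.out = 11)
  tgt <- fmcell:::fit_pl_target(b, rep(3.5, 11), 3L)
  expect_equal(tgt$p1, rep(0, 3))
  expect_equal(tgt$p0, rep(3.5, 3))
  expect_lt(tgt$sse, 1e-20)
})

test_that("richer fit types never fit worse", {
  cf <- make_coefficient_family(noise_sigma = 2)
  sse3 <- deviance(fit_fittype(cf$family, "PL3"))
  sse4 <- deviance(fit_fittype(cf$family, "PL4"))
  sse5 <- deviance(fit_fittype(cf$family, "PL5"))
  expect_lte(sse4, sse3 + 1e-9)
  expect_lte(sse5, sse4 + 1e-9)
})

test_that("reconstruction at training levels matches the direct fit", {
  fam <- san_family()
  ff <- suppressWarnings(fit_family(fam, n_segments = 20, restarts = 4))
  ft <- fit_fittype(ff, "PL5")
  for (lev in c(1L, 6L, 11L)) {
    pr <- predict_ap(ft, fam[[lev]]$ifb)
    m <- fit_metrics(fam[[lev]]$trace$v, pr$trace$v)
    expect_gt(m$r2, 0.99)
  }
  expect_error(predict_ap(ft, 1.2), "in \\[0, 1\\]")
  expect_error(predict_ap(ft, -0.1), "in \\[0, 1\\]")
})

test_that("interpolated blockade levels are bracketed by their neighbors", {
  fam <- san_family()
  ff <- suppressWarnings(fit_family(fam, n_segments = 20, restarts = 4))
  ft <- fit_fittype(ff, "PL5")
  # APD90 of predictions at intermediate blockade sits between neighbors
  for (mid in c(0.25, 0.55, 0.75)) {
    lo <- max(which(vapply(fam, `[[`, numeric(1), "ifb") <= mid - 0.05))
    hi <- min(which(vapply(fam, `[[`, numeric(1), "ifb") >= mid + 0.05))
    a_mid <- apd90(predict_ap(ft, mid)$trace)
    a_lo <- apd90(fam[[lo]]$trace)
    a_hi <- apd90(fam[[hi]]$trace)
    expect_lt(a_mid, a_lo + 2)   # APD decreasing in blockade
    expect_gt(a_mid, a_hi - 2)
  }
})
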
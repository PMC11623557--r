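test_that("uncoupled tissue fires only the stimulated cells", {
  cell <- fhn_fixture()$cell
  cfg <- tissue_config(c(1, 9), D = 0, dt = 0.1, cell = cell,
                       stim_cells = 5L, stim_time = 0)
  sim <- simulate_tissue(cfg, 100)
  peaks <- apply(sim$field, 2, max)
  expect_gt(peaks[5], cell$v_rest)
  expect_true(all(peaks[-5] == cell$v_rest))
})

test_that("a mid-chain stimulus propagates symmetrically outward", {
  cell <- fhn_fixture()$cell
  cfg <- tissue_config(c(1, 15), D = 1.02 * fhn_dmin(), dt = 0.1,
                       cell = cell, stim_cells = 8L, stim_time = 0)
  sim <- simulate_tissue(cfg, 150)
  Tp <- wavefront_metrics(sim)$Tp
  expect_true(all(is.finite(Tp)))
  expect_equal(Tp[1:7], Tp[15:9])            # mirror symmetry about cell 8
  expect_true(all(diff(Tp[8:15]) > 0))       # strictly outward
})

test_that("opposite-corner stimulations are exact mirror images", {
  cell <- fhn_fixture()$cell
  D <- 1.02 * fhn_dmin()
  s1 <- simulate_tissue(tissue_config(c(9, 9), D = D, dt = 0.1, cell = cell,
                                      stim_cells = 1L), 150)
  s2 <- simulate_tissue(tissue_config(c(9, 9), D = D, dt = 0.1, cell = cell,
                                      stim_cells = 81L), 150)
  expect_identical(s1$field, s2$field[, 81:1])
})

test_that("mid-cell stimulation yields four-fold symmetric timing", {
  cell <- fhn_fixture()$cell
  cfg <- tissue_config(c(9, 9), D = 1.02 * fhn_dmin(), dt = 0.1, cell = cell,
                       stim_cells = 41L)
  m <- wavefront_metrics(simulate_tissue(cfg, 150))
  expect_equal(m$Tp1, m$TpNN)
  expect_equal(m$T_mc1, m$T_mNN)
  expect_false(is.na(m$T_adj))
})

test_that("single-cell tissue collapses all probes onto one cell", {
  cell <- fhn_fixture()$cell
  cfg <- tissue_config(c(1, 1), D = 0.1, dt = 0.1, cell = cell,
                       stim_cells = 1L)
  m <- wavefront_metrics(simulate_tissue(cfg, 80))
  expect_equal(m$Tp1, m$Tpmid)
  expect_equal(m$Tpmid, m$TpNN)
  expect_equal(m$T_mc1, 0)
  expect_equal(m$T_mNN, 0)
})

test_that("non-propagating probes are reported as absent", {
  cell <- fhn_fixture()$cell
  cfg <- tissue_config(c(1, 5), D = 0, dt = 0.1, cell = cell,
                       stim_cells = 1L)
  m <- wavefront_metrics(simulate_tissue(cfg, 80))
  expect_true(is.na(m$TpNN))
  expect_true(is.na(m$T_mNN))
})

test_that("the minimum coupling search brackets the switch point", {
  cell <- fhn_fixture()$cell
  dmin <- fhn_dmin()
  two_cell <- function(D) {
    cfg <- tissue_config(c(1, 2), D = D, dt = 0.1, cell = cell,
                         stim_cells = 1L)
    sim <- simulate_tissue(cfg, 2 * cell$k * 0.1)
    max(sim$field[, 2]) > cell$v_rest + 1e-9
  }
  expect_true(two_cell(dmin))
  expect_false(two_cell(dmin * (1 - 10 * 1e-6 / dmin)))
  # dense sweep oracle around the reported value
  sweep <- seq(dmin - 5e-4, dmin + 5e-4, length.out = 21)
  fires <- vapply(sweep, two_cell, logical(1))
  expect_true(all(diff(fires) >= 0))                   # monotone predicate
  switch_at <- sweep[which(fires)[1]]
  expect_lt(abs(switch_at - dmin), 5e-4 + 1e-6)
  expect_error(find_dmin(cell, 0.1, c(0.5, 1)), "bracket invalid")
})

test_that("unstable coupling is reported with the failing step", {
  cell <- fhn_fixture()$cell
  cfg <- tissue_config(c(1, 4), D = 1e308, dt = 0.1, cell = cell,
                       stim_cells = 1L)
  expect_error(simulate_tissue(cfg, 10), "non-finite input at step")
})

test_that("dysfunction masking is validated and total masks silence the grid", {
  cell <- fhn_fixture()$cell
  cfg <- tissue_config(c(5, 5), D = 0.2, dt = 0.1, cell = cell,
                       stim_cells = 13L)
  expect_error(apply_dysfunction(cfg, 13L), "stimulated cell")
  expect_error(apply_dysfunction(cfg, 26L), "outside")

  all_but_stim <- setdiff(1:25, 13L)
  cfg2 <- apply_dysfunction(cfg, all_but_stim)
  sim <- simulate_tissue(cfg2, 80)
  peaks <- apply(sim$field, 2, max)
  expect_true(all(peaks[all_but_stim] == cfg2$clamp))
})

test_that("lesions reroute the wavefront without touching local timing", {
  cell <- fhn_fixture()$cell
  N <- 17L; mid <- (N^2 + 1L) %/% 2L
  # comfortably above threshold: cells on the lesion border lose voltage to
  # the clamped sink, and near-minimal coupling would leave them subthreshold
  D <- 1.5 * fhn_dmin()
  base <- tissue_config(c(N, N), D = D, dt = 0.1, cell = cell,
                        stim_cells = mid)
  m0 <- wavefront_metrics(simulate_tissue(base, 250))

  one <- apply_dysfunction(base, block_cells(c(N, N), rows = 12L, cols = 4:14))
  m1 <- wavefront_metrics(simulate_tissue(one, 250))
  expect_gt(m1$TpNN, m0$TpNN)                 # distal delay below the lesion
  expect_equal(m1$Tpmid, m0$Tpmid)            # local timing untouched
  expect_equal(m1$T_adj, m0$T_adj)
  expect_equal(m1$Tp1, m0$Tp1)                # path above is unaffected

  two <- apply_dysfunction(one, block_cells(c(N, N), rows = 6L, cols = 4:14))
  m2 <- wavefront_metrics(simulate_tissue(two, 250))
  expect_gt(m2$Tp1, m1$Tp1)
  expect_gte(m2$TpNN, m1$TpNN)
  expect_equal(m2$Tpmid, m0$Tpmid)
  expect_equal(m2$T_adj, m0$T_adj)

  # lesions never decrease any peak time
  Tp0 <- wavefront_metrics(simulate_tissue(base, 250))$Tp
  Tp2 <- m2$Tp
  live <- !two$mask
  expect_true(all(Tp2[live] >= Tp0[live] - 1e-9))
})

test_that("configuration errors are caught early", {
  cell <- fhn_fixture()$cell
  expect_error(tissue_config(c(2, 3), 0.1, 0.1, cell = cell), "N x N")
  expect_error(tissue_config(c(3, 3), -1, 0.1, cell = cell), "D")
  expect_error(tissue_config(c(3, 3), 0.1, 0.1, cell = cell,
                             stim_cells = 10L), "outside")
  expect_error(tissue_config(c(3, 3), 0.1, 0.1, cell = cell,
                             v_sti = cell$v_th - 1), "threshold")
  expect_error(tissue_config(c(3, 3), 0.1, 0.1, cell = cell,
                             clamp = cell$v_rest + 1), "below the resting")
})
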
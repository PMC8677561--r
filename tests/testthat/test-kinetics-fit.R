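test_that("basis fit recovers noiseless parameters with theta on the grid", {
  grid <- default_theta_grid()
  theta_true <- grid[35]
  k3 <- 0.3 * theta_true
  k2 <- theta_true - k3
  p <- fdg_params(0.091, k2, k3)
  tac <- simulate_tac_irreversible(p, fix_aif, fix_sched)
  fit <- fit_voxel_basis(tac, fix_aif, fix_sched)
  expect_equal(fit$theta, theta_true)
  expect_lt(abs(fit$params$K1 - p$K1) / p$K1, 0.02)
  expect_lt(abs(fit$params$k3 - p$k3) / p$k3, 0.02)
  expect_false(fit$degenerate)
})

test_that("an all-zero curve yields zero parameters flagged degenerate", {
  fit <- fit_voxel_basis(rep(0, nrow(fix_sched)), fix_aif, fix_sched)
  expect_true(fit$degenerate)
  expect_equal(unlist(fit$params[1, c("K1", "k2", "k3")]),
               c(K1 = 0, k2 = 0, k3 = 0))
})

test_that("basis-fit bias stays under 10% with 5% proportional noise", {
  p <- fdg_params(0.049, 0.131, 0.039) # penumbra-scale kinetics
  tac <- simulate_tac_irreversible(p, fix_aif, fix_sched)
  basis <- fdg_basis(fix_aif, fix_sched)
  est <- vapply(1:100, function(i) {
    noisy <- add_tac_noise(tac, 0.05, seed = 20000 + i)
    f <- fit_voxel_basis(noisy, basis = basis)
    c(f$params$K1, f$params$k3, influx_constant(f$params))
  }, numeric(3))
  truth <- c(p$K1, p$k3, influx_constant(p))
  bias <- abs(apply(est, 1, median) - truth) / truth
  expect_lt(max(bias), 0.10)
})

test_that("weights and theta tie-breaking behave as documented", {
  p <- fdg_params(0.09, 0.12, 0.05)
  tac <- simulate_tac_irreversible(p, fix_aif, fix_sched)
  fit_u <- fit_voxel_basis(tac, fix_aif, fix_sched)
  fit_d <- fit_voxel_basis(tac, fix_aif, fix_sched, weights = "duration")
  expect_lt(abs(fit_d$params$K1 - fit_u$params$K1) / fit_u$params$K1, 0.05)
  expect_error(fit_voxel_basis(tac, fix_aif, fix_sched, weights = 1:3),
               "match")
  # which.min picks the first (smallest) theta among tied minima
  expect_equal(which.min(c(1, 1, 2)), 1L)
  expect_error(fit_voxel_basis(tac$value, fix_aif, fix_sched,
                               theta_grid = c(0.5, 0.1)), "sorted")
})

test_that("the full regional fit recovers k4-inclusive parameters", {
  truth <- fdg_params(0.091, 0.128, 0.057, k4 = 0.006, Vb = 0.04)
  tac <- simulate_tac_reversible(truth, fix_aif, fix_sched)
  fit <- fit_region_full(tac, fix_aif, fix_sched)
  rel <- abs(unlist(fit$params[1, ]) - unlist(truth[1, ])) /
    pmax(unlist(truth[1, ]), 1e-9)
  expect_lt(max(rel), 0.05)
  expect_true(fit$converged)
})

test_that("k4 pins to its lower bound on irreversible data, preserving Ki", {
  truth <- fdg_params(0.091, 0.128, 0.057, Vb = 0.04)
  tac <- simulate_tac_irreversible(truth, fix_aif, fix_sched)
  fit <- fit_region_full(tac, fix_aif, fix_sched)
  expect_lt(fit$params$k4, 1e-6)
  ki_full <- influx_constant(fit$params)
  ki_basis <- influx_constant(fit_voxel_basis(tac, fix_aif, fix_sched)$params)
  expect_lt(abs(ki_full - ki_basis) / ki_basis, 0.03)
})

test_that("the one-tissue water fit recovers flow and distribution volume", {
  # f = 0.43 ml/ml/min, Vd = 0.9: simulate via the one-tissue limit
  truth <- fdg_params(K1 = 0.43, k2 = 0.43 / 0.9, k3 = 0)
  tac <- simulate_tac_irreversible(truth, fix_aif, fix_sched)
  h <- fit_h2o_flow(tac, fix_aif, fix_sched)
  expect_lt(abs(h$f - 0.43) / 0.43, 0.02)
  expect_lt(abs(h$Vd - 0.9) / 0.9, 0.02)
  expect_equal(h$CBF, 100 * h$f)

  z <- fit_h2o_flow(rep(0, nrow(fix_sched)), fix_aif, fix_sched)
  expect_true(z$degenerate)
  expect_equal(z$f, 0)

  est <- vapply(1:50, function(i) {
    fit_h2o_flow(add_tac_noise(tac, 0.05, seed = 31000 + i),
                 fix_aif, fix_sched)$f
  }, numeric(1))
  expect_lt(abs(median(est) - 0.43) / 0.43, 0.10)
})
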
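test_that("the influx constant follows K1 k3/(k2 + k3)", {
  expect_equal(influx_constant(fdg_params(0.1, 0.15, 0.05)), 0.025)
  expect_equal(influx_constant(fdg_params(0.1, 0.15, 0)), 0)
  expect_equal(influx_constant(fdg_params(0.091, 0.128, 0.057)), 0.02804,
               tolerance = 1e-4)
  expect_equal(influx_constant(fdg_params(0.1, 0, 0)), 0) # degenerate denominator
})

test_that("Ki never exceeds K1 and increases with k3", {
  set.seed(42)
  for (i in 1:50) {
    p <- fdg_params(runif(1, 0, 0.2), runif(1, 0, 0.3), runif(1, 0, 0.1))
    expect_lte(influx_constant(p), p$K1 + 1e-15)
  }
  k3s <- seq(0.01, 0.1, by = 0.01)
  kis <- vapply(k3s, function(k3) influx_constant(fdg_params(0.1, 0.15, k3)),
                numeric(1))
  expect_true(all(diff(kis) > 0))
})

test_that("the lumped constant reproduces published regional values", {
  conv <- lc_conversion(tau = 1.10, phi = 0.32)
  # healthy-volunteer medians
  expect_equal(lumped_constant(fdg_params(0.091, 0.128, 0.057), conv), 0.560,
               tolerance = 1e-3)
  # patient normal-appearing medians (printed median 0.41; ratio-of-medians
  # differs from median-of-ratios)
  expect_equal(lumped_constant(fdg_params(0.091, 0.173, 0.029), conv), 0.432,
               tolerance = 5e-4)
  # algebraic k3 -> 0 limit is phi
  expect_equal(lumped_constant(fdg_params(0.1, 0.15, 1e-12), conv), 0.32,
               tolerance = 1e-9)
  expect_warning(out <- lumped_constant(fdg_params(0.1, 0, 0), conv), "undefined")
  expect_true(is.na(out))
})

test_that("LC is bracketed by phi and tau and increases with k3 when tau > phi", {
  conv <- lc_conversion()
  set.seed(7)
  for (i in 1:50) {
    p <- fdg_params(0.1, runif(1, 0.01, 0.3), runif(1, 0.01, 0.1))
    lc <- lumped_constant(p, conv)
    expect_gte(lc, conv$phi)
    expect_lte(lc, conv$tau)
  }
  lcs <- vapply(seq(0.01, 0.1, 0.01), function(k3) {
    lumped_constant(fdg_params(0.1, 0.15, k3), conv)
  }, numeric(1))
  expect_true(all(diff(lcs) > 0))
})

test_that("CMRG follows 100 G_p Ki / LC", {
  expect_equal(cmrg_from_ki(0.030, 5.0, 0.50), 30.0)
  expect_equal(cmrg_from_ki(0, 5.0, 0.50), 0)
  expect_equal(cmrg_from_ki(0.034, 4.6, 0.56), 27.9, tolerance = 5e-3)
  expect_error(cmrg_from_ki(0.03, 5.0, 0), "positive")
})

test_that("brain tissue glucose follows the converted steady-state balance", {
  conv <- lc_conversion(tau = 1.10, phi = 0.32)
  g <- brain_glucose(fdg_params(0.091, 0.128, 0.057), 4.6, conv)
  expect_equal(g, 1.29, tolerance = 5e-3)
  expect_equal(brain_glucose(fdg_params(0, 0.1, 0.05), 4.6, conv), 0)
  # raising k3 at fixed K1, k2 strictly lowers tissue glucose
  gs <- vapply(seq(0.01, 0.1, 0.01), function(k3) {
    brain_glucose(fdg_params(0.091, 0.128, k3), 4.6, conv)
  }, numeric(1))
  expect_true(all(diff(gs) < 0))
})

test_that("the phosphorylation fraction spans its limits correctly", {
  conv <- lc_conversion(tau = 1.10, phi = 0.32)
  expect_equal(phosphorylation_fraction(fdg_params(0.1, 0.1, 0), conv), 0)
  expect_equal(phosphorylation_fraction(fdg_params(0.1, 0, 0.05), conv), 1)
  expect_equal(phosphorylation_fraction(fdg_params(0.091, 0.128, 0.057), conv),
               0.605, tolerance = 1e-3)
})
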
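test_that("Spearman association handles monotone, tied and constant inputs", {
  df <- data.frame(x = 1:8, y = exp(1:8))
  out <- spearman_assoc(df, x, y)
  expect_equal(out$rho, 1)
  expect_false(out$degenerate)
  cst <- spearman_assoc(data.frame(x = rep(1, 6), y = rnorm(6)), x, y)
  expect_true(cst$degenerate)
  expect_true(is.na(cst$rho))
  expect_error(spearman_assoc(data.frame(x = 1:3, y = 1:3), x, y), "at least 4")
  # average-rank tie handling matches cor on ranks
  set.seed(9)
  x <- sample(1:5, 20, replace = TRUE)
  y <- sample(1:5, 20, replace = TRUE)
  out2 <- spearman_assoc(data.frame(x, y), x, y)
  expect_equal(out2$rho, cor(rank(x), rank(y)))
})

test_that("small-sample Spearman p-values equal brute-force permutation", {
  set.seed(21)
  for (i in 1:5) {
    x <- rnorm(7); y <- rnorm(7)
    out <- spearman_assoc(data.frame(x, y), x, y)
    expect_equal(out$p_value, spearman_perm_p(x, y), tolerance = 1e-10)
    expect_equal(out$method, "spearman-exact")
  }
})

test_that("group comparisons pick the right test and flag significance", {
  set.seed(30)
  same <- data.frame(v = rep(rnorm(20), 2), g = rep(c("a", "b"), each = 20))
  gc0 <- group_compare(same, v, g)
  expect_equal(gc0$test$test, "mann-whitney")
  expect_gt(gc0$test$p_value, 0.9)
  expect_false(gc0$test$significant)

  shift <- data.frame(v = c(rnorm(20), rnorm(20) + 5),
                      g = rep(c("a", "b"), each = 20))
  gcs <- group_compare(shift, v, g)
  expect_lt(gcs$test$p_value, 0.005)
  expect_true(gcs$test$significant_strict)
  expect_error(group_compare(data.frame(v = 1:3, g = c("a", "a", "b")), v, g),
               "at least 2")
})

test_that("Kruskal-Wallis plus Dunn flags core against normal-appearing tissue", {
  set.seed(31)
  n <- 20
  df <- data.frame(
    v = c(rnorm(n, 12.2, 3), rnorm(n, 18.1, 3), rnorm(n, 27.4, 3),
          rnorm(n, 28.6, 3)),
    g = rep(c("core", "penumbra", "peri", "normal"), each = n)
  )
  gc <- group_compare(df, v, g)
  expect_equal(gc$test$test, "kruskal-wallis")
  expect_lt(gc$test$p_value, 0.005)
  ph <- tidy(gc, "posthoc")
  row <- ph[(ph$group_1 == "core" & ph$group_2 == "normal") |
              (ph$group_1 == "normal" & ph$group_2 == "core"), ]
  expect_true(row$significant_strict)
})

test_that("LOWESS reproduces a line exactly and is order-invariant", {
  set.seed(40)
  n <- 20000
  df <- data.frame(x = runif(n, 0, 10))
  df$y <- 2 * df$x
  lw <- lowess_relationship(df, x, y, n_boot = 0, seed = 1)
  expect_lt(max(abs(lw$curve$fit - 2 * lw$curve$x)), 1e-6)
  # permuting rows changes nothing; same seed reproduces the curve
  df2 <- df[sample(n), ]
  lw2 <- lowess_relationship(df2, x, y, n_boot = 0, seed = 1)
  expect_equal(lw$curve$fit, lw2$curve$fit)
  expect_error(lowess_relationship(df[1:500, ], x, y), "1000")
  expect_error(lowess_relationship(df, x, y, sample_frac = 0.001,
                                   smoothing_frac = 0.05), "window")
})

test_that("bootstrap bands cover the fit and respect the seed", {
  set.seed(41)
  n <- 4000
  df <- data.frame(x = runif(n, 0, 10))
  df$y <- sin(df$x) + rnorm(n, 0, 0.2)
  lw <- lowess_relationship(df, x, y, sample_frac = 0.25, n_boot = 50, seed = 5)
  expect_true(all(lw$curve$lwr <= lw$curve$fit + 1e-9))
  expect_true(all(lw$curve$upr >= lw$curve$fit - 1e-9))
  lwb <- lowess_relationship(df, x, y, sample_frac = 0.25, n_boot = 50, seed = 5)
  expect_equal(lw$curve, lwb$curve)
})

test_that("imaging epochs split at 24 hours, 5 days and 12 days", {
  expect_equal(as.character(epoch_assign(c(23.9, 24, 72, 120.1, 288, 13 * 24))),
               c("early", "early", "intermediate", "late", "late",
                 "out_of_window"))
  expect_error(epoch_assign(-1), "non-negative")
})
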
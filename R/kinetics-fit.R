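#' Default basis-function rate grid
#'
#' Sixty logarithmically spaced values of theta = k2 + k3 in \[0.01, 2.0\]
#' per minute, spanning the plausible range of tissue rate-constant sums with
#' headroom on both sides.
#'
#' @return Sorted numeric vector.
#' @export
default_theta_grid <- function() {
  exp(seq(log(0.01), log(2.0), length.out = 60))
}

#' Precompute basis functions for voxel-wise FDG fitting
#'
#' For each theta in the grid, the basis pair is B0(t) = integral of C_p and
#' B1(t) = exp(-theta t) convolved with C_p, evaluated at frame mid-times;
#' a whole-blood column is added when the blood volume fraction is fitted.
#' Precomputing the basis once lets many time-activity curves sharing one
#' input function be fitted cheaply.
#'
#' @inheritParams simulate_tac_irreversible
#' @param theta_grid Positive, sorted grid of theta values.
#' @return An object of class `fdg_basis`.
#' @export
fdg_basis <- function(aif, schedule, theta_grid = default_theta_grid(),
                      blood = NULL) {
  aif <- as_input_function(aif)
  schedule <- as_frame_schedule(schedule)
  if (any(theta_grid <= 0)) abort("`theta_grid` must be positive.")
  if (is.unsorted(theta_grid, strictly = TRUE)) abort("`theta_grid` must be sorted increasing.")
  mid <- schedule$mid_min
  B0 <- cumint_pl(aif$time_min, aif$value, mid)
  B1 <- vapply(theta_grid, function(th) {
    conv_exp_pl(aif$time_min, aif$value, th, mid)
  }, numeric(length(mid)))
  bl <- if (is.null(blood)) aif else as_input_function(blood)
  Cb <- interp_pl(bl$time_min, bl$value, mid)
  structure(
    list(theta_grid = theta_grid, mid = mid, B0 = B0, B1 = B1, Cb = Cb,
         schedule = schedule, aif = aif),
    class = "fdg_basis"
  )
}

# Non-negative weighted least squares for a small (p <= 3) design by active-set
# enumeration: solve ordinary WLS on every support, keep the feasible support
# with minimal weighted RSS. Exact for the NNLS optimum at this size.
nnls_small <- function(X, y, w) {
  p <- ncol(X)
  sw <- sqrt(w)
  Xw <- X * sw
  yw <- y * sw
  best_rss <- sum(yw^2)
  best_coef <- numeric(p)
  singular <- FALSE
  supports <- unlist(lapply(seq_len(p), function(k) {
    utils::combn(p, k, simplify = FALSE)
  }), recursive = FALSE)
  for (S in supports) {
    XS <- Xw[, S, drop = FALSE]
    fit <- tryCatch(qr(XS), error = function(e) NULL)
    if (is.null(fit) || fit$rank < length(S)) {
      singular <- TRUE
      next
    }
    cf <- qr.coef(fit, yw)
    if (any(!is.finite(cf)) || any(cf < 0)) next
    rss <- sum((yw - XS %*% cf)^2)
    if (rss < best_rss - 1e-12 * max(best_rss, 1)) {
      best_rss <- rss
      best_coef <- numeric(p)
      best_coef[S] <- cf
    }
  }
  list(coef = best_coef, rss = best_rss, singular = singular)
}

new_fdg_fit <- function(params, theta, wrss, degenerate, singular, fitted,
                        schedule, tac, method, extra = list()) {
  structure(
    c(list(params = params, theta = theta, wrss = wrss,
           degenerate = degenerate, singular = singular, fitted = fitted,
           schedule = schedule, tac = tac, method = method), extra),
    class = "fdg_fit"
  )
}

#' @export
print.fdg_fit <- function(x, ...) {
  cat("<fdg_fit> method:", x$method,
      if (x$degenerate) "(degenerate)" else "", "\n")
  print(x$params)
  cat("WRSS:", format(x$wrss, digits = 6), "\n")
  invisible(x)
}

#' Basis-function fit of the irreversible FDG model to one tissue curve
#'
#' For each theta on the grid the model is linear in the coefficients
#' a0 = K1 k3/theta (on the running integral of the input) and
#' a1 = K1 k2/theta (on the theta-exponential convolution), plus optionally
#' the whole-blood curve whose coefficient estimates Vb. Coefficients are
#' constrained non-negative (active-set solve, not post-hoc truncation); the
#' theta minimizing the weighted residual sum of squares wins, ties broken by
#' the smallest theta. Back-transform: K1 = a0 + a1, k2 = a1 theta/K1,
#' k3 = a0 theta/K1. When Vb is fitted the tissue coefficients are rescaled
#' by 1/(1 - Vb).
#'
#' @param tac A TAC tibble (as from [simulate_tac_irreversible()]) or a
#'   numeric vector of frame values matching the schedule.
#' @inheritParams fdg_basis
#' @param weights Per-frame weights; `NULL` for uniform, `"duration"` for
#'   frame-duration weights.
#' @param fit_vb Fit the blood volume fraction as a third non-negative
#'   coefficient (default) or fix it at `vb_fixed`.
#' @param vb_fixed Fixed blood volume fraction used when `fit_vb = FALSE`.
#' @param basis Optional precomputed [fdg_basis()]; when supplied, `aif`,
#'   `schedule`, `theta_grid` and `blood` are taken from it.
#' @param refine After the grid scan, continue with a continuous 1D
#'   optimization of theta between the neighbouring grid points (default
#'   TRUE), removing the grid-discretization bias; the refined theta is kept
#'   only when it strictly improves the weighted residual sum of squares.
#' @return An object of class `fdg_fit`; see [tidy.fdg_fit()] and
#'   [glance.fdg_fit()].
#' @export
#' @examples
#' aif <- feng_aif()
#' sched <- default_fdg_schedule()
#' tac <- simulate_tac_irreversible(fdg_params(0.091, 0.128, 0.057), aif, sched)
#' fit <- fit_voxel_basis(tac, aif, sched)
#' glance(fit)
fit_voxel_basis <- function(tac, aif = NULL, schedule = NULL,
                            theta_grid = default_theta_grid(),
                            weights = NULL, fit_vb = TRUE, vb_fixed = 0.05,
                            blood = NULL, basis = NULL, refine = TRUE) {
  if (is.null(basis)) {
    if (is.null(aif) || is.null(schedule)) {
      abort("Supply either `basis` or both `aif` and `schedule`.")
    }
    basis <- fdg_basis(aif, schedule, theta_grid, blood)
  }
  y <- if (is.data.frame(tac)) tac$value else as.numeric(tac)
  n <- length(basis$mid)
  if (length(y) != n) abort("TAC length must match the frame schedule.")
  w <- resolve_weights(weights, basis$schedule)

  zero_params <- fdg_params(0, 0, 0, 0, 0)
  if (all(y == 0) || !any(is.finite(y))) {
    return(new_fdg_fit(zero_params, NA_real_, 0, TRUE, FALSE,
                       rep(0, n), basis$schedule, y, "basis"))
  }

  ng <- length(basis$theta_grid)
  wrss <- rep(Inf, ng)
  coefs <- matrix(0, ng, if (fit_vb) 3L else 2L)
  any_singular <- FALSE
  for (j in seq_len(ng)) {
    X <- if (fit_vb) cbind(basis$B0, basis$B1[, j], basis$Cb)
         else cbind(basis$B0, basis$B1[, j])
    yj <- if (fit_vb) y else y - vb_fixed * basis$Cb
    sol <- nnls_small(X, yj, w)
    wrss[j] <- sol$rss
    coefs[j, ] <- sol$coef
    any_singular <- any_singular || sol$singular
  }
  j <- which.min(wrss) # first minimum = smallest theta on a tie
  theta <- basis$theta_grid[j]
  best <- list(rss = wrss[j], coef = coefs[j, ],
               B1 = basis$B1[, j])
  if (refine && !is.null(basis$aif)) {
    lo <- basis$theta_grid[max(1L, j - 1L)]
    hi <- basis$theta_grid[min(ng, j + 1L)]
    solve_at <- function(th) {
      B1 <- conv_exp_pl(basis$aif$time_min, basis$aif$value, th, basis$mid)
      X <- if (fit_vb) cbind(basis$B0, B1, basis$Cb) else cbind(basis$B0, B1)
      yj <- if (fit_vb) y else y - vb_fixed * basis$Cb
      c(nnls_small(X, yj, w), list(B1 = B1))
    }
    if (hi > lo) {
      opt <- optimize(function(th) solve_at(th)$rss, c(lo, hi), tol = 1e-7)
      if (opt$objective < best$rss * (1 - 1e-6)) {
        theta <- opt$minimum
        best <- solve_at(theta)
      }
    }
  }
  a0 <- best$coef[1]
  a1 <- best$coef[2]
  vb <- if (fit_vb) min(best$coef[3], 0.2) else vb_fixed
  scale <- if (vb < 1) 1 / (1 - vb) else 1
  K1 <- (a0 + a1) * scale
  if (K1 > 0) {
    k2 <- a1 * scale * theta / K1
    k3 <- a0 * scale * theta / K1
  } else {
    k2 <- 0; k3 <- 0
  }
  params <- fdg_params(K1, k2, k3, 0, vb)
  fitted <- a0 * basis$B0 + a1 * best$B1 +
    (if (fit_vb) best$coef[3] else vb_fixed) * basis$Cb
  new_fdg_fit(params, theta, best$rss, K1 <= 0, any_singular, fitted,
              basis$schedule, y, "basis",
              extra = list(wrss_profile = tibble(theta = basis$theta_grid,
                                                 wrss = wrss)))
}

resolve_weights <- function(weights, schedule) {
  n <- nrow(schedule)
  if (is.null(weights)) return(rep(1, n))
  if (identical(weights, "duration")) {
    d <- schedule$frame_end_min - schedule$frame_start_min
    return(d / mean(d))
  }
  if (length(weights) != n) abort("`weights` must match the number of frames.")
  if (any(weights < 0)) abort("`weights` must be non-negative.")
  as.numeric(weights)
}

#' Full nonlinear regional fit including dephosphorylation
#'
#' Bounded weighted nonlinear least squares over (K1, k2, k3, k4, Vb) for a
#' region-mean curve, using the analytic reversible model as the forward
#' function and multi-start Levenberg-Marquardt. k4 is free, so slow loss
#' from the phosphorylated pool is estimable at region scale where curves
#' are low-noise.
#'
#' @inheritParams fit_voxel_basis
#' @param init Optional [fdg_params()] starting point added to the built-in
#'   coarse multi-start grid.
#' @param upper Upper bounds for (K1, k2, k3, k4, Vb).
#' @return An object of class `fdg_fit` (method `"region"`) whose `params`
#'   include the fitted k4; `converged` reports Levenberg-Marquardt status
#'   of the best start.
#' @export
fit_region_full <- function(tac, aif, schedule, init = NULL, weights = NULL,
                            blood = NULL, upper = c(2, 2, 1, 0.1, 0.2)) {
  aif <- as_input_function(aif)
  schedule <- as_frame_schedule(schedule)
  y <- if (is.data.frame(tac)) tac$value else as.numeric(tac)
  if (length(y) < 6) abort("Regional fits need at least 6 frames.")
  if (length(y) != nrow(schedule)) abort("TAC length must match the frame schedule.")
  w <- resolve_weights(weights, schedule)
  sw <- sqrt(w)

  if (all(y == 0) || !any(is.finite(y))) {
    return(new_fdg_fit(fdg_params(0, 0, 0, 0, 0), NA_real_, 0, TRUE, FALSE,
                       rep(0, length(y)), schedule, y, "region",
                       extra = list(converged = TRUE)))
  }

  model <- function(p) {
    pars <- fdg_params(p[1], p[2], p[3], p[4], p[5])
    simulate_tac_reversible(pars, aif, schedule, blood)$value
  }
  resid_fn <- function(p) sw * (y - model(p))

  starts <- list()
  grid <- expand.grid(K1 = c(0.04, 0.09), k2 = c(0.08, 0.16),
                      k3 = c(0.02, 0.05), k4 = c(0, 0.008), Vb = 0.03)
  for (i in seq_len(nrow(grid))) starts[[i]] <- as.numeric(grid[i, ])
  if (!is.null(init)) {
    ip <- as_fdg_params_list(init)
    starts <- c(list(as.numeric(unlist(ip))), starts)
  }

  lower <- rep(0, 5)
  best <- NULL
  converged <- FALSE
  for (st in starts) {
    st <- pmin(pmax(st, lower), upper)
    fit <- tryCatch(
      minpack.lm::nls.lm(par = st, lower = lower, upper = upper, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss) {
      best <- list(par = fit$par, rss = rss, info = fit$info)
    }
  }
  if (is.null(best)) {
    return(new_fdg_fit(fdg_params(0, 0, 0, 0, 0), NA_real_, Inf, TRUE, TRUE,
                       rep(NA_real_, length(y)), schedule, y, "region",
                       extra = list(converged = FALSE)))
  }
  converged <- best$info %in% 1:3
  p <- best$par
  params <- fdg_params(p[1], p[2], p[3], p[4], p[5])
  new_fdg_fit(params, p[2] + p[3], best$rss, FALSE, FALSE, model(p),
              schedule, y, "region", extra = list(converged = converged))
}

#' One-tissue flow fit for a water tracer curve
#'
#' Fits the single-compartment model C_T(t) = f \[exp(-(f/Vd) t) * C_p\](t)
#' by a basis scan over the apparent clearance k = f/Vd with a golden-section
#' refinement between grid neighbours; the flow f is the (non-negative)
#' linear coefficient at the selected k and Vd = f/k. This is a simplified
#' flow estimator for phantom water curves, not a full multi-tracer
#' steady-state quantification.
#'
#' @inheritParams fit_voxel_basis
#' @param k_grid Grid of apparent clearance values (per min).
#' @param refine Continue with a 1D continuous optimization of k around the
#'   best grid point (default TRUE).
#' @return A list of class `h2o_fit` with elements `f` (ml/ml/min), `CBF`
#'   (ml/100 ml/min), `Vd`, `k`, `wrss`, `degenerate`, `fitted`.
#' @export
fit_h2o_flow <- function(tac, aif, schedule,
                         k_grid = exp(seq(log(0.02), log(3), length.out = 60)),
                         weights = NULL, refine = TRUE) {
  aif <- as_input_function(aif)
  schedule <- as_frame_schedule(schedule)
  y <- if (is.data.frame(tac)) tac$value else as.numeric(tac)
  if (length(y) != nrow(schedule)) abort("TAC length must match the frame schedule.")
  w <- resolve_weights(weights, schedule)
  mid <- schedule$mid_min

  if (all(y == 0) || !any(is.finite(y))) {
    return(structure(list(f = 0, CBF = 0, Vd = NA_real_, k = NA_real_,
                          wrss = 0, degenerate = TRUE,
                          fitted = rep(0, length(y))),
                     class = "h2o_fit"))
  }

  fit_at_k <- function(k) {
    B <- conv_exp_pl(aif$time_min, aif$value, k, mid)
    den <- sum(w * B^2)
    a <- if (den > 0) max(0, sum(w * B * y) / den) else 0
    list(a = a, wrss = sum(w * (y - a * B)^2), B = B)
  }
  wrss <- vapply(k_grid, function(k) fit_at_k(k)$wrss, numeric(1))
  j <- which.min(wrss)
  k_best <- k_grid[j]
  if (refine) {
    lo <- k_grid[max(1, j - 1)]
    hi <- k_grid[min(length(k_grid), j + 1)]
    if (hi > lo) {
      opt <- optimize(function(k) fit_at_k(k)$wrss, c(lo, hi), tol = 1e-8)
      if (opt$objective <= wrss[j]) k_best <- opt$minimum
    }
  }
  sol <- fit_at_k(k_best)
  structure(list(f = sol$a, CBF = 100 * sol$a,
                 Vd = if (k_best > 0) sol$a / k_best else NA_real_,
                 k = k_best, wrss = sol$wrss, degenerate = sol$a <= 0,
                 fitted = sol$a * sol$B),
            class = "h2o_fit")
}

#' @export
print.h2o_fit <- function(x, ...) {
  cat("<h2o_fit> CBF:", format(x$CBF, digits = 4), "ml/100 ml/min, Vd:",
      format(x$Vd, digits = 4), if (x$degenerate) "(degenerate)" else "", "\n")
  invisible(x)
}
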
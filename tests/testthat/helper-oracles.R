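# Shared fixtures and independent oracles used across the suite.

# One arterial input function and frame schedule reused by the kinetic tests.
fix_aif <- feng_aif()
fix_sched <- default_fdg_schedule()

# Independent stiff-ODE oracle for the two-tissue compartment model: the
# coupled system dC1/dt = K1 Cp - (k2 + k3) C1 + k4 C2, dC2/dt = k3 C1 -
# k4 C2 integrated numerically against the same piecewise-linear input.
ode_tac_oracle <- function(params, aif, schedule) {
  p <- as.list(params[1, ])
  cp <- stats::approxfun(aif$time_min, aif$value, yleft = 0, rule = 2)
  rhs <- function(t, y, parms) {
    list(c(p$K1 * cp(t) - (p$k2 + p$k3) * y[1] + p$k4 * y[2],
           p$k3 * y[1] - p$k4 * y[2]))
  }
  times <- c(0, schedule$mid_min)
  sol <- deSolve::ode(y = c(0, 0), times = times, func = rhs, parms = NULL,
                      method = "lsoda", rtol = 1e-10, atol = 1e-12)
  ct <- rowSums(sol[-1, 2:3, drop = FALSE])
  (1 - p$Vb) * ct + p$Vb * cp(schedule$mid_min)
}

# Relative error of a curve against an oracle, normalized by the oracle peak
# (the conventional scale for time-activity curves, whose early frames are
# near zero).
max_rel_err <- function(x, oracle) {
  max(abs(x - oracle)) / max(abs(oracle))
}

# All permutations of 1..n (n small) for brute-force rank statistics.
all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 0L
  for (i in seq_len(n)) {
    rest <- seq_len(n)[-i]
    for (j in seq_len(nrow(sub))) {
      r <- r + 1L
      out[r, ] <- c(i, rest[sub[j, ]])
    }
  }
  out
}

# Exact two-sided permutation p-value for the Spearman rho of untied pairs.
spearman_perm_p <- function(x, y) {
  n <- length(x)
  rx <- rank(x)
  ry <- rank(y)
  obs <- cor(rx, ry)
  perms <- all_perms(n)
  rhos <- apply(perms, 1, function(p) cor(rx, ry[p]))
  mean(abs(rhos) >= abs(obs) - 1e-12)
}

# Small uniform cube phantom helpers for ROI tests.
cube_mask <- function(d) array(TRUE, d)

with_seed_test <- function(seed, code) metabpet:::with_seed(seed, code)

# Self-cleaning temporary directory for I/O tests.
withr_local_tempdir <- function(env = parent.frame()) {
  d <- tempfile("metabpet-test-")
  dir.create(d)
  withr::defer(unlink(d, recursive = TRUE), envir = env)
  d
}
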
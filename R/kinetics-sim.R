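#' FDG micro rate constants
#'
#' Container for the two-tissue-compartment FDG rate constants of one voxel
#' or region: transport into tissue `K1` (ml blood per ml tissue per min),
#' efflux `k2` (/min), hexokinase phosphorylation `k3` (/min),
#' dephosphorylation `k4` (/min, 0 in the irreversible model), and the
#' fractional blood volume `Vb` (unitless, 0-0.2).
#'
#' @param K1,k2,k3,k4 Non-negative rate constants.
#' @param Vb Blood volume fraction in \[0, 0.2\].
#' @return A one-row tibble of class `fdg_params`.
#' @export
#' @examples
#' fdg_params(K1 = 0.091, k2 = 0.128, k3 = 0.057)
fdg_params <- function(K1, k2, k3, k4 = 0, Vb = 0) {
  for (nm in c("K1", "k2", "k3", "k4", "Vb")) {
    stop_if_not_scalar_number(get(nm), nm)
  }
  if (any(c(K1, k2, k3, k4) < 0)) abort("Rate constants must be non-negative.")
  if (Vb < 0 || Vb > 0.2) abort("`Vb` must lie in [0, 0.2].")
  out <- tibble(K1 = K1, k2 = k2, k3 = k3, k4 = k4, Vb = Vb)
  class(out) <- c("fdg_params", class(out))
  out
}

#' FDG-to-glucose conversion constants
#'
#' The lumped-constant decomposition used throughout the package: `tau` is
#' the transport preference of FDG over glucose (applied to K1 and k2), and
#' `phi` the phosphorylation preference (applied to k3), so the glucose rate
#' constants are K1/tau, k2/tau and k3/phi. The defaults reproduce the
#' healthy-volunteer lumped constant of 0.56 from typical volunteer rate
#' constants and give plausible lesion-region values.
#'
#' @param tau Transport preference ratio, > 0. Default 1.10.
#' @param phi Phosphorylation preference ratio, > 0. Default 0.32.
#' @return A list of class `lc_conversion`.
#' @export
lc_conversion <- function(tau = 1.10, phi = 0.32) {
  stop_if_not_scalar_number(tau, "tau")
  stop_if_not_scalar_number(phi, "phi")
  if (tau <= 0 || phi <= 0) abort("`tau` and `phi` must be positive.")
  structure(list(tau = tau, phi = phi), class = "lc_conversion")
}

as_fdg_params_list <- function(x) {
  if (is.data.frame(x)) {
    miss <- setdiff(c("K1", "k2", "k3"), names(x))
    if (length(miss)) abort(paste0("Missing FDG parameters: ", paste(miss, collapse = ", ")))
    return(list(K1 = x$K1[1], k2 = x$k2[1], k3 = x$k3[1],
                k4 = if ("k4" %in% names(x)) x$k4[1] else 0,
                Vb = if ("Vb" %in% names(x)) x$Vb[1] else 0))
  }
  if (is.list(x)) return(as_fdg_params_list(as_tibble(x)))
  abort("Expected fdg_params() output or a named list of rate constants.")
}

tac_tibble <- function(schedule, value) {
  tibble(
    frame_start_min = schedule$frame_start_min,
    frame_end_min = schedule$frame_end_min,
    mid_min = schedule$mid_min,
    value = value
  )
}

#' Simulate a tissue curve under the irreversible FDG model
#'
#' Analytic solution of the two-tissue compartment model with irreversible
#' phosphorylation (k4 = 0). With theta = k2 + k3 the tissue concentration is
#' \deqn{C_T(t) = \frac{K_1 k_3}{\theta}\int_0^t C_p +
#'   \frac{K_1 k_2}{\theta}\,[e^{-\theta t} * C_p](t)}
#' and the measured curve is (1 - Vb) C_T + Vb C_b. The convolution is exact
#' for a piecewise-linear input, so results do not depend on any internal
#' discretization grid. Curves are evaluated at frame mid-times.
#'
#' @param params An [fdg_params()] object (k4 must be 0).
#' @param aif Input-function tibble (`time_min`, `value`).
#' @param schedule Frame-schedule tibble.
#' @param blood Optional whole-blood curve for the Vb term; defaults to `aif`.
#' @return A tibble with columns `frame_start_min`, `frame_end_min`,
#'   `mid_min`, `value`.
#' @export
#' @examples
#' aif <- feng_aif()
#' tac <- simulate_tac_irreversible(fdg_params(0.091, 0.128, 0.057), aif,
#'                                  default_fdg_schedule())
simulate_tac_irreversible <- function(params, aif, schedule, blood = NULL) {
  aif <- as_input_function(aif)
  schedule <- as_frame_schedule(schedule)
  p <- as_fdg_params_list(params)
  if (p$k4 != 0) abort("Irreversible model requires k4 = 0; use simulate_tac_reversible().")
  mid <- schedule$mid_min
  theta <- p$k2 + p$k3
  ct <- if (p$K1 == 0) {
    numeric(length(mid))
  } else if (theta == 0) {
    p$K1 * cumint_pl(aif$time_min, aif$value, mid)
  } else {
    (p$K1 * p$k3 / theta) * cumint_pl(aif$time_min, aif$value, mid) +
      (p$K1 * p$k2 / theta) * conv_exp_pl(aif$time_min, aif$value, theta, mid)
  }
  meas <- (1 - p$Vb) * ct
  if (p$Vb > 0) {
    bl <- if (is.null(blood)) aif else as_input_function(blood)
    meas <- meas + p$Vb * interp_pl(bl$time_min, bl$value, mid)
  }
  tac_tibble(schedule, meas)
}

#' Simulate a tissue curve under the reversible (k4-inclusive) FDG model
#'
#' Closed-form bi-exponential impulse response of the two-tissue model with
#' dephosphorylation. The eigenrates are
#' \deqn{\alpha_{1,2} = \tfrac12\left[(k_2 + k_3 + k_4) \mp
#'   \sqrt{(k_2 + k_3 + k_4)^2 - 4 k_2 k_4}\right]}
#' and the impulse response K1\[(k3 + k4 - a1) e^{-a1 t} + (a2 - k3 - k4)
#' e^{-a2 t}\]/(a2 - a1) is convolved exactly against the piecewise-linear
#' input. Reduces exactly to the irreversible solution when k4 = 0.
#'
#' @inheritParams simulate_tac_irreversible
#' @return A TAC tibble as for [simulate_tac_irreversible()].
#' @export
simulate_tac_reversible <- function(params, aif, schedule, blood = NULL) {
  aif <- as_input_function(aif)
  schedule <- as_frame_schedule(schedule)
  p <- as_fdg_params_list(params)
  mid <- schedule$mid_min
  s <- p$k2 + p$k3 + p$k4
  disc <- s^2 - 4 * p$k2 * p$k4
  if (disc < -1e-9 * max(s^2, 1)) {
    abort("Eigenrate discriminant is negative beyond tolerance; invalid rates.")
  }
  disc <- max(disc, 0)
  a1 <- (s - sqrt(disc)) / 2
  a2 <- (s + sqrt(disc)) / 2
  times <- aif$time_min
  vals <- aif$value
  ct <- if (p$K1 == 0) {
    numeric(length(mid))
  } else if (a2 == 0) {
    # all rates zero: pure accumulation
    p$K1 * cumint_pl(times, vals, mid)
  } else {
    if ((a2 - a1) < 1e-9 * a2) {
      # coincident eigenrates: split them infinitesimally; the analytic limit
      # involves t e^{-at} terms and this perturbation is accurate to O(1e-9 t^2)
      a1 <- a1 * (1 - 1e-7) - 1e-12
      a2 <- a2 * (1 + 1e-7) + 1e-12
      a1 <- max(a1, 0)
    }
    conv1 <- if (a1 == 0) cumint_pl(times, vals, mid) else conv_exp_pl(times, vals, a1, mid)
    conv2 <- conv_exp_pl(times, vals, a2, mid)
    (p$K1 / (a2 - a1)) * ((p$k3 + p$k4 - a1) * conv1 + (a2 - p$k3 - p$k4) * conv2)
  }
  meas <- (1 - p$Vb) * ct
  if (p$Vb > 0) {
    bl <- if (is.null(blood)) aif else as_input_function(blood)
    meas <- meas + p$Vb * interp_pl(bl$time_min, bl$value, mid)
  }
  tac_tibble(schedule, meas)
}
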
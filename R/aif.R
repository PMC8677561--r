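#' Arterial input functions and frame schedules
#'
#' An input function is the arterial tracer concentration sampled over time;
#' it drives every kinetic model in the package. It is represented as a plain
#' tibble with columns `time_min` (minutes post-injection, strictly
#' increasing, first sample at or after 0) and `value` (activity
#' concentration, any consistent unit, non-negative). Between samples the
#' curve is treated as piecewise linear, and as zero before the first sample;
#' all convolution integrals in the package are exact under that assumption.
#'
#' @param times Numeric vector of sample times in minutes.
#' @param values Numeric vector of activity values, same length as `times`.
#' @return A tibble with columns `time_min`, `value`.
#' @export
#' @examples
#' aif <- input_function(c(0, 0.5, 1, 2, 5), c(0, 80, 40, 20, 10))
input_function <- function(times, values) {
  if (length(times) != length(values)) {
    abort("`times` and `values` must have equal length.")
  }
  if (length(times) < 4) abort("An input function needs at least 4 samples.")
  if (any(!is.finite(times)) || any(!is.finite(values))) {
    abort("Input-function samples must be finite.")
  }
  if (times[1] < 0) abort("Input-function times must start at or after 0.")
  if (any(diff(times) <= 0)) abort("Input-function times must be strictly increasing.")
  if (any(values < 0)) abort("Input-function activity must be non-negative.")
  tibble(time_min = as.numeric(times), value = as.numeric(values))
}

as_input_function <- function(x) {
  if (is.data.frame(x) && all(c("time_min", "value") %in% names(x))) {
    return(input_function(x$time_min, x$value))
  }
  abort("Expected an input function: a data frame with columns time_min, value.")
}

#' Build a PET frame schedule
#'
#' Frames are contiguous or gapped, non-overlapping time bins; frame mid-times
#' (arithmetic mean of start and end) are where tissue curves are evaluated.
#'
#' @param start,end Numeric vectors of frame start/end times in minutes.
#' @return A tibble with columns `frame_start_min`, `frame_end_min`,
#'   `mid_min`.
#' @export
frame_schedule <- function(start, end) {
  if (length(start) != length(end)) abort("`start` and `end` must match in length.")
  if (any(end <= start)) abort("Every frame must end after it starts.")
  if (any(start < 0)) abort("Frame times must be non-negative.")
  if (length(start) > 1 && any(start[-1] < end[-length(end)])) {
    abort("Frames must be non-overlapping and increasing.")
  }
  tibble(
    frame_start_min = as.numeric(start),
    frame_end_min = as.numeric(end),
    mid_min = (as.numeric(start) + as.numeric(end)) / 2
  )
}

as_frame_schedule <- function(x) {
  if (is.data.frame(x) && all(c("frame_start_min", "frame_end_min") %in% names(x))) {
    return(frame_schedule(x$frame_start_min, x$frame_end_min))
  }
  abort("Expected a frame schedule: columns frame_start_min, frame_end_min.")
}

#' Default 60-minute FDG frame schedule
#'
#' Seventeen frames spanning 0-60 min (6 x 0.5, 3 x 1, 2 x 2, 2 x 5,
#' 4 x 10 min), dense early while the input function changes quickly.
#'
#' @return A frame-schedule tibble.
#' @export
default_fdg_schedule <- function() {
  dur <- c(rep(0.5, 6), rep(1, 3), rep(2, 2), rep(5, 2), rep(10, 4))
  end <- cumsum(dur)
  frame_schedule(c(0, head(end, -1)), end)
}

#' Feng-form arterial input function
#'
#' The classic tri-exponential bolus parameterization
#' \deqn{C_p(t) = (A_1 t - A_2 - A_3) e^{-\lambda_1 t} + A_2 e^{-\lambda_2 t}
#'   + A_3 e^{-\lambda_3 t}}
#' clipped at zero, with an optional pure delay chosen so the continuous peak
#' falls at `t_peak`. Values are sampled densely (finer than any frame) so
#' the piecewise-linear representation is accurate.
#'
#' @param A1,A2,A3 Amplitudes (activity units; `A1` per minute).
#' @param l1,l2,l3 Decay rates per minute, all positive.
#' @param t_peak Time of the bolus peak in minutes.
#' @param t_end Last sample time in minutes.
#' @param dt_early,dt_late Sampling steps before/after 3 min.
#' @return An input-function tibble.
#' @export
#' @examples
#' aif <- feng_aif()
#' range(aif$value)
feng_aif <- function(A1 = 851.1, A2 = 21.9, A3 = 20.8,
                     l1 = 4.1339, l2 = 0.1191, l3 = 0.0104,
                     t_peak = 0.5, t_end = 60,
                     dt_early = 0.05, dt_late = 0.5) {
  if (any(c(l1, l2, l3) <= 0)) abort("Feng decay rates must be positive.")
  f <- function(t) {
    (A1 * t - A2 - A3) * exp(-l1 * t) + A2 * exp(-l2 * t) + A3 * exp(-l3 * t)
  }
  # intrinsic peak of the undelayed form, then shift so the peak sits at t_peak
  tg <- seq(0, 5, by = 0.001)
  delay <- max(0, t_peak - tg[which.max(f(tg))])
  times <- sort(unique(c(seq(0, min(3, t_end), by = dt_early),
                         if (t_end > 3) seq(3, t_end, by = dt_late), t_end)))
  v <- ifelse(times < delay, 0, f(times - delay))
  peak <- max(v)
  if (peak <= 0) return(input_function(times, rep(0, length(times))))
  if (min(v) < -1e-6 * peak) {
    abort("Feng parameters produce a negative tail; adjust amplitudes/rates.")
  }
  input_function(times, pmax(v, 0))
}

# ---- exact piecewise-linear integral transforms --------------------------

# Interpolate a piecewise-linear curve onto grid g; zero before the first
# sample, error past the last (models must be covered by the input function).
interp_pl <- function(times, values, g) {
  if (max(g) > max(times) + 1e-9) {
    abort("Input function does not cover the requested time span.")
  }
  if (times[1] > 0) {
    times <- c(0, times)
    values <- c(0, values)
  }
  approx(times, values, xout = pmin(g, max(times)), rule = 2)$y
}

# Running integral int_0^t C_p(s) ds of the piecewise-linear input,
# evaluated exactly at eval_times.
cumint_pl <- function(times, values, eval_times) {
  g <- sort(unique(c(times, eval_times, 0)))
  v <- interp_pl(times, values, g)
  y <- c(0, cumsum(diff(g) * (head(v, -1) + tail(v, -1)) / 2))
  y[match(eval_times, g)]
}

# Exponential convolution y(t) = int_0^t exp(-theta (t - s)) C_p(s) ds with
# C_p piecewise linear; exact per segment (grid-independent), stable as
# theta -> 0 where it reduces to the running integral.
conv_exp_pl <- function(times, values, theta, eval_times) {
  if (theta < 0) abort("Convolution rate must be non-negative.")
  g <- sort(unique(c(times, eval_times, 0)))
  v <- interp_pl(times, values, g)
  n <- length(g)
  y <- numeric(n)
  dt <- diff(g)
  for (i in seq_len(n - 1)) {
    h <- dt[i]
    c0 <- v[i]
    m <- (v[i + 1] - c0) / h
    if (theta * h < 1e-12) {
      y[i + 1] <- y[i] * (1 - theta * h) + h * (c0 + v[i + 1]) / 2
    } else {
      x <- theta * h
      E <- exp(-x)
      om <- -expm1(-x) # 1 - E without cancellation
      j2 <- if (x < 1e-4) {
        h^2 * (0.5 - x / 6 + x^2 / 24) # series for (x - 1 + e^-x)/theta^2
      } else {
        (x + expm1(-x)) / theta^2
      }
      y[i + 1] <- y[i] * E + c0 * om / theta + m * j2
    }
  }
  y[match(eval_times, g)]
}
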
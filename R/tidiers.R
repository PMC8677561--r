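# broom-style tidiers for the fitted objects.

#' Tidy an FDG kinetic fit
#'
#' @param x An `fdg_fit`.
#' @param conv [lc_conversion()] used for derived macro-parameters.
#' @param plasma_glucose Optional plasma glucose (mmol/l); adds CMRG and
#'   brain glucose rows when supplied.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`.
#' @export
tidy.fdg_fit <- function(x, conv = lc_conversion(), plasma_glucose = NULL,
                         ...) {
  p <- x$params
  ki <- influx_constant(p)
  lc <- suppressWarnings(lumped_constant(p, conv))
  out <- tibble(
    term = c("K1", "k2", "k3", "k4", "Vb", "Ki", "LC", "phospho_fraction"),
    estimate = c(p$K1, p$k2, p$k3, p$k4, p$Vb, ki, lc,
                 if (p$k2 + p$k3 > 0) phosphorylation_fraction(p, conv) else NA_real_)
  )
  if (!is.null(plasma_glucose)) {
    out <- dplyr::bind_rows(out, tibble(
      term = c("CMRG", "brain_glucose"),
      estimate = c(if (is.finite(lc) && lc > 0) cmrg_from_ki(ki, plasma_glucose, lc) else NA_real_,
                   suppressWarnings(brain_glucose(p, plasma_glucose, conv)))
    ))
  }
  out
}

#' Glance at an FDG kinetic fit
#'
#' @param x An `fdg_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `method`, `theta`, `wrss`, `n_frames`,
#'   `degenerate`, `singular`, and `converged` for regional fits.
#' @export
glance.fdg_fit <- function(x, ...) {
  tibble(method = x$method, theta = x$theta, wrss = x$wrss,
         n_frames = length(x$tac), degenerate = x$degenerate,
         singular = x$singular,
         converged = if (!is.null(x$converged)) x$converged else NA)
}

#' @export
tidy.h2o_fit <- function(x, ...) {
  tibble(term = c("CBF", "f", "Vd", "k"),
         estimate = c(x$CBF, x$f, x$Vd, x$k))
}

#' @export
glance.h2o_fit <- function(x, ...) {
  tibble(wrss = x$wrss, degenerate = x$degenerate)
}

#' Tidy a group comparison
#'
#' @param x A `group_comparison`.
#' @param which `"test"` (default) for the omnibus result, `"posthoc"` for
#'   Dunn's pairwise rows.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.group_comparison <- function(x, which = c("test", "posthoc"), ...) {
  which <- match.arg(which)
  if (which == "posthoc") {
    if (is.null(x$posthoc)) return(tibble())
    return(x$posthoc)
  }
  x$test
}

#' @export
glance.group_comparison <- function(x, ...) {
  x$test
}

#' @export
tidy.lowess_curve <- function(x, ...) {
  x$curve
}
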
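#' Spearman rank association
#'
#' Rank correlation with average-rank tie handling and a two-sided p-value:
#' exact (full permutation distribution) when n < 10 and the data are
#' untied, t-approximation otherwise. Data-frame-first so cohort tables can
#' be piped in.
#'
#' @param data A data frame, or a numeric vector (then `y` is the paired
#'   vector).
#' @param x,y Column selections (unquoted) when `data` is a data frame.
#' @return A one-row tibble: `rho`, `p_value`, `n`, `method`, `degenerate`.
#'   A constant input vector gives `rho = NA` with `degenerate = TRUE`.
#' @export
#' @examples
#' spearman_assoc(data.frame(a = 1:8, b = c(2, 1, 4, 3, 6, 5, 8, 7)), a, b)
spearman_assoc <- function(data, x, y) {
  if (is.data.frame(data)) {
    xv <- eval_tidy(enquo(x), data)
    yv <- eval_tidy(enquo(y), data)
  } else {
    xv <- data
    yv <- x
  }
  keep <- is.finite(xv) & is.finite(yv)
  xv <- xv[keep]
  yv <- yv[keep]
  n <- length(xv)
  if (n < 4) abort("Spearman association needs at least 4 complete pairs.")
  if (length(unique(xv)) == 1 || length(unique(yv)) == 1) {
    return(tibble(rho = NA_real_, p_value = NA_real_, n = n,
                  method = "spearman", degenerate = TRUE))
  }
  ties <- anyDuplicated(xv) > 0 || anyDuplicated(yv) > 0
  exact <- !ties && n < 10
  ct <- suppressWarnings(
    cor.test(xv, yv, method = "spearman", exact = exact,
             alternative = "two.sided")
  )
  tibble(rho = unname(ct$estimate), p_value = min(1, ct$p.value), n = n,
         method = if (exact) "spearman-exact" else "spearman-approx",
         degenerate = FALSE)
}

# Dunn's post-hoc z-tests on the pooled ranks after Kruskal-Wallis, with the
# standard tie correction; raw two-sided p-values (the global Bonferroni rule
# is applied at the reporting layer, not per pair).
dunn_posthoc <- function(values, groups) {
  r <- rank(values)
  N <- length(values)
  tie_tab <- table(values)
  tie_corr <- sum(tie_tab^3 - tie_tab) / (12 * (N - 1))
  lv <- levels(groups)
  mean_ranks <- tapply(r, groups, mean)
  ns <- tapply(r, groups, length)
  pairs <- utils::combn(lv, 2, simplify = FALSE)
  purrr::map_dfr(pairs, function(pr) {
    i <- pr[1]; j <- pr[2]
    se <- sqrt((N * (N + 1) / 12 - tie_corr) * (1 / ns[[i]] + 1 / ns[[j]]))
    z <- (mean_ranks[[i]] - mean_ranks[[j]]) / se
    tibble(group_1 = i, group_2 = j, z = z,
           p_value = 2 * pnorm(-abs(z)))
  })
}

#' Nonparametric group comparison
#'
#' Two groups are compared with the Mann-Whitney U-test; three or more with
#' Kruskal-Wallis followed (when significant at `alpha`) by Dunn's z-tests
#' for all pairs. Significance is flagged both at the nominal `alpha` and at
#' the stricter Bonferroni threshold used when eleven physiological
#' variables are examined together (P < 0.005).
#'
#' @param data A data frame in long format.
#' @param value,group Unquoted column names for the measurement and the
#'   group label.
#' @param posthoc Run Dunn's pairwise tests after a significant
#'   Kruskal-Wallis result.
#' @param alpha Nominal significance level (default 0.05).
#' @param alpha_strict Multiplicity-corrected threshold (default 0.005).
#' @return An object of class `group_comparison` with `test` (one-row
#'   tibble) and `posthoc` (tibble of pairs or NULL); see
#'   [tidy.group_comparison()].
#' @export
group_compare <- function(data, value, group, posthoc = TRUE,
                          alpha = 0.05, alpha_strict = 0.005) {
  v <- eval_tidy(enquo(value), data)
  g <- eval_tidy(enquo(group), data)
  keep <- is.finite(v) & !is.na(g)
  v <- v[keep]
  g <- droplevels(factor(g[keep]))
  ns <- table(g)
  if (length(ns) < 2) abort("Need at least 2 non-empty groups.")
  if (any(ns < 2)) abort("Every group needs at least 2 observations.")
  if (length(ns) == 2) {
    ht <- suppressWarnings(wilcox.test(v ~ g))
    test <- tibble(test = "mann-whitney", statistic = unname(ht$statistic),
                   df = NA_real_, p_value = ht$p.value,
                   n_groups = 2L,
                   significant = ht$p.value < alpha,
                   significant_strict = ht$p.value < alpha_strict)
    ph <- NULL
  } else {
    ht <- kruskal.test(v ~ g)
    test <- tibble(test = "kruskal-wallis", statistic = unname(ht$statistic),
                   df = unname(ht$parameter), p_value = ht$p.value,
                   n_groups = length(ns),
                   significant = ht$p.value < alpha,
                   significant_strict = ht$p.value < alpha_strict)
    ph <- if (posthoc && ht$p.value < alpha) {
      dunn_posthoc(v, g) |>
        dplyr::mutate(significant = .data$p_value < alpha,
                      significant_strict = .data$p_value < alpha_strict)
    } else {
      NULL
    }
  }
  structure(list(test = test, posthoc = ph, alpha = alpha,
                 alpha_strict = alpha_strict),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("<group_comparison>\n")
  print(x$test)
  if (!is.null(x$posthoc)) {
    cat("Dunn post-hoc:\n")
    print(x$posthoc)
  }
  invisible(x)
}

#' Voxel-wise LOWESS relationship curve
#'
#' Draws a seeded simple random subsample (default 2.5%) of the paired voxel
#' values, fits a tricube-weighted local linear regression (degree-1 loess)
#' and evaluates it on a regular grid, with an optional bootstrap 95%
#' confidence band from resamples of the subsample. Rows are sorted before
#' sampling, so the curve is invariant to the input voxel ordering and
#' reproducible under a fixed seed.
#'
#' @param data Data frame of paired voxel values (>= 1000 rows).
#' @param x,y Unquoted column names.
#' @param sample_frac Fraction of voxels sampled (default 0.025).
#' @param smoothing_frac loess span (default 0.3).
#' @param n_boot Bootstrap resamples for the band (default 200; 0 disables).
#' @param n_grid Evaluation grid size (default 100).
#' @param seed Seed for sampling and bootstrap.
#' @return An object of class `lowess_curve` with elements `curve` (tibble:
#'   `x`, `fit`, `lwr`, `upr`), `sample` (the subsample tibble), and the
#'   parameters used.
#' @export
lowess_relationship <- function(data, x, y, sample_frac = 0.025,
                                smoothing_frac = 0.3, n_boot = 200,
                                n_grid = 100, seed = NULL) {
  xv <- eval_tidy(enquo(x), data)
  yv <- eval_tidy(enquo(y), data)
  keep <- is.finite(xv) & is.finite(yv)
  xv <- xv[keep]
  yv <- yv[keep]
  if (length(xv) < 1000) abort("LOWESS relationship curves need >= 1000 voxels.")
  ord <- order(xv, yv)
  xv <- xv[ord]
  yv <- yv[ord]
  n_s <- max(10L, round(sample_frac * length(xv)))
  if (floor(n_s * smoothing_frac) < 4) {
    abort("Subsample smaller than the smoothing window; raise sample_frac or smoothing_frac.")
  }
  seeds <- if (is.null(seed)) list(NULL, NULL) else as.list(child_seeds(seed, 2))
  idx <- with_seed(seeds[[1]], sample.int(length(xv), n_s))
  xs <- xv[idx]
  ys <- yv[idx]
  grid <- seq(min(xs), max(xs), length.out = n_grid)
  fit_curve <- function(xx, yy) {
    m <- loess(yy ~ xx, span = smoothing_frac, degree = 1,
               family = "gaussian", surface = "direct",
               control = loess.control(statistics = "none"))
    predict(m, data.frame(xx = grid))
  }
  fit <- fit_curve(xs, ys)
  lwr <- upr <- rep(NA_real_, n_grid)
  if (n_boot > 0) {
    boot <- with_seed(seeds[[2]], {
      vapply(seq_len(n_boot), function(b) {
        bi <- sample.int(n_s, n_s, replace = TRUE)
        fit_curve(xs[bi], ys[bi])
      }, numeric(n_grid))
    })
    lwr <- apply(boot, 1, quantile, 0.025, na.rm = TRUE)
    upr <- apply(boot, 1, quantile, 0.975, na.rm = TRUE)
  }
  structure(list(curve = tibble(x = grid, fit = fit, lwr = lwr, upr = upr),
                 sample = tibble(x = xs, y = ys),
                 sample_frac = sample_frac, smoothing_frac = smoothing_frac,
                 n_boot = n_boot, seed = seed),
            class = "lowess_curve")
}

#' @export
print.lowess_curve <- function(x, ...) {
  cat(sprintf("<lowess_curve> %d sampled voxels, span %.2f, %d grid points\n",
              nrow(x$sample), x$smoothing_frac, nrow(x$curve)))
  invisible(x)
}

# Breakpoint locator for fitted relationship curves: the x where the fitted
# slope crosses halfway between its low-x and high-x plateau values. For a
# piecewise-linear underlying relationship smoothed by a symmetric kernel
# this crossing sits at the true breakpoint.
curve_breakpoint <- function(curve) {
  x <- curve$x
  f <- curve$fit
  sl <- diff(f) / diff(x)
  xm <- (head(x, -1) + tail(x, -1)) / 2
  k <- length(sl)
  lo <- median(sl[seq_len(max(3, floor(k * 0.15)))])
  hi <- median(sl[seq(k - max(3, floor(k * 0.15)) + 1, k)])
  half <- (lo + hi) / 2
  cross <- which(diff(sign(sl - half)) != 0)
  if (!length(cross)) return(NA_real_)
  i <- cross[1]
  # linear interpolation between the two slope samples
  xm[i] + (half - sl[i]) * (xm[i + 1] - xm[i]) / (sl[i + 1] - sl[i])
}

#' Assign the post-injury imaging epoch
#'
#' Sessions within 24 h are early, beyond that up to 5 days intermediate,
#' up to 12 days late; later sessions are flagged out-of-window.
#'
#' @param hours_post_injury Non-negative numeric vector of hours since
#'   injury.
#' @return Factor with levels early, intermediate, late, out_of_window.
#' @export
#' @examples
#' epoch_assign(c(12, 72, 200, 320))
epoch_assign <- function(hours_post_injury) {
  if (any(!is.finite(hours_post_injury)) || any(hours_post_injury < 0)) {
    abort("`hours_post_injury` must be non-negative and finite.")
  }
  cut(hours_post_injury, breaks = c(-Inf, 24, 120, 288, Inf),
      labels = c("early", "intermediate", "late", "out_of_window"))
}
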
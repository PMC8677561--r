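#' Cohort specification
#'
#' Study-condition defaults for the synthetic cohort: 26 patients imaged in
#' 34 sessions split 12/8/14 across the early (<= 24 h), intermediate
#' (2-5 d) and late (6-12 d) epochs, nine FDG healthy volunteers, plasma
#' glucose centred at 5.8 mmol/l in patients and 4.6 mmol/l in volunteers,
#' microdialysis available for 10 patient sessions with a strong positive
#' dependence on plasma glucose, and a negative coupling between brain
#' glucose availability and the phosphorylation rate k3.
#'
#' @param n_patients Number of patients.
#' @param epoch_sessions Named counts of patient sessions per epoch.
#' @param n_volunteers Number of healthy volunteers.
#' @param glucose_patient,glucose_volunteer Median and SD (mmol/l) of the
#'   plasma-glucose draws per group.
#' @param n_microdialysis Number of patient sessions carrying microdialysis.
#' @param md_slope Increase of microdialysis glucose per mmol/l of plasma
#'   glucose.
#' @param md_noise_sd SD of microdialysis glucose around that line (mmol/l).
#' @param k3_coupling Strength (in SD units per SD of brain-glucose
#'   availability) of the negative modulation of k3; 0 disables coupling.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 26,
                        epoch_sessions = c(early = 12, intermediate = 8, late = 14),
                        n_volunteers = 9,
                        glucose_patient = c(median = 5.8, sd = 1.04),
                        glucose_volunteer = c(median = 4.6, sd = 0.74),
                        n_microdialysis = 10,
                        md_slope = 0.55, md_noise_sd = 0.30,
                        k3_coupling = 1.0) {
  if (n_patients < 1 || n_volunteers < 1) abort("Cohort counts must be >= 1.")
  if (any(epoch_sessions < 0)) abort("Epoch session counts must be >= 0.")
  if (n_microdialysis > sum(epoch_sessions)) {
    abort("`n_microdialysis` cannot exceed the number of patient sessions.")
  }
  structure(list(n_patients = n_patients, epoch_sessions = epoch_sessions,
                 n_volunteers = n_volunteers,
                 glucose_patient = glucose_patient,
                 glucose_volunteer = glucose_volunteer,
                 n_microdialysis = n_microdialysis, md_slope = md_slope,
                 md_noise_sd = md_noise_sd, k3_coupling = k3_coupling),
            class = "cohort_spec")
}

#' Microdialysis assay defaults
#'
#' Median and IQR-derived SD of the bedside microdialysis assays used by
#' the cohort generator (glucose and lactate mmol/l, pyruvate and glutamate
#' micromol/l; 20-min sampling interval). The lactate/pyruvate ratio is
#' always computed from the generated lactate and pyruvate
#' (lactate converted to micromol/l), never drawn.
#'
#' @return A named list of `c(median, sd)` pairs.
#' @export
microdialysis_defaults <- function() {
  list(glucose = c(median = 1.6, sd = 1.9 / 1.35),
       lactate = c(median = 4.4, sd = 4.6 / 1.35),
       pyruvate = c(median = 138.4, sd = 86.1 / 1.35),
       glutamate = c(median = 10.4, sd = 18.2 / 1.35),
       interval_min = 20)
}

#' Simulate a study cohort with known dependence structure
#'
#' Generates one record per imaging session: group, epoch, plasma glucose
#' (per-group truncated Gaussians), microdialysis assays for a subset of
#' patient sessions (microdialysis glucose increases with plasma glucose),
#' and a per-session regional parameter table in which k3 (and hence Ki) is
#' modulated negatively by the session's brain-glucose availability with
#' the configured strength. All child seeds are recorded.
#'
#' @param spec A [cohort_spec()].
#' @param region_params Regional distribution tibble; defaults to
#'   [region_param_defaults()].
#' @param seed Master seed.
#' @return A tibble with one row per session: `study_id`, `subject_id`,
#'   `group`, `epoch`, `hours_post_injury`, `plasma_glucose`, microdialysis
#'   columns (`md_glucose`, `md_lactate`, `md_pyruvate`, `md_glutamate`,
#'   `md_lpr`, NA when absent), and a nested `regions` tibble of per-region
#'   parameter medians. Attribute `seeds` records the child seeds.
#' @export
#' @examples
#' coh <- simulate_cohort(cohort_spec(), seed = 1)
#' dplyr::count(coh, group, epoch)
simulate_cohort <- function(spec = cohort_spec(),
                            region_params = region_param_defaults(),
                            seed = 1) {
  seeds <- child_seeds(seed, 4)
  n_pat_sess <- sum(spec$epoch_sessions)
  md_def <- microdialysis_defaults()

  epochs <- rep(names(spec$epoch_sessions), spec$epoch_sessions)
  hours <- with_seed(seeds[1], {
    vapply(epochs, function(e) {
      switch(e,
             early = runif(1, 4, 24),
             intermediate = runif(1, 48, 120),
             late = runif(1, 144, 288))
    }, numeric(1))
  })
  subject <- if (spec$n_patients >= n_pat_sess) {
    seq_len(n_pat_sess)
  } else {
    # some subjects imaged twice, mirroring repeat sessions
    c(seq_len(spec$n_patients),
      seq_len(n_pat_sess - spec$n_patients))
  }

  gp <- spec$glucose_patient
  gv <- spec$glucose_volunteer
  plasma <- with_seed(seeds[2], {
    c(rtnorm(n_pat_sess, gp[["median"]], gp[["sd"]], lower = 2.5),
      rtnorm(spec$n_volunteers, gv[["median"]], gv[["sd"]], lower = 2.5))
  })

  md_rows <- with_seed(seeds[3], {
    idx <- sort(sample.int(n_pat_sess, spec$n_microdialysis))
    g <- pmax(0.2, md_def$glucose[["median"]] +
                spec$md_slope * (plasma[idx] - gp[["median"]]) +
                rnorm(length(idx), 0, spec$md_noise_sd))
    lac <- rtnorm(length(idx), md_def$lactate[["median"]],
                  md_def$lactate[["sd"]], lower = 0.2)
    pyr <- rtnorm(length(idx), md_def$pyruvate[["median"]],
                  md_def$pyruvate[["sd"]], lower = 20)
    glu <- rtnorm(length(idx), md_def$glutamate[["median"]],
                  md_def$glutamate[["sd"]], lower = 0.5)
    list(idx = idx, glucose = g, lactate = lac, pyruvate = pyr,
         glutamate = glu)
  })

  n_all <- n_pat_sess + spec$n_volunteers
  group <- c(rep("patient", n_pat_sess), rep("volunteer", spec$n_volunteers))
  md_glucose <- rep(NA_real_, n_all)
  md_glucose[md_rows$idx] <- md_rows$glucose
  md_lactate <- rep(NA_real_, n_all)
  md_lactate[md_rows$idx] <- md_rows$lactate
  md_pyruvate <- rep(NA_real_, n_all)
  md_pyruvate[md_rows$idx] <- md_rows$pyruvate
  md_glutamate <- rep(NA_real_, n_all)
  md_glutamate[md_rows$idx] <- md_rows$glutamate
  md_lpr <- 1000 * md_lactate / md_pyruvate # mmol/l -> micromol/l before ratio

  # brain-glucose availability proxy drives the k3 modulation: microdialysis
  # glucose where measured, otherwise the plasma level, each standardized by
  # its own generative SD so `k3_coupling` means SD units per SD of
  # availability
  md_sd_model <- sqrt((spec$md_slope * gp[["sd"]])^2 + spec$md_noise_sd^2)
  avail <- ifelse(!is.na(md_glucose),
                  (md_glucose - md_def$glucose[["median"]]) / md_sd_model,
                  (plasma - gp[["median"]]) / gp[["sd"]])
  avail[group == "volunteer"] <- 0

  regions <- with_seed(seeds[4], {
    lapply(seq_len(n_all), function(i) {
      rgs <- if (group[i] == "patient") REGION_LEVELS else "volunteer"
      rp <- region_params[region_params$region %in% rgs, ]
      draw <- purrr::pmap_dbl(rp[, c("variable", "mean", "sd")],
                              function(variable, mean, sd) {
        upper <- if (variable == "OEF") 1 else Inf
        rtnorm(1, mean, sd, lower = 0, upper = upper)
      })
      out <- tibble(region = rp$region, variable = rp$variable, value = draw)
      if (group[i] == "patient" && spec$k3_coupling != 0) {
        k3sel <- out$variable == "k3"
        sds <- rp$sd[k3sel]
        out$value[k3sel] <- pmax(0.001, out$value[k3sel] -
                                   spec$k3_coupling * sds * avail[i])
      }
      wide <- tidyr::pivot_wider(out, names_from = "variable",
                                 values_from = "value")
      wide$Ki <- influx_constant(wide)
      wide
    })
  })

  out <- tibble(
    study_id = seq_len(n_all),
    subject_id = c(paste0("P", formatC(subject, width = 2, flag = "0")),
                   paste0("V", formatC(seq_len(spec$n_volunteers), width = 2,
                                       flag = "0"))),
    group = group,
    epoch = c(epochs, rep(NA_character_, spec$n_volunteers)),
    hours_post_injury = c(hours, rep(NA_real_, spec$n_volunteers)),
    plasma_glucose = plasma,
    md_glucose = md_glucose, md_lactate = md_lactate,
    md_pyruvate = md_pyruvate, md_glutamate = md_glutamate, md_lpr = md_lpr,
    regions = regions
  )
  attr(out, "seeds") <- seeds
  out
}

#' Extract a per-session regional variable from a cohort
#'
#' Convenience accessor pulling one variable for one region out of the
#' nested `regions` tables of [simulate_cohort()] output.
#'
#' @param cohort Cohort tibble from [simulate_cohort()].
#' @param variable Variable name (e.g. `"k3"`).
#' @param region Region name (default `"normal_appearing"`; volunteers
#'   report their `"volunteer"` region automatically).
#' @return Numeric vector aligned with the cohort rows.
#' @export
cohort_regional <- function(cohort, variable, region = "normal_appearing") {
  vapply(seq_len(nrow(cohort)), function(i) {
    tb <- cohort$regions[[i]]
    rg <- if (cohort$group[i] == "volunteer") "volunteer" else region
    val <- tb[[variable]][tb$region == rg]
    if (length(val)) val else NA_real_
  }, numeric(1))
}
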
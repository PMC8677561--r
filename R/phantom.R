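#' Default regional parameter distributions
#'
#' Study-condition defaults for the phantom generator: per-region medians
#' and IQR-derived Gaussian SDs (IQR/1.35) of the drawn variables (K1, k2,
#' k3, CBF, CBV, OEF) for lesion core, penumbra, peri-penumbra and
#' normal-appearing patient tissue, plus healthy-volunteer values. OEF is a
#' fraction. Derived maps (Ki, LC, CMRG, CMRO2, MR) are computed from these,
#' never drawn, so every phantom satisfies the macro-parameter identities
#' exactly.
#'
#' @return A tibble: `region`, `variable`, `mean`, `sd`.
#' @export
region_param_defaults <- function() {
  med <- list(
    core             = c(K1 = 0.039, k2 = 0.154, k3 = 0.044, CBF = 12.2, CBV = 2.7, OEF = 0.300),
    penumbra         = c(K1 = 0.049, k2 = 0.131, k3 = 0.039, CBF = 18.1, CBV = 2.8, OEF = 0.385),
    peri_penumbra    = c(K1 = 0.084, k2 = 0.156, k3 = 0.030, CBF = 27.4, CBV = 3.5, OEF = 0.423),
    normal_appearing = c(K1 = 0.091, k2 = 0.173, k3 = 0.029, CBF = 28.6, CBV = 4.3, OEF = 0.421),
    volunteer        = c(K1 = 0.091, k2 = 0.128, k3 = 0.057, CBF = 42.9, CBV = 3.5, OEF = 0.439)
  )
  iqr <- list(
    core             = c(K1 = 0.021, k2 = 0.069, k3 = 0.021, CBF = 10.7, CBV = 0.9, OEF = 0.201),
    penumbra         = c(K1 = 0.018, k2 = 0.048, k3 = 0.010, CBF = 6.4,  CBV = 0.8, OEF = 0.144),
    peri_penumbra    = c(K1 = 0.022, k2 = 0.052, k3 = 0.012, CBF = 8.1,  CBV = 0.9, OEF = 0.122),
    normal_appearing = c(K1 = 0.025, k2 = 0.055, k3 = 0.010, CBF = 4.9,  CBV = 0.9, OEF = 0.104),
    volunteer        = c(K1 = 0.007, k2 = 0.029, k3 = 0.009, CBF = 11.5, CBV = 0.5, OEF = 0.045)
  )
  purrr::map_dfr(names(med), function(rg) {
    tibble(region = rg, variable = names(med[[rg]]),
           mean = unname(med[[rg]]), sd = unname(iqr[[rg]]) / 1.35)
  })
}

#' Phantom specification
#'
#' Describes the synthetic imaging session the generator builds: an
#' ellipsoidal brain in a 3D grid, a spherical haemorrhagic core with a
#' penumbral shell, a peri-penumbral cuff, regional parameter distributions,
#' and planted k3-hotspot / high-OEF pathology of known volume so recovery
#' can be scored against ground truth.
#'
#' @param dim Grid dimensions (default 64^3).
#' @param voxel_size_mm Voxel size in mm (default 2 mm isotropic).
#' @param brain_axes_mm Ellipsoid semi-axes in mm; default 85% of the grid
#'   half-extent per axis.
#' @param lesion_centre_mm Lesion centre in world mm; default offset +26 mm
#'   along x from the brain centre.
#' @param core_radius_mm,penumbra_radius_mm Core radius and outer penumbra
#'   radius (mm); core < penumbra. Radius 0 disables the lesion.
#' @param cuff_mm Peri-penumbral cuff width (mm).
#' @param region_params Regional distribution tibble as from
#'   [region_param_defaults()].
#' @param hotspot_volume_ml Planted k3 hotspot volume (ml; 0 disables).
#' @param hotspot_centre_mm Hotspot centre in world mm; default -26 mm
#'   along x.
#' @param hotspot_sd_mult Hotspot intensity above the normal-appearing mean,
#'   in SD units (default +6).
#' @param high_oef_volume_ml Planted high-OEF patch volume (ml; 0 disables).
#' @param high_oef_centre_mm Patch centre; default +30 mm along y.
#' @param high_oef_value OEF inside the patch (default 0.60).
#' @param blood Arterial [blood_chemistry()]; the patient default carries
#'   plasma glucose 5.8 mmol/l.
#' @param lc [lc_conversion()] used for the derived LC/CMRG maps.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(dim = c(64, 64, 64), voxel_size_mm = c(2, 2, 2),
                         brain_axes_mm = NULL, lesion_centre_mm = NULL,
                         core_radius_mm = 10, penumbra_radius_mm = 15,
                         cuff_mm = 10,
                         region_params = region_param_defaults(),
                         hotspot_volume_ml = 56, hotspot_centre_mm = NULL,
                         hotspot_sd_mult = 6,
                         high_oef_volume_ml = 7, high_oef_centre_mm = NULL,
                         high_oef_value = 0.60,
                         blood = blood_chemistry(),
                         lc = lc_conversion()) {
  if (core_radius_mm > 0 && penumbra_radius_mm <= core_radius_mm) {
    abort("`penumbra_radius_mm` must exceed `core_radius_mm`.")
  }
  extent <- dim * voxel_size_mm
  centre <- extent / 2
  if (is.null(brain_axes_mm)) brain_axes_mm <- 0.85 * extent / 2
  if (is.null(lesion_centre_mm)) lesion_centre_mm <- centre + c(26, 0, 0)
  if (is.null(hotspot_centre_mm)) hotspot_centre_mm <- centre + c(-26, 0, 0)
  if (is.null(high_oef_centre_mm)) high_oef_centre_mm <- centre + c(0, 30, 0)
  structure(list(dim = dim, voxel_size_mm = voxel_size_mm,
                 brain_axes_mm = brain_axes_mm, centre_mm = centre,
                 lesion_centre_mm = lesion_centre_mm,
                 core_radius_mm = core_radius_mm,
                 penumbra_radius_mm = penumbra_radius_mm, cuff_mm = cuff_mm,
                 region_params = region_params,
                 hotspot_volume_ml = hotspot_volume_ml,
                 hotspot_centre_mm = hotspot_centre_mm,
                 hotspot_sd_mult = hotspot_sd_mult,
                 high_oef_volume_ml = high_oef_volume_ml,
                 high_oef_centre_mm = high_oef_centre_mm,
                 high_oef_value = high_oef_value,
                 blood = blood, lc = lc),
            class = "phantom_spec")
}

ellipsoid_mask <- function(dim3, voxel_size_mm, centre_mm, axes_mm) {
  cx <- (voxel_centres(dim3[1], voxel_size_mm[1]) - centre_mm[1]) / axes_mm[1]
  cy <- (voxel_centres(dim3[2], voxel_size_mm[2]) - centre_mm[2]) / axes_mm[2]
  cz <- (voxel_centres(dim3[3], voxel_size_mm[3]) - centre_mm[3]) / axes_mm[3]
  d2 <- outer(outer(cx^2, cy^2, "+"), cz^2, "+")
  array(d2 <= 1, dim3)
}

radius_for_volume_ml <- function(volume_ml) {
  (3 * volume_ml * 1000 / (4 * pi))^(1 / 3)
}

#' Build a synthetic parametric map set with known ground truth
#'
#' Generates co-registered CBF, CBV, OEF, K1, k2, k3 maps (truncated
#' Gaussians per structural region), derives Ki, LC, CMRG, CMRO2 and MR so
#' that the macro identities hold exactly at every voxel, and plants a k3
#' hotspot and a high-OEF patch of configured volumes inside the brain.
#' Returns the maps, labels and a ground-truth record sufficient to score
#' recovery of every derived quantity.
#'
#' @param spec A [phantom_spec()].
#' @param seed Seed for all draws (recorded in the truth record).
#' @return A list of class `phantom`: `maps` ([physio_maps()]), `labels`
#'   ([region_labels()]), and `truth` (planted masks/volumes, regional
#'   parameters, blood chemistry, CaO2, seed).
#' @export
#' @examples
#' ph <- build_phantom_maps(phantom_spec(dim = c(24, 24, 24)), seed = 1)
#' ph$truth$hotspot_volume_ml
build_phantom_maps <- function(spec, seed = 1) {
  d <- spec$dim
  vs <- spec$voxel_size_mm
  brain <- ellipsoid_mask(d, vs, spec$centre_mm, spec$brain_axes_mm)
  brain_ml <- voxels_to_ml(sum(brain), vs)
  if (spec$hotspot_volume_ml > brain_ml) {
    abort("Planted hotspot volume exceeds the brain volume.")
  }

  core <- if (spec$core_radius_mm > 0) {
    sphere_mask(d, vs, spec$lesion_centre_mm, spec$core_radius_mm) & brain
  } else {
    array(FALSE, d)
  }
  pen <- if (spec$core_radius_mm > 0) {
    sphere_mask(d, vs, spec$lesion_centre_mm, spec$penumbra_radius_mm) &
      brain & !core
  } else {
    array(FALSE, d)
  }
  labels <- build_structural_labels(core, pen, brain, vs, spec$cuff_mm)

  rp <- spec$region_params
  drawn_vars <- c("K1", "k2", "k3", "CBF", "CBV", "OEF")
  lower <- c(K1 = 0, k2 = 0, k3 = 0, CBF = 0, CBV = 0, OEF = 0)
  upper <- c(K1 = Inf, k2 = Inf, k3 = Inf, CBF = Inf, CBV = Inf, OEF = 1)

  maps <- setNames(
    lapply(drawn_vars, function(v) array(NA_real_, d)),
    drawn_vars
  )
  with_seed(seed, {
    for (code in 1:4) {
      rg <- region_name(code)
      sel <- labels$labels == code
      n <- sum(sel)
      if (n == 0) next
      for (v in drawn_vars) {
        row <- rp[rp$region == rg & rp$variable == v, ]
        if (nrow(row) != 1) abort(sprintf("Missing phantom distribution for %s/%s.", rg, v))
        maps[[v]][sel] <- rtnorm(n, row$mean, row$sd, lower[[v]], upper[[v]])
      }
    }
  })

  # plant pathology of known geometry
  norm_row <- function(v) rp[rp$region == "normal_appearing" & rp$variable == v, ]
  hotspot <- array(FALSE, d)
  if (spec$hotspot_volume_ml > 0) {
    r <- radius_for_volume_ml(spec$hotspot_volume_ml)
    hotspot <- sphere_mask(d, vs, spec$hotspot_centre_mm, r) & brain
    k3row <- norm_row("k3")
    maps$k3[hotspot] <- k3row$mean + spec$hotspot_sd_mult * k3row$sd
  }
  high_oef <- array(FALSE, d)
  if (spec$high_oef_volume_ml > 0) {
    r <- radius_for_volume_ml(spec$high_oef_volume_ml)
    high_oef <- sphere_mask(d, vs, spec$high_oef_centre_mm, r) & brain
    maps$OEF[high_oef] <- spec$high_oef_value
  }

  # derived maps: internally consistent by construction
  cao2 <- arterial_o2_content(spec$blood)
  gp <- spec$blood$plasma_glucose
  pk <- list(K1 = maps$K1, k2 = maps$k2, k3 = maps$k3)
  maps$Ki <- influx_constant(pk)
  maps$Ki[!brain] <- NA_real_
  maps$LC <- suppressWarnings(lumped_constant(pk, spec$lc))
  maps$CMRG <- cmrg_from_ki(maps$Ki, gp, pmax(maps$LC, 1e-9))
  maps$CMRO2 <- cmro2_from_maps(maps$CBF, maps$OEF, cao2)
  maps$MR <- suppressWarnings(metabolic_ratio(maps$CMRO2, maps$CMRG))

  pm <- physio_maps(maps, vs, brain)
  truth <- list(seed = seed,
                hotspot_mask = hotspot,
                hotspot_volume_ml = voxels_to_ml(sum(hotspot), vs),
                hotspot_nominal_ml = spec$hotspot_volume_ml,
                high_oef_mask = high_oef,
                high_oef_volume_ml = voxels_to_ml(sum(high_oef), vs),
                high_oef_nominal_ml = spec$high_oef_volume_ml,
                region_params = rp, blood = spec$blood, cao2 = cao2,
                plasma_glucose = gp, lc = spec$lc,
                brain_volume_ml = brain_ml)
  structure(list(maps = pm, labels = labels, truth = truth, spec = spec),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat("<phantom>\n")
  print(x$maps)
  cat(sprintf("  planted hotspot %.1f ml, high-OEF patch %.1f ml\n",
              x$truth$hotspot_volume_ml, x$truth$high_oef_volume_ml))
  invisible(x)
}

#' Add measurement noise to a time-activity curve
#'
#' Proportional Gaussian noise (SD = scale x value) or a count-scaled model
#' whose variance is proportional to value/duration, seeded and
#' reproducible. Scale 0 returns the curve unchanged.
#'
#' @param tac A TAC tibble or numeric vector.
#' @param model `"proportional"` or `"count"`.
#' @param scale Noise scale (>= 0).
#' @param seed Seed for reproducibility.
#' @return Same shape as `tac`.
#' @export
add_tac_noise <- function(tac, scale = 0.05,
                          model = c("proportional", "count"), seed = NULL) {
  model <- match.arg(model)
  if (scale < 0) abort("`scale` must be non-negative.")
  is_df <- is.data.frame(tac)
  y <- if (is_df) tac$value else as.numeric(tac)
  if (scale > 0) {
    sdv <- if (model == "proportional") {
      scale * abs(y)
    } else {
      dur <- if (is_df && all(c("frame_start_min", "frame_end_min") %in% names(tac))) {
        tac$frame_end_min - tac$frame_start_min
      } else {
        rep(1, length(y))
      }
      scale * sqrt(pmax(abs(y), 0) / dur)
    }
    y <- with_seed(seed, y + rnorm(length(y), 0, sdv))
  }
  if (is_df) {
    tac$value <- y
    tac
  } else {
    y
  }
}
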
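# Voxel-centre world coordinate of 1-based index i along one axis:
# voxel i spans [(i-1)v, iv], centre (i - 0.5) v.
voxel_centres <- function(n, v) (seq_len(n) - 0.5) * v

# Logical sphere mask: voxel centres within radius_mm of centre_mm (world mm).
sphere_mask <- function(dim3, voxel_size_mm, centre_mm, radius_mm) {
  cx <- voxel_centres(dim3[1], voxel_size_mm[1])
  cy <- voxel_centres(dim3[2], voxel_size_mm[2])
  cz <- voxel_centres(dim3[3], voxel_size_mm[3])
  dx2 <- (cx - centre_mm[1])^2
  dy2 <- (cy - centre_mm[2])^2
  dz2 <- (cz - centre_mm[3])^2
  d2 <- outer(outer(dx2, dy2, "+"), dz2, "+")
  array(d2 <= radius_mm^2, dim3)
}

# Binary dilation of a mask by a Euclidean ball of radius_mm in world (mm)
# coordinates: the result marks every voxel whose centre lies within
# radius_mm of some mask-voxel centre (a thresholded anisotropic-aware
# Euclidean distance transform). Offsets are enumerated in voxel steps.
dilate_mm <- function(mask, voxel_size_mm, radius_mm) {
  if (radius_mm < 0) abort("`radius_mm` must be non-negative.")
  if (!any(mask) || radius_mm == 0) return(mask)
  d <- dim(mask)
  r <- floor(radius_mm / voxel_size_mm)
  offs <- expand.grid(dx = -r[1]:r[1], dy = -r[2]:r[2], dz = -r[3]:r[3])
  dist <- sqrt((offs$dx * voxel_size_mm[1])^2 +
               (offs$dy * voxel_size_mm[2])^2 +
               (offs$dz * voxel_size_mm[3])^2)
  offs <- offs[dist <= radius_mm & dist > 0, , drop = FALSE]
  out <- mask
  for (i in seq_len(nrow(offs))) {
    dx <- offs$dx[i]; dy <- offs$dy[i]; dz <- offs$dz[i]
    tx <- max(1, 1 + dx):min(d[1], d[1] + dx)
    ty <- max(1, 1 + dy):min(d[2], d[2] + dy)
    tz <- max(1, 1 + dz):min(d[3], d[3] + dz)
    out[tx, ty, tz] <- out[tx, ty, tz] | mask[tx - dx, ty - dy, tz - dz]
  }
  out
}

#' Build structural region labels around a lesion
#'
#' Partitions the brain mask into lesion core, penumbra, a peri-penumbral
#' cuff of normal-appearing tissue within `cuff_mm` Euclidean distance (in
#' world mm, robust to anisotropic voxels) of the lesion, and remaining
#' normal-appearing brain. Label precedence: core > penumbra >
#' peri-penumbra > normal. Voxels claimed by both core and penumbra go to
#' core with a warning.
#'
#' @param core_mask,penumbra_mask,brain_mask Logical 3D arrays on one grid;
#'   core and penumbra must lie inside the brain.
#' @param voxel_size_mm Length-3 voxel size in mm.
#' @param cuff_mm Peri-penumbral cuff width in mm (default 10 = 1 cm).
#' @return A [region_labels()] object.
#' @export
build_structural_labels <- function(core_mask, penumbra_mask, brain_mask,
                                    voxel_size_mm, cuff_mm = 10) {
  check_same_dim(core_mask, brain_mask, "core and brain masks")
  check_same_dim(penumbra_mask, brain_mask, "penumbra and brain masks")
  if (any(core_mask & !brain_mask) || any(penumbra_mask & !brain_mask)) {
    abort("Core and penumbra must lie inside the brain mask.")
  }
  if (any(core_mask & penumbra_mask)) {
    warn("Core and penumbra overlap; overlapping voxels assigned to core.")
    penumbra_mask <- penumbra_mask & !core_mask
  }
  lesion <- core_mask | penumbra_mask
  peri <- dilate_mm(lesion, voxel_size_mm, cuff_mm) & brain_mask & !lesion
  labels <- array(0L, dim(brain_mask))
  labels[brain_mask] <- 4L
  labels[peri] <- 3L
  labels[penumbra_mask] <- 2L
  labels[core_mask] <- 1L
  region_labels(labels, voxel_size_mm)
}

#' Spherical tissue cuff around a microdialysis catheter tip
#'
#' Voxels whose centres lie within `radius_mm` of the catheter tip (world mm
#' coordinates), intersected with the brain mask. The default 10 mm radius
#' reads the "10 mm circular cuff" as a radius; pass `radius_mm = 5` for the
#' diameter reading.
#'
#' @param tip_mm Length-3 tip position in world mm; must fall inside the
#'   brain mask.
#' @param brain_mask Logical 3D array.
#' @param voxel_size_mm Length-3 voxel size in mm.
#' @param radius_mm Cuff radius in mm.
#' @return Logical 3D array.
#' @export
catheter_cuff_mask <- function(tip_mm, brain_mask, voxel_size_mm,
                               radius_mm = 10) {
  d <- dim(brain_mask)
  idx <- pmin(pmax(floor(tip_mm / voxel_size_mm) + 1L, 1L), d)
  if (!brain_mask[idx[1], idx[2], idx[3]]) {
    abort("Catheter tip lies outside the brain mask.")
  }
  m <- sphere_mask(d, voxel_size_mm, tip_mm, radius_mm)
  m[idx[1], idx[2], idx[3]] <- TRUE # radius 0 keeps the tip voxel
  m & brain_mask
}

#' Detect k3 hyperglycolysis hotspots
#'
#' Flags brain voxels whose phosphorylation rate exceeds the individual
#' threshold mean + z x SD computed over normal-appearing voxels (population
#' SD, per imaging session). By default the hotspot mask may include lesion
#' voxels; supply `exclude_mask` (e.g. core plus penumbra) for the
#' lesion-excluded variant.
#'
#' @param k3_map Numeric 3D array of k3 (/min), `NA` outside the brain.
#' @param normal_mask Logical 3D array of normal-appearing voxels (used for
#'   the threshold moments); must be non-empty.
#' @param brain_mask Logical 3D array of voxels eligible for flagging.
#' @param voxel_size_mm Length-3 voxel size in mm.
#' @param z Threshold multiplier (default 1.96, the upper 95% bound).
#' @param exclude_mask Optional logical array removed from the hotspot mask.
#' @return A list of class `hotspot_result`: `threshold` (/min), `mask`,
#'   `volume_ml`, `normal_mean`, `normal_sd`.
#' @export
k3_hotspot <- function(k3_map, normal_mask, brain_mask, voxel_size_mm,
                       z = 1.96, exclude_mask = NULL) {
  check_same_dim(k3_map, brain_mask, "k3 map and brain mask")
  vals <- k3_map[normal_mask]
  vals <- vals[is.finite(vals)]
  if (!length(vals)) abort("`normal_mask` selects no finite k3 voxels.")
  m <- mean(vals)
  s <- sd_pop(vals)
  if (s == 0) warn("Normal-appearing k3 has zero SD; threshold equals the mean.")
  thr <- m + z * s
  mask <- brain_mask & !is.na(k3_map) & (k3_map > thr)
  if (!is.null(exclude_mask)) mask <- mask & !exclude_mask
  structure(list(threshold = thr, mask = mask,
                 volume_ml = voxels_to_ml(sum(mask), voxel_size_mm),
                 normal_mean = m, normal_sd = s, z = z),
            class = "hotspot_result")
}

#' @export
print.hotspot_result <- function(x, ...) {
  cat(sprintf("<hotspot_result> threshold %.4f /min, volume %.1f ml\n",
              x$threshold, x$volume_ml))
  invisible(x)
}

#' Individualized critical OEF threshold
#'
#' The OEF above which tissue oxygen delivery cannot meet a critical venous
#' reserve. The default "venous-reserve" strategy computes
#' oef_crit = (CaO2 - CvO2_crit)/CaO2 where CvO2_crit is the oxygen content
#' of blood at a critical venous saturation (default 0.50) and venous
#' tension (default 4 kPa) at the patient's own haemoglobin. The
#' "demand-supply" strategy returns the per-voxel threshold
#' CMRO2_crit/(CBF x CaO2). The strategy used is recorded in the result.
#'
#' @param blood A [blood_chemistry()] row.
#' @param strategy `"venous-reserve"` or `"demand-supply"`.
#' @param sv_crit Critical venous saturation (fraction), venous-reserve.
#' @param pv_kpa Critical venous oxygen tension (kPa), venous-reserve.
#' @param cmro2_crit Critical oxygen metabolism (micromol/100 ml/min),
#'   demand-supply strategy.
#' @param cbf CBF map/vector (ml/100 ml/min), demand-supply strategy.
#' @return Numeric threshold (scalar, or per-voxel for demand-supply) with
#'   attribute `strategy`.
#' @export
#' @examples
#' critical_oef_threshold(blood_chemistry(Hb = 13, SaO2 = 0.98, PaO2 = 13))
critical_oef_threshold <- function(blood,
                                   strategy = c("venous-reserve", "demand-supply"),
                                   sv_crit = 0.50, pv_kpa = 4,
                                   cmro2_crit = 40, cbf = NULL) {
  strategy <- match.arg(strategy)
  cao2 <- arterial_o2_content(blood)
  if (cao2 <= 0) abort("Arterial oxygen content must be positive.")
  if (strategy == "venous-reserve") {
    cv <- o2_content(blood$Hb, sv_crit, pv_kpa)
    out <- (cao2 - cv) / cao2
  } else {
    if (is.null(cbf)) abort("`cbf` is required for the demand-supply strategy.")
    out <- cmro2_crit / (cbf * cao2)
  }
  attr(out, "strategy") <- strategy
  out
}

#' Ischaemic brain volume
#'
#' Brain voxels whose measured OEF exceeds the individualized critical
#' threshold; monotone non-increasing in the threshold.
#'
#' @param oef_map Numeric 3D array of OEF fractions, `NA` outside the brain.
#' @param oef_crit Critical OEF threshold in (0, 1).
#' @param brain_mask Logical 3D array.
#' @param voxel_size_mm Length-3 voxel size in mm.
#' @return A list of class `ibv_result`: `oef_crit`, `mask`, `volume_ml`.
#' @export
ischaemic_brain_volume <- function(oef_map, oef_crit, brain_mask,
                                   voxel_size_mm) {
  check_same_dim(oef_map, brain_mask, "OEF map and brain mask")
  oef_crit <- as.numeric(oef_crit)
  if (oef_crit <= 0 || oef_crit >= 1) abort("`oef_crit` must lie in (0, 1).")
  mask <- brain_mask & !is.na(oef_map) & (oef_map > oef_crit)
  structure(list(oef_crit = oef_crit, mask = mask,
                 volume_ml = voxels_to_ml(sum(mask), voxel_size_mm)),
            class = "ibv_result")
}

#' @export
print.ibv_result <- function(x, ...) {
  cat(sprintf("<ibv_result> OEF > %.3f, volume %.1f ml\n",
              x$oef_crit, x$volume_ml))
  invisible(x)
}

#' Spatial overlap of two tissue-class masks
#'
#' Dice similarity coefficient 2|A n B|/(|A| + |B|) with overlap and input
#' volumes in ml. Two empty masks give Dice 0 with `both_empty = TRUE`
#' rather than NaN.
#'
#' @param mask_a,mask_b Logical 3D arrays on one grid (hotspot/IBV results
#'   are also accepted).
#' @param voxel_size_mm Length-3 voxel size in mm.
#' @return A one-row tibble: `dice`, `overlap_ml`, `volume_a_ml`,
#'   `volume_b_ml`, `both_empty`.
#' @export
#' @examples
#' a <- array(FALSE, c(4, 4, 4)); a[1:2, , ] <- TRUE
#' mask_overlap(a, a, c(2, 2, 2))
mask_overlap <- function(mask_a, mask_b, voxel_size_mm) {
  if (inherits(mask_a, c("hotspot_result", "ibv_result"))) mask_a <- mask_a$mask
  if (inherits(mask_b, c("hotspot_result", "ibv_result"))) mask_b <- mask_b$mask
  check_same_dim(mask_a, mask_b, "overlap masks")
  na <- sum(mask_a)
  nb <- sum(mask_b)
  ni <- sum(mask_a & mask_b)
  both_empty <- (na + nb) == 0
  dice <- if (both_empty) 0 else 2 * ni / (na + nb)
  tibble(dice = dice,
         overlap_ml = voxels_to_ml(ni, voxel_size_mm),
         volume_a_ml = voxels_to_ml(na, voxel_size_mm),
         volume_b_ml = voxels_to_ml(nb, voxel_size_mm),
         both_empty = both_empty)
}

REGION_TABLE_VARS <- c("K1", "k2", "k3", "Ki", "CMRG", "LC", "CBF", "CMRO2",
                       "OEF", "CBV", "MR")

#' Per-region medians and interquartile ranges
#'
#' Summarises the eleven standard variables (K1, k2, k3, Ki, CMRG, LC, CBF,
#' CMRO2, OEF, CBV and the CMRO2/CMRG metabolic ratio MR) over each
#' structural region: median, IQR, quartiles and voxel count. Non-finite
#' (degenerate or masked) voxels are excluded; empty regions yield
#' missing-value rows. OEF is reported in percent.
#'
#' @param maps A [physio_maps()] object.
#' @param labels A [region_labels()] object on the same grid.
#' @return A tibble with columns `region`, `variable`, `median`, `iqr`,
#'   `q25`, `q75`, `n_voxels`.
#' @export
region_table <- function(maps, labels) {
  check_same_dim(maps$mask, labels$labels, "maps and labels")
  vars <- intersect(REGION_TABLE_VARS, names(maps$maps))
  out <- vector("list", 4L * length(vars))
  k <- 0L
  for (code in 1:4) {
    sel <- labels$labels == code
    for (v in vars) {
      vals <- maps$maps[[v]][sel]
      vals <- vals[is.finite(vals)]
      if (v == "OEF") vals <- 100 * vals
      k <- k + 1L
      out[[k]] <- tibble(
        region = region_name(code),
        variable = v,
        median = if (length(vals)) median(vals) else NA_real_,
        iqr = if (length(vals) > 1) IQR(vals) else NA_real_,
        q25 = if (length(vals)) quantile(vals, 0.25, names = FALSE) else NA_real_,
        q75 = if (length(vals)) quantile(vals, 0.75, names = FALSE) else NA_real_,
        n_voxels = length(vals)
      )
    }
  }
  dplyr::bind_rows(out)
}
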
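KPA_TO_MMHG <- 7.50062
O2_ML_PER_MMOL <- 22.4 # molar volume at STP

#' Arterial blood chemistry
#'
#' One arterial sample per imaging session: haemoglobin `Hb` (g/dl),
#' arterial oxygen saturation `SaO2` (fraction), arterial oxygen tension
#' `PaO2` (kPa) and plasma glucose (mmol/l).
#'
#' @param Hb Haemoglobin, g/dl, in (5, 25).
#' @param SaO2 Arterial saturation fraction in (0, 1].
#' @param PaO2 Arterial oxygen tension, kPa, > 0.
#' @param plasma_glucose Plasma glucose, mmol/l.
#' @return A one-row tibble of class `blood_chemistry`.
#' @export
blood_chemistry <- function(Hb = 13, SaO2 = 0.98, PaO2 = 13,
                            plasma_glucose = 5.8) {
  if (Hb <= 5 || Hb >= 25) abort("`Hb` must lie in (5, 25) g/dl.")
  if (SaO2 <= 0 || SaO2 > 1) abort("`SaO2` must lie in (0, 1].")
  if (PaO2 <= 0) abort("`PaO2` must be positive (kPa).")
  out <- tibble(Hb = Hb, SaO2 = SaO2, PaO2 = PaO2,
                plasma_glucose = plasma_glucose)
  class(out) <- c("blood_chemistry", class(out))
  out
}

# Oxygen content of blood at a given saturation/tension, in micromol O2/ml.
o2_content <- function(Hb, sat, po2_kpa) {
  ml_per_dl <- 1.34 * Hb * sat + 0.003 * (po2_kpa * KPA_TO_MMHG)
  # ml O2/dl -> mmol/100 ml -> micromol/ml
  ml_per_dl / O2_ML_PER_MMOL / 100 * 1000
}

#' Arterial oxygen content
#'
#' Haemoglobin-bound plus dissolved oxygen,
#' CaO2 = 1.34 Hb SaO2 + 0.003 PaO2\[mmHg\] in ml O2/dl, converted to
#' micromol O2 per ml blood via the 22.4 ml/mmol molar volume.
#'
#' @param blood A [blood_chemistry()] row.
#' @return CaO2 in micromol O2 per ml blood.
#' @export
#' @examples
#' arterial_o2_content(blood_chemistry(Hb = 15, SaO2 = 1, PaO2 = 13))
arterial_o2_content <- function(blood) {
  o2_content(blood$Hb, blood$SaO2, blood$PaO2)
}

#' Voxel-wise oxygen metabolism
#'
#' CMRO2 = CBF x OEF x CaO2 (micromol/100 ml/min), applied voxel-wise to
#' co-registered maps or element-wise to vectors.
#'
#' @param cbf CBF map/vector, ml/100 ml/min.
#' @param oef OEF map/vector, fraction.
#' @param cao2 Arterial oxygen content, micromol O2/ml.
#' @return CMRO2 with the shape of the inputs.
#' @export
#' @examples
#' cmro2_from_maps(40, 0.40, 8.0)
cmro2_from_maps <- function(cbf, oef, cao2) {
  if (!is.null(dim(cbf)) || !is.null(dim(oef))) check_same_dim(cbf, oef, "CBF/OEF maps")
  cbf * oef * cao2
}

#' Oxygen/glucose metabolic ratio
#'
#' Molar CMRO2/CMRG; about 6 when glucose is fully oxidized, lower where
#' non-oxidative glycolysis contributes. Zero oxygen metabolism gives 0;
#' zero glucose metabolism with non-zero CMRO2 is undefined and returned as
#' `NA` with a warning.
#'
#' @param cmro2 CMRO2, micromol/100 ml/min.
#' @param cmrg CMRG, micromol/100 ml/min.
#' @return Metabolic ratio, same shape as the inputs.
#' @export
#' @examples
#' metabolic_ratio(120, 20)
metabolic_ratio <- function(cmro2, cmrg) {
  und <- is.finite(cmrg) & cmrg <= 0 & is.finite(cmro2) & cmro2 > 0
  if (any(und)) warn("CMRG = 0 with CMRO2 > 0: metabolic ratio undefined (NA).")
  out <- ifelse(is.finite(cmro2) & cmro2 == 0, 0, cmro2 / cmrg)
  out[und] <- NA_real_
  out
}

#' Blood volume from an equilibrium blood-pool tracer
#'
#' CBV = 100 x tissue / (R x blood) in ml/100 ml, where R is the
#' small-to-large vessel haematocrit ratio (default 0.85). A simplified
#' equilibrium estimator for phantom data.
#'
#' @param tissue_activity Tissue concentration (same units as blood).
#' @param blood_activity Whole-blood concentration, > 0.
#' @param hct_ratio Small-to-large vessel haematocrit ratio.
#' @return CBV in ml/100 ml.
#' @export
#' @examples
#' cbv_from_equilibrium(0.034, 1, 0.85)
cbv_from_equilibrium <- function(tissue_activity, blood_activity,
                                 hct_ratio = 0.85) {
  if (any(blood_activity <= 0)) abort("`blood_activity` must be positive.")
  if (hct_ratio <= 0) abort("`hct_ratio` must be positive.")
  100 * tissue_activity / (hct_ratio * blood_activity)
}
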
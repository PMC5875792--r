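#' Optical geometry of the imaged eye
#'
#' The retinal magnification (`um_per_deg`) carries two documented
#' conventions for the mouse eye, which are mutually inconsistent in the
#' source measurements this package reproduces: `34.4` um/deg back-solves the
#' published retinal-irradiance values exactly, while `32.0` um/deg matches
#' the published field conversion (5 deg = 160 um). Neither is silently
#' preferred; pick the convention that matches the quantity you are checking.
#'
#' @param um_per_deg retinal magnification in micrometers per degree (> 0).
#' @param numerical_aperture eye NA (> 0); mouse ~0.49, human ~0.24.
#' @return An object of class `optical_geometry`.
#' @export
optical_geometry <- function(um_per_deg = 34.4, numerical_aperture = 0.49) {
  if (um_per_deg <= 0 || !is.finite(um_per_deg))
    stopf("um_per_deg must be positive and finite")
  if (numerical_aperture <= 0 || !is.finite(numerical_aperture))
    stopf("numerical_aperture must be positive and finite")
  structure(list(um_per_deg = um_per_deg,
                 numerical_aperture = numerical_aperture),
            class = "optical_geometry")
}

#' Mouse retinal magnification reproducing the published irradiance values
#' @export
UM_PER_DEG_DOSIMETRY <- 34.4

#' Mouse retinal magnification matching the published field conversion
#' (160 um / 5 deg)
#' @export
UM_PER_DEG_FIELD <- 32.0

#' ANSI Z136 maximum permissible exposure at 620 nm for up to 8 h, in uW.
#' Stored for report annotation only; not recomputed.
#' @export
MPE_620NM_8H_UW <- 40

#' Retinal irradiance of a uniform circular stimulus patch
#'
#' Divides the power entering the pupil by the retinal area of the stimulated
#' patch: `irradiance = power / (pi * (d/2 * um_per_deg -> cm)^2)`.
#'
#' @param power_uW stimulus power at the pupil in microwatts (>= 0).
#' @param patch_diameter_deg stimulated patch diameter in degrees (> 0).
#' @param geometry an [optical_geometry()].
#' @return irradiance in mW per cm^2, with the geometry attached as attribute
#'   `geometry`.
#' @export
retinal_irradiance <- function(power_uW, patch_diameter_deg,
                               geometry = optical_geometry()) {
  if (power_uW < 0) stopf("power_uW must be >= 0")
  if (patch_diameter_deg <= 0) stopf("patch_diameter_deg must be positive")
  radius_cm <- patch_diameter_deg / 2 * geometry$um_per_deg * 1e-4
  out <- (power_uW * 1e-3) / (pi * radius_cm^2)
  attr(out, "geometry") <- geometry
  out
}

#' Power scaling between eyes of different numerical aperture
#'
#' The retinal irradiance produced by a given pupil power scales with the
#' square of the eye's numerical aperture, so the power producing equivalent
#' irradiance in a target eye is `power * (na_source / na_target)^2` (e.g.
#' mouse 0.49 to human 0.24 scales 100 uW to 416.8 uW).
#'
#' @param power_uW power in the source eye, microwatts.
#' @param na_source,na_target numerical apertures (> 0).
#' @return equivalent power in microwatts.
#' @export
na_equivalent_power <- function(power_uW, na_source, na_target) {
  if (na_source <= 0 || na_target <= 0) stopf("numerical apertures must be positive")
  power_uW * (na_source / na_target)^2
}

#' Expected cell count in an imaging field from areal density
#'
#' @param density_per_mm2 cells per square millimeter (>= 0).
#' @param field_um length-2 `(width, height)` of the field in micrometers.
#' @return list with `expected` (real-valued product) and `rounded`
#'   (nearest integer).
#' @export
expected_cell_count <- function(density_per_mm2, field_um = c(160, 215)) {
  if (density_per_mm2 < 0) stopf("density must be >= 0")
  area_mm2 <- prod(field_um) * 1e-6
  x <- density_per_mm2 * area_mm2
  list(expected = x, rounded = round(x))
}

#' Convert a visual angle to retinal distance
#'
#' @param extent_deg extent in degrees.
#' @param geometry an [optical_geometry()].
#' @return micrometers on the retina.
#' @export
deg_to_um <- function(extent_deg, geometry = optical_geometry()) {
  if (!all(is.finite(extent_deg))) stopf("extent_deg must be finite")
  extent_deg * geometry$um_per_deg
}

#' Dosimetry summary table
#'
#' Convenience wrapper collecting the study's light-dosimetry arithmetic into
#' one data frame: retinal irradiance per stimulus, NA-equivalent human
#' power, and the expected melanopsin-cell count per field.
#'
#' @param stimuli data frame with columns `label`, `power_uW`,
#'   `patch_diameter_deg`.
#' @param geometry an [optical_geometry()] (dosimetry convention by default).
#' @param na_human human-eye numerical aperture.
#' @param melanopsin_density_per_mm2 areal density of M1+M2 ipRGCs.
#' @param field_um imaging-field size in micrometers.
#' @return data frame, one row per stimulus, plus attributes
#'   `expected_melanopsin` and `mpe_620nm_8h_uW`.
#' @export
dosimetry_table <- function(stimuli,
                            geometry = optical_geometry(UM_PER_DEG_DOSIMETRY),
                            na_human = 0.24,
                            melanopsin_density_per_mm2 = 60,
                            field_um = c(160, 215)) {
  out <- stimuli
  out$irradiance_mW_cm2 <- vapply(seq_len(nrow(stimuli)), function(i)
    as.numeric(retinal_irradiance(stimuli$power_uW[i],
                                  stimuli$patch_diameter_deg[i], geometry)),
    0)
  out$human_equiv_power_uW <- na_equivalent_power(
    stimuli$power_uW, geometry$numerical_aperture, na_human)
  attr(out, "expected_melanopsin") <-
    expected_cell_count(melanopsin_density_per_mm2, field_um)
  attr(out, "mpe_620nm_8h_uW") <- MPE_620NM_8H_UW
  out
}
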
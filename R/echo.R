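#' Canine body surface area (Meeh formula)
#'
#' `BSA = k * BW^(2/3)` with the classical canine Meeh constant
#' `k = 0.101` (m^2 with BW in kg).
#'
#' @param bw_kg Body weight, kg (> 0).
#' @param k Meeh constant.
#' @return BSA in m^2 (vectorized).
#' @export
bsa <- function(bw_kg, k = 0.101) {
  if (any(bw_kg <= 0)) stop("body weight must be > 0")
  k * bw_kg^(2 / 3)
}

#' Left ventricular mass (cube formula)
#'
#' `LVM (g) = 0.0008 * (1.04 * (LVEDD + LVPW + IVS)^3 - LVEDD^3 + 0.6)`
#' with all wall/diameter inputs in mm.  The `+0.6` term sits inside the
#' outer braces, as reported; `mode = "devereux"` uses the conventional
#' placement `0.0008 * 1.04 * ((...)^3 - LVEDD^3) + 0.6` for comparison
#' (the two differ by a few tenths of a gram at canine dimensions,
#' immaterial against masses of 45-85 g).
#'
#' @param lvedd_mm,lvpw_mm,ivs_mm Diameter and wall thicknesses, mm (> 0).
#' @param mode `"printed"` (default) or `"devereux"`.
#' @return LVM in grams (vectorized).
#' @export
lvm <- function(lvedd_mm, lvpw_mm, ivs_mm, mode = c("printed", "devereux")) {
  mode <- match.arg(mode)
  if (any(c(lvedd_mm, lvpw_mm, ivs_mm) <= 0))
    stop("all inputs must be > 0")
  s3 <- (lvedd_mm + lvpw_mm + ivs_mm)^3
  if (mode == "printed")
    0.0008 * (1.04 * s3 - lvedd_mm^3 + 0.6)
  else
    0.0008 * 1.04 * (s3 - lvedd_mm^3) + 0.6
}

#' Teichholz left ventricular volume
#'
#' Cube-based M-mode volume estimate `V = 7 D^3 / (2.4 + D)` with the
#' diameter D in cm (mm input is converted), yielding ml.  Applied to LVEDD
#' for end-diastolic and LVESD for end-systolic volume.
#'
#' @param d_mm Internal diameter, mm (> 0).
#' @return Volume in ml (vectorized).
#' @export
teichholz_volume <- function(d_mm) {
  if (any(d_mm <= 0)) stop("diameter must be > 0")
  d_cm <- d_mm / 10
  (7 / (2.4 + d_cm)) * d_cm^3
}

#' Ejection fraction
#'
#' `EF = 100 * (EDV - ESV) / EDV` percent; requires `EDV > ESV >= 0`.
#'
#' @param edv_ml,esv_ml End-diastolic and end-systolic volumes, ml.
#' @return EF in percent (vectorized).
#' @export
ef <- function(edv_ml, esv_ml) {
  if (any(esv_ml < 0)) stop("ESV must be >= 0")
  if (any(edv_ml <= esv_ml)) stop("EDV must exceed ESV")
  100 * (edv_ml - esv_ml) / edv_ml
}

#' Derive all echocardiographic indices of a panel
#'
#' Fills every derived field of an echo panel from the raw linear
#' measurements: BSA, LVM (and LVMi = LVM/BSA), Teichholz EDV/ESV, EF,
#' LAVi = LAV/BSA, and the per-BW and per-BSA normalizations of the raw
#' fields.  All derived fields are deterministic pure functions of the raw
#' fields; any component failure is re-raised annotated with the field
#' name.
#'
#' @param panel An `"echo_panel"` (see [generate_echo_panel()]) or any
#'   data frame with columns `ivs_mm`, `lvpw_mm`, `lvesd_mm`, `lvedd_mm`,
#'   `lav_ml`, `bw_kg`.
#' @param bsa_k Meeh constant passed to [bsa()].
#' @return The panel with derived columns `bsa_m2`, `lvm_g`, `lvmi_g_m2`,
#'   `edv_ml`, `esv_ml`, `ef_pct`, `lavi_ml_m2`, `ivs_bw_mm_kg`,
#'   `lvpw_bw_mm_kg`, `lvesd_bsa_mm_m2`, `lvedd_bsa_mm_m2`,
#'   `edv_bsa_ml_m2`, `esv_bsa_ml_m2`.
#' @export
derive_echo_panel <- function(panel, bsa_k = 0.101) {
  raw <- c("ivs_mm", "lvpw_mm", "lvesd_mm", "lvedd_mm", "lav_ml", "bw_kg")
  miss <- setdiff(raw, names(panel))
  if (length(miss))
    stop("missing raw field(s): ", paste(miss, collapse = ", "))
  with_field <- function(field, expr) {
    tryCatch(expr, error = function(e)
      stop(field, ": ", conditionMessage(e), call. = FALSE))
  }
  panel$bsa_m2 <- with_field("bsa_m2", bsa(panel$bw_kg, k = bsa_k))
  panel$lvm_g <- with_field("lvm_g",
                            lvm(panel$lvedd_mm, panel$lvpw_mm, panel$ivs_mm))
  panel$lvmi_g_m2 <- panel$lvm_g / panel$bsa_m2
  panel$edv_ml <- with_field("edv_ml", teichholz_volume(panel$lvedd_mm))
  panel$esv_ml <- with_field("esv_ml", teichholz_volume(panel$lvesd_mm))
  panel$ef_pct <- with_field("ef_pct", ef(panel$edv_ml, panel$esv_ml))
  panel$lavi_ml_m2 <- panel$lav_ml / panel$bsa_m2
  panel$ivs_bw_mm_kg <- panel$ivs_mm / panel$bw_kg
  panel$lvpw_bw_mm_kg <- panel$lvpw_mm / panel$bw_kg
  panel$lvesd_bsa_mm_m2 <- panel$lvesd_mm / panel$bsa_m2
  panel$lvedd_bsa_mm_m2 <- panel$lvedd_mm / panel$bsa_m2
  panel$edv_bsa_ml_m2 <- panel$edv_ml / panel$bsa_m2
  panel$esv_bsa_ml_m2 <- panel$esv_ml / panel$bsa_m2
  panel
}
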
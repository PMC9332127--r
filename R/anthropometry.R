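#' Body mass index
#'
#' @param mass_kg body mass, kg.
#' @param height_m height, m.
#' @return BMI, kg/m^2.
#' @export
bmi <- function(mass_kg, height_m) {
  if (any(height_m <= 0)) stop("height must be > 0", call. = FALSE)
  mass_kg / height_m^2
}

#' Skeletal muscle mass from bioelectrical impedance (Janssen equation)
#'
#' SMM (kg) = 0.401 x (height_cm^2 / resistance) + 3.825 x male - 0.071 x
#' age + 5.102, the whole-body BIA prediction equation for skeletal muscle
#' mass. Coefficients are configurable through the calibration list.
#' BIA assumes normal hydration; estimates exceeding the participant's
#' fat-free mass should be treated as data-quality flags (see
#' [derive_components()]'s cohort workflow), not corrected.
#'
#' @param height_cm height, cm.
#' @param resistance_ohm whole-body resistance, ohm.
#' @param sex `"male"` or `"female"`.
#' @param age_years age, years.
#' @param calib calibration list.
#' @return skeletal muscle mass, kg.
#' @export
#' @examples
#' janssen_smm(177, 500, "male", 67)  # ~29.3 kg
janssen_smm <- function(height_cm, resistance_ohm, sex = "male", age_years,
                        calib = default_calibration()) {
  if (any(resistance_ohm <= 0)) stop("resistance must be > 0", call. = FALSE)
  sex <- match.arg(sex, c("male", "female"), several.ok = TRUE)
  j <- calib$janssen
  j[["ht2_res"]] * height_cm^2 / resistance_ohm +
    j[["male"]] * as.numeric(sex == "male") +
    j[["age"]] * age_years + j[["intercept"]]
}

#' Katch-McArdle basal metabolic rate
#'
#' BMR (kcal/d) = 370 + 21.6 x fat-free mass (kg).
#'
#' @param ffm_kg fat-free mass, kg.
#' @param calib calibration list.
#' @return basal metabolic rate, kcal/d.
#' @export
katch_mcardle_bmr <- function(ffm_kg, calib = default_calibration()) {
  if (any(ffm_kg <= 0)) stop("ffm_kg must be > 0", call. = FALSE)
  k <- calib$katch_mcardle
  k[["intercept"]] + k[["slope"]] * ffm_kg
}

#' Chamber energy prescription
#'
#' The energy intake prescribed for a chamber stay is basal metabolic
#' rate times an activity factor (default 1.47, matching a day containing
#' three 30-min step-exercise bouts). The prescription is first issued
#' from the predicted (Katch-McArdle) BMR and then re-issued from the
#' resting metabolic rate measured in the chamber the next morning; the
#' `basis` argument records which was used.
#'
#' @param basal_kcal_d predicted BMR or measured RMR, kcal/d.
#' @param activity_factor multiplier applied to the basal rate.
#' @param basis `"predicted_bmr"` or `"measured_rmr"`.
#' @return list with `ei_kcal_d`, `activity_factor` and `basis`.
#' @export
energy_prescription <- function(basal_kcal_d, activity_factor = 1.47,
                                basis = c("predicted_bmr", "measured_rmr")) {
  if (any(basal_kcal_d <= 0)) stop("basal rate must be > 0", call. = FALSE)
  basis <- match.arg(basis)
  list(ei_kcal_d = basal_kcal_d * activity_factor,
       activity_factor = activity_factor, basis = basis)
}

#' Build the chamber diet from an energy prescription
#'
#' Splits prescribed energy into macronutrient grams at fixed energy
#' shares (default 45% carbohydrate, 20% protein, 35% fat) using Atwater
#' densities, so the macro energies re-sum to the prescription exactly.
#'
#' @param ei_kcal_d prescribed energy intake, kcal/d.
#' @param shares length-3 energy shares `c(cho, protein, fat)`; must sum
#'   to 1.
#' @param calib calibration list.
#' @return a [macronutrient_intake()] record.
#' @export
#' @examples
#' build_chamber_diet(2000)  # 225 g CHO, 100 g protein, ~77.8 g fat
build_chamber_diet <- function(ei_kcal_d, shares = c(0.45, 0.20, 0.35),
                               calib = default_calibration()) {
  if (ei_kcal_d < 0) stop("ei_kcal_d must be >= 0", call. = FALSE)
  if (length(shares) != 3 || abs(sum(shares) - 1) > 1e-9) {
    stop("`shares` must be three energy fractions summing to 1",
         call. = FALSE)
  }
  at <- calib$atwater
  macronutrient_intake(
    energy_kcal = ei_kcal_d,
    cho_g = shares[1] * ei_kcal_d / at[["cho"]],
    protein_g = shares[2] * ei_kcal_d / at[["protein"]],
    fat_g = shares[3] * ei_kcal_d / at[["fat"]],
    calib = calib
  )
}
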
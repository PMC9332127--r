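#' Default stoichiometric and device calibration constants
#'
#' Returns the full set of calibration constants used throughout the
#' package: the Brouwer coefficients that convert gas volumes and protein
#' oxidation into energy expenditure and substrate oxidation rates, the
#' abbreviated Weir coefficients, the urinary-nitrogen-to-protein factor,
#' Atwater energy densities, the Janssen bioelectrical-impedance
#' skeletal-muscle equation, the Katch-McArdle basal metabolic rate
#' formula, and a linear counts-to-PAL/AEE accelerometer calibration.
#'
#' The Brouwer set (per litre of gas, per gram of protein) is the standard
#' respiration-chamber form: carbohydrate (g) = 4.170 VCO2 - 2.965 VO2 -
#' 0.390 P; fat (g) = 1.718 (VO2 - VCO2) - 0.315 P; energy (kJ) = 16.20
#' VO2 + 5.00 VCO2 - 0.95 P. Protein oxidation P = 6.25 x urinary
#' nitrogen. The Weir abbreviated form is EE (kcal) = 3.941 VO2 + 1.106
#' VCO2 - 2.17 N. The accelerometer calibration is a placeholder at the
#' scale of healthy older adults wearing a wrist device and is not an
#' authoritative published equation; supply study-specific coefficients
#' via [read_calibration()] for real analyses.
#'
#' @param overrides optional named list merged over the defaults
#'   (recursively, via [utils::modifyList()]).
#' @return A named list of class `"calor_calibration"`.
#' @seealso [read_calibration()] to load overrides from a YAML file.
#' @export
#' @examples
#' cal <- default_calibration()
#' cal$brouwer$ee_kj
default_calibration <- function(overrides = NULL) {
  cal <- list(
    protein_factor = 6.25,
    brouwer = list(
      cho  = c(vco2 = 4.170, vo2 = -2.965, protein = -0.390),
      fat  = c(o2_co2_diff = 1.718, protein = -0.315),
      ee_kj = c(vo2 = 16.20, vco2 = 5.00, protein = -0.95)
    ),
    weir = c(vo2 = 3.941, vco2 = 1.106, nitrogen = -2.17),
    kj_per_kcal = 4.184,
    atwater = c(cho = 4, protein = 4, fat = 9),
    atwater_tolerance = 0.05,
    rq_range = c(0.65, 1.05),
    janssen = c(ht2_res = 0.401, male = 3.825, age = -0.071,
                intercept = 5.102),
    katch_mcardle = c(intercept = 370, slope = 21.6),
    accel_calibration = list(pal_intercept = 1.40, pal_slope = 6.0e-7,
                             aee_intercept_kcal_d = 300, aee_slope = 1.5e-3)
  )
  if (!is.null(overrides)) {
    stopifnot(is.list(overrides))
    cal <- merge_calibration(cal, overrides)
  }
  class(cal) <- c("calor_calibration", "list")
  cal
}

# Recursive merge that also merges named numeric vectors element-wise,
# so a partial override (e.g. only `weir$vo2`) keeps sibling defaults.
merge_calibration <- function(base, over) {
  for (nm in names(over)) {
    if (is.list(base[[nm]]) && is.list(over[[nm]])) {
      base[[nm]] <- merge_calibration(base[[nm]], over[[nm]])
    } else if (is.numeric(base[[nm]]) && !is.null(names(base[[nm]])) &&
               is.numeric(over[[nm]]) && !is.null(names(over[[nm]]))) {
      v <- base[[nm]]
      v[names(over[[nm]])] <- over[[nm]]
      base[[nm]] <- v
    } else {
      base[[nm]] <- over[[nm]]
    }
  }
  base
}

#' Read calibration overrides from a YAML file
#'
#' Loads a YAML file whose top-level keys mirror the structure of
#' [default_calibration()] (e.g. `brouwer:`, `weir:`, `protein_factor:`,
#' `atwater:`, `accel_calibration:`) and merges it over the shipped
#' defaults. Keys absent from the file keep their default values, so a
#' file may override a single coefficient.
#'
#' @param path path to a YAML file.
#' @return A `"calor_calibration"` list.
#' @export
read_calibration <- function(path) {
  stopifnot(file.exists(path))
  raw <- yaml::read_yaml(path)
  # yaml returns nested lists; collapse a block back to a named numeric
  # vector exactly where the corresponding default is one.
  shape <- function(x, ref) {
    if (is.numeric(ref) && !is.null(names(ref)) && is.list(x) &&
        all(vapply(x, is.numeric, TRUE)) && all(lengths(x) == 1L)) {
      return(unlist(x))
    }
    if (is.list(x) && is.list(ref)) {
      for (nm in intersect(names(x), names(ref))) {
        x[[nm]] <- shape(x[[nm]], ref[[nm]])
      }
    }
    x
  }
  default_calibration(overrides = shape(raw, default_calibration()))
}

#' @export
print.calor_calibration <- function(x, ...) {
  cat("Indirect calorimetry calibration\n")
  cat(sprintf("  protein = %.3f x urinary N\n", x$protein_factor))
  cat(sprintf("  Brouwer EE (kJ/L, kJ/g): VO2 %.2f, VCO2 %.2f, protein %.2f\n",
              x$brouwer$ee_kj[["vo2"]], x$brouwer$ee_kj[["vco2"]],
              x$brouwer$ee_kj[["protein"]]))
  cat(sprintf("  Weir EE (kcal): %.3f VO2 + %.3f VCO2 %+.2f N\n",
              x$weir[["vo2"]], x$weir[["vco2"]], x$weir[["nitrogen"]]))
  cat(sprintf("  Atwater (kcal/g): CHO %g, protein %g, fat %g\n",
              x$atwater[["cho"]], x$atwater[["protein"]], x$atwater[["fat"]]))
  invisible(x)
}
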
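#' Protein oxidation from urinary nitrogen
#'
#' Urinary nitrogen excretion is converted to grams of protein oxidized
#' using the conventional factor of 6.25 g protein per g nitrogen (mixed
#' dietary protein is ~16% nitrogen by mass).
#'
#' @param nitrogen_g urinary nitrogen excreted (g); vectorised.
#' @param calib calibration list from [default_calibration()].
#' @return grams of protein oxidized.
#' @export
#' @examples
#' protein_oxidation(16)   # 100 g
protein_oxidation <- function(nitrogen_g, calib = default_calibration()) {
  if (any(!is.finite(nitrogen_g)) || any(nitrogen_g < 0)) {
    stop("`nitrogen_g` must be finite and non-negative", call. = FALSE)
  }
  calib$protein_factor * nitrogen_g
}

#' Respiratory quotient
#'
#' @param vo2_l total (or rate of) oxygen consumption, L.
#' @param vco2_l total (or rate of) carbon dioxide production, L.
#' @return VCO2/VO2, dimensionless.
#' @export
respiratory_quotient <- function(vo2_l, vco2_l) {
  if (any(!is.finite(vo2_l)) || any(vo2_l <= 0)) {
    stop("`vo2_l` must be finite and > 0", call. = FALSE)
  }
  vco2_l / vo2_l
}

#' Brouwer energy expenditure and substrate oxidation
#'
#' Converts total gas volumes over a measurement window, together with the
#' grams of protein oxidized in that window, into energy expenditure and
#' carbohydrate/fat oxidation using the Brouwer stoichiometry (see
#' [default_calibration()] for the coefficient set). Energy is returned in
#' kcal. A respiratory quotient outside the physiological range flags the
#' result (`rq_flag`) rather than raising an error, so batch pipelines can
#' log and continue.
#'
#' @param vo2_l total oxygen consumed in the window, L (STPD).
#' @param vco2_l total carbon dioxide produced in the window, L (STPD).
#' @param protein_g grams of protein oxidized in the window.
#' @param window optional numeric length-2 window bounds in session
#'   minutes, carried through to the result.
#' @param calib calibration list.
#' @return An object of class `"substrate_rates"`: a list with elements
#'   `ee_kcal`, `cho_g`, `fat_g`, `protein_g`, `rq`, `window` and
#'   `rq_flag`.
#' @export
#' @examples
#' # one gram of glucosyl units: RQ = 1, ~4.2 kcal
#' brouwer_rates(0.829, 0.829)
brouwer_rates <- function(vo2_l, vco2_l, protein_g = 0, window = c(NA, NA),
                          calib = default_calibration()) {
  stopifnot(length(vo2_l) == 1, length(vco2_l) == 1, length(protein_g) == 1)
  if (!is.finite(vo2_l) || vo2_l <= 0) {
    stop("`vo2_l` must be finite and > 0", call. = FALSE)
  }
  if (!is.finite(vco2_l) || vco2_l <= 0) {
    stop("`vco2_l` must be finite and > 0", call. = FALSE)
  }
  if (!is.finite(protein_g) || protein_g < 0) {
    stop("`protein_g` must be finite and >= 0", call. = FALSE)
  }
  b <- calib$brouwer
  cho <- b$cho[["vco2"]] * vco2_l + b$cho[["vo2"]] * vo2_l +
    b$cho[["protein"]] * protein_g
  fat <- b$fat[["o2_co2_diff"]] * (vo2_l - vco2_l) +
    b$fat[["protein"]] * protein_g
  ee_kj <- b$ee_kj[["vo2"]] * vo2_l + b$ee_kj[["vco2"]] * vco2_l +
    b$ee_kj[["protein"]] * protein_g
  rq <- vco2_l / vo2_l
  rq_flag <- rq < calib$rq_range[1] || rq > calib$rq_range[2]
  if (rq_flag) {
    warning(sprintf("RQ %.3f outside physiological range [%.2f, %.2f]",
                    rq, calib$rq_range[1], calib$rq_range[2]), call. = FALSE)
  }
  structure(
    list(ee_kcal = ee_kj / calib$kj_per_kcal, cho_g = cho, fat_g = fat,
         protein_g = protein_g, rq = rq, window = window, rq_flag = rq_flag),
    class = "substrate_rates"
  )
}

#' @export
print.substrate_rates <- function(x, ...) {
  w <- if (all(is.finite(x$window))) {
    sprintf(" [%g, %g) min", x$window[1], x$window[2])
  } else ""
  cat(sprintf("Substrate oxidation%s\n", w))
  cat(sprintf("  EE %.1f kcal | RQ %.3f%s\n", x$ee_kcal, x$rq,
              if (isTRUE(x$rq_flag)) " (flagged)" else ""))
  cat(sprintf("  CHO %.1f g | fat %.1f g | protein %.1f g\n",
              x$cho_g, x$fat_g, x$protein_g))
  invisible(x)
}

#' Weir energy expenditure
#'
#' Abbreviated Weir equation: EE (kcal) = 3.941 VO2 + 1.106 VCO2 - 2.17 N,
#' with VO2/VCO2 in litres and urinary nitrogen N in grams. Used in the
#' chamber workflow to re-issue the day-2 energy prescription from the
#' measured resting metabolic rate.
#'
#' @inheritParams brouwer_rates
#' @param nitrogen_g urinary nitrogen excreted in the window, g.
#' @return energy expenditure, kcal.
#' @export
weir_ee <- function(vo2_l, vco2_l, nitrogen_g = 0,
                    calib = default_calibration()) {
  if (any(vo2_l < 0) || any(vco2_l < 0) || any(nitrogen_g < 0)) {
    stop("gas volumes and nitrogen must be non-negative", call. = FALSE)
  }
  calib$weir[["vo2"]] * vo2_l + calib$weir[["vco2"]] * vco2_l +
    calib$weir[["nitrogen"]] * nitrogen_g
}

#' Integrate a gas-exchange trace over a time window
#'
#' Sums rate samples into window totals using midpoint-in-window rectangle
#' integration at the trace's native resolution: a sample at time `t`
#' covers `[t, t + dt)` and is counted if its midpoint lies in
#' `[start, end)`. Gaps up to `max_gap_min` are filled by linear
#' interpolation (with a warning); larger gaps are an error.
#'
#' @param trace data frame with columns `t_min`, `vo2_lpm`, `vco2_lpm`
#'   (and optionally `activity_pct`), as read by [read_chamber_trace()].
#' @param window numeric length-2, `[start, end)` in session minutes.
#' @param interval sampling interval in minutes; inferred from the time
#'   column when `NULL`.
#' @param max_gap_min largest gap (minutes) repaired by interpolation.
#' @return named numeric vector `c(vo2_l = , vco2_l = )`, total litres.
#' @export
integrate_trace <- function(trace, window = c(0, 1440), interval = NULL,
                            max_gap_min = 5) {
  stopifnot(is.data.frame(trace),
            all(c("t_min", "vo2_lpm", "vco2_lpm") %in% names(trace)),
            length(window) == 2, window[2] > window[1])
  trace <- trace[order(trace$t_min), , drop = FALSE]
  trace <- fill_trace_gaps(trace, interval = interval,
                           max_gap_min = max_gap_min)
  dt <- attr(trace, "interval")
  mid <- trace$t_min + dt / 2
  keep <- mid >= window[1] & mid < window[2]
  c(vo2_l = sum(trace$vo2_lpm[keep]) * dt,
    vco2_l = sum(trace$vco2_lpm[keep]) * dt)
}

# Regularise a trace onto its native grid; interpolate small gaps, error
# on large ones. Returns the trace with an "interval" attribute.
fill_trace_gaps <- function(trace, interval = NULL, max_gap_min = 5) {
  t <- trace$t_min
  if (anyDuplicated(t)) stop("duplicated time points in trace", call. = FALSE)
  if (is.null(interval)) {
    interval <- if (length(t) > 1) min(diff(t)) else 1
  }
  full <- seq(min(t), max(t), by = interval)
  if (length(full) == length(t) && all(full == t)) {
    attr(trace, "interval") <- interval
    return(trace)
  }
  gaps <- diff(t)
  worst <- max(gaps)
  if (worst > max_gap_min) {
    at <- t[which.max(gaps)]
    stop(sprintf("trace gap of %g min starting at minute %g exceeds %g min",
                 worst, at, max_gap_min), call. = FALSE)
  }
  warning(sprintf("interpolating %d missing sample(s) across gaps <= %g min",
                  length(full) - length(t), max_gap_min), call. = FALSE)
  out <- data.frame(t_min = full)
  for (col in setdiff(names(trace), "t_min")) {
    out[[col]] <- stats::approx(t, trace[[col]], xout = full)$y
  }
  attr(out, "interval") <- interval
  out
}

#' Macronutrient intake record
#'
#' Bundles total energy intake with the macronutrient grams consumed and
#' checks the energy value against its Atwater (4/4/9 kcal/g)
#' reconstruction; a mismatch beyond the configured tolerance attaches a
#' warning flag.
#'
#' @param energy_kcal total energy intake, kcal.
#' @param cho_g,protein_g,fat_g grams consumed.
#' @param calib calibration list (Atwater factors and tolerance).
#' @return list of class `"macronutrient_intake"` with an
#'   `atwater_flag` element.
#' @export
macronutrient_intake <- function(energy_kcal, cho_g, protein_g, fat_g,
                                 calib = default_calibration()) {
  vals <- c(energy_kcal, cho_g, protein_g, fat_g)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("intake values must be finite and non-negative", call. = FALSE)
  }
  at <- calib$atwater
  recon <- at[["cho"]] * cho_g + at[["protein"]] * protein_g +
    at[["fat"]] * fat_g
  flag <- energy_kcal > 0 &&
    abs(recon - energy_kcal) / energy_kcal > calib$atwater_tolerance
  if (flag) {
    warning(sprintf(
      "Atwater reconstruction (%.0f kcal) differs from stated energy (%.0f kcal) by > %.0f%%",
      recon, energy_kcal, 100 * calib$atwater_tolerance), call. = FALSE)
  }
  structure(list(energy_kcal = energy_kcal, cho_g = cho_g,
                 protein_g = protein_g, fat_g = fat_g,
                 atwater_flag = flag),
            class = "macronutrient_intake")
}

#' Intake-minus-oxidation substrate and energy balances
#'
#' Macronutrient balances are intake minus oxidation over the same 24-h
#' period (g/d); energy balance is energy intake minus total energy
#' expenditure (kcal/d).
#'
#' @param intake a [macronutrient_intake()] record.
#' @param oxidation a `"substrate_rates"` object covering the same period
#'   (24-h totals).
#' @param tee_kcal total energy expenditure for the period, kcal.
#' @return list of class `"substrate_balance"` with `protein_bal_g`,
#'   `cho_bal_g`, `fat_bal_g` and `eb_kcal`.
#' @export
substrate_balances <- function(intake, oxidation, tee_kcal) {
  stopifnot(inherits(intake, "macronutrient_intake"),
            inherits(oxidation, "substrate_rates"),
            is.finite(tee_kcal))
  structure(
    list(protein_bal_g = intake$protein_g - oxidation$protein_g,
         cho_bal_g = intake$cho_g - oxidation$cho_g,
         fat_bal_g = intake$fat_g - oxidation$fat_g,
         eb_kcal = intake$energy_kcal - tee_kcal),
    class = "substrate_balance"
  )
}
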
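#' Apply the accelerometer wear-time inclusion rule
#'
#' A free-living week is usable when at least `min_days` days have at
#' least `min_wear_min` minutes of valid wear (default: 5 days of >= 10
#' h). Days failing the wear rule are dropped; if too few remain the
#' participant's week is excluded with an error the caller can catch and
#' record.
#'
#' @param days data frame with columns `day_index`, `counts`, `wear_min`.
#' @param min_wear_min minimum wear time per day, minutes.
#' @param min_days minimum number of valid days.
#' @param id optional participant label used in the exclusion message.
#' @return the subset of `days` passing the wear rule.
#' @export
validate_wear <- function(days, min_wear_min = 600, min_days = 5,
                          id = NULL) {
  stopifnot(is.data.frame(days),
            all(c("counts", "wear_min") %in% names(days)))
  if (any(days$counts < 0) || any(days$wear_min < 0 | days$wear_min > 1440)) {
    stop("counts must be >= 0 and wear_min in [0, 1440]", call. = FALSE)
  }
  keep <- days[days$wear_min >= min_wear_min, , drop = FALSE]
  if (nrow(keep) < min_days) {
    stop(sprintf(
      "participant %s excluded: only %d day(s) with >= %g min wear (need %d)",
      if (is.null(id)) "?" else id, nrow(keep), min_wear_min, min_days),
      call. = FALSE)
  }
  keep
}

#' Estimate PAL and activity energy expenditure from daily counts
#'
#' Linear counts-to-energy calibration: `pal = pal_intercept + pal_slope x
#' counts` and `aee = aee_intercept + aee_slope x counts`, with
#' coefficients taken from the calibration list's `accel_calibration`
#' block. The shipped coefficients are placeholders at the scale of
#' healthy older adults and must be replaced with the study's published
#' calibration for real analyses. An estimated PAL below 1 is clamped to
#' 1 with a warning, since total energy expenditure cannot fall below the
#' resting rate.
#'
#' @param mean_counts mean accelerometer counts per day over valid days.
#' @param calib calibration list.
#' @return list with `pal` and `aee_kcal_d`.
#' @export
estimate_pal_aee <- function(mean_counts, calib = default_calibration()) {
  if (any(mean_counts < 0)) stop("mean_counts must be >= 0", call. = FALSE)
  a <- calib$accel_calibration
  if (a$pal_slope < 0 || a$aee_slope < 0) {
    stop("accelerometer calibration slopes must be non-negative",
         call. = FALSE)
  }
  pal <- a$pal_intercept + a$pal_slope * mean_counts
  if (any(pal < 1)) {
    warning("estimated PAL < 1 clamped to 1", call. = FALSE)
    pal <- pmax(pal, 1)
  }
  list(pal = pal,
       aee_kcal_d = a$aee_intercept_kcal_d + a$aee_slope * mean_counts)
}

#' Free-living total energy expenditure from chamber RMR and PAL
#'
#' @param rmr_kcal_d resting metabolic rate measured in the chamber,
#'   kcal/d.
#' @param pal physical activity level estimated from accelerometry.
#' @return total energy expenditure, kcal/d.
#' @export
tee_from_pal <- function(rmr_kcal_d, pal) {
  if (any(rmr_kcal_d <= 0)) stop("rmr_kcal_d must be > 0", call. = FALSE)
  if (any(pal < 1)) stop("pal must be >= 1", call. = FALSE)
  rmr_kcal_d * pal
}

#' Free-living energy balance and self-report underreporting
#'
#' Energy balance is self-reported intake minus accelerometry-estimated
#' total expenditure. Under weight stability a persistent negative
#' balance is evidence of self-report underreporting, quantified as
#' `100 x (TEE - EI) / TEE`; the returned `caveat` records that this
#' interpretation assumes stable body mass.
#'
#' @param self_report_ei_kcal_d self-reported energy intake, kcal/d.
#' @param tee_accel_kcal_d accelerometry-estimated total energy
#'   expenditure, kcal/d.
#' @return list with `eb_kcal_d`, `underreporting_pct` and `caveat`.
#' @export
free_living_energy_balance <- function(self_report_ei_kcal_d,
                                       tee_accel_kcal_d) {
  if (any(self_report_ei_kcal_d <= 0) || any(tee_accel_kcal_d <= 0)) {
    stop("intake and expenditure must be > 0", call. = FALSE)
  }
  list(eb_kcal_d = self_report_ei_kcal_d - tee_accel_kcal_d,
       underreporting_pct = 100 * (tee_accel_kcal_d - self_report_ei_kcal_d) /
         tee_accel_kcal_d,
       caveat = "underreporting interpretation assumes weight stability")
}

#' Summarise a free-living accelerometer week
#'
#' Applies the wear-time rule, averages counts over the valid days, and
#' derives PAL, activity energy expenditure and total energy expenditure
#' anchored to the chamber resting metabolic rate.
#'
#' @param days data frame of daily summaries (see [validate_wear()]).
#' @param rmr_kcal_d chamber resting metabolic rate, kcal/d.
#' @param calib calibration list.
#' @param id optional participant label.
#' @return list of class `"free_living_summary"` with
#'   `mean_counts_per_day`, `valid_days`, `pal_accel`, `aee_accel_kcal_d`
#'   and `tee_accel_kcal_d`.
#' @export
free_living_summary <- function(days, rmr_kcal_d,
                                calib = default_calibration(), id = NULL) {
  valid <- validate_wear(days, id = id)
  mean_counts <- mean(valid$counts)
  est <- estimate_pal_aee(mean_counts, calib)
  structure(list(
    mean_counts_per_day = mean_counts,
    valid_days = nrow(valid),
    pal_accel = est$pal,
    aee_accel_kcal_d = est$aee_kcal_d,
    tee_accel_kcal_d = tee_from_pal(rmr_kcal_d, est$pal)
  ), class = "free_living_summary")
}
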
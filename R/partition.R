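#' Total 24-h energy expenditure
#'
#' Brouwer energy expenditure integrated over the full 2000-2000 h
#' measurement day, using both 12-h urinary nitrogen collections for the
#' protein correction, expressed as kcal/d.
#'
#' @param session a [chamber_session()].
#' @param calib calibration list.
#' @return total energy expenditure, kcal/d.
#' @export
total_ee <- function(session, calib = default_calibration()) {
  gas <- integrate_trace(session$trace, c(0, 1440),
                         interval = session$interval)
  p <- protein_in_window(session, c(0, 1440), calib)
  br <- brouwer_rates(gas[["vo2_l"]], gas[["vco2_l"]], p,
                      window = c(0, 1440), calib = calib)
  br$ee_kcal
}

# Sliding-window means of a minute series via cumulative sums.
# Returns means of windows [starts, starts + len) for every feasible
# start on the native grid.
window_means <- function(t, x, range_min, range_max, len, dt) {
  idx <- which(t >= range_min & t < range_max)
  if (!length(idx)) return(NULL)
  t0 <- t[idx]; x0 <- x[idx]
  if (length(t0) * dt < len || any(diff(t0) != dt)) return(NULL)
  n_win <- length(x0) - len / dt + 1
  if (n_win < 1) return(NULL)
  cs <- c(0, cumsum(x0))
  k <- len / dt
  means <- (cs[(k + 1):(length(cs))] - cs[1:n_win]) / k
  list(start = t0[1:n_win], mean = means)
}

#' Detect sleeping metabolic rate
#'
#' SMR is the lowest mean energy expenditure over any continuous 3-h
#' window fully inside 0000-0600 h (session minutes 240-600), found by
#' sliding a 180-min window at the trace's native resolution. Ties are
#' broken by earliest start. The window mean is extrapolated to 24 h.
#'
#' @param session a [chamber_session()].
#' @param window_min window length, minutes.
#' @param search search bounds in session minutes.
#' @param calib calibration list.
#' @return list with `window` (`c(start, end)` in session minutes) and
#'   `smr_kcal_d`.
#' @export
detect_smr <- function(session, window_min = 180, search = c(240, 600),
                       calib = default_calibration()) {
  em <- minute_energy(session, calib)
  wm <- window_means(em$t_min, em$ee_kcal_min, search[1], search[2],
                     window_min, session$interval)
  if (is.null(wm)) {
    stop(sprintf(
      "need %d min of contiguous data in [%g, %g) to detect SMR",
      window_min, search[1], search[2]), call. = FALSE)
  }
  # earliest window within numerical tolerance of the minimum (exact
  # ties arise on constant traces, where cumsum rounding must not bias
  # the tie-break away from the earliest start)
  i <- which(wm$mean <= min(wm$mean) + 1e-10)[1]
  list(window = c(wm$start[i], wm$start[i] + window_min),
       smr_kcal_d = wm$mean[i] * 1440)
}

#' Detect resting metabolic rate
#'
#' RMR is measured supine but awake during the 0700-0800 h rest period;
#' after discarding the first 20 and last 10 min, the least restless
#' consecutive 20-min window between 0720 and 0750 h (session minutes
#' 680-710) is selected by minimising mean radar activity. Ties are broken
#' by lower mean energy expenditure, then by earliest start. If the
#' activity channel is missing, the window minimising the variance of
#' energy expenditure is used instead (with a warning).
#'
#' @param session a [chamber_session()].
#' @param window_min window length, minutes.
#' @param search search bounds in session minutes (window must fit inside).
#' @param calib calibration list.
#' @return list with `window` and `rmr_kcal_d`.
#' @export
detect_rmr <- function(session, window_min = 20, search = c(680, 710),
                       calib = default_calibration()) {
  em <- minute_energy(session, calib)
  dt <- session$interval
  idx <- which(em$t_min >= search[1] & em$t_min < search[2])
  if (!length(idx) || length(idx) * dt < window_min ||
      any(diff(em$t_min[idx]) != dt)) {
    stop(sprintf("need contiguous data across [%g, %g) to detect RMR",
                 search[1], search[2]), call. = FALSE)
  }
  k <- window_min / dt
  starts <- idx[seq_len(length(idx) - k + 1)]
  win_stat <- function(x, f) {
    vapply(starts, function(s) f(x[s:(s + k - 1)]), numeric(1))
  }
  mean_ee <- win_stat(em$ee_kcal_min, mean)
  act <- em$activity_pct
  if (all(!is.finite(act[idx]))) {
    warning("activity channel missing; selecting RMR window by EE variance",
            call. = FALSE)
    crit1 <- win_stat(em$ee_kcal_min, stats::var)
    crit2 <- mean_ee
  } else {
    crit1 <- win_stat(act, mean)
    crit2 <- mean_ee
  }
  # lexicographic tie-break: crit1, then mean EE, then earliest start
  best <- order(crit1, crit2, em$t_min[starts])[1]
  s <- em$t_min[starts[best]]
  list(window = c(s, s + window_min), rmr_kcal_d = mean_ee[best] * 1440)
}

#' Steady-state exercise energy expenditure
#'
#' The energy cost of a scheduled step-exercise bout is the mean energy
#' expenditure over the longest window (at least `min_window` min) inside
#' the bout for which the coefficients of variation of both gas channels
#' are at or below `cv_threshold_pct`. Among equally long qualifying
#' windows the earliest is taken.
#'
#' @param session a [chamber_session()].
#' @param bout_index which exercise bout (1-based, in start order).
#' @param cv_threshold_pct steady-state CV threshold, % (both gases).
#' @param min_window minimum steady-state window, minutes.
#' @param calib calibration list.
#' @return list with `window`, `cv_vo2_pct`, `cv_vco2_pct` and
#'   `mean_ee_kcal_min`.
#' @export
exercise_ee <- function(session, bout_index = 1, cv_threshold_pct = 10,
                        min_window = 5, calib = default_calibration()) {
  bouts <- session$exercise_bouts[order(session$exercise_bouts$start_min), ,
                                  drop = FALSE]
  if (bout_index < 1 || bout_index > nrow(bouts)) {
    stop("no such exercise bout", call. = FALSE)
  }
  b <- bouts[bout_index, ]
  tr <- session$trace
  em <- minute_energy(session, calib)
  dt <- session$interval
  idx <- which(tr$t_min >= b$start_min &
                 tr$t_min < b$start_min + b$duration_min)
  if (length(idx) * dt < min_window) {
    stop("insufficient data within the bout", call. = FALSE)
  }
  cv <- function(x) 100 * stats::sd(x) / mean(x)
  best_cv <- c(Inf, Inf)
  k_min <- max(2L, as.integer(round(min_window / dt)))
  for (k in rev(seq(k_min, length(idx)))) {   # longest window first
    for (s in seq_len(length(idx) - k + 1)) {
      w <- idx[s:(s + k - 1)]
      cvs <- c(cv(tr$vo2_lpm[w]), cv(tr$vco2_lpm[w]))
      if (all(cvs <= cv_threshold_pct)) {
        return(list(
          window = c(tr$t_min[w[1]], tr$t_min[w[k]] + dt),
          cv_vo2_pct = cvs[1], cv_vco2_pct = cvs[2],
          mean_ee_kcal_min = mean(em$ee_kcal_min[w])
        ))
      }
      if (sum(cvs) < sum(best_cv)) best_cv <- cvs
    }
  }
  stop(sprintf(
    "no steady-state window (>= %g min with both gas CVs <= %g%%); best CVs VO2 %.1f%%, VCO2 %.1f%%",
    min_window, cv_threshold_pct, best_cv[1], best_cv[2]), call. = FALSE)
}

#' Intercept-method partition of sedentary and activity energy
#'
#' Bins energy expenditure (kcal/min) and radar activity (%) into
#' fixed-width bins over the whole day, excludes bins overlapping an
#' exercise bout or its post-exercise washout, and fits ordinary least
#' squares `EE = alpha + beta * activity`. The zero-activity intercept
#' extrapolated to 24 h estimates sedentary energy expenditure (the fed,
#' at-rest cost of the day); the slope prices spontaneous activity in
#' kcal/min per radar %.
#'
#' @param session a [chamber_session()].
#' @param bin_min bin width, minutes.
#' @param washout_min minutes excluded after each exercise bout (excess
#'   post-exercise oxygen consumption would otherwise contaminate the
#'   activity slope).
#' @param min_bins minimum usable bins.
#' @param calib calibration list.
#' @return list with `sedentary_ee_kcal_d`, `spa_slope_kcal_min_per_pct`,
#'   `r_squared`, `n_bins` and `slope_flag` (TRUE when the fitted slope is
#'   negative).
#' @export
intercept_partition <- function(session, bin_min = 15, washout_min = 15,
                                min_bins = 24, calib = default_calibration()) {
  em <- minute_energy(session, calib)
  bins <- bin_day(em$t_min, em$ee_kcal_min, em$activity_pct, bin_min,
                  session$exercise_bouts, washout_min)
  if (nrow(bins) < min_bins) {
    stop(sprintf("only %d usable bins (need >= %d)", nrow(bins), min_bins),
         call. = FALSE)
  }
  if (stats::var(bins$activity) == 0) {
    stop("activity is constant across bins; intercept regression is degenerate",
         call. = FALSE)
  }
  fit <- stats::lm(ee ~ activity, data = bins)
  beta <- unname(stats::coef(fit))
  slope_flag <- beta[2] < 0
  if (slope_flag) {
    warning("negative activity slope: activity should cost energy",
            call. = FALSE)
  }
  r2 <- 1 - sum(stats::resid(fit)^2) / sum((bins$ee - mean(bins$ee))^2)
  list(sedentary_ee_kcal_d = beta[1] * 1440,
       spa_slope_kcal_min_per_pct = beta[2],
       r_squared = r2,
       n_bins = nrow(bins),
       slope_flag = slope_flag)
}

# Fixed-width bin means of EE and activity with exercise/washout bins
# dropped; shared between the estimator and the simulator's internal
# consistency calibration.
bin_day <- function(t, ee, activity, bin_min, bouts, washout_min) {
  bin <- floor(t / bin_min)
  keep_bin <- !is.na(bin)
  if (nrow(bouts)) {
    for (i in seq_len(nrow(bouts))) {
      ex0 <- bouts$start_min[i]
      ex1 <- bouts$start_min[i] + bouts$duration_min[i] + washout_min
      # a bin overlaps the exclusion zone if any part of it does
      bad <- seq(floor(ex0 / bin_min), floor((ex1 - 1e-9) / bin_min))
      keep_bin <- keep_bin & !(bin %in% bad)
    }
  }
  ok <- keep_bin & is.finite(ee) & is.finite(activity)
  if (!any(ok)) return(data.frame(ee = numeric(0), activity = numeric(0)))
  ee_b <- tapply(ee[ok], bin[ok], mean)
  ac_b <- tapply(activity[ok], bin[ok], mean)
  data.frame(ee = as.numeric(ee_b), activity = as.numeric(ac_b))
}

#' Derive the full 24-h energy component decomposition
#'
#' Runs the component pipeline on one chamber session: total energy
#' expenditure, sleeping and resting metabolic rate, the intercept-method
#' sedentary/activity split, and per-bout steady-state exercise cost; then
#' assembles diet-induced thermogenesis (sedentary EE minus SMR), activity
#' energy expenditure (TEE minus sedentary EE), spontaneous physical
#' activity (AEE minus net exercise cost, where each bout's net cost is
#' its steady-state rate minus the sedentary rate times its duration),
#' the physical activity level TEE/RMR, and the 24-h radar activity
#' percentage.
#'
#' Negative DIT or SPA values are reported with a quality flag rather
#' than clamped; modest negative values are legitimate outputs on noisy
#' days.
#'
#' @param session a [chamber_session()].
#' @param calib calibration list.
#' @param ... passed to [intercept_partition()] (e.g. `bin_min`,
#'   `washout_min`).
#' @return list of class `"energy_components"`.
#' @export
derive_components <- function(session, calib = default_calibration(), ...) {
  tee <- total_ee(session, calib)
  smr <- detect_smr(session, calib = calib)
  rmr <- detect_rmr(session, calib = calib)
  ip <- intercept_partition(session, calib = calib, ...)
  sed <- ip$sedentary_ee_kcal_d
  sed_rate <- sed / 1440
  nb <- nrow(session$exercise_bouts)
  ex <- vector("list", nb)
  net_ex <- 0
  if (nb) {
    for (i in seq_len(nb)) {
      ex[[i]] <- exercise_ee(session, i, calib = calib)
      net_ex <- net_ex + (ex[[i]]$mean_ee_kcal_min - sed_rate) *
        session$exercise_bouts$duration_min[order(
          session$exercise_bouts$start_min)][i]
    }
  }
  dit <- sed - smr$smr_kcal_d
  aee <- tee - sed
  spa <- aee - net_ex
  act <- session$trace$activity_pct
  structure(list(
    tee_kcal_d = tee,
    smr_kcal_d = smr$smr_kcal_d, smr_window = smr$window,
    rmr_kcal_d = rmr$rmr_kcal_d, rmr_window = rmr$window,
    sedentary_ee_kcal_d = sed,
    dit_kcal_d = dit,
    dit_pct_ei = 100 * dit / session$diet$energy_kcal,
    aee_kcal_d = aee,
    spa_kcal_d = spa,
    net_exercise_kcal_d = net_ex,
    exercise_ee_kcal_min = vapply(ex, function(e) e$mean_ee_kcal_min,
                                  numeric(1)),
    exercise_windows = lapply(ex, `[[`, "window"),
    pal = tee / rmr$rmr_kcal_d,
    activity_pct_24h = mean(act[is.finite(act)]),
    spa_slope_kcal_min_per_pct = ip$spa_slope_kcal_min_per_pct,
    fit = ip[c("r_squared", "n_bins", "slope_flag")],
    flags = c(negative_dit = dit < 0, negative_spa = spa < 0)
  ), class = "energy_components")
}

#' @export
print.energy_components <- function(x, ...) {
  cat("24-h energy expenditure components (kcal/d)\n")
  cat(sprintf("  TEE %8.0f   PAL %.2f   activity %.1f%%\n",
              x$tee_kcal_d, x$pal, x$activity_pct_24h))
  cat(sprintf("  SMR %8.0f   [%g, %g) min\n", x$smr_kcal_d,
              x$smr_window[1], x$smr_window[2]))
  cat(sprintf("  RMR %8.0f   [%g, %g) min\n", x$rmr_kcal_d,
              x$rmr_window[1], x$rmr_window[2]))
  cat(sprintf("  sedentary %.0f   DIT %.0f (%.1f%% of EI)%s\n",
              x$sedentary_ee_kcal_d, x$dit_kcal_d, x$dit_pct_ei,
              if (x$flags[["negative_dit"]]) " [flag]" else ""))
  cat(sprintf("  AEE %.0f = SPA %.0f + exercise %.0f%s\n",
              x$aee_kcal_d, x$spa_kcal_d, x$net_exercise_kcal_d,
              if (x$flags[["negative_spa"]]) " [flag]" else ""))
  if (length(x$exercise_ee_kcal_min)) {
    cat(sprintf("  bout EE: %s kcal/min\n",
                paste(sprintf("%.2f", x$exercise_ee_kcal_min),
                      collapse = ", ")))
  }
  invisible(x)
}

#' Convert a change in 24-h activity percentage to minutes per day
#'
#' A change of `delta_activity_pct` percentage points of the day
#' corresponds to `1440 * delta/100` minutes, reported to the nearest
#' minute (e.g. a 1.9 point reduction is 27 min/d).
#'
#' @param delta_activity_pct change in activity, percentage points of the
#'   24-h day.
#' @return minutes per day (rounded).
#' @export
activity_fraction_minutes <- function(delta_activity_pct) {
  if (any(abs(delta_activity_pct) > 100)) {
    stop("|delta_activity_pct| cannot exceed 100", call. = FALSE)
  }
  round(1440 * delta_activity_pct / 100)
}

#' Scheduled step count of a chamber day
#'
#' Total steps prescribed by a session's step-exercise schedule
#' (step rate x duration summed over bouts).
#'
#' @param exercise_bouts data frame with `duration_min` and `step_rate`,
#'   or a [chamber_session()].
#' @return total steps.
#' @export
chamber_step_count <- function(exercise_bouts) {
  if (inherits(exercise_bouts, "chamber_session")) {
    exercise_bouts <- exercise_bouts$exercise_bouts
  }
  sum(exercise_bouts$duration_min * exercise_bouts$step_rate)
}

#' Physical activity level
#'
#' @param tee_kcal_d total energy expenditure, kcal/d.
#' @param rmr_kcal_d resting metabolic rate, kcal/d.
#' @return TEE/RMR, dimensionless.
#' @export
physical_activity_level <- function(tee_kcal_d, rmr_kcal_d) {
  if (any(rmr_kcal_d <= 0)) stop("rmr_kcal_d must be > 0", call. = FALSE)
  tee_kcal_d / rmr_kcal_d
}
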
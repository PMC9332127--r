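#' Invert the Brouwer equation: gas volumes from energy and RQ
#'
#' Solves the 2x2 linear system `{c1 vo2 + c2 vco2 = ee_kj - cp P,
#' vco2 = rq vo2}` for the configured Brouwer coefficients, so that
#' [brouwer_rates()] applied to the output reproduces the requested
#' energy expenditure, respiratory quotient and protein oxidation to
#' numerical precision. This is the generative core of the chamber
#' simulator.
#'
#' @param ee_kcal energy expenditure over the interval, kcal; vectorised.
#' @param rq respiratory quotient, in `[0.65, 1.05]`.
#' @param protein_g grams of protein oxidized over the interval.
#' @param calib calibration list.
#' @return list with `vo2_l` and `vco2_l` (litres over the interval; if
#'   `ee_kcal` is a per-minute rate these are L/min).
#' @export
#' @examples
#' g <- gas_from_energy(5, 1, 0)       # RQ 1: vo2 = vco2 = 0.9868 L
#' brouwer_rates(g$vo2_l, g$vco2_l)$ee_kcal
gas_from_energy <- function(ee_kcal, rq, protein_g = 0,
                            calib = default_calibration()) {
  if (any(ee_kcal <= 0)) stop("ee_kcal must be > 0", call. = FALSE)
  if (any(rq < 0.65 | rq > 1.05)) {
    stop("rq must lie in [0.65, 1.05]", call. = FALSE)
  }
  if (any(protein_g < 0)) stop("protein_g must be >= 0", call. = FALSE)
  b <- calib$brouwer$ee_kj
  vo2 <- (ee_kcal * calib$kj_per_kcal - b[["protein"]] * protein_g) /
    (b[["vo2"]] + b[["vco2"]] * rq)
  if (any(vo2 <= 0)) {
    stop("non-positive gas volume: infeasible (ee, rq, protein) combination",
         call. = FALSE)
  }
  list(vo2_l = vo2, vco2_l = rq * vo2)
}

#' Simulation parameters for a synthetic chamber session
#'
#' Returns the parameter list consumed by [simulate_session()], with
#' defaults emulating one 2000-2000 h chamber day of a healthy older man
#' at energy balance: a circadian resting curve whose trough is planted
#' overnight, meal-locked diet-induced thermogenesis (exponential decay),
#' radar activity generated as an episodic (alternating quiet/active)
#' process coupled to energy expenditure through `spa_slope`, three
#' scheduled 30-min step-exercise bouts at 0830, 1445 and 1915 h
#' (75 steps/min), a protein-oxidation schedule split between the
#' overnight and daytime urine collections, and multiplicative Gaussian
#' measurement noise on both gas channels.
#'
#' Two shape parameters are calibrated internally by the generator rather
#' than set directly: the circadian trough amplitude is solved so the
#' lowest 3-h overnight window of the noiseless day equals `smr_kcal_d`,
#' and the waking (upright/fed) elevation above the supine resting rate is
#' solved so the zero-activity intercept of the binned noiseless day
#' equals `(smr_kcal_d + dit_fraction * ei_kcal_d)/1440`. This makes the
#' ground-truth ledger internally consistent: sedentary EE = SMR + DIT
#' holds exactly for the noiseless session under the package's own
#' component definitions, so recovery errors measure measurement noise,
#' not model mismatch.
#'
#' @param rmr_kcal_d resting metabolic rate (supine, awake, fasted),
#'   kcal/d; sets the resting rate in the 0720-0750 h window.
#' @param smr_kcal_d sleeping metabolic rate target, kcal/d (lowest 3-h
#'   overnight window); must not exceed what the night can reach.
#' @param ei_kcal_d chamber diet energy, kcal/d.
#' @param dit_fraction fraction of energy intake routed to meal-locked
#'   thermogenesis, in `[0, 0.15]`.
#' @param meals data frame `start_min`, `share` (shares of EI and of DIT).
#' @param dit_decay_min exponential decay constant of each meal's
#'   thermogenic response, minutes.
#' @param spa_slope energy cost of radar activity, kcal/min per activity %.
#' @param exercise data frame `start_min`, `duration_min`, `step_rate`,
#'   `gross_kcal_min` for the scheduled bouts.
#' @param ex_transient_min on-transient length at the start of each bout,
#'   minutes (EE ramps through low values before the steady-state
#'   plateau).
#' @param activity list of episodic-process settings for `waking` and
#'   `sleep` states: `quiet_mean_min`, `active_mean_min`, `level_range`,
#'   `base_pct`.
#' @param activity_level_mult multiplier on active-episode levels
#'   (interventions that suppress spontaneous activity scale this down).
#' @param sleep_onset_min,wake_min sleep period bounds, session minutes.
#' @param rest_window supine rest period for the RMR measurement.
#' @param trough_window support of the circadian trough, session minutes.
#' @param target_rq_24h 24-h respiratory quotient of the gas totals.
#' @param protein_ox_g_d protein oxidized over 24 h, g.
#' @param overnight_fraction fraction of protein oxidation in the
#'   overnight (2000-0800 h) collection.
#' @param diet_shares energy shares `c(cho, protein, fat)` of the chamber
#'   diet.
#' @param noise_sd_pct multiplicative Gaussian noise SD on each gas
#'   channel, %.
#' @param sampling_interval_min trace resolution, minutes.
#' @param restless_spike optional `c(start_min, end_min, level_pct)`
#'   activity artefact (e.g. to plant restlessness in the RMR window).
#' @return list of class `"sim_params"`.
#' @export
sim_params <- function(rmr_kcal_d = 1625,
                       smr_kcal_d = 1570,
                       ei_kcal_d = 2450,
                       dit_fraction = 0.06,
                       meals = data.frame(start_min = c(795, 1020, 1320),
                                          share = c(0.30, 0.35, 0.35)),
                       dit_decay_min = 120,
                       spa_slope = 0.022,
                       exercise = data.frame(start_min = c(750, 1125, 1395),
                                             duration_min = 30,
                                             step_rate = 75,
                                             gross_kcal_min = 4.8),
                       ex_transient_min = 5,
                       activity = list(
                         waking = list(quiet_mean_min = 14,
                                       active_mean_min = 6,
                                       level_range = c(30, 80),
                                       base_pct = 3),
                         sleep = list(quiet_mean_min = 120,
                                      active_mean_min = 2,
                                      level_range = c(2, 8),
                                      base_pct = 0.5)),
                       activity_level_mult = 1,
                       sleep_onset_min = 210, wake_min = 650,
                       rest_window = c(660, 720),
                       trough_window = c(345, 555),
                       target_rq_24h = 0.85,
                       protein_ox_g_d = 90,
                       overnight_fraction = 0.45,
                       diet_shares = c(0.45, 0.20, 0.35),
                       noise_sd_pct = 2,
                       sampling_interval_min = 1,
                       restless_spike = NULL) {
  p <- as.list(environment())
  stopifnot(p$dit_fraction >= 0, p$dit_fraction <= 0.15,
            p$target_rq_24h >= 0.71, p$target_rq_24h <= 1.0,
            p$overnight_fraction >= 0, p$overnight_fraction <= 1,
            abs(sum(p$meals$share) - 1) < 1e-9 || nrow(p$meals) == 0,
            abs(sum(p$diet_shares) - 1) < 1e-9)
  class(p) <- c("sim_params", "list")
  p
}

# Alternating quiet/active episodic process for one contiguous block of
# minutes; returns per-minute activity levels (%).
episodic_activity <- function(n_min, cfg, level_mult = 1) {
  a <- rep(cfg$base_pct, n_min)
  t <- 1 + stats::rexp(1, 1 / cfg$quiet_mean_min)   # start somewhere quiet
  while (t < n_min) {
    dur <- 1 + stats::rexp(1, 1 / cfg$active_mean_min)
    lev <- stats::runif(1, cfg$level_range[1], cfg$level_range[2]) *
      level_mult
    i0 <- max(1L, ceiling(t)); i1 <- min(n_min, floor(t + dur))
    if (i1 >= i0) a[i0:i1] <- a[i0:i1] + lev
    t <- t + dur + 1 + stats::rexp(1, 1 / cfg$quiet_mean_min)
  }
  # radar jitter, unless the channel is configured fully silent
  jit <- if (cfg$base_pct <= 0 && max(cfg$level_range) <= 0) 0 else 0.3
  pmin(pmax(a + stats::rnorm(n_min, 0, jit), 0), 100)
}

# Population OLS intercept of binned (EE, activity) with the default
# exclusions; used by the generator's internal consistency calibration.
binned_intercept <- function(t, ee, act, bouts, bin_min = 15,
                             washout_min = 15) {
  b <- bin_day(t, ee, act, bin_min, bouts, washout_min)
  fit <- stats::lm.fit(cbind(1, b$activity), b$ee)
  unname(fit$coefficients[1])
}

#' Simulate one ground-truth-labelled chamber session
#'
#' Builds a minute-level 24-h energy-expenditure day from its components
#' (circadian resting curve, meal-locked thermogenesis, activity-coupled
#' spontaneous energy, scheduled exercise bouts), inverts it to gas
#' volumes with a time-varying respiratory quotient normalised to the
#' 24-h target, splits protein oxidation into the two urine collections,
#' applies multiplicative gas noise, and returns both the resulting
#' [chamber_session()] and a `truth` ledger holding every injected
#' component value (computed before noise), for recovery testing.
#'
#' The ledger satisfies `tee = sedentary + aee` and
#' `dit = dit_fraction * ei` exactly; `sedentary = smr + dit` holds by
#' the generator's internal calibration (see [sim_params()]).
#'
#' @param params a [sim_params()] list.
#' @param seed integer seed; every source of randomness in the session is
#'   derived from it.
#' @param calib calibration list (shared with the analysis side).
#' @return list with elements `session` (a [chamber_session()]), `truth`
#'   (named list of injected component values) and `shape` (the
#'   internally calibrated trough amplitude and waking elevation).
#' @export
simulate_session <- function(params = sim_params(), seed = NULL,
                             calib = default_calibration()) {
  if (!is.null(seed)) set.seed(seed)
  p <- params
  dt <- p$sampling_interval_min
  t <- seq(0, 1440 - dt, by = dt)
  n <- length(t)
  bouts <- p$exercise[order(p$exercise$start_min), , drop = FALSE]

  ## --- radar activity -------------------------------------------------
  act <- numeric(n)
  sleep <- t >= p$sleep_onset_min & t < p$wake_min
  rest <- t >= p$rest_window[1] & t < p$rest_window[2]
  in_bout <- rep(FALSE, n)
  for (i in seq_len(nrow(bouts))) {
    in_bout <- in_bout | (t >= bouts$start_min[i] &
                            t < bouts$start_min[i] + bouts$duration_min[i])
  }
  waking <- !sleep & !rest
  act[waking] <- episodic_activity(sum(waking), p$activity$waking,
                                   p$activity_level_mult)
  act[sleep] <- episodic_activity(sum(sleep), p$activity$sleep)
  # light fidgeting during the supine rest period makes the "least
  # restless" 20-min RMR window uniquely identified by the radar channel
  act[rest] <- stats::runif(sum(rest), 0, 0.8)
  act[in_bout] <- pmin(100, 90 + stats::rnorm(sum(in_bout), 0, 2))
  if (!is.null(p$restless_spike)) {
    sp <- t >= p$restless_spike[1] & t < p$restless_spike[2]
    act[sp] <- pmax(act[sp], p$restless_spike[3])
  }

  ## --- diet-induced thermogenesis (exact total) -----------------------
  dit_total <- p$dit_fraction * p$ei_kcal_d
  dit <- numeric(n)
  if (nrow(p$meals) && dit_total > 0) {
    for (i in seq_len(nrow(p$meals))) {
      k <- ifelse(t >= p$meals$start_min[i],
                  exp(-(t - p$meals$start_min[i]) / p$dit_decay_min), 0)
      dit <- dit + p$meals$share[i] * dit_total * k / sum(k * dt)
    }
  }

  ## --- exercise gross profile -----------------------------------------
  ex <- numeric(n)
  for (i in seq_len(nrow(bouts))) {
    rel <- (t - bouts$start_min[i]) / 1   # minutes into the bout
    inb <- rel >= 0 & rel < bouts$duration_min[i]
    ramp <- seq(1.4, 2.0, length.out = max(1, p$ex_transient_min / dt))
    prof <- ifelse(rel[inb] < p$ex_transient_min,
                   ramp[pmin(length(ramp), floor(rel[inb] / dt) + 1)],
                   bouts$gross_kcal_min[i])
    ex[inb] <- prof
  }

  ## --- circadian trough: solve amplitude for the SMR target -----------
  r_w <- p$rmr_kcal_d / 1440
  # trapezoidal dip: flat bottom of the detector's window length with
  # short linear shoulders, so the lowest 3-h window is unique and the
  # window-mean landscape falls off linearly away from it
  tw <- p$trough_window
  ramp <- max(1, (tw[2] - tw[1] - 180) / 2)
  bump <- pmin(1, pmax(0, pmin((t - tw[1]) / ramp, (tw[2] - t) / ramp)))
  base_night <- r_w + dit + p$spa_slope * act   # pre-trough resting day
  smr_of <- function(A) {
    wm <- window_means(t, base_night - A * r_w * bump, 240, 600, 180, dt)
    1440 * min(wm$mean)
  }
  smr0 <- smr_of(0)
  if (smr0 <= p$smr_kcal_d + 1e-9) {
    if (smr0 < p$smr_kcal_d - 1e-6) {
      stop(sprintf(
        "smr_kcal_d (%g) is not below the un-troughed night level (%.1f); infeasible parameters",
        p$smr_kcal_d, smr0), call. = FALSE)
    }
    amp <- 0   # degenerate flat night (smr target equals the night level)
  } else {
    amp <- stats::uniroot(function(A) smr_of(A) - p$smr_kcal_d,
                          c(0, 0.6), tol = 1e-10)$root
  }
  wm_n <- window_means(t, base_night - amp * r_w * bump, 240, 600, 180, dt)
  smr_window_true <- wm_n$start[which.min(wm_n$mean)] + c(0, 180)

  ## --- waking elevation: solve for intercept consistency --------------
  w_mask <- as.numeric(waking)   # upright/aroused minutes (not supine rest)
  ee_of <- function(gam) {
    ee <- r_w * (1 - amp * bump) + gam * w_mask + dit + p$spa_slope * act
    ee[in_bout] <- ex[in_bout]
    ee
  }
  target_alpha <- (p$smr_kcal_d + dit_total) / 1440
  if (stats::var(act) < 1e-12) {
    gamma <- 0   # degenerate day: no activity, no intercept regression
  } else {
    a0 <- binned_intercept(t, ee_of(0), act, bouts)
    a1 <- binned_intercept(t, ee_of(0.2), act, bouts)
    gamma <- 0.2 * (target_alpha - a0) / (a1 - a0)
  }
  ee <- ee_of(gamma)
  if (min(ee) <= 0.1) {
    stop("infeasible component combination: minute EE fell below 0.1 kcal/min",
         call. = FALSE)
  }
  # The ledger's activity slope is the intercept method's estimand on the
  # noiseless day: the full-day regression prices activity more steeply
  # than the instantaneous coupling because sleep couples low EE with low
  # activity (a property of the method, not of measurement noise).
  slope_true <- if (stats::var(act) < 1e-12) NA_real_ else {
    b <- bin_day(t, ee, act, 15, bouts, 15)
    unname(stats::lm.fit(cbind(1, b$activity), b$ee)$coefficients[2])
  }

  ## --- protein schedule and RQ trajectory ------------------------------
  p_ovn <- p$overnight_fraction * p$protein_ox_g_d
  p_day <- p$protein_ox_g_d - p_ovn
  prot <- ifelse(t < 720, p_ovn / 720, p_day / 720) * dt
  q <- 0.80 + 0.12 * if (max(dit) > 0) dit / max(dit) else 0
  rq_of <- function(delta) {
    g <- gas_from_energy(ee * dt, pmin(pmax(q + delta, 0.66), 1.04),
                         prot, calib)
    sum(g$vco2_l) / sum(g$vo2_l)
  }
  delta <- stats::uniroot(function(d) rq_of(d) - p$target_rq_24h,
                          c(-0.12, 0.2), tol = 1e-10)$root
  q <- pmin(pmax(q + delta, 0.66), 1.04)
  gas <- gas_from_energy(ee * dt, q, prot, calib)
  vo2 <- gas$vo2_l / dt; vco2 <- gas$vco2_l / dt

  ## --- ground truth (pre-noise) ----------------------------------------
  sed_true <- p$smr_kcal_d + dit_total
  tee_true <- sum(ee) * dt
  net_ex <- sum((bouts$gross_kcal_min - sed_true / 1440) *
                  bouts$duration_min)
  ox <- brouwer_rates(sum(gas$vo2_l), sum(gas$vco2_l), p$protein_ox_g_d,
                      window = c(0, 1440), calib = calib)
  # noiseless RMR window under the least-restless selection rule
  rmr_starts <- seq(680, 710 - 20, by = dt)
  rmr_crit <- vapply(rmr_starts, function(s) {
    i <- t >= s & t < s + 20
    c(mean(act[i]), mean(ee[i]))
  }, numeric(2))
  rmr_pick <- order(rmr_crit[1, ], rmr_crit[2, ], rmr_starts)[1]
  rmr_true <- 1440 * rmr_crit[2, rmr_pick]
  truth <- list(
    tee_kcal_d = tee_true,
    smr_kcal_d = p$smr_kcal_d,
    smr_window = smr_window_true,
    # ledger RMR: noiseless EE over the least-restless window (includes
    # the energetic cost of residual fidgeting in the rest period)
    rmr_kcal_d = rmr_true,
    rmr_window = rmr_starts[rmr_pick] + c(0, 20),
    sedentary_ee_kcal_d = sed_true,
    dit_kcal_d = dit_total,
    dit_pct_ei = 100 * p$dit_fraction,
    aee_kcal_d = tee_true - sed_true,
    net_exercise_kcal_d = net_ex,
    spa_kcal_d = tee_true - sed_true - net_ex,
    exercise_ee_kcal_min = bouts$gross_kcal_min,
    pal = tee_true / rmr_true,
    activity_pct_24h = mean(act),
    spa_slope_kcal_min_per_pct = slope_true,
    spa_coupling_kcal_min_per_pct = p$spa_slope,
    protein_ox_g_d = p$protein_ox_g_d,
    protein_ox_ovn_g_d = p_ovn,
    protein_ox_day_g_d = p_day,
    cho_ox_g_d = ox$cho_g, fat_ox_g_d = ox$fat_g, rq_24h = ox$rq,
    ei_kcal_d = p$ei_kcal_d,
    nitrogen_g = c(overnight = p_ovn, daytime = p_day) /
      calib$protein_factor
  )

  ## --- noise and assembly ----------------------------------------------
  sd <- p$noise_sd_pct / 100
  vo2_n <- vo2 * pmax(1 + stats::rnorm(n, 0, sd), 0.5)
  vco2_n <- vco2 * pmax(1 + stats::rnorm(n, 0, sd), 0.5)
  trace <- data.frame(t_min = t, vo2_lpm = vo2_n, vco2_lpm = vco2_n,
                      activity_pct = act)
  nitrogen <- data.frame(
    window = c("overnight", "daytime"),
    start_min = c(0, 720), end_min = c(720, 1440),
    nitrogen_g = unname(truth$nitrogen_g))
  diet <- build_chamber_diet(p$ei_kcal_d, p$diet_shares, calib)
  meals <- data.frame(start_min = p$meals$start_min,
                      energy_kcal = p$meals$share * p$ei_kcal_d)
  session <- chamber_session(trace, nitrogen, diet, meals,
                             bouts[, c("start_min", "duration_min",
                                       "step_rate")],
                             interval = dt)
  list(session = session, truth = truth,
       shape = list(trough_amplitude = amp, waking_elevation = gamma,
                    rq_shift = delta))
}
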
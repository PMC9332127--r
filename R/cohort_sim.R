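#' Simulate a free-living accelerometer week
#'
#' Draws seven daily count totals around a participant-level mean tied to
#' the participant's true free-living PAL through the configured
#' counts-to-PAL calibration, assigns wear minutes (with optional invalid
#' low-wear days), and produces a self-reported energy intake that
#' underreports the true free-living total energy expenditure by a known
#' percentage — the recovery target for the energy-balance check.
#'
#' @param rmr_kcal_d chamber resting metabolic rate, kcal/d.
#' @param pal_true true free-living physical activity level.
#' @param underreporting_pct injected self-report underreporting, % of
#'   true TEE.
#' @param counts_cv day-to-day coefficient of variation of counts.
#' @param wear_mean,wear_sd wear minutes of valid days (Gaussian).
#' @param n_invalid number of days forced below the 10-h wear rule.
#' @param n_days days of wear.
#' @param calib calibration list.
#' @return list with `days` (data frame `day_index`, `counts`,
#'   `wear_min`), `self_report_ei_kcal_d` and `truth` (mean counts, PAL,
#'   TEE, underreporting).
#' @export
simulate_accel_week <- function(rmr_kcal_d, pal_true = 1.60,
                                underreporting_pct = 20,
                                counts_cv = 0.10,
                                wear_mean = 930, wear_sd = 60,
                                n_invalid = 0, n_days = 7,
                                calib = default_calibration()) {
  a <- calib$accel_calibration
  counts_mean <- max(0, (pal_true - a$pal_intercept) / a$pal_slope)
  counts <- pmax(0, counts_mean * (1 + stats::rnorm(n_days, 0, counts_cv)))
  wear <- pmin(1440, pmax(601, stats::rnorm(n_days, wear_mean, wear_sd)))
  if (n_invalid > 0) {
    bad <- sample.int(n_days, n_invalid)
    wear[bad] <- stats::runif(n_invalid, 100, 550)
  }
  tee_true <- rmr_kcal_d * pal_true
  list(
    days = data.frame(day_index = seq_len(n_days), counts = counts,
                      wear_min = wear),
    self_report_ei_kcal_d = tee_true * (1 - underreporting_pct / 100),
    truth = list(counts_mean = counts_mean, pal = pal_true,
                 tee_kcal_d = tee_true,
                 underreporting_pct = underreporting_pct)
  )
}

#' Intervention-effect configuration for cohort simulation
#'
#' Additive week-12 effects of the two crossed interventions (resistance
#' exercise vs non-exercise; high-protein supplementation vs isocaloric
#' control) together with between-subject SDs of the individual change
#' scores and the cohort design. Defaults are the effect magnitudes of a
#' 12-week trial in healthy older men: resistance exercise raises
#' fat-free mass (+1.0 kg), RMR (+36 kcal/d), SMR (+45 kcal/d) and
#' sedentary EE (+60 kcal/d) while suppressing in-chamber spontaneous
#' activity (-1.9 percentage points) and free-living activity energy
#' expenditure (-90 kcal/d); protein supplementation lowers fat mass
#' (-0.5 kg) and, once the extra protein is withdrawn for the chamber
#' day, raises overnight protein oxidation (+30 g/d) with a smaller
#' daytime reduction so 24-h protein balance falls by about 20 g/d.
#'
#' @param n_re_con,n_re_pro,n_nonex_con,n_nonex_pro cell sizes of the
#'   crossed design (defaults 8/9/8/8, i.e. 17 exercise vs 16
#'   non-exercise and 17 protein vs 16 control).
#' @param re,pro named lists of additive week-12 effects for each arm.
#' @param sd named list of between-subject change-score SDs.
#' @param rmr_activity_coupling within-subject coupling of the RMR change
#'   to the spontaneous-activity change (kcal/d per percentage point);
#'   produces the inverse partial correlation seen between the two.
#' @param baseline named list of baseline population settings.
#' @return list of class `"effect_config"`.
#' @export
effect_config <- function(n_re_con = 8, n_re_pro = 9, n_nonex_con = 8,
                          n_nonex_pro = 8,
                          re = list(d_ffm_kg = 1.0, d_rmr = 36, d_smr = 45,
                                    d_sed = 60, d_activity_pp = -1.9,
                                    d_counts = -6e4),
                          pro = list(d_fm_kg = -0.5, d_protein_ovn = 30,
                                     d_protein_day = -11),
                          sd = list(ffm = 0.88, fm = 0.86, rmr = 37,
                                    smr = 20, dit = 45, activity_pp = 3.15,
                                    protein_ovn = 17, protein_day = 10,
                                    counts = 4.7e4),
                          rmr_activity_coupling = -4.6,
                          baseline = list(
                            ffm_mean = 60, ffm_sd = 6.5,
                            fm_mean = 19.5, fm_sd = 5,
                            height_mean = 1.77, height_sd = 0.055,
                            age_mean = 67, age_sd = 4,
                            rmr_scale = 0.97, rmr_sd = 100,
                            smr_ratio = 0.966, smr_sd = 30,
                            dit_fraction = 0.06, dit_fraction_sd = 0.015,
                            pal_accel_mean = 1.60, pal_accel_sd = 0.07,
                            gross_ex_mean = 4.8, gross_ex_sd = 0.4,
                            protein_ox_mean = 90, protein_ox_sd = 12,
                            underreporting_mean = 20,
                            underreporting_sd = 4)) {
  structure(as.list(environment()), class = c("effect_config", "list"))
}

# Draw one participant's latent physiology and visit-level parameters.
draw_participant <- function(id, re, pro, cfg) {
  b <- cfg$baseline
  ffm <- stats::rnorm(1, b$ffm_mean, b$ffm_sd)
  fm <- max(5, stats::rnorm(1, b$fm_mean, b$fm_sd))
  height <- stats::rnorm(1, b$height_mean, b$height_sd)
  age <- round(stats::rnorm(1, b$age_mean, b$age_sd))
  smm_target <- 0.44 * ffm
  cal <- default_calibration()
  j <- cal$janssen
  resistance <- j[["ht2_res"]] * (100 * height)^2 /
    (smm_target - j[["male"]] - j[["age"]] * age - j[["intercept"]])
  rmr_b <- b$rmr_scale * katch_mcardle_bmr(ffm) +
    stats::rnorm(1, 0, b$rmr_sd)
  smr_b <- min(rmr_b * 0.995,
               b$smr_ratio * rmr_b + stats::rnorm(1, 0, b$smr_sd))
  ei <- energy_prescription(katch_mcardle_bmr(ffm))$ei_kcal_d
  dit_b <- min(0.14, max(0.01,
                         stats::rnorm(1, b$dit_fraction, b$dit_fraction_sd)))
  p_ovn_b <- 0.45 * stats::rnorm(1, b$protein_ox_mean, b$protein_ox_sd)
  p_day_b <- p_ovn_b / 0.45 * 0.55

  ## week-12 change draws
  eff_re <- cfg$re; eff_pro <- cfg$pro; s <- cfg$sd
  d_act <- re * eff_re$d_activity_pp + stats::rnorm(1, 0, s$activity_pp)
  d_act_dev <- d_act - re * eff_re$d_activity_pp
  d_rmr <- re * eff_re$d_rmr + cfg$rmr_activity_coupling * d_act_dev +
    stats::rnorm(1, 0, s$rmr)
  d_smr <- re * eff_re$d_smr + stats::rnorm(1, 0, s$smr)
  d_dit_kcal <- re * (eff_re$d_sed - eff_re$d_smr) +
    stats::rnorm(1, 0, s$dit)
  ffm12 <- ffm + re * eff_re$d_ffm_kg + stats::rnorm(1, 0, s$ffm)
  fm12 <- max(4, fm + pro * eff_pro$d_fm_kg + stats::rnorm(1, 0, s$fm))
  p_ovn12 <- max(5, p_ovn_b + pro * eff_pro$d_protein_ovn +
                   stats::rnorm(1, 0, s$protein_ovn))
  p_day12 <- max(5, p_day_b + pro * eff_pro$d_protein_day +
                   stats::rnorm(1, 0, s$protein_day))
  rmr12 <- rmr_b + d_rmr
  smr12 <- min(rmr12 * 0.995, smr_b + d_smr)
  dit12 <- min(0.14, max(0.01, dit_b + d_dit_kcal / ei))

  # active-episode level multiplier shift producing the requested change
  # in 24-h radar activity (see the per-mult activity sensitivity below)
  act_per_mult <- activity_sensitivity()
  mult_b <- max(0.3, stats::rnorm(1, 1, 0.08))
  mult12 <- max(0.2, mult_b + d_act / act_per_mult)

  pal_b <- stats::rnorm(1, b$pal_accel_mean, b$pal_accel_sd)
  cal_a <- cal$accel_calibration
  counts_b <- max(1e4, (pal_b - cal_a$pal_intercept) / cal_a$pal_slope)
  counts12 <- max(1e4, counts_b + re * eff_re$d_counts +
                    stats::rnorm(1, 0, s$counts))
  list(
    id = id, re = re, pro = pro, age = age, height_m = height,
    resistance_ohm = resistance, ei_kcal_d = ei,
    underreporting = max(0, stats::rnorm(1, b$underreporting_mean,
                                         b$underreporting_sd)),
    gross_ex = max(3, stats::rnorm(1, b$gross_ex_mean, b$gross_ex_sd)),
    visits = list(
      baseline = list(ffm = ffm, fm = fm, rmr = rmr_b, smr = smr_b,
                      dit_fraction = dit_b, p_ovn = p_ovn_b,
                      p_day = p_day_b, act_mult = mult_b,
                      counts = counts_b),
      week12 = list(ffm = ffm12, fm = fm12, rmr = rmr12, smr = smr12,
                    dit_fraction = dit12, p_ovn = p_ovn12,
                    p_day = p_day12, act_mult = mult12,
                    counts = counts12)
    )
  )
}

# Expected change in 24-h radar activity (%) per unit change of the
# active-episode level multiplier, under the default activity process.
activity_sensitivity <- function(params = sim_params()) {
  w <- params$activity$waking
  frac <- w$active_mean_min / (w$active_mean_min + w$quiet_mean_min)
  waking_min <- (params$sleep_onset_min +
                   (1440 - params$wake_min)) -
    diff(params$rest_window) -
    sum(params$exercise$duration_min)
  frac * mean(w$level_range) * waking_min / 1440
}

#' Simulate a two-arm (crossed) intervention cohort
#'
#' Draws a cohort of participants at the scale of healthy older men,
#' applies arm-specific week-12 effects plus between-subject change
#' noise ([effect_config()]), renders both visits through
#' [simulate_session()] and [simulate_accel_week()], runs the full
#' partition pipeline on every rendered session, and returns a tidy
#' participant-visit table ready for [group_by_time_ancova()]. The
#' injected per-visit parameter values are returned alongside as the
#' recovery ledger.
#'
#' @param effects an [effect_config()].
#' @param seed integer seed.
#' @param render `"full"` renders chamber sessions and runs the
#'   partition pipeline (slow); `"anthropometry"` skips the chamber and
#'   accelerometer stages, filling only body-composition columns (useful
#'   for effects that do not involve the chamber, e.g. fat mass).
#' @param calib calibration list.
#' @return list with `cohort` (data frame, one row per participant-visit)
#'   and `truth` (data frame of injected per-visit parameters).
#' @export
simulate_cohort <- function(effects = effect_config(), seed = NULL,
                            render = c("full", "anthropometry"),
                            calib = default_calibration()) {
  if (!is.null(seed)) set.seed(seed)
  render <- match.arg(render)
  cells <- rbind(
    data.frame(re = 1, pro = 0, n = effects$n_re_con),
    data.frame(re = 1, pro = 1, n = effects$n_re_pro),
    data.frame(re = 0, pro = 0, n = effects$n_nonex_con),
    data.frame(re = 0, pro = 1, n = effects$n_nonex_pro))
  rows <- list(); truths <- list(); id <- 0
  for (ci in seq_len(nrow(cells))) {
    for (k in seq_len(cells$n[ci])) {
      id <- id + 1
      pp <- draw_participant(id, cells$re[ci], cells$pro[ci], effects)
      for (visit in c("baseline", "week12")) {
        v <- pp$visits[[visit]]
        row <- data.frame(
          id = pp$id, visit = visit,
          group_exercise = if (pp$re) "RE" else "non-exercise",
          group_diet = if (pp$pro) "PRO" else "CON",
          age = pp$age, sex = "male", height_m = pp$height_m,
          mass_kg = v$ffm + v$fm, ffm_kg = v$ffm, fm_kg = v$fm,
          resistance_ohm = pp$resistance_ohm,
          smm_kg = janssen_smm(100 * pp$height_m, pp$resistance_ohm,
                               "male", pp$age, calib),
          bmi = bmi(v$ffm + v$fm, pp$height_m),
          ei_kcal_d = pp$ei_kcal_d)
        if (render == "full") {
          sp <- sim_params(rmr_kcal_d = v$rmr, smr_kcal_d = v$smr,
                           ei_kcal_d = pp$ei_kcal_d,
                           dit_fraction = v$dit_fraction,
                           activity_level_mult = v$act_mult,
                           protein_ox_g_d = v$p_ovn + v$p_day,
                           overnight_fraction = v$p_ovn /
                             (v$p_ovn + v$p_day))
          sp$exercise$gross_kcal_min <- pp$gross_ex
          sim <- simulate_session(sp, calib = calib)
          comp <- derive_components(sim$session, calib = calib)
          gas <- integrate_trace(sim$session$trace, c(0, 1440))
          ox24 <- brouwer_rates(gas[["vo2_l"]], gas[["vco2_l"]],
                                protein_in_window(sim$session, c(0, 1440),
                                                  calib),
                                window = c(0, 1440), calib = calib)
          bal <- substrate_balances(sim$session$diet, ox24,
                                    comp$tee_kcal_d)
          wk <- simulate_accel_week(
            rmr_kcal_d = comp$rmr_kcal_d,
            pal_true = calib$accel_calibration$pal_intercept +
              calib$accel_calibration$pal_slope * v$counts,
            underreporting_pct = pp$underreporting, calib = calib)
          fl <- free_living_summary(wk$days, comp$rmr_kcal_d, calib,
                                    id = pp$id)
          eb <- free_living_energy_balance(wk$self_report_ei_kcal_d,
                                           fl$tee_accel_kcal_d)
          n_ovn <- sim$session$nitrogen
          row <- cbind(row, data.frame(
            tee_chamber = comp$tee_kcal_d,
            smr = comp$smr_kcal_d, rmr = comp$rmr_kcal_d,
            sedentary_ee = comp$sedentary_ee_kcal_d,
            dit = comp$dit_kcal_d, dit_pct_ei = comp$dit_pct_ei,
            aee_chamber = comp$aee_kcal_d, spa = comp$spa_kcal_d,
            pal_chamber = comp$pal,
            activity_chamber_pct = comp$activity_pct_24h,
            protein_ox = ox24$protein_g,
            protein_ox_ovn = protein_oxidation(
              n_ovn$nitrogen_g[n_ovn$window == "overnight"], calib),
            protein_ox_day = protein_oxidation(
              n_ovn$nitrogen_g[n_ovn$window == "daytime"], calib),
            cho_ox = ox24$cho_g, fat_ox = ox24$fat_g, rq_24h = ox24$rq,
            protein_bal = bal$protein_bal_g, cho_bal = bal$cho_bal_g,
            fat_bal = bal$fat_bal_g, eb_chamber = bal$eb_kcal,
            counts_per_day = fl$mean_counts_per_day,
            pal_accel = fl$pal_accel, aee_accel = fl$aee_accel_kcal_d,
            tee_accel = fl$tee_accel_kcal_d,
            self_report_ei = wk$self_report_ei_kcal_d,
            eb_free_living = eb$eb_kcal_d,
            underreporting_est_pct = eb$underreporting_pct))
        }
        rows[[length(rows) + 1]] <- row
        truths[[length(truths) + 1]] <- data.frame(
          id = pp$id, visit = visit, re = pp$re, pro = pp$pro,
          rmr_true = v$rmr, smr_true = v$smr,
          sed_true = v$smr + v$dit_fraction * pp$ei_kcal_d,
          dit_fraction_true = v$dit_fraction,
          protein_ovn_true = v$p_ovn, protein_day_true = v$p_day,
          counts_true = v$counts, ffm_true = v$ffm, fm_true = v$fm,
          underreporting_true = pp$underreporting)
      }
    }
  }
  list(cohort = do.call(rbind, rows), truth = do.call(rbind, truths))
}

#' Repeated-cohort effect-recovery study
#'
#' Simulates independent intervention cohorts and estimates each injected
#' effect with the baseline-adjusted change-score ANCOVA, returning one
#' row per cohort and outcome. Chamber outcomes (RMR, SMR, sedentary EE,
#' overnight protein oxidation, protein balance) are contrasted between
#' the exercise arms or diet arms with the co-intervention as covariate;
#' fat mass is contrasted between the diet arms.
#'
#' @param n_seeds number of independent cohorts.
#' @param effects an [effect_config()].
#' @param seed base seed; cohort `i` uses `seed + 1000 * i`.
#' @param render passed to [simulate_cohort()]; `"anthropometry"`
#'   restricts the study to body-composition outcomes.
#' @param calib calibration list.
#' @return data frame with columns `seed`, `outcome`, `contrast`,
#'   `effect`, `se`, `p`.
#' @export
cohort_effect_study <- function(n_seeds = 20, effects = effect_config(),
                                seed = 1, render = "full",
                                calib = default_calibration()) {
  plan <- list(
    list(outcome = "rmr", by = "exercise"),
    list(outcome = "smr", by = "exercise"),
    list(outcome = "sedentary_ee", by = "exercise"),
    list(outcome = "protein_ox_ovn", by = "diet"),
    list(outcome = "protein_bal", by = "diet"),
    list(outcome = "fm_kg", by = "diet"))
  if (render == "anthropometry") {
    plan <- Filter(function(p) p$outcome == "fm_kg", plan)
  }
  out <- list()
  for (i in seq_len(n_seeds)) {
    co <- simulate_cohort(effects, seed = seed + 1000 * i,
                          render = render, calib = calib)$cohort
    b <- co[co$visit == "baseline", ]
    w <- co[co$visit == "week12", ]
    w <- w[match(b$id, w$id), ]
    for (pl in plan) {
      grp <- if (pl$by == "exercise") b$group_exercise else b$group_diet
      cov <- if (pl$by == "exercise") b$group_diet else b$group_exercise
      # order factor levels so the effect is reported for the active arm
      grp <- factor(grp, levels = if (pl$by == "exercise") {
        c("non-exercise", "RE")
      } else c("CON", "PRO"))
      r <- group_by_time_ancova(b[[pl$outcome]], w[[pl$outcome]], grp,
                                covariates = data.frame(co_arm = cov),
                                outcome = pl$outcome)
      out[[length(out) + 1]] <- data.frame(
        seed = seed + 1000 * i, outcome = pl$outcome,
        contrast = r$contrast, effect = r$effect, se = r$se, p = r$p)
    }
  }
  do.call(rbind, out)
}
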
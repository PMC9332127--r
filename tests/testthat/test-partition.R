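test_that("a flat day integrates to 1440 times the minute rate", {
  s <- flat_session(vo2 = 0.25, vco2 = 0.2125)
  expect_equal(total_ee(s), 1440 * flat_ee_min(0.25, 0.2125),
               tolerance = 1e-10)
})

test_that("SMR window detection follows the minimum-EE rule", {
  # monotonically decreasing EE through the night: minimum at the end
  vo2 <- 0.3 - 0.00005 * (0:1439)
  tr <- data.frame(t_min = 0:1439, vo2_lpm = vo2, vco2_lpm = 0.85 * vo2,
                   activity_pct = 0)
  s <- flat_session(); s$trace <- tr
  d <- detect_smr(s)
  expect_equal(d$window, c(420, 600))

  # constant EE: tie broken by earliest start; SMR is the 24-h rate
  s2 <- flat_session(vo2 = 0.25, vco2 = 0.2125)
  d2 <- detect_smr(s2)
  expect_equal(d2$window, c(240, 420))
  expect_equal(d2$smr_kcal_d, 1440 * flat_ee_min(0.25, 0.2125),
               tolerance = 1e-10)

  # insufficient contiguous data in range
  s3 <- flat_session()
  s3$trace <- s3$trace[s3$trace$t_min < 300 | s3$trace$t_min >= 500, ]
  expect_error(detect_smr(s3), "contiguous")
})

test_that("RMR selection minimises restlessness with a full tie cascade", {
  # zero activity everywhere: earliest window 0720-0740
  s <- flat_session()
  expect_equal(detect_rmr(s)$window, c(680, 700))

  # a restless spell in 0740-0750 pushes the window fully clear of it
  act <- rep(0, 1440); act[701:710] <- 40   # minutes 700-709
  s2 <- flat_session(activity = act)
  d2 <- detect_rmr(s2)
  expect_equal(d2$window, c(680, 700))
  expect_equal(window_overlap(c(700, 710), d2$window), 0)

  # missing activity channel falls back to EE variance with a warning
  s3 <- flat_session(activity = NA_real_)
  expect_warning(d3 <- detect_rmr(s3), "variance")
  expect_equal(d3$rmr_kcal_d, 1440 * flat_ee_min(0.25, 0.2125),
               tolerance = 1e-10)
})

test_that("window detectors are translation-equivariant", {
  set.seed(42)
  vo2 <- 0.25 + cumsum(rnorm(1440, 0, 1e-4))
  vo2 <- pmax(vo2, 0.05)
  mk <- function(shift) {
    v <- c(tail(vo2, shift), head(vo2, 1440 - shift))   # rotate by +shift
    tr <- data.frame(t_min = 0:1439, vo2_lpm = v, vco2_lpm = 0.85 * v,
                     activity_pct = 0)
    s <- flat_session(); s$trace <- tr; s
  }
  k <- 30
  d0 <- detect_smr(mk(0), search = c(240, 570))
  dk <- detect_smr(mk(k), search = c(240 + k, 570 + k))
  expect_equal(dk$window, d0$window + k)
  expect_equal(dk$smr_kcal_d, d0$smr_kcal_d, tolerance = 1e-12)
})

test_that("steady-state exercise EE finds the plateau and excludes transients", {
  bouts <- data.frame(start_min = 750, duration_min = 30, step_rate = 75)
  # constant-rate bout: the whole bout qualifies
  s <- flat_session(vo2 = 0.25, vco2 = 0.2125, bouts = bouts)
  r <- exercise_ee(s, 1)
  expect_equal(r$window, c(750, 780))
  expect_equal(r$mean_ee_kcal_min, flat_ee_min(0.25, 0.2125),
               tolerance = 1e-10)

  # low on-transient then plateau: plateau recovered, transient excluded
  vo2 <- rep(0.25, 1440)
  vo2[751:755] <- c(0.28, 0.33, 0.38, 0.41, 0.43)   # minutes 750-754
  vo2[756:780] <- 1.0                                # plateau 755-779
  tr <- data.frame(t_min = 0:1439, vo2_lpm = vo2, vco2_lpm = 0.9 * vo2,
                   activity_pct = 0)
  s2 <- flat_session(bouts = bouts); s2$trace <- tr
  r2 <- exercise_ee(s2, 1)
  expect_gte(r2$window[1], 755)
  expect_equal(r2$mean_ee_kcal_min, flat_ee_min(1.0, 0.9), tolerance = 1e-10)

  # wildly oscillating bout: no steady state, error reports best CVs
  vo2[751:780] <- rep(c(0.3, 1.2), 15)
  s3 <- flat_session(bouts = bouts)
  s3$trace$vo2_lpm <- vo2
  s3$trace$vco2_lpm <- 0.9 * vo2
  expect_error(exercise_ee(s3, 1), "best CVs")
  expect_error(exercise_ee(s, 99), "no such")
})

test_that("intercept regression solves the two-level day exactly", {
  # half the day at zero activity / 1.2 kcal/min, half at 40% / 2.0:
  # alpha = 1.2, beta = 0.02 by construction
  ee_lo <- 1.2; ee_hi <- 2.0
  g_lo <- gas_from_energy(ee_lo, 0.85)
  g_hi <- gas_from_energy(ee_hi, 0.85)
  lo <- rep(c(TRUE, FALSE), each = 15, times = 48)
  tr <- data.frame(t_min = 0:1439,
                   vo2_lpm = ifelse(lo, g_lo$vo2_l, g_hi$vo2_l),
                   vco2_lpm = ifelse(lo, g_lo$vco2_l, g_hi$vco2_l),
                   activity_pct = ifelse(lo, 0, 40))
  s <- flat_session(); s$trace <- tr
  ip <- intercept_partition(s)
  expect_equal(ip$sedentary_ee_kcal_d, 1.2 * 1440, tolerance = 1e-6)
  expect_equal(ip$spa_slope_kcal_min_per_pct, 0.02, tolerance = 1e-9)
  expect_equal(ip$r_squared, 1, tolerance = 1e-9)

  # degenerate: constant activity has no regression
  expect_error(intercept_partition(flat_session()), "constant")

  # negative slope is flagged, not fatal
  tr2 <- tr; tr2$activity_pct <- ifelse(lo, 40, 0)
  s2 <- flat_session(); s2$trace <- tr2
  expect_warning(ip2 <- intercept_partition(s2), "negative activity slope")
  expect_true(ip2$slope_flag)
})

test_that("component decomposition identities hold by construction", {
  sim <- simulate_session(sim_params(), seed = 7)
  comp <- derive_components(sim$session)
  expect_equal(comp$tee_kcal_d,
               comp$sedentary_ee_kcal_d + comp$aee_kcal_d)
  expect_equal(comp$dit_kcal_d,
               comp$sedentary_ee_kcal_d - comp$smr_kcal_d)
  expect_equal(comp$aee_kcal_d,
               comp$spa_kcal_d + comp$net_exercise_kcal_d)
  expect_equal(comp$pal * comp$rmr_kcal_d, comp$tee_kcal_d)
  expect_equal(comp$dit_pct_ei,
               100 * comp$dit_kcal_d / sim$session$diet$energy_kcal)
  expect_output(print(comp), "energy expenditure components")
})

test_that("a quiet no-meal no-exercise day has vanishing non-resting components", {
  p <- sim_params(rmr_kcal_d = 1600, smr_kcal_d = 1600, dit_fraction = 0,
                  meals = data.frame(start_min = numeric(0),
                                     share = numeric(0)),
                  exercise = data.frame(start_min = numeric(0),
                                        duration_min = numeric(0),
                                        step_rate = numeric(0),
                                        gross_kcal_min = numeric(0)),
                  noise_sd_pct = 0)
  p$activity$waking$level_range <- c(0, 0)
  p$activity$waking$base_pct <- 0
  p$activity$sleep$level_range <- c(0, 0)
  p$activity$sleep$base_pct <- 0
  p$rest_window <- c(660, 660)   # no separate fidget-free rest block
  sim <- simulate_session(p, seed = 3)
  expect_equal(total_ee(sim$session), sim$truth$smr_kcal_d,
               tolerance = 1e-6)
  expect_equal(sim$truth$tee_kcal_d, sim$truth$smr_kcal_d)
  expect_equal(sim$truth$dit_kcal_d, 0)
  expect_equal(sim$truth$aee_kcal_d, 0, tolerance = 1e-9)
  expect_equal(sim$truth$spa_kcal_d, 0, tolerance = 1e-9)
})

test_that("activity percentage converts to minutes of the day", {
  expect_equal(activity_fraction_minutes(1.9), 27)
  expect_equal(activity_fraction_minutes(0), 0)
  expect_equal(activity_fraction_minutes(50), 720)
  expect_error(activity_fraction_minutes(101), "100")
})

test_that("the scheduled chamber day prescribes ~6750 steps", {
  s <- flat_session(bouts = data.frame(start_min = c(750, 1125, 1395),
                                       duration_min = 30, step_rate = 75))
  expect_equal(chamber_step_count(s), 6750)
})
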
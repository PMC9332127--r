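test_that("gas inversion matches the RQ-1 closed form and errors on bad input", {
  g <- gas_from_energy(5, 1, 0)
  expect_equal(g$vo2_l, 5 * 4.184 / 21.20, tolerance = 1e-12)
  expect_equal(g$vco2_l, g$vo2_l)
  expect_error(gas_from_energy(-1, 0.85), "> 0")
  expect_error(gas_from_energy(5, 0.5), "0.65")
})

test_that("gas inversion round-trips through the Brouwer equation", {
  for (ee in c(0.8, 1.4, 4.8)) {
    for (rq in c(0.71, 0.85, 1.0)) {
      for (pr in c(0, 0.12)) {
        g <- gas_from_energy(ee, rq, pr)
        back <- suppressWarnings(brouwer_rates(g$vo2_l, g$vco2_l, pr))
        expect_equal(back$ee_kcal, ee, tolerance = 1e-9 * ee)
        expect_equal(back$rq, rq, tolerance = 1e-12)
      }
    }
  }
  # fat-dominated limit: carbohydrate oxidation vanishes
  g <- gas_from_energy(2, 0.71, 0)
  r <- brouwer_rates(g$vo2_l, g$vco2_l)
  expect_lt(abs(r$cho_g) / r$fat_g, 0.05)
})

test_that("identical parameters and seed reproduce byte-identical sessions", {
  a <- simulate_session(sim_params(), seed = 99)
  b <- simulate_session(sim_params(), seed = 99)
  expect_identical(a$session$trace, b$session$trace)
  expect_identical(a$truth, b$truth)
})

test_that("the ground-truth ledger is internally consistent", {
  sim <- simulate_session(sim_params(), seed = 12)
  tr <- sim$truth
  expect_equal(tr$tee_kcal_d, tr$sedentary_ee_kcal_d + tr$aee_kcal_d)
  expect_equal(tr$sedentary_ee_kcal_d, tr$smr_kcal_d + tr$dit_kcal_d)
  expect_equal(tr$dit_kcal_d, 0.06 * tr$ei_kcal_d)
  expect_equal(tr$aee_kcal_d,
               tr$spa_kcal_d + tr$net_exercise_kcal_d)
  expect_equal(unname(tr$nitrogen_g["overnight"] * 6.25),
               tr$protein_ox_ovn_g_d)
})

test_that("a noise-free session integrates exactly to its ledger", {
  p <- sim_params(noise_sd_pct = 0)
  sim <- simulate_session(p, seed = 13)
  expect_equal(total_ee(sim$session), sim$truth$tee_kcal_d,
               tolerance = 1e-9)
  # window detectors on the noiseless day reproduce the ledger exactly
  smr <- detect_smr(sim$session)
  expect_equal(smr$smr_kcal_d, sim$truth$smr_kcal_d, tolerance = 1e-6)
  expect_equal(smr$window, sim$truth$smr_window)
  rmr <- detect_rmr(sim$session)
  expect_equal(rmr$rmr_kcal_d, sim$truth$rmr_kcal_d, tolerance = 1e-6)
  expect_equal(rmr$window, sim$truth$rmr_window)
  ip <- intercept_partition(sim$session)
  expect_equal(ip$sedentary_ee_kcal_d, sim$truth$sedentary_ee_kcal_d,
               tolerance = 1e-6)
  # whole-day RQ hits its target exactly before noise
  gas <- integrate_trace(sim$session$trace, c(0, 1440))
  expect_equal(unname(gas[["vco2_l"]] / gas[["vo2_l"]]), 0.85,
               tolerance = 1e-9)
})

test_that("session recovery at default noise stays within module tolerances", {
  errs <- t(sapply(1:8, function(s) {
    sim <- simulate_session(sim_params(), seed = 100 + s)
    comp <- derive_components(sim$session)
    tr <- sim$truth
    c(smr = abs(comp$smr_kcal_d / tr$smr_kcal_d - 1),
      sed = abs(comp$sedentary_ee_kcal_d / tr$sedentary_ee_kcal_d - 1),
      dit = abs(comp$dit_kcal_d / tr$dit_kcal_d - 1),
      rmr = abs(comp$rmr_kcal_d / tr$rmr_kcal_d - 1),
      tee = abs(comp$tee_kcal_d / tr$tee_kcal_d - 1))
  }))
  expect_lt(max(errs[, "smr"]), 0.01)
  expect_lt(max(errs[, "sed"]), 0.02)
  expect_lt(max(errs[, "dit"]), 0.15)
  expect_lt(max(errs[, "rmr"]), 0.01)
  expect_lt(max(errs[, "tee"]), 0.005)
})

test_that("planted exercise plateaus are recovered excluding the transient", {
  sim <- simulate_session(sim_params(), seed = 41)
  for (i in 1:3) {
    ss <- exercise_ee(sim$session, i)
    expect_lt(abs(ss$mean_ee_kcal_min - 4.8), 0.05)
    # steady-state window starts after the 5-min on-transient
    expect_gte(ss$window[1],
               sim$session$exercise_bouts$start_min[i] + 4)
  }
})

test_that("recovered DIT increases with the injected thermogenic fraction", {
  rec <- sapply(c(0.03, 0.06, 0.09), function(f) {
    mean(sapply(1:4, function(s) {
      sim <- simulate_session(sim_params(dit_fraction = f), seed = 200 + s)
      ip <- intercept_partition(sim$session)
      ip$sedentary_ee_kcal_d - detect_smr(sim$session)$smr_kcal_d
    }))
  })
  expect_true(all(diff(rec) > 0))
})

test_that("restless-spike artefacts are dodged by the RMR window", {
  p <- sim_params(restless_spike = c(695, 705, 60))
  sim <- simulate_session(p, seed = 55)
  d <- detect_rmr(sim$session)
  expect_equal(d$window, sim$truth$rmr_window)
  expect_lt(window_overlap(c(695, 705), d$window), 0.5)
  expect_lt(abs(d$rmr_kcal_d / sim$truth$rmr_kcal_d - 1), 0.01)
})

test_that("infeasible parameter combinations are rejected", {
  expect_error(simulate_session(sim_params(smr_kcal_d = 1700,
                                           rmr_kcal_d = 1625), seed = 1),
               "infeasible")
  expect_error(sim_params(dit_fraction = 0.5), "dit_fraction")
})

test_that("cohort simulation produces paired, labelled, recoverable rows", {
  eff <- effect_config(n_re_con = 2, n_re_pro = 2, n_nonex_con = 2,
                       n_nonex_pro = 2)
  co <- simulate_cohort(eff, seed = 61)
  ch <- co$cohort
  expect_equal(nrow(ch), 16)
  expect_setequal(unique(ch$visit), c("baseline", "week12"))
  # each id appears at both visits with constant group labels
  for (i in unique(ch$id)) {
    sub <- ch[ch$id == i, ]
    expect_equal(nrow(sub), 2)
    expect_equal(length(unique(sub$group_exercise)), 1)
    expect_equal(length(unique(sub$group_diet)), 1)
  }
  # chamber outcomes track their injected per-visit parameters
  tr <- co$truth
  expect_lt(max(abs(ch$smr - tr$smr_true) / tr$smr_true), 0.01)
  # measured RMR carries the small energetic cost of residual
  # fidgeting in the rest window on top of the latent resting rate
  expect_lt(max(abs(ch$rmr - tr$rmr_true) / tr$rmr_true), 0.02)
  expect_equal(ch$protein_ox_ovn, tr$protein_ovn_true, tolerance = 1e-6)

  # anthropometry-only rendering is cheap and carries body composition
  co2 <- simulate_cohort(effect_config(), seed = 62,
                         render = "anthropometry")
  expect_equal(nrow(co2$cohort), 66)
  expect_false("tee_chamber" %in% names(co2$cohort))
  expect_equal(co2$cohort$ffm_kg[co2$cohort$visit == "baseline"],
               co2$truth$ffm_true[co2$truth$visit == "baseline"])
})
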
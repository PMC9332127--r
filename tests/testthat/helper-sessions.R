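# Shared builders for hand-crafted chamber sessions and small utilities.

# A session with constant gas rates (and hence constant EE), optionally a
# custom activity channel; nitrogen chosen so protein oxidation is
# `protein_g_d` split evenly across collections.
flat_session <- function(vo2 = 0.25, vco2 = 0.2125, activity = 0,
                         protein_g_d = 0, ei_kcal_d = 2400,
                         meals = NULL, bouts = NULL) {
  t <- 0:1439
  act <- if (length(activity) == 1) rep(activity, 1440) else activity
  trace <- data.frame(t_min = t, vo2_lpm = vo2, vco2_lpm = vco2,
                      activity_pct = act)
  nitrogen <- data.frame(window = c("overnight", "daytime"),
                         start_min = c(0, 720), end_min = c(720, 1440),
                         nitrogen_g = rep(protein_g_d / 6.25 / 2, 2))
  chamber_session(trace, nitrogen, build_chamber_diet(ei_kcal_d),
                  meals = meals, exercise_bouts = bouts)
}

# Fractional overlap of window `a` with reference window `b`.
window_overlap <- function(a, b) {
  max(0, min(a[2], b[2]) - max(a[1], b[1])) / (b[2] - b[1])
}

# Constant-rate Brouwer EE per minute for given gas rates (no protein).
flat_ee_min <- function(vo2, vco2, calib = default_calibration()) {
  b <- calib$brouwer$ee_kj
  (b[["vo2"]] * vo2 + b[["vco2"]] * vco2) / calib$kj_per_kcal
}
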
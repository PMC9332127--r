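---
title: "Partitioning 24-h energy expenditure from whole-room calorimetry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning 24-h energy expenditure from whole-room calorimetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(calorchamber)
```

## The measurement problem

A whole-room respiration chamber measures a person's oxygen consumption
($\dot VO_2$) and carbon dioxide production ($\dot VCO_2$) minute by
minute over a full day, together with radar-sensed physical activity and
urine collected in two 12-h pools. From these, indirect calorimetry
reconstructs both *how much* energy the person expended and *on what* —
sleeping metabolism, resting metabolism, the thermic response to meals,
structured exercise, and spontaneous movement — plus which fuels
(carbohydrate, fat, protein) supplied it.

`calorchamber` implements this reconstruction for the common trial
design in exercise and nutrition physiology: a 24-h chamber day running
from 2000 h to 2000 h (session minute 0 = 2000 h), three scheduled
30-min step-exercise bouts (0830, 1445, 1915 h at 75 steps/min, the
first fasted), a eucaloric chamber diet with ~45/20/35% of energy from
carbohydrate/protein/fat, and a two-timepoint randomized comparison of
intervention arms. A free-living arm estimates total energy expenditure
for the same participants from a week of wrist accelerometry anchored to
the chamber resting metabolic rate.

## Stoichiometry

Energy expenditure and substrate oxidation come from the Brouwer
relations. With gas volumes in litres (STPD) and protein oxidation $P$
(g) obtained as $6.25 \times$ urinary nitrogen:

$$\mathrm{CHO\,(g)} = 4.170\,VCO_2 - 2.965\,VO_2 - 0.390\,P$$
$$\mathrm{Fat\,(g)} = 1.718\,(VO_2 - VCO_2) - 0.315\,P$$
$$\mathrm{EE\,(kJ)} = 16.20\,VO_2 + 5.00\,VCO_2 - 0.95\,P$$

The coefficient set is the standard one used with respiration chambers;
because chamber software versions differ in their exact constants, every
coefficient lives in a configuration object (`default_calibration()`,
overridable from YAML with `read_calibration()`) and the abbreviated
Weir equation ($3.941\,VO_2 + 1.106\,VCO_2 - 2.17\,N$, kcal) is provided
alongside for the day-2 energy-prescription adjustment. On identical
input the two agree within 2% across the physiological RQ range — a
property the test suite asserts. Protein oxidation from each 12-h urine
pool is apportioned pro-rata in time when a window (such as an exercise
bout) spans only part of a collection.

Non-goals at this layer: alcohol and ketone terms, analyzer drift
correction, and chamber washout deconvolution — gas volumes are taken as
delivered (STPD) by the instrument.

## Component definitions

* **TEE** — Brouwer energy integrated over minutes 0–1440, with
  midpoint-in-window rectangle integration at the native 1-min cadence
  (`total_ee()`). Gaps up to 5 min are linearly interpolated with a
  warning; larger gaps are an error.
* **SMR** — the lowest mean energy expenditure over any continuous 3-h
  window inside 0000–0600 h, ties resolved to the earliest start
  (`detect_smr()`).
* **RMR** — the mean energy expenditure of the least restless (minimum
  mean radar activity) consecutive 20-min window within 0720–0750 h,
  i.e. the 0700–0800 rest hour with its first 20 and last 10 minutes
  discarded; ties fall back to lower mean energy, then earliest start
  (`detect_rmr()`).
* **Sedentary EE** — the *intercept method*: energy expenditure
  (kcal/min) and activity (%) are averaged in fixed 15-min bins over the
  whole day, bins overlapping an exercise bout or a 15-min post-exercise
  washout are excluded, and ordinary least squares
  $EE = \alpha + \beta \cdot \mathrm{activity}$ is fitted. Sedentary EE
  is $1440\alpha$; $\beta$ is the energy price of radar activity
  (`intercept_partition()`).
* **DIT** = sedentary EE − SMR; **AEE** = TEE − sedentary EE;
  **exercise EE** = the mean rate over the longest window (≥ 5 min)
  within each bout whose gas-channel coefficients of variation are both
  ≤ 10% (`exercise_ee()`); net exercise cost subtracts the sedentary
  rate over the bout duration; **SPA** = AEE − net exercise cost;
  **PAL** = TEE/RMR (`derive_components()`).

Several of these choices close gaps the method description leaves open,
and are deliberate:

* *Bin width and washout.* 15-min bins echo the classical use of the
  intercept method; the washout prevents excess post-exercise oxygen
  consumption from steepening the activity slope. Both are arguments,
  not constants.
* *DIT as sedentary EE minus SMR* rather than an area under the
  post-meal curve: it is the only construction consistent with the
  intercept method, where the fed zero-activity level already contains
  the thermic effect of the day's meals.
* *Net exercise baseline.* Exercise displaces fed sedentary time, not
  sleep, so the sedentary rate ($\alpha$), not RMR, is subtracted.
* *Steady state* is operationalised as ≥ 5 consecutive minutes with both
  gas CVs ≤ 10%, the convention used for metabolic-cart measurements.
* Negative DIT or SPA are reported with a quality flag, never clamped —
  at realistic noise levels mildly negative estimates are legitimate
  outputs of the subtraction.

## The synthetic chamber

No raw chamber data accompany the trial design this package targets, so
every estimator is validated against `simulate_session()`, which builds
a minute-level day *from its components* and returns the injected values
as a ground-truth ledger:

* a resting curve with a planted circadian trough (trapezoidal dip whose
  flat bottom matches the 3-h detector window, centred ~0330 h);
* meal-locked thermogenesis: an exponential impulse (default time
  constant 120 min) per meal, normalised so the in-session integral is
  exactly `dit_fraction × EI`;
* an episodic activity process (alternating quiet and active spells)
  coupled to energy at `spa_slope` kcal/min per radar %, with sparse,
  low-level movement during sleep and light fidgeting during the supine
  rest hour so the "least restless" RMR window is uniquely identified;
* three exercise bouts with a deliberately low 5-min on-transient
  followed by a constant gross plateau (default 4.8 kcal/min);
* a postprandially elevated RQ trajectory, shifted so the 24-h gas
  totals hit the target RQ exactly, inverted to gas volumes through
  `gas_from_energy()` (the exact inverse of the Brouwer equation);
* multiplicative Gaussian noise (default 2% SD) applied independently to
  each gas channel — instruments measure gases, not energy.

Two shape parameters are not set directly but *solved* by the generator:
the trough amplitude, so the lowest 3-h window of the noiseless day
equals the requested SMR; and a waking (posture/arousal) elevation of
the resting curve, so the zero-activity intercept of the binned
noiseless day equals $(SMR + DIT)/1440$. The solved elevation comes out
near +0.1 kcal/min (~7% above supine rest), which is the textbook cost
of sitting versus lying. This self-calibration makes the ledger identity
*sedentary EE = SMR + DIT* hold exactly for the noiseless day under the
package's own definitions, so recovery tests measure measurement noise
rather than model mismatch.

One ledger entry needs care: the **activity slope**. The full-day
regression estimand is systematically steeper than the instantaneous
minute-level coupling, because sleep contributes bins where low energy
expenditure co-occurs with low activity — an omitted circadian variable
that no physiologically shaped activity process removes. This is a
property of the intercept method itself, not of noise. The ledger
therefore records `spa_slope` as the OLS slope of the *noiseless* binned
day (the method's estimand), keeping the generative coupling alongside
as `spa_coupling`; at default settings the estimand exceeds the coupling
by roughly 10–40%.

Default magnitudes (RMR 1625, SMR 1570 kcal/d, EI 2450 kcal/d, DIT 6% of
EI, exercise 4.8 kcal/min gross, 24-h RQ 0.85, protein oxidation 90 g/d
with 45% overnight, radar activity ~17–19% of the day) were chosen once
to reproduce the daily summaries typical of healthy older men in
eucaloric chamber studies, and the simulator's TEE then lands near 2450–
2500 kcal/d with PAL ≈ 1.5 as an emergent property.

What the simulator does *not* emulate — and what passing tests therefore
cannot certify on real data: gas-mixing washout dynamics of a physical
chamber, analyzer drift, sleep-stage structure within the night,
behavioural meal-to-meal variation in the thermic response, EPOC beyond
the washout exclusion, and any nonlinearity in the radar-to-energy
coupling (a linear coupling is the model-matched default; a robustness
knob can break it).

## Cohorts, effects and statistics

`simulate_cohort()` draws participants at the scale of healthy older men
(FFM ~60 kg, BIA-derived skeletal muscle ~44% of FFM, Katch–McArdle
energy prescription × 1.47) in a crossed two-factor design (resistance
exercise vs none; protein supplementation vs isocaloric control; cells
8/9/8/8), applies arm-specific week-12 effects with between-subject
change noise, and renders both visits through the full session and
accelerometer simulators. Injected defaults follow the reported effects
of such trials: exercise raises fat-free mass (+1.0 kg), RMR
(+36 kcal/d), SMR (+45 kcal/d) and sedentary EE (+60 kcal/d) while
lowering in-chamber spontaneous activity (−1.9 percentage points);
protein lowers fat mass (−0.5 kg) and, with the supplement withdrawn on
the chamber day, raises overnight protein oxidation (+30 g/d) so 24-h
protein balance falls by ~20 g/d. Change-score SDs are set so the
analysis reproduces the reported standard errors where physiology
permits; for sedentary EE the SD is capped by the requirement that the
thermogenic fraction stay within its admissible range, giving a somewhat
smaller SE than reported — the reported one presumably contains
measurement components the simulator does not model. A within-subject
coupling between the RMR change and the activity change (−4.6 kcal/d per
percentage point) reproduces the inverse partial correlation between the
two.

The group-by-time analysis is the baseline-adjusted change-score ANCOVA:
regress (week 12 − baseline) on the group indicator, the baseline value,
and the co-intervention indicator (`group_by_time_ancova()`). For a
two-timepoint design this estimates the same contrast as a mixed-model
ANCOVA with time as the within-subject factor, without committing to an
unstated covariance structure or degrees-of-freedom method. Supporting
procedures: single-pass ±3 SD group-wise outlier removal with a removal
log (`remove_outliers()`), paired within-group t-tests
(`paired_change_test()`), Pearson partial correlation controlled for
group (`partial_correlation()`), and baseline-fitted body-composition
adjustment whose recentred predictions preserve the baseline cohort mean
exactly (`fit_adjustment_model()`, `adjust_value()`). Rank-based
alternatives for non-normalisable outcomes are out of scope; such data
route through the same ANCOVA with a logged warning at the caller's
discretion. No multiple-testing correction is applied.

The accelerometer arm uses a deliberately simple linear counts-to-PAL
and counts-to-AEE contract with config-supplied coefficients; the
shipped values are placeholders at the right scale for wrist-worn
devices in older adults and are *not* an authoritative published
calibration. Days with under 10 h wear are dropped and at least 5 valid
days are required; free-living TEE is chamber RMR × PAL. The
energy-balance check interprets a persistent negative free-living
balance under stable weight as self-report underreporting,
$100\,(TEE - EI)/TEE$.

## Numerical choices and problem sizes

Ties in window detectors resolve to the earliest start (with a 1e-10
tolerance so floating-point rounding cannot override an exact tie).
The intercept regression refuses rank-deficient activity and flags
negative slopes. `gas_from_energy()` rejects parameter combinations
yielding non-positive gas volumes, and the session generator rejects
SMR targets at or above what the night can reach. All randomness flows
from explicit integer seeds; identical parameters and seed give
byte-identical sessions.

Validation sizes were chosen to characterise each estimator while
keeping the default check fast: 50 seeds for window-detector and
intercept recovery (observed: SMR window overlap ≥ 0.95, EE errors
≤ 0.3%, sedentary ≤ 0.2%, DIT/EI = 6.0 ± 0.2 when 6% is injected),
30 full-rendered cohorts plus 200 anthropometry-only cohorts for
end-to-end effect recovery, and 4000 lightweight replicates for the
ANCOVA's type-I error (0.05 ± 0.01).

## Known limitations

* The intercept method's slope is reported against its own estimand (see
  above); users comparing slopes across populations with different
  sleep/wake structure should be aware the estimand shifts with that
  structure.
* Measured RMR includes the energetic cost of residual fidgeting in the
  rest window (up to ~1% above the latent supine rate), exactly as it
  does in a real chamber.
* BIA-based body composition assumes normal hydration; skeletal-muscle
  estimates exceeding fat-free mass should be treated as data-quality
  flags.
* The accelerometer calibration is a linear placeholder; all derived
  free-living quantities inherit whatever bias the supplied coefficients
  carry.
* Sub-12-h protein corrections assume uniform oxidation within each
  urine collection; short windows with strongly time-varying protein
  oxidation will be mis-corrected.
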
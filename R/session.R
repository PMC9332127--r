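#' Assemble a 24-h chamber session
#'
#' Bundles the minute-resolution gas/activity trace with the urinary
#' nitrogen collections, the chamber diet, and the meal and exercise
#' schedule for one 2000-2000 h measurement day. Session time is measured
#' in minutes since 2000 h, so minute 0 is 2000 h, minute 720 is 0800 h
#' and minute 1439 ends the day at 1959 h.
#'
#' @param trace data frame with columns `t_min`, `vo2_lpm`, `vco2_lpm`,
#'   `activity_pct` (radar activity, % of interval active; may be `NA`).
#' @param nitrogen data frame with columns `window` (labels `"overnight"`
#'   and `"daytime"`), `start_min`, `end_min`, `nitrogen_g`. The two
#'   collections must partition `[0, 1440)`.
#' @param diet a [macronutrient_intake()] record for the chamber diet.
#' @param meals data frame with columns `start_min`, `energy_kcal`.
#' @param exercise_bouts data frame with columns `start_min`,
#'   `duration_min`, `step_rate` (steps/min).
#' @param interval sampling interval of the trace, minutes.
#' @param min_coverage minimum fraction of the 1440-min day the trace must
#'   cover.
#' @return list of class `"chamber_session"`.
#' @export
chamber_session <- function(trace, nitrogen, diet, meals = NULL,
                            exercise_bouts = NULL, interval = 1,
                            min_coverage = 0.95) {
  stopifnot(is.data.frame(trace),
            all(c("t_min", "vo2_lpm", "vco2_lpm") %in% names(trace)))
  if (!"activity_pct" %in% names(trace)) trace$activity_pct <- NA_real_
  ok <- is.finite(trace$vo2_lpm) & is.finite(trace$vco2_lpm)
  if (any(trace$vo2_lpm[ok] <= 0) || any(trace$vco2_lpm[ok] <= 0)) {
    stop("gas rates must be strictly positive", call. = FALSE)
  }
  act <- trace$activity_pct
  if (any(act[is.finite(act)] < 0 | act[is.finite(act)] > 100)) {
    stop("activity_pct must lie in [0, 100]", call. = FALSE)
  }
  coverage <- nrow(trace) * interval / 1440
  if (coverage < min_coverage) {
    stop(sprintf("trace covers %.1f%% of the day (< %.0f%%)",
                 100 * coverage, 100 * min_coverage), call. = FALSE)
  }
  nitrogen <- validate_nitrogen(nitrogen)
  stopifnot(inherits(diet, "macronutrient_intake"))
  if (is.null(meals)) {
    meals <- data.frame(start_min = numeric(0), energy_kcal = numeric(0))
  }
  if (is.null(exercise_bouts)) {
    exercise_bouts <- data.frame(start_min = numeric(0),
                                 duration_min = numeric(0),
                                 step_rate = numeric(0))
  }
  stopifnot(all(c("start_min", "energy_kcal") %in% names(meals)),
            all(c("start_min", "duration_min") %in% names(exercise_bouts)))
  if (!"step_rate" %in% names(exercise_bouts)) {
    exercise_bouts$step_rate <- 75
  }
  tmax <- max(trace$t_min) + interval
  ends <- exercise_bouts$start_min + exercise_bouts$duration_min
  if (nrow(exercise_bouts) &&
      (any(exercise_bouts$start_min < min(trace$t_min)) || any(ends > tmax))) {
    stop("exercise bouts must lie within the trace", call. = FALSE)
  }
  if (nrow(exercise_bouts) > 1) {
    o <- order(exercise_bouts$start_min)
    if (any(exercise_bouts$start_min[o][-1] < ends[o][-nrow(exercise_bouts)])) {
      stop("exercise bouts overlap", call. = FALSE)
    }
  }
  structure(
    list(trace = trace[order(trace$t_min), , drop = FALSE],
         nitrogen = nitrogen, diet = diet, meals = meals,
         exercise_bouts = exercise_bouts, interval = interval),
    class = "chamber_session"
  )
}

validate_nitrogen <- function(nitrogen) {
  stopifnot(is.data.frame(nitrogen),
            all(c("window", "start_min", "end_min", "nitrogen_g") %in%
                  names(nitrogen)))
  if (any(nitrogen$nitrogen_g < 0)) {
    stop("nitrogen_g must be non-negative", call. = FALSE)
  }
  n <- nitrogen[order(nitrogen$start_min), , drop = FALSE]
  if (n$start_min[1] != 0 || n$end_min[nrow(n)] != 1440 ||
      (nrow(n) > 1 && any(n$start_min[-1] != n$end_min[-nrow(n)]))) {
    stop("nitrogen collections must partition [0, 1440) without overlap",
         call. = FALSE)
  }
  n
}

#' @export
print.chamber_session <- function(x, ...) {
  cat("24-h chamber session\n")
  cat(sprintf("  trace: %d samples at %g-min resolution\n",
              nrow(x$trace), x$interval))
  cat(sprintf("  nitrogen: %s\n",
              paste(sprintf("%s %.2f g", x$nitrogen$window,
                            x$nitrogen$nitrogen_g), collapse = ", ")))
  cat(sprintf("  diet: %.0f kcal (CHO %.0f g, protein %.0f g, fat %.0f g)\n",
              x$diet$energy_kcal, x$diet$cho_g, x$diet$protein_g,
              x$diet$fat_g))
  cat(sprintf("  %d meal(s), %d exercise bout(s)\n", nrow(x$meals),
              nrow(x$exercise_bouts)))
  invisible(x)
}

#' Read a chamber trace from delimited text
#'
#' Expects a CSV with header `t_min,vo2_lpm,vco2_lpm,activity_pct`
#' (UTF-8, empty cells for missing values).
#'
#' @param path file path.
#' @return data frame suitable for [chamber_session()].
#' @export
read_chamber_trace <- function(path) {
  tr <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("t_min", "vo2_lpm", "vco2_lpm")
  if (!all(need %in% names(tr))) {
    stop("trace file must have columns t_min, vo2_lpm, vco2_lpm",
         call. = FALSE)
  }
  tr
}

#' Read urinary nitrogen collections from CSV
#'
#' Expects columns `window,start_min,end_min,nitrogen_g` with one row per
#' 12-h collection (overnight 2000-0800 h = minutes 0-720; daytime
#' 0800-2000 h = minutes 720-1440).
#'
#' @param path file path.
#' @return validated nitrogen data frame.
#' @export
read_nitrogen <- function(path) {
  validate_nitrogen(utils::read.csv(path, stringsAsFactors = FALSE))
}

# Per-sample protein oxidation rate (g/min) from the 12-h nitrogen
# collections, apportioned pro-rata by time within each collection.
protein_rate_per_min <- function(session, calib = default_calibration()) {
  t <- session$trace$t_min
  p <- numeric(length(t))
  for (i in seq_len(nrow(session$nitrogen))) {
    w <- session$nitrogen[i, ]
    inw <- t >= w$start_min & t < w$end_min
    p[inw] <- protein_oxidation(w$nitrogen_g, calib) /
      (w$end_min - w$start_min)
  }
  p
}

#' Minute-level energy expenditure series for a session
#'
#' Applies the Brouwer stoichiometry sample-by-sample, with protein
#' oxidation apportioned pro-rata across each 12-h nitrogen collection,
#' yielding the energy-expenditure time series that the window detectors
#' and the intercept regression consume.
#'
#' @param session a [chamber_session()].
#' @param calib calibration list.
#' @return data frame with columns `t_min`, `ee_kcal_min`, `activity_pct`.
#' @export
minute_energy <- function(session, calib = default_calibration()) {
  tr <- session$trace
  dt <- session$interval
  p <- protein_rate_per_min(session, calib)
  b <- calib$brouwer$ee_kj
  ee_kj <- b[["vo2"]] * tr$vo2_lpm + b[["vco2"]] * tr$vco2_lpm +
    b[["protein"]] * p
  data.frame(t_min = tr$t_min, ee_kcal_min = ee_kj / calib$kj_per_kcal,
             activity_pct = tr$activity_pct)
}

# Protein oxidized (g) within [start, end), pro-rata across collections.
protein_in_window <- function(session, window,
                              calib = default_calibration()) {
  tot <- 0
  for (i in seq_len(nrow(session$nitrogen))) {
    w <- session$nitrogen[i, ]
    overlap <- max(0, min(window[2], w$end_min) - max(window[1], w$start_min))
    tot <- tot + protein_oxidation(w$nitrogen_g, calib) * overlap /
      (w$end_min - w$start_min)
  }
  tot
}
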
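#' Fit a baseline body-composition adjustment model
#'
#' Energy-expenditure outcomes scale with body size, so between-group
#' comparisons are adjusted for body mass and composition using ordinary
#' least-squares regressions fitted on the baseline visit only. The
#' fitted coefficients and baseline covariate means are stored and
#' reused unchanged at follow-up.
#'
#' @param baseline data frame of baseline rows.
#' @param outcome name of the outcome column.
#' @param covariates character vector of covariate columns (default
#'   fat-free mass and fat mass).
#' @return list of class `"adjustment_model"` with `coefficients`,
#'   `covariate_means`, `outcome`, `covariates` and `r_squared`.
#' @export
fit_adjustment_model <- function(baseline, outcome,
                                 covariates = c("ffm_kg", "fm_kg")) {
  stopifnot(is.data.frame(baseline),
            outcome %in% names(baseline),
            all(covariates %in% names(baseline)))
  if (nrow(baseline) < 10) {
    stop("need at least 10 baseline rows to fit an adjustment model",
         call. = FALSE)
  }
  X <- baseline[, covariates, drop = FALSE]
  degen <- vapply(X, function(x) stats::var(x) == 0, TRUE)
  if (any(degen)) {
    stop(sprintf("degenerate covariate(s): %s",
                 paste(covariates[degen], collapse = ", ")), call. = FALSE)
  }
  f <- stats::reformulate(covariates, response = outcome)
  fit <- stats::lm(f, data = baseline)
  if (any(is.na(stats::coef(fit)))) {
    stop(sprintf("singular design: collinear covariates among %s",
                 paste(covariates, collapse = ", ")), call. = FALSE)
  }
  structure(list(
    outcome = outcome,
    covariates = covariates,
    coefficients = stats::coef(fit)[covariates],
    covariate_means = colMeans(X),
    r_squared = 1 - sum(stats::resid(fit)^2) /
      sum((baseline[[outcome]] - mean(baseline[[outcome]]))^2)
  ), class = "adjustment_model")
}

#' Adjust an outcome for body composition
#'
#' Subtracts the fitted covariate effects around the baseline cohort
#' means: `adjusted = raw - sum_i beta_i (cov_i - baseline mean_i)`. By
#' construction the baseline cohort mean of the adjusted outcome equals
#' the mean of the raw outcome.
#'
#' @param row a one-row data frame (or list) holding the raw outcome and
#'   the covariates.
#' @param model an [fit_adjustment_model()] result.
#' @return the adjusted outcome value (`NA` with a warning if a covariate
#'   is missing).
#' @export
adjust_value <- function(row, model) {
  stopifnot(inherits(model, "adjustment_model"))
  raw <- row[[model$outcome]]
  covs <- vapply(model$covariates, function(v) {
    x <- row[[v]]
    if (is.null(x)) NA_real_ else as.numeric(x)
  }, numeric(1))
  if (any(!is.finite(covs)) || is.null(raw) || !is.finite(raw)) {
    warning("missing covariate or outcome; row flagged for exclusion",
            call. = FALSE)
    return(NA_real_)
  }
  raw - sum(model$coefficients * (covs - model$covariate_means))
}

#' Remove group-wise outliers beyond 3 SD
#'
#' Single-pass rule: a value more than `k` standard deviations from its
#' group mean (mean and SD computed on all values of that group) is
#' removed. The rule is deliberately non-iterative; re-screening retained
#' data is a separate, explicit call.
#'
#' @param values numeric vector.
#' @param groups group labels, same length.
#' @param k SD multiple (default 3).
#' @param ids optional identifiers for the removal log.
#' @return list with `retained` (logical vector) and `log` (data frame of
#'   removed ids, values and z-scores).
#' @export
remove_outliers <- function(values, groups, k = 3, ids = NULL) {
  stopifnot(length(values) == length(groups))
  if (is.null(ids)) ids <- seq_along(values)
  groups <- as.character(groups)
  if (any(table(groups) < 3)) {
    stop("need at least 3 values per group", call. = FALSE)
  }
  z <- numeric(length(values))
  for (g in unique(groups)) {
    i <- groups == g
    mu <- mean(values[i]); s <- stats::sd(values[i])
    z[i] <- if (s == 0) 0 else (values[i] - mu) / s
  }
  out <- abs(z) > k
  list(retained = !out,
       log = data.frame(id = ids[out], group = groups[out],
                        value = values[out], z = z[out]))
}

#' Group-by-time effect via baseline-adjusted change-score ANCOVA
#'
#' For a two-timepoint randomized design the group-by-time interaction of
#' a mixed-model ANCOVA is estimated equivalently by regressing the
#' change score (follow-up minus baseline) on the group indicator, the
#' baseline value, and any co-intervention covariates. The group
#' coefficient is the adjusted between-group difference in change; its
#' standard error and two-sided p-value are reported.
#'
#' @param baseline,followup numeric vectors, paired by position.
#' @param group factor/character of group labels (two levels); the effect
#'   is reported for the second level relative to the first.
#' @param covariates optional data frame of additional covariates (e.g.
#'   the co-intervention indicator).
#' @param outcome optional outcome name for the result.
#' @param outlier_k if non-`NULL`, change scores are screened group-wise
#'   with [remove_outliers()] at this SD multiple before fitting.
#' @param ids optional identifiers for the removal log.
#' @return list of class `"effect_result"`: `effect`, `se`, `p`, `df`,
#'   `n_per_group`, `outliers_removed` and `contrast`.
#' @export
group_by_time_ancova <- function(baseline, followup, group,
                                 covariates = NULL, outcome = NULL,
                                 outlier_k = NULL, ids = NULL) {
  stopifnot(length(baseline) == length(followup),
            length(group) == length(baseline))
  group <- factor(group)
  if (nlevels(group) != 2) stop("need exactly two groups", call. = FALSE)
  ok <- is.finite(baseline) & is.finite(followup)
  if (!all(ok)) {
    message(sprintf("excluding %d unpaired/missing row(s)", sum(!ok)))
  }
  d <- data.frame(change = followup - baseline, baseline = baseline,
                  group = group)[ok, , drop = FALSE]
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)[ok, , drop = FALSE]
    d <- cbind(d, covariates)
  }
  removed <- data.frame()
  if (!is.null(outlier_k)) {
    scr <- remove_outliers(d$change, d$group, k = outlier_k,
                           ids = if (is.null(ids)) which(ok) else ids[ok])
    removed <- scr$log
    d <- d[scr$retained, , drop = FALSE]
  }
  f <- stats::reformulate(c("group", "baseline",
                            if (!is.null(covariates)) names(covariates)),
                          response = "change")
  fit <- stats::lm(f, data = d)
  if (stats::df.residual(fit) < 1) {
    stop("zero residual degrees of freedom", call. = FALSE)
  }
  sm <- summary(fit)$coefficients
  term <- paste0("group", levels(group)[2])
  structure(list(
    outcome = outcome,
    contrast = sprintf("%s vs %s", levels(group)[2], levels(group)[1]),
    effect = sm[term, "Estimate"],
    se = sm[term, "Std. Error"],
    p = sm[term, "Pr(>|t|)"],
    df = stats::df.residual(fit),
    n_per_group = table(d$group),
    outliers_removed = removed
  ), class = "effect_result")
}

#' @export
print.effect_result <- function(x, ...) {
  cat(sprintf("%s%s: effect %.2f (SE %.2f), p = %.4g [n = %s]\n",
              if (is.null(x$outcome)) "" else paste0(x$outcome, ", "),
              x$contrast, x$effect, x$se, x$p,
              paste(x$n_per_group, collapse = "/")))
  if (nrow(x$outliers_removed)) {
    cat(sprintf("  %d outlier(s) removed\n", nrow(x$outliers_removed)))
  }
  invisible(x)
}

#' Within-group paired change test
#'
#' Two-sided paired t-test on follow-up minus baseline. Zero variance of
#' the differences is reported as exact equality with an undefined
#' p-value flag rather than an error.
#'
#' @param baseline,followup paired numeric vectors.
#' @return list with `mean_change`, `t`, `p`, `df` and `p_defined`.
#' @export
paired_change_test <- function(baseline, followup) {
  stopifnot(length(baseline) == length(followup), length(baseline) >= 3)
  d <- followup - baseline
  if (stats::sd(d) == 0) {
    return(list(mean_change = mean(d), t = NA_real_, p = NA_real_,
                df = length(d) - 1, p_defined = FALSE))
  }
  tt <- stats::t.test(followup, baseline, paired = TRUE)
  list(mean_change = unname(tt$estimate), t = unname(tt$statistic),
       p = tt$p.value, df = unname(tt$parameter), p_defined = TRUE)
}

#' Partial correlation controlled for group
#'
#' Pearson correlation of the residuals of `x` and `y` after regressing
#' each on the group indicator; isolates the within-group association
#' from between-group (intervention) differences.
#'
#' @param x,y numeric vectors.
#' @param group group labels.
#' @return list with `r`, `n` and `defined` (FALSE when either residual
#'   variance is zero).
#' @export
partial_correlation <- function(x, y, group) {
  stopifnot(length(x) == length(y), length(group) == length(x))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]; g <- factor(group[ok])
  if (length(x) < 4) stop("need n >= 4", call. = FALSE)
  rx <- stats::resid(stats::lm(x ~ g))
  ry <- stats::resid(stats::lm(y ~ g))
  tol <- 1e-10 * (stats::sd(x) + stats::sd(y) + 1)
  if (stats::sd(rx) < tol || stats::sd(ry) < tol) {
    return(list(r = NA_real_, n = length(x), defined = FALSE))
  }
  list(r = stats::cor(rx, ry), n = length(x), defined = TRUE)
}
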
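test_that("baseline adjustment model recovers exact and noisy coefficients", {
  set.seed(21)
  base <- data.frame(ffm_kg = rnorm(40, 60, 6), fm_kg = rnorm(40, 19, 4))
  base$rmr <- 370 + 21.6 * base$ffm_kg          # exactly linear, no noise
  m <- fit_adjustment_model(base, "rmr", covariates = "ffm_kg")
  expect_equal(unname(m$coefficients[["ffm_kg"]]), 21.6)
  expect_equal(m$r_squared, 1)

  base$rmr_noisy <- 370 + 21.6 * base$ffm_kg + rnorm(40, 0, 50)
  m2 <- fit_adjustment_model(base, "rmr_noisy")
  expect_lt(abs(m2$coefficients[["ffm_kg"]] - 21.6), 3)

  base$const <- 1
  expect_error(fit_adjustment_model(base, "rmr", covariates = "const"),
               "degenerate")
  expect_error(fit_adjustment_model(base[1:5, ], "rmr"), "10 baseline rows")
})

test_that("adjustment recentres on baseline covariate means", {
  set.seed(22)
  base <- data.frame(ffm_kg = rnorm(30, 60, 5), fm_kg = rnorm(30, 20, 4))
  base$ee <- 500 + 20 * base$ffm_kg + 5 * base$fm_kg + rnorm(30, 0, 30)
  m <- fit_adjustment_model(base, "ee")

  # a row sitting at the covariate means is returned unchanged
  at_mean <- data.frame(ee = 1700,
                        ffm_kg = m$covariate_means[["ffm_kg"]],
                        fm_kg = m$covariate_means[["fm_kg"]])
  expect_equal(adjust_value(at_mean, m), 1700)

  # two rows differing only by 1 kg FFM adjust to equality when raw
  # values differ by exactly the FFM coefficient
  b <- m$coefficients[["ffm_kg"]]
  r1 <- data.frame(ee = 1700, ffm_kg = 60, fm_kg = 20)
  r2 <- data.frame(ee = 1700 + b, ffm_kg = 61, fm_kg = 20)
  expect_equal(adjust_value(r1, m), adjust_value(r2, m))

  # cohort mean preservation at baseline
  adj <- vapply(seq_len(nrow(base)), function(i) {
    adjust_value(base[i, ], m)
  }, numeric(1))
  expect_equal(mean(adj), mean(base$ee))

  # missing covariate flags the row
  expect_warning(na <- adjust_value(data.frame(ee = 1, ffm_kg = NA,
                                               fm_kg = 20), m), "missing")
  expect_true(is.na(na))
})

test_that("outlier screening is a single non-iterative 3-SD pass", {
  same <- remove_outliers(rep(5, 10), rep("a", 10))
  expect_true(all(same$retained))

  # a single extreme value can hide by inflating its own group SD
  vals <- c(rep(0, 9), 100)
  r <- remove_outliers(vals, rep("a", 10))
  expect_true(all(r$retained))          # z of the 100 is only 2.85
  expect_equal(nrow(r$log), 0)

  # a genuine 5-SD artefact against background scatter is removed
  set.seed(23)
  x <- c(rnorm(15, 0, 10), 120)
  r2 <- remove_outliers(x, rep("g", 16), ids = sprintf("P%02d", 1:16))
  expect_false(r2$retained[16])
  expect_equal(sum(!r2$retained), 1)
  expect_equal(r2$log$id, "P16")
  expect_error(remove_outliers(1:4, c("a", "a", "b", "b")), "3 values")
})

test_that("change-score ANCOVA is null on label-permuted identical groups", {
  set.seed(24)
  base <- rnorm(12, 100, 10); fol <- base + rnorm(12, 5, 3)
  baseline <- c(base, base); followup <- c(fol, fol)
  grp <- rep(c("A", "B"), each = 12)
  r <- group_by_time_ancova(baseline, followup, grp)
  expect_equal(r$effect, 0, tolerance = 1e-10)
  expect_gt(r$p, 0.99)
})

test_that("ANCOVA recovers an injected effect and ignores common shifts", {
  set.seed(25)
  n <- 40
  grp <- rep(c("ctl", "trt"), each = n)
  base <- rnorm(2 * n, 1600, 120)
  fol <- base + 10 + 36 * (grp == "trt") + rnorm(2 * n, 0, 30)
  r <- group_by_time_ancova(base, fol, grp)
  expect_lt(abs(r$effect - 36), 3 * r$se)
  expect_lt(r$p, 0.01)

  # invariance to adding a constant to every follow-up value
  r2 <- group_by_time_ancova(base, fol + 500, grp)
  expect_equal(r2$effect, r$effect)
  expect_equal(r2$se, r$se)

  # co-intervention covariate is accepted and reported
  co <- rep(c("x", "y"), n)
  r3 <- group_by_time_ancova(base, fol, grp,
                             covariates = data.frame(diet = co),
                             outcome = "rmr")
  expect_match(r3$contrast, "trt vs ctl")
  expect_output(print(r3), "rmr")

  # group-wise outlier screen on the change scores
  fol_out <- fol; fol_out[1] <- base[1] + 2000
  r4 <- group_by_time_ancova(base, fol_out, grp, outlier_k = 3)
  expect_equal(nrow(r4$outliers_removed), 1)
})

test_that("paired change test matches hand-computed t statistics", {
  b <- c(10, 20, 30, 40, 50)
  expect_equal(paired_change_test(b, b)$mean_change, 0)
  r <- paired_change_test(b, b + c(1, 2, 3, 4, 5))
  expect_equal(r$mean_change, 3)
  expect_equal(r$t, 4.2426, tolerance = 1e-4)
  expect_equal(r$df, 4)

  z <- paired_change_test(b, b + 2)
  expect_false(z$p_defined)
  expect_equal(z$mean_change, 2)
})

test_that("partial correlation isolates within-group association", {
  set.seed(26)
  g <- rep(c("a", "b"), each = 20)
  x <- rnorm(40)
  # y = x within groups: r = 1 despite a big between-group offset
  y <- x + ifelse(g == "a", 100, -100)
  expect_equal(partial_correlation(x, y, g)$r, 1)

  # association living purely between groups vanishes
  x2 <- rnorm(40) + ifelse(g == "a", 10, -10)
  y2 <- rnorm(40) + ifelse(g == "a", 10, -10)
  expect_lt(abs(partial_correlation(x2, y2, g)$r), 0.4)

  expect_error(partial_correlation(1:3, 1:3, c("a", "a", "b")), "n >= 4")
  und <- partial_correlation(c(1, 1, 2, 2), c(5, 5, 7, 7),
                             c("a", "a", "b", "b"))
  expect_false(und$defined)
})

test_that("ANCOVA attains nominal type-I error under the null", {
  set.seed(27)
  hits <- replicate(800, {
    grp <- rep(c("A", "B"), c(16, 17))
    base <- rnorm(33, 1600, 120)
    fol <- base + rnorm(33, 0, 40)
    group_by_time_ancova(base, fol, grp)$p < 0.05
  })
  expect_lt(abs(mean(hits) - 0.05), 0.025)
})
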
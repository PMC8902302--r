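# two-pass oracle variances used to cross-check the percent-scale estimators
brute_var <- function(x) {
  m <- sum(x) / length(x)
  sum((x - m)^2) / (length(x) - 1)
}

test_that("percent change follows the baseline-relative definition", {
  expect_equal(percent_change(100, 95), -5)
  expect_equal(percent_change(250, 250), 0)
  expect_equal(percent_change(61.8, 63), (63 - 61.8) / 61.8 * 100)
  expect_error(percent_change(0, 5), "positive")
  expect_error(percent_change(-2, 5), "positive")
  # scale invariance
  set.seed(41)
  for (i in 1:20) {
    x <- runif(1, 50, 500); y <- runif(1, 50, 500); c0 <- runif(1, 0.1, 10)
    expect_equal(percent_change(c0 * x, c0 * y), percent_change(x, y),
                 tolerance = 1e-12)
  }
})

test_that("observed uncertainty is the unbiased variance of percent changes", {
  expect_equal(observed_uncertainty(c(-1, -3)), 2)
  expect_equal(observed_uncertainty(c(-4, -4, -4)), 0)
  set.seed(7)
  for (i in 1:25) {
    x <- rnorm(7, -3, 2)
    expect_equal(observed_uncertainty(x), brute_var(x), tolerance = 1e-12)
  }
  expect_error(observed_uncertainty(-5), "at least 2")
})

test_that("per-subject measurement uncertainty is on the percent^2 scale", {
  expect_equal(subject_measurement_uncertainty(c(85, 85)), 0)
  expect_equal(subject_measurement_uncertainty(c(100, 102)),
               2 * (100 / 101)^2)
  expect_equal(subject_measurement_uncertainty(c(98, 100, 102)), 4)
  set.seed(8)
  for (i in 1:25) {
    x <- runif(2, 200, 400)
    expect_equal(subject_measurement_uncertainty(x),
                 brute_var(x) * (100 / mean(x))^2, tolerance = 1e-12)
  }
  expect_error(subject_measurement_uncertainty(100), "at least 2")
})

test_that("pooling averages per-subject uncertainties", {
  expect_equal(pooled_measurement_uncertainty(c(1, 3)), 2)
  expect_equal(pooled_measurement_uncertainty(0.73), 0.73)
  expect_error(pooled_measurement_uncertainty(numeric(0)), "no per-subject")
})

test_that("the donor rule resolves own, borrowed and fallback cases", {
  um <- reference_umeas()
  own <- assign_measurement_uncertainty("RSL", "TIBIA_04", um)
  expect_equal(own, list(u_meas = 0.09, provenance = "own", donor = "RSL"))

  # manual TIBIA_66 detection steers MEP to LTBR, not to the smaller RSL value
  mep <- assign_measurement_uncertainty("MEP", "TIBIA_66", um)
  expect_equal(mep$u_meas, 0.15)
  expect_equal(mep$donor, "LTBR")
  expect_equal(mep$provenance, "borrowed")

  # frontal proximal scout steers Planhab's TIBIA_98 to Valdoltra
  p98 <- assign_measurement_uncertainty("Planhab", "TIBIA_98", um)
  expect_equal(p98$u_meas, 1.92)
  expect_equal(p98$donor, "Valdoltra")

  # Planhab's preferred donor (Valdoltra) lacks MUSCLE_66: fallback maximum
  pm <- assign_measurement_uncertainty("Planhab", "MUSCLE_66", um)
  expect_equal(pm$u_meas, 2.95)
  expect_equal(pm$provenance, "fallback_max")
  expect_equal(pm$donor, "LTBR")

  # sagittal scout + automatic detection steer AGBRESA to RSL
  ag <- assign_measurement_uncertainty("AGBRESA", "MUSCLE_38", um)
  expect_equal(ag$u_meas, 0.73)
  expect_equal(ag$donor, "RSL")

  expect_error(
    assign_measurement_uncertainty("MEP", "TIBIA_04_COMP", um),
    "no study provides")
})

test_that("the borrowing rule is total over the packaged studies and the
          recomputed subtractions agree with the published table", {
  rd <- reference_decomposition()
  expect_equal(nrow(rd), nrow(reference_uobs()))
  expect_true(all(rd$u_meas >= 0))
  # every recomputed value within one unit of the last printed decimal
  expect_lte(max(abs(rd$u_ir - rd$u_ir_published)), 0.02 + 1e-12)
  # exact rows are exactly reproduced (incl. the preserved negative)
  exact <- function(study, site) {
    r <- rd[rd$study == study & rd$site == site, ]
    expect_equal(r$u_ir, r$u_ir_published, tolerance = 1e-12)
  }
  exact("AGBRESA", "MUSCLE_38")
  exact("RSL", "MUSCLE_66")
  exact("LTBR", "MUSCLE_66")
  exact("Planhab", "MUSCLE_66")
  exact("MEP", "TIBIA_66")
  exact("Planhab", "TIBIA_98")
  expect_lt(rd$u_ir[rd$study == "MEP" & rd$site == "TIBIA_66"], 0)
})

test_that("individual response uncertainty is subtraction, preserved if
          negative, and ABD handles its degenerate cases", {
  expect_equal(individual_response_uncertainty(18.85, 0.73), 18.12)
  expect_equal(individual_response_uncertainty(0.08, 0.15), -0.07)
  expect_equal(individual_response_uncertainty(5, 0), 5)

  expect_equal(adjusted_between_subject_deviation(4, -4, 4), 0.125)
  expect_equal(adjusted_between_subject_deviation(0, -2, 3), 0)
  expect_true(is.na(adjusted_between_subject_deviation(-0.07, -1, 3)))
  expect_true(is.na(adjusted_between_subject_deviation(4, 0, 3)))
  # sign convention: dispersion is positive whatever the sign of the mean
  expect_equal(adjusted_between_subject_deviation(4, 4, 4), 0.125)
})

test_that("decompose satisfies the superposition identity and recovers the
          generating parameters", {
  # zero-noise cohort: all measurement uncertainty zero, U_IR = U_Obs
  cfg0 <- muscle_config(n = 30, response_sd = 2, noise_sd = 0)
  d0 <- decompose(generate_cohort(cfg0, seed = 3))
  expect_equal(d0$u_meas, rep(0, nrow(d0)))
  expect_equal(d0$u_ir, d0$u_obs)

  # identity holds to machine precision on a noisy cohort
  cfg <- muscle_config(n = 40, response_sd = 3, noise_sd = 1)
  dd <- decompose(generate_cohort(cfg, seed = 4))
  expect_equal(dd$u_ir, dd$u_obs - dd$u_meas, tolerance = 1e-14)
  expect_true(all(dd$u_meas_provenance == "own"))

  # single-replicate recovery at n = 500 against the truth table
  cfg5 <- muscle_config(n = 500, response_sd = 3, noise_sd = 1)
  d5 <- decompose(generate_cohort(cfg5, seed = 19))
  tt <- truth_table(cfg5)
  j <- dplyr::inner_join(d5, tt, by = c("study", "site"))
  expect_lt(max(abs(j$u_meas - j$true_u_meas) / j$true_u_meas), 0.15)
  expect_lt(max(abs(j$u_ir - j$true_u_ir) / j$true_u_ir), 0.15)
})

test_that("one-way ANOVA matches the between/within mean-square oracle", {
  g <- list(a = c(1, 2, 3), b = c(1, 2, 3))
  expect_equal(compare_uncertainties_anova(g)$f, 0)

  # textbook three-group comparison against the closed form
  g3 <- list(a = c(6.2, 5.9, 6.8, 6.1), b = c(7.5, 7.1, 6.9),
             c = c(5.1, 5.6, 5.3, 5.2, 5.5))
  res <- compare_uncertainties_anova(g3)
  y <- unlist(g3); k <- length(g3); n <- length(y)
  gm <- mean(y)
  ssb <- sum(vapply(g3, function(v) length(v) * (mean(v) - gm)^2, numeric(1)))
  ssw <- sum(vapply(g3, function(v) sum((v - mean(v))^2), numeric(1)))
  f_oracle <- (ssb / (k - 1)) / (ssw / (n - k))
  expect_equal(res$f, f_oracle, tolerance = 1e-10)
  expect_equal(res$p, stats::pf(f_oracle, k - 1, n - k, lower.tail = FALSE),
               tolerance = 1e-10)

  expect_true(compare_uncertainties_anova(list(a = c(1, 1), b = c(1, 1)))$degenerate)
  expect_error(compare_uncertainties_anova(list(a = 1:3)), "groups")
})

test_that("ANOVA type-I error is nominal under the null", {
  set.seed(90)
  reject <- replicate(1000, {
    g <- list(a = rnorm(8), b = rnorm(8))
    compare_uncertainties_anova(g)$p < 0.05
  })
  expect_lt(abs(mean(reject) - 0.05), 0.02)
})

test_that("the paired change test matches the difference closed form and has
          power against a real shift", {
  x <- c(100, 110, 95, 102)
  res0 <- paired_change_test(x, x)
  expect_true(res0$degenerate)
  expect_equal(res0$t, 0)
  expect_equal(res0$p, 1)

  y <- c(96, 104, 94, 97)
  res <- paired_change_test(x, y)
  d <- y - x
  t_oracle <- mean(d) / (sd(d) / sqrt(length(d)))
  expect_equal(res$t, t_oracle, tolerance = 1e-12)
  expect_equal(res$df, 3)
  expect_equal(res$p, 2 * stats::pt(-abs(t_oracle), 3), tolerance = 1e-12)

  set.seed(123)
  hits <- replicate(200, {
    b <- rnorm(10, 100, 2)
    r <- b * 0.95 + rnorm(10, 0, 0.5)
    paired_change_test(b, r)$p < 0.01
  })
  expect_gt(mean(hits), 0.95)
})
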
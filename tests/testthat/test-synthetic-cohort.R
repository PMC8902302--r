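test_that("zero-noise, zero-spread cohorts show exactly the configured loss", {
  tp <- tibble::tibble(study = "SIM", site = "MUSCLE_66", true_pc = -5)
  cfg <- muscle_config(n = 8, response_sd = 0, noise_sd = 0,
                       sites = "MUSCLE_66", true_pc = tp)
  ds <- generate_cohort(cfg, seed = 1)
  pcs <- pc_table(ds)
  expect_equal(pcs$pc, rep(-5, 8), tolerance = 1e-12)
})

test_that("generation is a pure function of config and seed", {
  cfg <- muscle_config(n = 10, seed = 99)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$records, b$records)
  c <- generate_cohort(cfg, seed = 100)
  expect_false(isTRUE(all.equal(a$records$value, c$records$value)))
})

test_that("truth_table reports generating parameters on the estimator scale", {
  cfg <- muscle_config(n = 5, response_sd = 3, noise_sd = 0.5)
  tt <- truth_table(cfg)
  expect_setequal(tt$site, c("MUSCLE_38", "MUSCLE_66"))
  expect_equal(tt$true_u_ir, rep(9, 2))
  expect_equal(tt$true_u_meas, rep(0.25, 2))

  # completeness over a multi-study design, including compartments
  cfg8 <- sim_config(seed = 1)
  tt8 <- truth_table(cfg8)
  d <- bundled_designs()
  want <- sum(vapply(seq_len(nrow(d)), function(i) {
    tot <- c(d$muscle_sites[[i]], d$bone_sites[[i]])
    epi <- sum(site_class(tot) == "epiphysis" & site_tissue(tot) == "bone")
    length(tot) + 2 * epi
  }, numeric(1)))
  expect_equal(nrow(tt8), want)
})

test_that("duplicate baselines recover the configured noise variance", {
  cfg <- muscle_config(n = 500, response_sd = 3, noise_sd = 1,
                       sites = "MUSCLE_66")
  ds <- generate_cohort(cfg, seed = 202)
  um <- duplicate_baseline_umeas(ds)
  expect_equal(um$n_pairs, 500)
  expect_lt(abs(um$u_meas - 1.0) / 1.0, 0.10)
})

test_that("percent-change variance obeys the noise-mode accounting", {
  # single_draw: Var(pc) ~ U_IR + U_Meas; per_scan: ~ U_IR + 2 U_Meas
  # (the per_scan accounting is a small-change approximation, so the mean
  # loss is kept small here)
  for (mode in c("single_draw", "per_scan")) {
    des <- toy_design(n_subjects = 2000, muscle_sites = "MUSCLE_66")
    cfg <- sim_config(designs = des, response_sd = c(MUSCLE_66 = 2),
                      scan_noise_sd_pct = c(MUSCLE_66 = 1.5),
                      true_pc = tibble::tibble(study = "SIM",
                                               site = "MUSCLE_66",
                                               true_pc = -2),
                      noise_mode = mode, seed = 7)
    pcs <- pc_table(generate_cohort(cfg, seed = 31))
    expected <- 4 + 1.5^2 * (if (mode == "per_scan") 2 else 1)
    expect_lt(abs(var(pcs$pc) - expected) / expected, 0.10,
              label = paste("relative variance error,", mode))
  }
})

test_that("inter-site correlation of simulated responses tracks the config", {
  base <- function(rho, seed) {
    cfg <- muscle_config(n = 500, response_sd = 3, noise_sd = 0, rho = rho)
    pcs <- pc_table(generate_cohort(cfg, seed = seed))
    wide <- tidyr::pivot_wider(pcs[, c("subject", "site", "pc")],
                               names_from = "site", values_from = "pc")
    cor(wide$MUSCLE_38, wide$MUSCLE_66)
  }
  expect_gt(base(1, 11), 0.999)
  expect_lt(abs(base(0, 12)), 0.15)
})

test_that("epiphyseal compartments sum exactly to the total series", {
  des <- toy_design(muscle_sites = character(0),
                    bone_sites = c("TIBIA_04", "TIBIA_98"), n_subjects = 12)
  cfg <- sim_config(designs = des, seed = 5)
  ds <- generate_cohort(cfg, seed = 5)
  rec <- ds$records
  for (parent in c("TIBIA_04", "TIBIA_98")) {
    tot <- rec$value[rec$site == parent]
    comp <- rec$value[rec$site == paste0(parent, "_COMP")]
    trab <- rec$value[rec$site == paste0(parent, "_TRAB")]
    expect_equal(comp + trab, tot, tolerance = 1e-12)
  }
})

test_that("both-legs studies add baseline-only left-leg series", {
  des <- toy_design(study = "LEGS", muscle_sites = "MUSCLE_66",
                    n_subjects = 15)
  cfg <- sim_config(designs = des, both_legs_studies = "LEGS", seed = 2)
  ds <- generate_cohort(cfg, seed = 2)
  left <- ds$records[ds$records$side == "L", ]
  expect_setequal(unique(left$timepoint), c("BDC1", "BDC2"))
  expect_equal(nrow(dplyr::distinct(left, subject)), 15)
  um <- duplicate_baseline_umeas(ds)
  expect_equal(um$n_pairs, 30)  # both legs pooled
})

test_that("pathological configs that drive values non-positive error out", {
  tp <- tibble::tibble(study = "SIM", site = "MUSCLE_66", true_pc = -150)
  cfg <- muscle_config(n = 4, response_sd = 0, noise_sd = 0,
                       sites = "MUSCLE_66", true_pc = tp)
  expect_error(generate_cohort(cfg, seed = 1), "non-positive")
})
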
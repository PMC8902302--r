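#' Default generator parameters
#'
#' Baseline site means, between-subject response SDs and per-scan noise SDs
#' used by [sim_config()]. Magnitudes are chosen to be typical of lower-leg
#' pQCT in bed-rest cohorts: tibia BMC of a few hundred mg/mm rising from
#' the distal epiphysis to the proximal one, calf muscle CSA of several
#' thousand mm2, scan noise below ~1% for bone (larger at the proximal
#' epiphysis, where frontal scout views are hard to reposition) and around
#' 1% for muscle, and response spreads of a few percent for muscle and
#' under two percent for bone.
#'
#' @return Named numeric vector keyed by site code.
#' @export
default_site_means <- function() {
  c(MUSCLE_38 = 6200, MUSCLE_66 = 7400,
    TIBIA_04 = 310, TIBIA_38 = 345, TIBIA_66 = 395, TIBIA_98 = 620)
}

#' @rdname default_site_means
#' @export
default_response_sd <- function() {
  c(MUSCLE_38 = 3.0, MUSCLE_66 = 3.0,
    TIBIA_04 = 1.8, TIBIA_38 = 0.8, TIBIA_66 = 0.8, TIBIA_98 = 1.8,
    TIBIA_04_COMP = 2.0, TIBIA_04_TRAB = 2.0,
    TIBIA_98_COMP = 2.0, TIBIA_98_TRAB = 2.0)
}

#' @rdname default_site_means
#' @export
default_scan_noise_sd <- function() {
  c(MUSCLE_38 = 0.85, MUSCLE_66 = 1.10,
    TIBIA_04 = 0.50, TIBIA_38 = 0.30, TIBIA_66 = 0.30, TIBIA_98 = 1.00)
}

#' Default mean percent changes per study and site
#'
#' Muscle wasting follows an exponential approach to a ~24% plateau
#' calibrated so that ~6% is lost after 8 days (time constant ~27.8 days);
#' bone loss accrues at 1.25% of BMC per month of bed rest. Both are the
#' canonical magnitudes for disuse in the lower leg.
#'
#' @param designs Design table.
#' @return Tibble `study, site, true_pc` covering every designed site and
#'   the compact/trabecular compartments of epiphyseal sites.
#' @export
default_true_pc <- function(designs = bundled_designs()) {
  meta <- site_table()
  rows <- purrr::pmap(designs, function(study, duration_days, muscle_sites,
                                        bone_sites, ...) {
    sites <- c(muscle_sites, bone_sites)
    sites <- c(sites, meta$site[meta$parent_site %in% sites &
                                  meta$compartment != "total"])
    pc <- ifelse(
      site_tissue(sites) == "muscle",
      -24 * (1 - exp(-duration_days / 27.8)),
      -1.25 * duration_days / 30
    )
    tibble::tibble(study = study, site = sites, true_pc = pc)
  })
  dplyr::bind_rows(rows)
}

#' Simulation configuration
#'
#' Bundles and validates all parameters of the synthetic multi-study cohort
#' generator. Generation is a pure function of `(config, seed)`.
#'
#' Variance-structure defaults follow the mixed-model components reported
#' for this class of data: baseline between-subject SD 47.1 mg/mm for bone
#' and 8.9 mm2 for muscle, between-study SD 4.9 mg/mm and 3.0 mm2, and
#' inter-site response correlations of 0.9 within muscle and 0.4 within
#' bone (compact vs trabecular compartments of the same epiphysis
#' uncorrelated).
#'
#' @param designs Design table of the studies to simulate.
#' @param n_subjects Named integer vector (study -> cohort size); defaults
#'   to the `n_subjects` column of `designs`.
#' @param control_fraction Fraction of each cohort assigned to the control
#'   group (default 1; intervention subjects contribute to measurement
#'   uncertainty estimation only).
#' @param site_means Named vector of baseline means (mg/mm or mm2).
#' @param subject_sd,study_sd Named vectors `c(bone = , muscle = )` of
#'   baseline between-subject and between-study SDs.
#' @param true_pc Tibble `study, site, true_pc` of mean percent changes;
#'   defaults to [default_true_pc()]. Compartment sites inherit their
#'   parent's value when omitted.
#' @param response_sd Named vector of between-subject response SDs (%).
#' @param intersite_rho Named vector `c(muscle = , bone = )`: correlation
#'   of a subject's response deviations across sites of a tissue.
#' @param comp_trab_rho Correlation between compact and trabecular response
#'   deviations of the same epiphysis (default 0).
#' @param scan_noise_sd_pct Named vector of per-scan noise SDs (%).
#'   Compartment series share their parent scan's noise draw (one scan, one
#'   repositioning error).
#' @param noise_mode `"single_draw"` (default): exactly one noise draw
#'   enters each percent change, so the superposition identity
#'   U_Obs = U_IR + U_Meas holds exactly in expectation; `"per_scan"`:
#'   every scan gets independent noise (realistic; then
#'   U_Obs ~ U_IR + 2 U_Meas).
#' @param endo_model List `slope` (mg/mm of absolute bone loss per mm of
#'   endocortical circumference), `resid_sd` (mg/mm), `mean` (named vector
#'   of endocortical circumferences per bone site, mm), `sd` (mm).
#' @param comp_fraction Named vector: compact-bone fraction of epiphyseal
#'   BMC.
#' @param both_legs_studies Studies for which both legs are scanned at
#'   baseline (extra leg used for measurement-uncertainty estimation only).
#' @param seed Integer seed.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(designs = bundled_designs(),
                       n_subjects = NULL,
                       control_fraction = 1,
                       site_means = default_site_means(),
                       subject_sd = c(bone = 47.1, muscle = 8.9),
                       study_sd = c(bone = 4.9, muscle = 3.0),
                       true_pc = NULL,
                       response_sd = default_response_sd(),
                       intersite_rho = c(muscle = 0.9, bone = 0.4),
                       comp_trab_rho = 0,
                       scan_noise_sd_pct = default_scan_noise_sd(),
                       noise_mode = c("single_draw", "per_scan"),
                       endo_model = list(slope = 0.5, resid_sd = 0,
                                         mean = c(TIBIA_04 = 80, TIBIA_38 = 35,
                                                  TIBIA_66 = 42, TIBIA_98 = 110),
                                         sd = 5),
                       comp_fraction = c(TIBIA_04 = 0.35, TIBIA_98 = 0.25),
                       both_legs_studies = character(0),
                       seed = 1L) {
  noise_mode <- match.arg(noise_mode)
  if (is.null(n_subjects)) {
    n_subjects <- stats::setNames(designs$n_subjects, designs$study)
  }
  if (anyNA(n_subjects) || any(n_subjects < 1)) {
    stop("n_subjects must be >= 1 for every study", call. = FALSE)
  }
  if (is.null(true_pc)) true_pc <- default_true_pc(designs)
  stopifnot(all(c("study", "site", "true_pc") %in% names(true_pc)))
  if (any(response_sd < 0) || any(scan_noise_sd_pct < 0) ||
      any(subject_sd < 0) || any(study_sd < 0)) {
    stop("all SDs must be >= 0", call. = FALSE)
  }
  if (any(abs(intersite_rho) > 1) || abs(comp_trab_rho) > 1) {
    stop("correlations must lie in [-1, 1]", call. = FALSE)
  }
  stopifnot(control_fraction > 0, control_fraction <= 1)
  cfg <- list(designs = designs, n_subjects = n_subjects,
              control_fraction = control_fraction, site_means = site_means,
              subject_sd = subject_sd, study_sd = study_sd,
              true_pc = tibble::as_tibble(true_pc),
              response_sd = response_sd, intersite_rho = intersite_rho,
              comp_trab_rho = comp_trab_rho,
              scan_noise_sd_pct = scan_noise_sd_pct,
              noise_mode = noise_mode, endo_model = endo_model,
              comp_fraction = comp_fraction,
              both_legs_studies = both_legs_studies,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> ", nrow(x$designs), " studies, ",
      sum(x$n_subjects[x$designs$study]), " subjects, noise_mode=",
      x$noise_mode, ", seed=", x$seed, "\n", sep = "")
  invisible(x)
}

# --- internal helpers ------------------------------------------------------

# sites a study generates: designed totals plus epiphyseal compartments
study_sites <- function(design_row) {
  meta <- site_table()
  totals <- design_sites(design_row)
  comps <- meta$site[meta$parent_site %in% totals & meta$compartment != "total"]
  list(totals = totals, components = comps)
}

lookup_param <- function(vec, site, what) {
  if (!site %in% names(vec)) {
    stop("no ", what, " configured for site ", site, call. = FALSE)
  }
  unname(vec[[site]])
}

lookup_true_pc <- function(cfg, study, site) {
  hit <- cfg$true_pc$true_pc[cfg$true_pc$study == study &
                               cfg$true_pc$site == site]
  if (length(hit)) return(hit[[1]])
  parent <- site_table()$parent_site[site_table()$site == site]
  hit <- cfg$true_pc$true_pc[cfg$true_pc$study == study &
                               cfg$true_pc$site == parent]
  if (length(hit)) return(hit[[1]])
  stop(sprintf("no true_pc configured for (%s, %s)", study, site),
       call. = FALSE)
}

# exchangeable correlation over generated sites of one tissue, with the
# compact/trabecular pair of one epiphysis at its own correlation
response_sigma <- function(cfg, gen_sites) {
  k <- length(gen_sites)
  meta <- site_table()
  tiss <- site_tissue(gen_sites)
  rho <- matrix(0, k, k)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i == j) { rho[i, j] <- 1; next }
      pi <- meta$parent_site[meta$site == gen_sites[i]]
      pj <- meta$parent_site[meta$site == gen_sites[j]]
      rho[i, j] <- if (pi == pj) cfg$comp_trab_rho
                   else unname(cfg$intersite_rho[[tiss[i]]])
    }
  }
  sds <- vapply(gen_sites, function(s)
    lookup_param(cfg$response_sd, s, "response_sd"), numeric(1))
  sigma <- diag(sds, k) %*% rho %*% diag(sds, k)
  if (min(eigen(sigma, symmetric = TRUE, only.values = TRUE)$values) < -1e-8) {
    stop("response correlation structure is not positive semi-definite",
         call. = FALSE)
  }
  sigma
}

draw_mvn <- function(n, sigma) {
  if (all(sigma == 0)) {
    return(matrix(0, n, ncol(sigma)))
  }
  MASS::mvrnorm(n, mu = rep(0, ncol(sigma)), Sigma = sigma, tol = 1e-7)
}

# --- generator -------------------------------------------------------------

#' Generate a synthetic multi-study cohort
#'
#' Simulates scan records under the variance model the decomposition
#' assumes. Per subject and tissue, a baseline level is the site mean plus
#' a study effect and a subject effect; the true response (percent change)
#' at each site is the study-site mean change plus a mean-zero multivariate
#' normal subject deviation with the configured inter-site correlation; for
#' bone an endocortical-circumference covariate tilts the response through
#' the configured linear link. Epiphyseal sites are generated as compact
#' plus trabecular compartments whose sum is emitted as the total series.
#' Observed values carry multiplicative per-scan noise according to
#' `noise_mode` (see [sim_config()]).
#'
#' @param config A [sim_config()].
#' @param seed Overrides `config$seed` when given.
#' @return A [bedrest_dataset()].
#' @export
generate_cohort <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  recs <- lapply(seq_len(nrow(config$designs)), function(i) {
    generate_study(config, config$designs[i, ])
  })
  records <- dplyr::bind_rows(recs)
  if (any(records$value <= 0)) {
    stop("simulation produced non-positive scan values; ",
         "check mean losses and SDs", call. = FALSE)
  }
  bedrest_dataset(records, config$designs)
}

generate_study <- function(cfg, d) {
  study <- d$study
  n <- unname(cfg$n_subjects[[study]])
  ss <- study_sites(d)
  meta <- site_table()
  n_ctl <- max(1L, ceiling(n * cfg$control_fraction))
  subjects <- tibble::tibble(
    subject = sprintf("%s_S%03d", study, seq_len(n)),
    group = rep(c("control", "intervention"), c(n_ctl, n - n_ctl))
  )

  # generated (primary) sites: muscle totals, diaphyseal bone totals,
  # epiphyseal compartments
  gen_sites <- c(ss$totals[site_tissue(ss$totals) == "muscle"],
                 ss$totals[site_tissue(ss$totals) == "bone" &
                             site_class(ss$totals) == "diaphysis"],
                 ss$components)
  b <- matrix(0, n, length(gen_sites),
              dimnames = list(NULL, gen_sites))
  for (tiss in c("muscle", "bone")) {
    cols <- gen_sites[site_tissue(gen_sites) == tiss]
    if (!length(cols)) next
    b[, cols] <- draw_mvn(n, response_sigma(cfg, cols))
  }

  # baseline true levels per total site
  study_eff <- c(muscle = stats::rnorm(1, 0, cfg$study_sd[["muscle"]]),
                 bone = stats::rnorm(1, 0, cfg$study_sd[["bone"]]))
  subj_eff <- cbind(muscle = stats::rnorm(n, 0, cfg$subject_sd[["muscle"]]),
                    bone = stats::rnorm(n, 0, cfg$subject_sd[["bone"]]))
  base_total <- sapply(ss$totals, function(s) {
    tiss <- site_tissue(s)
    lookup_param(cfg$site_means, s, "site_means") + study_eff[[tiss]] +
      subj_eff[, tiss]
  })
  base_total <- matrix(base_total, nrow = n,
                       dimnames = list(NULL, ss$totals))

  # endocortical covariate and its response tilt (bone totals)
  bone_totals <- ss$totals[site_tissue(ss$totals) == "bone"]
  em <- cfg$endo_model
  endo <- matrix(NA_real_, n, length(bone_totals),
                 dimnames = list(NULL, bone_totals))
  tilt <- matrix(0, n, length(bone_totals),
                 dimnames = list(NULL, bone_totals))
  for (s in bone_totals) {
    mu <- lookup_param(em$mean, s, "endo mean")
    endo[, s] <- stats::rnorm(n, mu, em$sd)
    mean_s <- lookup_param(cfg$site_means, s, "site_means")
    tilt[, s] <- -100 * em$slope * (endo[, s] - mu) / mean_s +
      stats::rnorm(n, 0, 100 * em$resid_sd / mean_s)
  }

  # per-site percent change for generated sites
  pc_gen <- sapply(gen_sites, function(s) {
    parent <- meta$parent_site[meta$site == s]
    out <- lookup_true_pc(cfg, study, s) + b[, s]
    if (site_tissue(s) == "bone") out <- out + tilt[, parent]
    out
  })
  pc_gen <- matrix(pc_gen, nrow = n, dimnames = list(NULL, gen_sites))

  rows <- list()
  for (s_tot in ss$totals) {
    tiss <- site_tissue(s_tot)
    epi <- tiss == "bone" && site_class(s_tot) == "epiphysis"
    if (epi) {
      frac <- lookup_param(cfg$comp_fraction, s_tot, "comp_fraction")
      comp_site <- paste0(s_tot, "_COMP")
      trab_site <- paste0(s_tot, "_TRAB")
      parts <- list(
        list(site = comp_site, base = base_total[, s_tot] * frac,
             pc = pc_gen[, comp_site]),
        list(site = trab_site, base = base_total[, s_tot] * (1 - frac),
             pc = pc_gen[, trab_site])
      )
    } else {
      parts <- list(list(site = s_tot, base = base_total[, s_tot],
                         pc = pc_gen[, s_tot]))
    }
    sigma <- lookup_param(cfg$scan_noise_sd_pct, s_tot, "scan_noise_sd_pct")
    resp_tp <- response_timepoint(tiss)
    dup <- d$has_duplicate_baseline
    sides <- if (study %in% cfg$both_legs_studies) c("R", "L") else "R"

    # one noise draw per scan event, shared by the compartments of a site
    eps <- scan_noise_draws(cfg$noise_mode, n, sigma, resp_tp, dup,
                            extra_side = length(sides) > 1)
    tps <- c("BDC1", if (dup) "BDC2", "END_BR", "FOLLOWUP_14")
    endo_val <- if (tiss == "bone") endo[, s_tot] else rep(NA_real_, n)
    emit <- function(site, side, tp, value) {
      day <- switch(tp, BDC1 = -4L, BDC2 = -2L,
                    END_BR = d$duration_days,
                    FOLLOWUP_14 = d$duration_days + 14L)
      tibble::tibble(study = study, subject = subjects$subject,
                     group = subjects$group, side = side, site = site,
                     timepoint = tp, day = day, value = value,
                     endo = endo_val)
    }
    for (tp in tps) {
      total_value <- 0
      for (part in parts) {
        pc_eff <- if (tp %in% c("END_BR", "FOLLOWUP_14")) part$pc else 0
        # single_draw composes noise additively on the percent scale so the
        # observed change is exactly true change + noise (the superposition
        # identity); per_scan is multiplicative per scan, as a real scanner
        value <- if (cfg$noise_mode == "single_draw") {
          part$base * (1 + (pc_eff + eps[[tp]]) / 100)
        } else {
          part$base * (1 + pc_eff / 100) * (1 + eps[[tp]] / 100)
        }
        total_value <- total_value + value
        if (epi) rows[[length(rows) + 1L]] <- emit(part$site, "R", tp, value)
      }
      rows[[length(rows) + 1L]] <- emit(s_tot, "R", tp, total_value)
    }
    if (length(sides) > 1) {
      for (tp in c("BDC1", if (dup) "BDC2")) {
        total_value <- 0
        for (part in parts) {
          value <- part$base * (1 + eps[[paste0("L_", tp)]] / 100)
          total_value <- total_value + value
          if (epi) rows[[length(rows) + 1L]] <- emit(part$site, "L", tp, value)
        }
        rows[[length(rows) + 1L]] <- emit(s_tot, "L", tp, total_value)
      }
    }
  }
  dplyr::bind_rows(rows)
}

# Noise draws per scan event. single_draw: exactly one draw enters the
# percent change (response scan noisy, BDC1 clean) and BDC2 carries a
# sqrt(2)-scaled deviation so the duplicate-pair variance estimator stays
# unbiased for sigma^2. per_scan: independent noise on every scan.
scan_noise_draws <- function(noise_mode, n, sigma, resp_tp, dup, extra_side) {
  z <- function(s) stats::rnorm(n, 0, s)
  if (noise_mode == "per_scan") {
    out <- list(BDC1 = z(sigma), BDC2 = if (dup) z(sigma) else NULL,
                END_BR = z(sigma), FOLLOWUP_14 = z(sigma))
  } else {
    resp <- z(sigma)
    out <- list(
      BDC1 = numeric(n),
      BDC2 = if (dup) z(sigma * sqrt(2)) else NULL,
      END_BR = if (resp_tp == "END_BR") resp else numeric(n),
      FOLLOWUP_14 = if (resp_tp == "FOLLOWUP_14") resp else numeric(n)
    )
  }
  if (extra_side) {
    out$L_BDC1 <- z(sigma)
    if (dup) {
      out$L_BDC2 <- if (noise_mode == "per_scan") z(sigma)
                    else z(sigma * sqrt(2))
    }
  }
  out
}

#' Generating truth for recovery tests
#'
#' Returns, per (study, site), the generator parameters on the scale of the
#' decomposition estimators: the mean percent change, the measurement
#' uncertainty (noise variance, %^2) and the individual-response variance
#' implied by the configured response SDs, correlations, compartment mixing
#' and endocortical link.
#'
#' @param config A [sim_config()].
#' @return Tibble `study, site, true_pc, true_u_meas, true_u_ir`.
#' @export
truth_table <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  meta <- site_table()
  em <- config$endo_model
  rows <- lapply(seq_len(nrow(config$designs)), function(i) {
    d <- config$designs[i, ]
    ss <- study_sites(d)
    all_sites <- c(ss$totals, ss$components)
    purrr::map_dfr(all_sites, function(s) {
      parent <- meta$parent_site[meta$site == s]
      tiss <- site_tissue(s)
      sigma2 <- lookup_param(config$scan_noise_sd_pct, parent,
                             "scan_noise_sd_pct")^2
      tilt_var <- if (tiss == "bone") {
        mean_p <- lookup_param(config$site_means, parent, "site_means")
        (100 * em$slope * em$sd / mean_p)^2 +
          (100 * em$resid_sd / mean_p)^2
      } else 0
      epi_total <- tiss == "bone" && site_class(s) == "epiphysis" &&
        meta$compartment[meta$site == s] == "total"
      if (epi_total) {
        w <- lookup_param(config$comp_fraction, s, "comp_fraction")
        sd_c <- lookup_param(config$response_sd, paste0(s, "_COMP"),
                             "response_sd")
        sd_t <- lookup_param(config$response_sd, paste0(s, "_TRAB"),
                             "response_sd")
        u_ir <- w^2 * sd_c^2 + (1 - w)^2 * sd_t^2 +
          2 * w * (1 - w) * config$comp_trab_rho * sd_c * sd_t + tilt_var
        pc <- w * lookup_true_pc(config, d$study, paste0(s, "_COMP")) +
          (1 - w) * lookup_true_pc(config, d$study, paste0(s, "_TRAB"))
      } else {
        u_ir <- lookup_param(config$response_sd, s, "response_sd")^2 +
          tilt_var
        pc <- lookup_true_pc(config, d$study, s)
      }
      tibble::tibble(study = d$study, site = s, true_pc = pc,
                     true_u_meas = sigma2, true_u_ir = u_ir)
    })
  })
  dplyr::bind_rows(rows)
}
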
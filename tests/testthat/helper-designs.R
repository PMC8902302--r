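# Small design/config builders used across the suite.

toy_design <- function(study = "SIM", n_subjects = 20, duration_days = 60,
                       position = "HDT", device = "XCT3000",
                       scout_98 = "sagittal", tibia66_detection = "automatic",
                       has_duplicate_baseline = TRUE,
                       muscle_sites = c("MUSCLE_38", "MUSCLE_66"),
                       bone_sites = character(0)) {
  lst <- list(list(n_subjects = n_subjects, duration_days = duration_days,
                   position = position, device = device, scout_98 = scout_98,
                   tibia66_detection = tibia66_detection,
                   has_duplicate_baseline = has_duplicate_baseline,
                   muscle_sites = muscle_sites, bone_sites = bone_sites))
  names(lst) <- study
  as_design_table(lst)
}

# one-study muscle config with explicit noise and response SDs; the
# endocortical link is irrelevant for muscle-only designs
muscle_config <- function(n = 50, response_sd = 3, noise_sd = 1,
                          sites = c("MUSCLE_38", "MUSCLE_66"),
                          true_pc = NULL, rho = 0.9, dup = TRUE, seed = 1) {
  des <- toy_design(n_subjects = n, muscle_sites = sites,
                    has_duplicate_baseline = dup)
  cfg <- sim_config(
    designs = des,
    response_sd = stats::setNames(rep(response_sd, length(sites)), sites),
    scan_noise_sd_pct = stats::setNames(rep(noise_sd, length(sites)), sites),
    intersite_rho = c(muscle = rho, bone = 0.4),
    true_pc = true_pc,
    seed = seed
  )
  cfg
}

# a tiny hand-written scan table: 1 control subject, muscle + 2 bone sites
hand_scan_table <- function(path) {
  lines <- c(
    "study,subject,group,side,site,timepoint,day,value,endo",
    "RSL,S1,control,R,MUSCLE_66,BDC1,-4,7400,",
    "RSL,S1,control,R,MUSCLE_66,END_BR,60,6956,",
    "RSL,S1,control,R,TIBIA_38,BDC1,-4,345,35.2",
    "RSL,S1,control,R,TIBIA_38,FOLLOWUP_14,74,338.1,35.2",
    "RSL,S1,control,R,TIBIA_66,BDC1,-4,395,41.8",
    "RSL,S1,control,R,TIBIA_66,FOLLOWUP_14,74,391,41.8"
  )
  writeLines(lines, path)
  path
}
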
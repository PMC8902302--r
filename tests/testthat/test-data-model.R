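test_that("a hand-written scan table round-trips through read and write", {
  p <- withr::local_tempfile(fileext = ".csv")
  hand_scan_table(p)
  ds <- read_scan_table(p)
  expect_s3_class(ds, "bedrest_dataset")
  expect_equal(nrow(ds$records), 6)
  expect_setequal(unique(ds$records$site),
                  c("MUSCLE_66", "TIBIA_38", "TIBIA_66"))

  p2 <- withr::local_tempfile(fileext = ".csv")
  write_scan_table(ds, p2)
  ds2 <- read_scan_table(p2)
  ord <- function(d) dplyr::arrange(d$records, site, timepoint)
  expect_equal(ord(ds2), ord(ds))
})

test_that("invalid scan tables are rejected with informative errors", {
  p <- withr::local_tempfile(fileext = ".csv")
  hand_scan_table(p)
  tab <- read.csv(p, colClasses = c(endo = "numeric"))

  bad <- tab; bad$value[2] <- 0
  expect_error(bedrest_dataset(bad, bundled_designs()), "non-positive")
  bad <- tab; bad$site[1] <- "FEMUR_50"
  expect_error(bedrest_dataset(bad, bundled_designs()), "unknown site")
  bad <- tab[, setdiff(names(tab), "value")]
  expect_error(bedrest_dataset(bad, bundled_designs()), "lacks column")
  bad <- tab; bad$endo[1] <- 30  # endo on a muscle row
  expect_error(bedrest_dataset(bad, bundled_designs()), "muscle site")
  bad <- rbind(tab, tab[1, ])
  expect_error(bedrest_dataset(bad, bundled_designs()), "duplicate")
  bad <- tab; bad$study <- "NOWHERE"
  expect_error(bedrest_dataset(bad, bundled_designs()), "design")
  bad <- tab[tab$timepoint != "BDC1", ]
  expect_error(bedrest_dataset(bad, bundled_designs()), "BDC1")
})

test_that("the packaged eight-study designs carry the documented metadata", {
  d <- bundled_designs()
  expect_setequal(d$study, c("AGBRESA", "BBR", "LTBR", "MEP", "NUC",
                             "Planhab", "RSL", "Valdoltra"))
  dur <- setNames(d$duration_days, d$study)
  expect_equal(dur[c("AGBRESA", "Planhab", "LTBR", "BBR", "Valdoltra")],
               c(AGBRESA = 60L, Planhab = 21L, LTBR = 90L, BBR = 56L,
                 Valdoltra = 35L))
  expect_equal(d$duration_weeks, d$duration_days / 7)
  scout <- setNames(d$scout_98, d$study)
  expect_equal(unname(scout[c("AGBRESA", "RSL")]), rep("sagittal", 2))
  expect_equal(unname(scout[c("BBR", "LTBR", "MEP", "NUC", "Planhab",
                              "Valdoltra")]), rep("frontal", 6))
  det <- setNames(d$tibia66_detection, d$study)
  expect_equal(unname(det[c("BBR", "LTBR", "MEP", "NUC")]), rep("manual", 4))
  expect_equal(unname(det[c("AGBRESA", "Planhab", "RSL", "Valdoltra")]),
               rep("automatic", 4))
  expect_setequal(d$study[d$has_duplicate_baseline],
                  c("LTBR", "RSL", "Valdoltra"))
  # devices
  expect_setequal(d$study[d$device == "XCT2000"],
                  c("BBR", "LTBR", "Valdoltra"))
})

test_that("response pairs follow the tissue timepoint convention", {
  p <- withr::local_tempfile(fileext = ".csv")
  hand_scan_table(p)
  ds <- read_scan_table(p)
  # muscle reads END_BR, bone reads FOLLOWUP_14
  expect_equal(select_response_pair(ds, "RSL", "S1", "MUSCLE_66"),
               c(baseline = 7400, response = 6956))
  expect_equal(select_response_pair(ds, "RSL", "S1", "TIBIA_38"),
               c(baseline = 345, response = 338.1))
  # muscle series has no FOLLOWUP_14 here, but that is not required;
  # a bone series lacking FOLLOWUP_14 errors
  rec <- ds$records[!(ds$records$site == "TIBIA_66" &
                        ds$records$timepoint == "FOLLOWUP_14"), ]
  ds2 <- bedrest_dataset(rec, ds$designs)
  expect_error(select_response_pair(ds2, "RSL", "S1", "TIBIA_66"),
               "FOLLOWUP_14")
})

test_that("duplicate-baseline mean is an explicit opt-in for the baseline", {
  rec <- tibble::tibble(
    study = "RSL", subject = "S1", group = "control", side = "R",
    site = "MUSCLE_66",
    timepoint = c("BDC1", "BDC2", "END_BR"), day = c(-4L, -2L, 60L),
    value = c(100, 102, 95), endo = NA_real_)
  ds <- bedrest_dataset(rec, bundled_designs())
  expect_equal(select_response_pair(ds, "RSL", "S1", "MUSCLE_66")[["baseline"]],
               100)
  expect_equal(select_response_pair(ds, "RSL", "S1", "MUSCLE_66",
                                    baseline = "mean")[["baseline"]], 101)
  pc_b1 <- pc_table(ds)$pc
  pc_mean <- pc_table(ds, baseline = "mean")$pc
  expect_equal(pc_b1, -5)
  expect_equal(pc_mean, (95 - 101) / 101 * 100)
})
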
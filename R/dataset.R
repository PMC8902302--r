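#' Bed-rest scan datasets
#'
#' A `bedrest_dataset` bundles tidy scan-level records with per-study design
#' metadata. Each record is one pQCT outcome: bone mineral content (BMC,
#' mg/mm) at a tibia site or anatomical muscle cross-sectional area (CSA,
#' mm2) at a diaphyseal site, for one subject, leg side, and timepoint.
#'
#' Invariants enforced at construction:
#' * `value > 0` (percent change is undefined at zero baseline);
#' * `endo` (endocortical circumference, mm) present only for bone sites;
#' * `(study, subject, side, site, timepoint)` unique;
#' * every record's study has a design row;
#' * every `(subject, side, site)` series has a `BDC1` record.
#'
#' Left/right leg duplicates are carried as distinct `(subject, side)`
#' series; percent-change analyses use one leg per subject (see
#' [pc_table()]) while measurement-uncertainty estimation uses all sides.
#'
#' @param records Tibble/data.frame with columns `study`, `subject`,
#'   `group` (`"control"`/`"intervention"`), `side`, `site`, `timepoint`,
#'   `day`, `value`, `endo` (`NA` allowed).
#' @param designs Design table as returned by [read_study_designs()].
#' @return An object of class `bedrest_dataset`: a list with elements
#'   `records` and `designs`.
#' @export
bedrest_dataset <- function(records, designs) {
  records <- tibble::as_tibble(records)
  needed <- c("study", "subject", "group", "side", "site", "timepoint",
              "day", "value", "endo")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols)) {
    stop("scan table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  records <- records[, needed]
  records$day <- as.integer(records$day)
  records$value <- as.numeric(records$value)
  records$endo <- as.numeric(records$endo)

  unknown <- !(records$site %in% known_sites())
  if (any(unknown)) {
    stop("unknown site code(s) in rows ",
         paste(utils::head(which(unknown), 10), collapse = ", "),
         ": ", paste(unique(records$site[unknown]), collapse = ", "),
         call. = FALSE)
  }
  bad_tp <- !(records$timepoint %in% timepoint_levels())
  if (any(bad_tp)) {
    stop("invalid timepoint in rows ",
         paste(utils::head(which(bad_tp), 10), collapse = ", "), call. = FALSE)
  }
  bad_grp <- !(records$group %in% c("control", "intervention"))
  if (any(bad_grp)) {
    stop("group must be 'control' or 'intervention' (rows ",
         paste(utils::head(which(bad_grp), 10), collapse = ", "), ")",
         call. = FALSE)
  }
  nonpos <- !is.finite(records$value) | records$value <= 0
  if (any(nonpos)) {
    off <- records[nonpos, ]
    stop("non-positive scan value for (",
         paste(sprintf("%s, %s, %s", off$study, off$subject, off$site)[
           seq_len(min(5, nrow(off)))], collapse = "; "), ")", call. = FALSE)
  }
  muscle_endo <- !is.na(records$endo) & site_tissue(records$site) == "muscle"
  if (any(muscle_endo)) {
    stop("endocortical circumference given for muscle site rows ",
         paste(utils::head(which(muscle_endo), 10), collapse = ", "),
         call. = FALSE)
  }
  key <- paste(records$study, records$subject, records$side,
               records$site, records$timepoint)
  if (anyDuplicated(key)) {
    stop("duplicate (study, subject, side, site, timepoint) records: ",
         paste(utils::head(unique(key[duplicated(key)]), 5), collapse = "; "),
         call. = FALSE)
  }
  no_design <- setdiff(unique(records$study), designs$study)
  if (length(no_design)) {
    stop("no design metadata for study(ies): ",
         paste(no_design, collapse = ", "), call. = FALSE)
  }
  series <- dplyr::distinct(records, .data$study, .data$subject, .data$side,
                            .data$site)
  base <- dplyr::filter(records, .data$timepoint == "BDC1")
  series$has_bdc1 <- paste(series$study, series$subject, series$side,
                           series$site) %in%
    paste(base$study, base$subject, base$side, base$site)
  if (!all(series$has_bdc1)) {
    off <- series[!series$has_bdc1, ]
    stop("missing BDC1 baseline for (",
         paste(sprintf("%s, %s, %s", off$study, off$subject, off$site)[
           seq_len(min(5, nrow(off)))], collapse = "; "), ")", call. = FALSE)
  }

  structure(list(records = records, designs = designs),
            class = "bedrest_dataset")
}

#' @export
print.bedrest_dataset <- function(x, ...) {
  cat("<bedrest_dataset>\n")
  cat("  studies:  ", length(unique(x$records$study)), " (",
      paste(sort(unique(x$records$study)), collapse = ", "), ")\n", sep = "")
  cat("  subjects: ", nrow(dplyr::distinct(x$records, .data$study, .data$subject)),
      "\n", sep = "")
  cat("  sites:    ", paste(sort(unique(x$records$site)), collapse = ", "),
      "\n", sep = "")
  cat("  records:  ", nrow(x$records), "\n", sep = "")
  invisible(x)
}

#' Read and write tidy scan tables
#'
#' The on-disk format is a UTF-8 CSV with columns `study`, `subject`,
#' `group`, `side`, `site`, `timepoint`, `day`, `value`, `endo` (empty for
#' muscle sites) and `.` as decimal separator. `read_scan_table()` joins
#' the design metadata and validates the result; `write_scan_table()`
#' writes the records back in a stable column order so that
#' read-after-write is the identity.
#'
#' @param path CSV file path.
#' @param designs Design table (default: the packaged eight-study fixture).
#' @return `read_scan_table()` returns a [bedrest_dataset()];
#'   `write_scan_table()` returns `path` invisibly.
#' @export
read_scan_table <- function(path, designs = bundled_designs()) {
  if (!file.exists(path)) stop("scan table not found: ", path, call. = FALSE)
  records <- utils::read.csv(path, stringsAsFactors = FALSE,
                             colClasses = c(endo = "numeric"))
  bedrest_dataset(records, designs)
}

#' @rdname read_scan_table
#' @param dataset A [bedrest_dataset()].
#' @export
write_scan_table <- function(dataset, path) {
  stopifnot(inherits(dataset, "bedrest_dataset"))
  out <- dplyr::arrange(dataset$records, .data$study, .data$site,
                        .data$subject, .data$side, .data$timepoint)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Baseline/response value pair for one subject-site series
#'
#' Returns the baseline and response values that enter the percent-change
#' computation: baseline is the first baseline scan (BDC1; optionally the
#' mean of the duplicate baselines), and the response is the end-of-bed-rest
#' scan for muscle or the 14-day follow-up scan for bone.
#'
#' @param dataset A [bedrest_dataset()].
#' @param study,subject,site Identifiers of the series.
#' @param side Leg side (default `"R"`).
#' @param baseline `"bdc1"` (default) or `"mean"` (mean of BDC1/BDC2 where a
#'   duplicate baseline exists).
#' @return Named numeric vector `c(baseline = , response = )`.
#' @export
select_response_pair <- function(dataset, study, subject, site, side = "R",
                                 baseline = c("bdc1", "mean")) {
  baseline <- match.arg(baseline)
  stopifnot(inherits(dataset, "bedrest_dataset"))
  rec <- dplyr::filter(dataset$records, .data$study == !!study,
                       .data$subject == !!subject, .data$site == !!site,
                       .data$side == !!side)
  if (!nrow(rec)) {
    stop(sprintf("no records for (%s, %s, %s)", study, subject, site),
         call. = FALSE)
  }
  tp_resp <- response_timepoint(site_tissue(site))
  val <- function(tp) rec$value[rec$timepoint == tp]
  b1 <- val("BDC1")
  resp <- val(tp_resp)
  if (!length(resp)) {
    stop(sprintf("missing %s record for (%s, %s, %s)", tp_resp, study,
                 subject, site), call. = FALSE)
  }
  b <- if (baseline == "mean" && length(val("BDC2"))) {
    mean(c(b1, val("BDC2")))
  } else {
    b1
  }
  c(baseline = b, response = resp)
}

#' Per-subject percent changes
#'
#' Tabulates the observed percent change for every subject-site series,
#' using the tissue-specific response timepoint convention. One leg per
#' subject enters (preferring the right side when both were scanned), since
#' leg duplicates are reserved for measurement-uncertainty estimation.
#' Series lacking the required response timepoint are dropped.
#'
#' @inheritParams select_response_pair
#' @param group `"control"` (default; observed-uncertainty analyses use
#'   control groups only) or `"all"`.
#' @return Tibble with columns `study`, `subject`, `group`, `site`,
#'   `tissue`, `site_class`, `baseline`, `response`, `pc`, `endo`.
#' @export
pc_table <- function(dataset, group = c("control", "all"),
                     baseline = c("bdc1", "mean")) {
  group <- match.arg(group)
  baseline <- match.arg(baseline)
  stopifnot(inherits(dataset, "bedrest_dataset"))
  rec <- dataset$records
  if (group == "control") rec <- dplyr::filter(rec, .data$group == "control")
  # one leg per subject-site: prefer "R", else first side alphabetically
  rec <- rec |>
    dplyr::group_by(.data$study, .data$subject, .data$site) |>
    dplyr::filter(.data$side == if (any(.data$side == "R")) "R"
                  else min(.data$side)) |>
    dplyr::ungroup()
  rec$tissue <- site_tissue(rec$site)
  rec$resp_tp <- response_timepoint(rec$tissue)

  wide <- rec |>
    dplyr::group_by(.data$study, .data$subject, .data$group, .data$site,
                    .data$tissue) |>
    dplyr::summarise(
      b1 = .data$value[.data$timepoint == "BDC1"][1],
      b2 = .data$value[.data$timepoint == "BDC2"][1],
      response = .data$value[.data$timepoint == .data$resp_tp[1]][1],
      endo = .data$endo[.data$timepoint == "BDC1"][1],
      .groups = "drop"
    ) |>
    dplyr::filter(!is.na(.data$response))
  wide$baseline <- if (baseline == "mean") {
    ifelse(is.na(wide$b2), wide$b1, (wide$b1 + wide$b2) / 2)
  } else {
    wide$b1
  }
  wide$pc <- percent_change(wide$baseline, wide$response)
  wide$site_class <- site_class(wide$site)
  wide[, c("study", "subject", "group", "site", "tissue", "site_class",
           "baseline", "response", "pc", "endo")]
}
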
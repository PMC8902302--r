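#' Study design metadata
#'
#' Per-study design metadata drive the response-timepoint convention
#' (through bed-rest duration), the adjusted between-subject deviation
#' (duration in weeks) and, centrally, the donor rule that borrows
#' measurement uncertainty between studies with similar measurement
#' conditions (device, scout-view orientation at the proximal tibia,
#' detection mode of the 66% diaphyseal site).
#'
#' `read_study_designs()` reads a YAML or JSON file mapping study name to
#' its design fields; `bundled_designs()` returns the packaged fixture for
#' the eight bed-rest studies the framework was developed on (AGBRESA,
#' BBR, LTBR, MEP, NUC, Planhab, RSL, Valdoltra).
#'
#' @param path Path to a YAML (`.yaml`/`.yml`) or JSON (`.json`) file.
#' @return A tibble with one row per study and columns `study`, `year`,
#'   `n_subjects`, `duration_days`, `duration_weeks`, `position`
#'   (`"HDT"`/`"HBR"`), `device` (`"XCT2000"`/`"XCT3000"`), `scout_98`
#'   (`"frontal"`/`"sagittal"`), `tibia66_detection`
#'   (`"manual"`/`"automatic"`), `has_duplicate_baseline`, and list-columns
#'   `muscle_sites`, `bone_sites`.
#' @export
#' @examples
#' bundled_designs()
read_study_designs <- function(path) {
  if (!file.exists(path)) stop("design file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  as_design_table(raw)
}

#' @rdname read_study_designs
#' @export
bundled_designs <- function() {
  read_study_designs(system.file("extdata", "study_designs.yaml",
                                 package = "bedrestvar", mustWork = TRUE))
}

#' Build a design table from a named list
#'
#' @param x Named list (study -> list of design fields) as produced by
#'   reading the YAML/JSON design format.
#' @return A validated design tibble (see [read_study_designs()]).
#' @export
as_design_table <- function(x) {
  stopifnot(is.list(x), length(x) > 0, !is.null(names(x)))
  rows <- purrr::imap(x, function(d, nm) {
    tibble::tibble(
      study = nm,
      year = as.integer(d$year %||% NA_integer_),
      n_subjects = as.integer(d$n_subjects %||% NA_integer_),
      duration_days = as.integer(d$duration_days),
      position = d$position,
      device = d$device,
      scout_98 = d$scout_98,
      tibia66_detection = d$tibia66_detection,
      has_duplicate_baseline = isTRUE(d$has_duplicate_baseline),
      muscle_sites = list(as.character(unlist(d$muscle_sites))),
      bone_sites = list(as.character(unlist(d$bone_sites)))
    )
  })
  designs <- dplyr::bind_rows(rows)
  designs$duration_weeks <- designs$duration_days / 7
  validate_designs(designs)
  designs[, c("study", "year", "n_subjects", "duration_days", "duration_weeks",
              "position", "device", "scout_98", "tibia66_detection",
              "has_duplicate_baseline", "muscle_sites", "bone_sites")]
}

validate_designs <- function(designs) {
  stopifnot(!anyDuplicated(designs$study))
  if (any(designs$duration_days <= 0)) {
    stop("duration_days must be positive", call. = FALSE)
  }
  check_enum <- function(col, allowed) {
    bad <- setdiff(unique(designs[[col]]), allowed)
    if (length(bad)) {
      stop(sprintf("invalid %s value(s): %s", col, paste(bad, collapse = ", ")),
           call. = FALSE)
    }
  }
  check_enum("position", c("HDT", "HBR"))
  check_enum("device", c("XCT2000", "XCT3000"))
  check_enum("scout_98", c("frontal", "sagittal"))
  check_enum("tibia66_detection", c("manual", "automatic"))
  all_sites <- unlist(c(designs$muscle_sites, designs$bone_sites))
  unknown <- setdiff(all_sites, known_sites())
  if (length(unknown)) {
    stop("unknown site code(s) in design: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  invisible(designs)
}

design_sites <- function(design_row) {
  c(design_row$muscle_sites[[1]], design_row$bone_sites[[1]])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
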
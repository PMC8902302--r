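#' Measurement-site metadata
#'
#' The lower-leg pQCT measurement sites handled by the package. Site codes
#' follow the convention `<TISSUE>_<position>` where the number is the scan
#' position as a percentage of tibia length from the ankle joint (4% and 98%
#' are epiphyseal bone sites, 38% and 66% diaphyseal; muscle cross-sections
#' are taken at the 38% and 66% diaphyseal positions). Epiphyseal bone sites
#' additionally exist as compact (`_COMP`) and trabecular (`_TRAB`)
#' compartment series obtained by density-threshold segmentation.
#'
#' @return A tibble with columns `site`, `tissue` (`"muscle"`/`"bone"`),
#'   `site_class` (`"diaphysis"`/`"epiphysis"`), `compartment`
#'   (`"total"`, `"compact"`, `"trabecular"`), and `parent_site` (the total
#'   site a compartment series belongs to; equal to `site` for totals).
#' @export
#' @examples
#' site_table()
site_table <- function() {
  tibble::tribble(
    ~site,            ~tissue,  ~site_class,  ~compartment,  ~parent_site,
    "MUSCLE_38",      "muscle", "diaphysis",  "total",       "MUSCLE_38",
    "MUSCLE_66",      "muscle", "diaphysis",  "total",       "MUSCLE_66",
    "TIBIA_04",       "bone",   "epiphysis",  "total",       "TIBIA_04",
    "TIBIA_38",       "bone",   "diaphysis",  "total",       "TIBIA_38",
    "TIBIA_66",       "bone",   "diaphysis",  "total",       "TIBIA_66",
    "TIBIA_98",       "bone",   "epiphysis",  "total",       "TIBIA_98",
    "TIBIA_04_COMP",  "bone",   "epiphysis",  "compact",     "TIBIA_04",
    "TIBIA_04_TRAB",  "bone",   "epiphysis",  "trabecular",  "TIBIA_04",
    "TIBIA_98_COMP",  "bone",   "epiphysis",  "compact",     "TIBIA_98",
    "TIBIA_98_TRAB",  "bone",   "epiphysis",  "trabecular",  "TIBIA_98"
  )
}

#' @rdname site_table
#' @param site character vector of site codes.
#' @export
site_tissue <- function(site) {
  lookup_site(site, "tissue")
}

#' @rdname site_table
#' @export
site_class <- function(site) {
  lookup_site(site, "site_class")
}

lookup_site <- function(site, what) {
  meta <- site_table()
  idx <- match(site, meta$site)
  if (anyNA(idx)) {
    stop("unknown site code(s): ", paste(unique(site[is.na(idx)]), collapse = ", "),
         call. = FALSE)
  }
  meta[[what]][idx]
}

known_sites <- function() site_table()$site

#' Valid scan timepoints
#'
#' `BDC1`/`BDC2` are the first and second baseline data collections,
#' `END_BR` the last day of bed rest (muscle response timepoint) and
#' `FOLLOWUP_14` the scan 14 days after re-ambulation (bone response
#' timepoint, since bone loss continues for another 10-20 days after
#' bed rest while muscle does not).
#'
#' @return Character vector of timepoint labels in temporal order.
#' @export
timepoint_levels <- function() c("BDC1", "BDC2", "END_BR", "FOLLOWUP_14")

#' Response timepoint convention per tissue
#'
#' Muscle responses are read at the end of bed rest, bone responses at the
#' 14-day follow-up.
#'
#' @param tissue `"muscle"` or `"bone"` (vectorised).
#' @return Character vector of timepoint labels.
#' @export
response_timepoint <- function(tissue) {
  stopifnot(all(tissue %in% c("muscle", "bone")))
  ifelse(tissue == "muscle", "END_BR", "FOLLOWUP_14")
}
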
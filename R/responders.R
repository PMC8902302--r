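#' Measurement-uncertainty confidence interval for a study-site cell
#'
#' The 95% interval around the cell's mean percent change that individual
#' responses must exceed before they count as genuine between-subject
#' variation. In the default `"sd"` mode the half-width is
#' `1.96 * sqrt(U_Meas)` (the measurement uncertainty expressed as an SD on
#' the percent scale, dimensionally consistent with the percent change);
#' `"literal"` uses `1.96 * U_Meas`, mixing %^2 with %, and is kept as an
#' option for fidelity to the wording the framework was first described
#' with.
#'
#' @param pc_mean Cell mean percent change (%).
#' @param u_meas Measurement uncertainty of the cell (%^2, >= 0).
#' @param mode `"sd"` (default) or `"literal"`.
#' @return Numeric `c(low, high)`.
#' @export
#' @examples
#' confidence_interval(-5, 4)  # -5 +/- 1.96 * 2
confidence_interval <- function(pc_mean, u_meas, mode = c("sd", "literal")) {
  mode <- match.arg(mode)
  stopifnot(is.finite(u_meas), u_meas >= 0)
  half <- if (mode == "sd") 1.96 * sqrt(u_meas) else 1.96 * u_meas
  c(low = pc_mean - half, high = pc_mean + half)
}

#' Classify individual responses against the measurement interval
#'
#' A subject whose percent change falls outside the closed interval is a
#' responder in the between-subject-variation sense (their deviation from
#' the group mean cannot be explained by measurement uncertainty alone).
#' Values exactly on a bound do not exceed.
#'
#' @param pcs Named or plain numeric vector of per-subject percent changes.
#' @param pc_mean,u_meas,mode As in [confidence_interval()].
#' @return Tibble `pc, ci_low, ci_high, exceeds, ci_mode`.
#' @export
classify_responders <- function(pcs, pc_mean, u_meas,
                                mode = c("sd", "literal")) {
  mode <- match.arg(mode)
  ci <- confidence_interval(pc_mean, u_meas, mode)
  tibble::tibble(
    pc = as.numeric(pcs),
    ci_low = ci[["low"]], ci_high = ci[["high"]],
    exceeds = pcs < ci[["low"]] | pcs > ci[["high"]],
    ci_mode = mode
  )
}

#' Responder classification over a whole dataset
#'
#' Builds per-cell confidence intervals from a decomposition table and
#' classifies every control-group subject's percent change against the
#' interval of its own (study, site) cell.
#'
#' @param dataset A [bedrest_dataset()].
#' @param uncertainty Decomposition table from [decompose()] (columns
#'   `study, site, pc_mean, u_meas`).
#' @param mode `"sd"` or `"literal"` interval mode.
#' @param baseline Baseline convention for percent change.
#' @return Tibble `study, subject, site, tissue, site_class, pc, ci_low,
#'   ci_high, exceeds, ci_mode`.
#' @export
classify_dataset <- function(dataset, uncertainty = decompose(dataset),
                             mode = c("sd", "literal"),
                             baseline = c("bdc1", "mean")) {
  mode <- match.arg(mode)
  baseline <- match.arg(baseline)
  pcs <- pc_table(dataset, group = "control", baseline = baseline)
  joined <- dplyr::inner_join(
    pcs, uncertainty[, c("study", "site", "pc_mean", "u_meas")],
    by = c("study", "site"))
  half <- if (mode == "sd") 1.96 * sqrt(joined$u_meas) else 1.96 * joined$u_meas
  joined$ci_low <- joined$pc_mean - half
  joined$ci_high <- joined$pc_mean + half
  joined$exceeds <- joined$pc < joined$ci_low | joined$pc > joined$ci_high
  joined$ci_mode <- mode
  joined[, c("study", "subject", "site", "tissue", "site_class", "pc",
             "ci_low", "ci_high", "exceeds", "ci_mode")]
}

#' Between-subject-variation summary fractions
#'
#' Fraction of individual responses exceeding their cell's measurement
#' interval, overall and split by tissue and by site class.
#'
#' @param results Classification tibble from [classify_dataset()] (needs
#'   columns `exceeds`, `tissue`, `site_class`).
#' @return Tibble `category, level, n_exceed, n_total, fraction_pct`.
#' @export
bsv_summary <- function(results) {
  if (!nrow(results)) stop("no responder results to summarise", call. = FALSE)
  one <- function(category, level, flags) {
    tibble::tibble(category = category, level = level,
                   n_exceed = sum(flags), n_total = length(flags),
                   fraction_pct = 100 * mean(flags))
  }
  dplyr::bind_rows(
    one("overall", "all", results$exceeds),
    dplyr::bind_rows(lapply(split(results, results$tissue), function(g)
      one("tissue", g$tissue[1], g$exceeds))),
    dplyr::bind_rows(lapply(split(results, results$site_class), function(g)
      one("site_class", g$site_class[1], g$exceeds)))
  )
}
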
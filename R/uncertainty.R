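#' Percent change of an outcome relative to baseline
#'
#' The observed individual response is the percent change between the first
#' baseline scan and the post-intervention scan; negative values are losses.
#'
#' @param x_baseline Baseline value(s), strictly positive.
#' @param x_response Response value(s).
#' @return Percent change `(x_response - x_baseline) / x_baseline * 100`.
#' @export
#' @examples
#' percent_change(100, 95)  # -5
percent_change <- function(x_baseline, x_response) {
  if (any(!is.finite(x_baseline) | x_baseline <= 0)) {
    stop("baseline values must be positive", call. = FALSE)
  }
  (x_response - x_baseline) / x_baseline * 100
}

#' Observed uncertainty of a study-site cell
#'
#' The observed uncertainty U_Obs is the unbiased sample variance (divisor
#' n - 1) of the individual percent changes within one study x site cell,
#' in percent-squared.
#'
#' @param pcs Numeric vector of percent changes (length >= 2).
#' @return Variance in %^2.
#' @export
observed_uncertainty <- function(pcs) {
  pcs <- pcs[is.finite(pcs)]
  if (length(pcs) < 2) {
    stop("at least 2 percent changes needed for observed uncertainty",
         call. = FALSE)
  }
  stats::var(pcs)
}

#' Measurement uncertainty from duplicate baseline scans
#'
#' `subject_measurement_uncertainty()` converts the within-subject variance
#' of repeated baseline scans to the percent scale: sample variance of the
#' baselines times `(100 / mean)^2`, yielding %^2 so it is commensurate
#' with the variance of percent changes. `pooled_measurement_uncertainty()`
#' averages these per-subject variances over all subjects of a study
#' (intervention and control groups alike, and both legs where scanned, for
#' precision).
#'
#' @param baselines Numeric vector of one subject's baseline scans
#'   (length >= 2, typically 2).
#' @return Measurement uncertainty in %^2.
#' @export
#' @examples
#' subject_measurement_uncertainty(c(100, 102))  # ~1.96
subject_measurement_uncertainty <- function(baselines) {
  if (length(baselines) < 2) {
    stop("at least 2 baseline scans needed per subject", call. = FALSE)
  }
  m <- mean(baselines)
  if (!is.finite(m) || m <= 0) {
    stop("mean baseline must be positive", call. = FALSE)
  }
  stats::var(baselines) * (100 / m)^2
}

#' @rdname subject_measurement_uncertainty
#' @param per_subject Numeric vector of per-subject measurement
#'   uncertainties (%^2).
#' @export
pooled_measurement_uncertainty <- function(per_subject) {
  per_subject <- per_subject[is.finite(per_subject)]
  if (!length(per_subject)) {
    stop("no per-subject measurement uncertainties to pool", call. = FALSE)
  }
  mean(per_subject)
}

#' Assign measurement uncertainty to a study-site cell
#'
#' Only studies with duplicate baseline scans support direct estimation of
#' measurement uncertainty. For any other study the value is borrowed from
#' the duplicate-baseline study with the most similar measurement
#' conditions, determined by an ordered filter over the design metadata:
#' scout-view orientation at the proximal tibia, then the detection mode of
#' the 66% diaphyseal site, then the device model. If the best-matching
#' donor did not measure the requested site, the rule falls back to the
#' maximum pooled measurement uncertainty among studies that did (a
#' conservative choice).
#'
#' @param study Study identifier.
#' @param site Site code.
#' @param umeas_table Tibble with columns `study`, `site`, `u_meas`: pooled
#'   duplicate-baseline measurement uncertainties. Typically produced by
#'   [decompose()] from the data, or supplied as a published reference
#'   table ([reference_umeas()]).
#' @param designs Design table covering `study` and all donor studies.
#' @return List with elements `u_meas` (%^2), `provenance` (`"own"`,
#'   `"borrowed"`, `"fallback_max"`) and `donor` (study the value comes
#'   from; equals `study` for `"own"`).
#' @export
assign_measurement_uncertainty <- function(study, site, umeas_table,
                                           designs = bundled_designs()) {
  stopifnot(all(c("study", "site", "u_meas") %in% names(umeas_table)))
  if (!study %in% designs$study) {
    stop("no design metadata for study ", study, call. = FALSE)
  }
  own <- umeas_table[umeas_table$study == study & umeas_table$site == site, ]
  if (nrow(own)) {
    return(list(u_meas = own$u_meas[[1]], provenance = "own", donor = study))
  }
  providers <- unique(umeas_table$study[umeas_table$site == site])
  if (!length(providers)) {
    stop("no study provides a measurement uncertainty for site ", site,
         call. = FALSE)
  }
  donor <- match_donor_study(study, unique(umeas_table$study), designs)
  if (donor %in% providers) {
    val <- umeas_table$u_meas[umeas_table$study == donor &
                                umeas_table$site == site][[1]]
    return(list(u_meas = val, provenance = "borrowed", donor = donor))
  }
  # preferred donor lacks the site: conservative fallback to the maximum
  sub <- umeas_table[umeas_table$site == site, ]
  i <- which.max(sub$u_meas)
  list(u_meas = sub$u_meas[[i]], provenance = "fallback_max",
       donor = sub$study[[i]])
}

# Ordered similarity filter over donor candidates; each criterion narrows
# the candidate set only if at least one candidate matches it.
match_donor_study <- function(study, donors, designs) {
  target <- designs[designs$study == study, ]
  cand <- designs[designs$study %in% setdiff(donors, study), ]
  if (!nrow(cand)) stop("no donor studies available", call. = FALSE)
  for (crit in c("scout_98", "tibia66_detection", "device")) {
    hit <- cand[[crit]] == target[[crit]]
    if (any(hit)) cand <- cand[hit, ]
    if (nrow(cand) == 1L) break
  }
  cand$study[[1]]
}

#' Individual response uncertainty
#'
#' Under the superposition assumption the observed percent-change variance
#' is the sum of measurement uncertainty and the biological between-subject
#' response variance, so the latter is estimated by subtraction. Negative
#' results (possible when the true response is near zero and the borrowed
#' measurement uncertainty exceeds the observed variance) are preserved,
#' not truncated: they are meaningful flags.
#'
#' @param u_obs Observed uncertainty (%^2).
#' @param u_meas Measurement uncertainty (%^2).
#' @return `u_obs - u_meas` (%^2, may be negative).
#' @export
individual_response_uncertainty <- function(u_obs, u_meas) {
  stopifnot(is.finite(u_obs), is.finite(u_meas), u_obs >= 0, u_meas >= 0)
  u_obs - u_meas
}

#' Adjusted between-subject deviation
#'
#' Normalises the individual-response spread for comparison across studies
#' of different durations: the SD of the individual response divided by the
#' magnitude of the mean percent change, divided by the bed-rest duration
#' in weeks. Undefined (returns `NA` with a warning-free signal) when the
#' individual-response uncertainty is negative or the mean change is zero.
#'
#' @param u_ir Individual response uncertainty (%^2).
#' @param pc_mean Mean percent change of the cell (%; sign ignored).
#' @param weeks Bed-rest duration in weeks (> 0).
#' @return Dimensionless rate per week, or `NA_real_` when undefined.
#' @export
adjusted_between_subject_deviation <- function(u_ir, pc_mean, weeks) {
  stopifnot(is.finite(weeks), weeks > 0)
  if (!is.finite(u_ir) || u_ir < 0 || !is.finite(pc_mean) || pc_mean == 0) {
    return(NA_real_)
  }
  sqrt(u_ir) / abs(pc_mean) / weeks
}

#' Decompose observed variance into measurement and response components
#'
#' Orchestrates the full per-cell decomposition over a dataset: percent
#' changes of control-group subjects give the observed uncertainty and mean
#' percent change of every study x site cell; duplicate-baseline scans of
#' all subjects (both groups, both legs) give pooled measurement
#' uncertainties where available; the borrowing rule assigns a measurement
#' uncertainty to every cell; subtraction yields the individual response
#' uncertainty, and the adjusted between-subject deviation is added where
#' defined.
#'
#' @param dataset A [bedrest_dataset()].
#' @param baseline Baseline convention for percent change (see
#'   [pc_table()]).
#' @param umeas_override Optional tibble `study, site, u_meas` replacing the
#'   internally estimated duplicate-baseline table (e.g.
#'   [reference_umeas()]).
#' @return Tibble with one row per (study, site): `study`, `site`, `n`
#'   (control subjects), `pc_mean`, `u_obs`, `u_meas`, `u_meas_provenance`,
#'   `u_meas_donor`, `u_ir`, `abd`. Satisfies `u_ir == u_obs - u_meas`
#'   exactly.
#' @export
decompose <- function(dataset, baseline = c("bdc1", "mean"),
                      umeas_override = NULL) {
  baseline <- match.arg(baseline)
  stopifnot(inherits(dataset, "bedrest_dataset"))
  pcs <- pc_table(dataset, group = "control", baseline = baseline)
  umeas_tab <- umeas_override %||% duplicate_baseline_umeas(dataset)

  cells <- pcs |>
    dplyr::group_by(.data$study, .data$site) |>
    dplyr::summarise(n = dplyr::n(), pc_mean = mean(.data$pc),
                     u_obs = if (dplyr::n() >= 2) stats::var(.data$pc)
                             else NA_real_,
                     .groups = "drop") |>
    dplyr::filter(!is.na(.data$u_obs))

  assigned <- purrr::pmap(cells, function(study, site, n, pc_mean, u_obs) {
    a <- assign_measurement_uncertainty(study, site, umeas_tab,
                                        dataset$designs)
    weeks <- dataset$designs$duration_weeks[dataset$designs$study == study]
    u_ir <- individual_response_uncertainty(u_obs, a$u_meas)
    tibble::tibble(
      study = study, site = site, n = n, pc_mean = pc_mean, u_obs = u_obs,
      u_meas = a$u_meas, u_meas_provenance = a$provenance,
      u_meas_donor = a$donor, u_ir = u_ir,
      abd = adjusted_between_subject_deviation(u_ir, pc_mean, weeks)
    )
  })
  dplyr::arrange(dplyr::bind_rows(assigned), .data$study, .data$site)
}

#' Pooled duplicate-baseline measurement uncertainties of a dataset
#'
#' Estimates, for every (study, site) with duplicate baseline scans, the
#' pooled measurement uncertainty over all subjects (both groups) and all
#' scanned leg sides.
#'
#' @param dataset A [bedrest_dataset()].
#' @return Tibble `study, site, u_meas, n_pairs`.
#' @export
duplicate_baseline_umeas <- function(dataset) {
  rec <- dplyr::filter(dataset$records,
                       .data$timepoint %in% c("BDC1", "BDC2"))
  rec |>
    dplyr::group_by(.data$study, .data$site, .data$subject, .data$side) |>
    dplyr::filter(dplyr::n() >= 2) |>
    dplyr::summarise(u_i = subject_measurement_uncertainty(.data$value),
                     .groups = "drop") |>
    dplyr::group_by(.data$study, .data$site) |>
    dplyr::summarise(u_meas = pooled_measurement_uncertainty(.data$u_i),
                     n_pairs = dplyr::n(), .groups = "drop")
}

#' One-way ANOVA comparison of uncertainty values
#'
#' Fixed-effects one-way ANOVA (equal-variance F test) used to compare
#' measurement or response uncertainties between groups of cells, e.g.
#' between duplicate-baseline studies at one site.
#'
#' @param groups Named list mapping group label to a numeric vector
#'   (>= 2 groups with >= 2 values each).
#' @return List with `f`, `df1`, `df2`, `p`, and `degenerate` (`TRUE` when
#'   all values are identical so F is undefined).
#' @export
compare_uncertainties_anova <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (any(lengths(groups) < 2)) {
    stop("each group needs at least 2 values", call. = FALSE)
  }
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups) %||% seq_along(groups), lengths(groups)))
  if (stats::var(y) == 0) {
    return(list(f = NA_real_, df1 = nlevels(g) - 1L,
                df2 = length(y) - nlevels(g), p = NA_real_,
                degenerate = TRUE))
  }
  fit <- stats::oneway.test(y ~ g, var.equal = TRUE)
  list(f = unname(fit$statistic), df1 = unname(fit$parameter[1]),
       df2 = unname(fit$parameter[2]), p = unname(fit$p.value),
       degenerate = FALSE)
}

#' Paired t test of change from baseline
#'
#' Two-sided paired t test on response minus baseline, used per study and
#' site to test whether bed rest changed the outcome at all.
#'
#' @param baseline,response Equal-length numeric vectors paired by subject.
#' @return List with `t`, `df`, `p`, `mean_diff`, and `degenerate` (`TRUE`
#'   when the differences have zero variance; then `t` is 0 for identical
#'   vectors or signed infinity for a constant non-zero shift).
#' @export
paired_change_test <- function(baseline, response) {
  stopifnot(length(baseline) == length(response), length(baseline) >= 2)
  d <- response - baseline
  if (stats::sd(d) == 0) {
    t <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
    return(list(t = t, df = length(d) - 1L,
                p = if (mean(d) == 0) 1 else 0,
                mean_diff = mean(d), degenerate = TRUE))
  }
  fit <- stats::t.test(response, baseline, paired = TRUE)
  list(t = unname(fit$statistic), df = unname(fit$parameter),
       p = unname(fit$p.value), mean_diff = unname(fit$estimate),
       degenerate = FALSE)
}
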
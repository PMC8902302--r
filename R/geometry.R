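#' Absolute bone loss
#'
#' Difference between baseline and post-bed-rest bone mineral content;
#' positive values are losses.
#'
#' @param bmc_baseline,bmc_post Positive BMC values (mg/mm).
#' @return `bmc_baseline - bmc_post` (mg/mm).
#' @export
bone_loss <- function(bmc_baseline, bmc_post) {
  stopifnot(all(bmc_baseline > 0), all(bmc_post > 0))
  bmc_baseline - bmc_post
}

#' Ordinary least-squares simple regression
#'
#' OLS fit of `y ~ x` with a two-sided t test on the slope (n - 2 df),
#' used for the endocortical-geometry analyses.
#'
#' @param x,y Equal-length numeric vectors, n >= 3.
#' @return List `slope`, `intercept`, `r_squared`, `p_slope`, `n`.
#' @export
fit_simple_regression <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 points", call. = FALSE)
  if (stats::sd(x) == 0) stop("predictor is constant", call. = FALSE)
  fit <- stats::lm(y ~ x)
  s <- summary(fit)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = s$r.squared,
       p_slope = unname(s$coefficients[2, 4]),
       n = length(x))
}

#' Endocortical geometry regressions
#'
#' Two complementary analyses of how bone geometry relates to disuse bone
#' loss, per study and pooled over all eligible studies:
#' * `ENDO -> BL`: absolute bone loss (mg/mm) regressed on endocortical
#'   circumference (mm) -- a larger endocortical (remodeling) surface is
#'   expected to permit more resorption;
#' * `ENDO/BMC -> pc`: percent change regressed on the baseline ratio of
#'   endocortical circumference to BMC, a surface-to-volume marker.
#'
#' Only total bone sites with an endocortical covariate enter, and only
#' studies measuring at least three of the four bone sites are fitted (the
#' others are skipped with a message). Control-group subjects, one leg.
#'
#' @param dataset A [bedrest_dataset()].
#' @param min_sites Minimum distinct bone sites per study (default 3).
#' @return Tibble `scope, predictor, response, slope, intercept, r_squared,
#'   p_slope, n` with one row per (study or `"pooled"`) x analysis.
#' @export
endo_analyses <- function(dataset, min_sites = 3) {
  pcs <- pc_table(dataset, group = "control")
  pts <- pcs |>
    dplyr::filter(.data$tissue == "bone",
                  .data$site %in% c("TIBIA_04", "TIBIA_38",
                                    "TIBIA_66", "TIBIA_98"),
                  !is.na(.data$endo))
  if (!nrow(pts)) stop("no bone records with endocortical data", call. = FALSE)
  pts$bl <- bone_loss(pts$baseline, pts$response)
  pts$ratio <- pts$endo / pts$baseline

  site_count <- pts |>
    dplyr::group_by(.data$study) |>
    dplyr::summarise(k = dplyr::n_distinct(.data$site), .groups = "drop")
  eligible <- site_count$study[site_count$k >= min_sites]
  skipped <- setdiff(site_count$study, eligible)
  if (length(skipped)) {
    message("endo_analyses: skipping study(ies) with < ", min_sites,
            " bone sites: ", paste(skipped, collapse = ", "))
  }
  pts <- pts[pts$study %in% eligible, ]
  if (!nrow(pts)) stop("no eligible studies for geometry analysis",
                       call. = FALSE)

  fit_scope <- function(df, scope) {
    dplyr::bind_rows(
      c(scope = scope, predictor = "ENDO", response = "BL",
        fit_simple_regression(df$endo, df$bl)),
      c(scope = scope, predictor = "ENDO_over_BMC", response = "pc",
        fit_simple_regression(df$ratio, df$pc))
    )
  }
  per_study <- dplyr::bind_rows(lapply(split(pts, pts$study), function(df)
    fit_scope(df, df$study[1])))
  out <- dplyr::bind_rows(per_study, fit_scope(pts, "pooled"))
  out$slope <- as.numeric(out$slope)
  out$intercept <- as.numeric(out$intercept)
  out$r_squared <- as.numeric(out$r_squared)
  out$p_slope <- as.numeric(out$p_slope)
  out$n <- as.integer(out$n)
  tibble::as_tibble(out)
}
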
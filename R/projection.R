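#' Upper-tail normal quantile for the largest of a crew
#'
#' For a crew of n, the heuristic places the largest expected individual
#' response at the 1 - 1/n quantile of the normal response distribution.
#'
#' @param crew_n Crew size (integer >= 2; at n = 2 the quantile is the
#'   median, 0).
#' @return Standard-normal quantile at `1 - 1/crew_n`.
#' @export
#' @examples
#' upper_tail_z(6)  # ~0.967
upper_tail_z <- function(crew_n) {
  if (crew_n < 2) stop("crew_n must be >= 2 for a tail quantile",
                       call. = FALSE)
  stats::qnorm(1 - 1 / crew_n)
}

#' Worst-case projected loss in a crew
#'
#' Projects the largest expected cumulative loss among `crew_n` crew
#' members when the mean loss rate and its between-subject SD both scale
#' linearly with mission duration (an individual's deviation from the mean
#' rate persists month to month):
#' `months * mean_rate + months * bsv_sd_rate * upper_tail_z(crew_n)`.
#' A crew of one gets the mean term only.
#'
#' The default `"quantile"` method is the plug-in 1 - 1/n quantile
#' heuristic. It underestimates the true expected maximum of n independent
#' normal deviates; `"mc"` estimates that expected maximum by Monte Carlo
#' instead.
#'
#' @param mean_rate Mean loss rate (% per month).
#' @param bsv_sd_rate Between-subject SD of the loss rate (% per month).
#' @param months Mission duration in months.
#' @param crew_n Crew size (>= 1).
#' @param method `"quantile"` (default) or `"mc"`.
#' @param reps Monte Carlo replicates for `method = "mc"`.
#' @return Projected worst-case loss (%; positive = loss).
#' @export
#' @examples
#' worst_case_loss(1, 1, 12, 6)  # ~23.6
worst_case_loss <- function(mean_rate, bsv_sd_rate, months, crew_n,
                            method = c("quantile", "mc"), reps = 1e5) {
  method <- match.arg(method)
  stopifnot(bsv_sd_rate >= 0, months > 0, crew_n >= 1)
  mean_term <- months * mean_rate
  if (crew_n == 1 || bsv_sd_rate == 0) {
    if (method == "quantile" || crew_n == 1) return(mean_term)
  }
  sd_cum <- months * bsv_sd_rate
  if (method == "quantile") {
    mean_term + sd_cum * upper_tail_z(crew_n)
  } else {
    draws <- matrix(stats::rnorm(reps * crew_n), nrow = reps)
    mean_term + sd_cum * mean(apply(draws, 1, max))
  }
}
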
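#' Pearson correlation with t-based significance
#'
#' Thin wrapper around the sample Pearson coefficient with the usual
#' t-transform p-value on n - 2 degrees of freedom, returning the
#' pairwise-complete sample size alongside.
#'
#' @param x,y Numeric vectors paired by subject (NA pairs dropped).
#' @return List `r`, `p`, `n`, and `degenerate` (`TRUE` when either vector
#'   has zero variance, in which case `r` and `p` are `NA`).
#' @export
pearson <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(r = NA_real_, p = NA_real_, n = n, degenerate = TRUE))
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = unname(ct$p.value), n = n,
       degenerate = FALSE)
}

#' Qualitative strength of a correlation coefficient
#'
#' Conventional magnitude bands: |r| < 0.3 negligible, 0.3-0.5 low,
#' 0.5-0.7 moderate, 0.7-0.9 high, 0.9-1.0 very high; exact cutpoints go to
#' the higher category. The sign is reported separately by callers.
#'
#' @param r Correlation coefficient(s) in [-1, 1].
#' @return Character vector of band labels.
#' @export
#' @examples
#' label_strength(c(0.29, 0.3, 0.52, 0.9))
label_strength <- function(r) {
  if (any(abs(r) > 1, na.rm = TRUE)) {
    stop("|r| must not exceed 1", call. = FALSE)
  }
  cut(abs(r), breaks = c(-Inf, 0.3, 0.5, 0.7, 0.9, Inf), right = FALSE,
      labels = c("negligible", "low", "moderate", "high", "very high")) |>
    as.character()
}

#' Inter-site correlation matrix of individual percent changes
#'
#' Quantifies within-subject variation: if a subject's responses tracked
#' each other perfectly across sites, inter-site correlations of the
#' percent changes would be 1; imperfect correlation is within-subject
#' variation. Subjects are pooled across studies, pairwise-complete: every
#' cell uses all subjects providing both sites, and cells with fewer than
#' 3 shared subjects are left `NA`.
#'
#' @param dataset A [bedrest_dataset()].
#' @param sites Site codes to include (default: all sites present).
#' @param group Subject group filter as in [pc_table()].
#' @return Object of class `intersite_cor`: list with matrices `r`, `p`,
#'   `n`, `label` and the site order `sites`.
#' @export
correlation_matrix <- function(dataset, sites = NULL,
                               group = c("control", "all")) {
  group <- match.arg(group)
  pcs <- pc_table(dataset, group = group)
  if (is.null(sites)) {
    sites <- intersect(site_table()$site, unique(pcs$site))
  }
  wide <- pcs |>
    dplyr::mutate(uid = paste(.data$study, .data$subject, sep = ":")) |>
    dplyr::select("uid", "site", "pc") |>
    tidyr::pivot_wider(names_from = "site", values_from = "pc")
  k <- length(sites)
  r <- p <- matrix(NA_real_, k, k, dimnames = list(sites, sites))
  nmat <- matrix(0L, k, k, dimnames = list(sites, sites))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i == j) {
        r[i, j] <- 1
        nmat[i, j] <- sum(!is.na(wide[[sites[i]]]))
        next
      }
      if (!all(c(sites[i], sites[j]) %in% names(wide))) next
      x <- wide[[sites[i]]]; y <- wide[[sites[j]]]
      n_ij <- sum(is.finite(x) & is.finite(y))
      nmat[i, j] <- n_ij
      if (n_ij < 3) next
      res <- pearson(x, y)
      if (!res$degenerate) {
        r[i, j] <- res$r
        p[i, j] <- res$p
      }
    }
  }
  lab <- matrix(label_strength(r), k, k, dimnames = list(sites, sites))
  structure(list(sites = sites, r = r, p = p, n = nmat, label = lab),
            class = "intersite_cor")
}

#' @export
print.intersite_cor <- function(x, ...) {
  cat("<intersite_cor> ", length(x$sites), " sites\n", sep = "")
  print(round(x$r, 2))
  invisible(x)
}

#' Long-format view of an inter-site correlation matrix
#'
#' @param m An `intersite_cor` object.
#' @return Tibble `site_a, site_b, r, p, n, label, significant` over the
#'   upper triangle (computed cells only).
#' @export
correlation_long <- function(m) {
  stopifnot(inherits(m, "intersite_cor"))
  k <- length(m$sites)
  idx <- which(upper.tri(m$r), arr.ind = TRUE)
  out <- tibble::tibble(
    site_a = m$sites[idx[, 1]], site_b = m$sites[idx[, 2]],
    r = m$r[idx], p = m$p[idx], n = m$n[idx],
    label = m$label[idx]
  )
  out <- out[!is.na(out$r), ]
  out$significant <- out$p < 0.05
  out
}

#' Within-subject-variation report
#'
#' Groups the computed correlation cells into muscle-muscle, bone-bone
#' (split into diaphyseal, epiphyseal and cross pairs) and muscle-bone
#' blocks. Cells with p >= 0.05 are reported as "no correlation" whatever
#' their r (the conventional narrative treatment); the block verdict calls
#' within-subject variation "low" when the mean significant correlation of
#' the block is at least 0.7 and "substantial" otherwise.
#'
#' @param m An `intersite_cor` object.
#' @return Tibble `block, n_pairs, n_significant, mean_r, verdict`.
#' @export
wsv_report <- function(m) {
  cells <- correlation_long(m)
  if (!nrow(cells)) stop("no computed correlation cells", call. = FALSE)
  ta <- site_tissue(cells$site_a); tb <- site_tissue(cells$site_b)
  ca <- site_class(cells$site_a); cb <- site_class(cells$site_b)
  cells$block <- dplyr::case_when(
    ta == "muscle" & tb == "muscle" ~ "muscle-muscle",
    ta != tb ~ "muscle-bone",
    ca == "diaphysis" & cb == "diaphysis" ~ "bone-bone (diaphyseal)",
    ca == "epiphysis" & cb == "epiphysis" ~ "bone-bone (epiphyseal)",
    TRUE ~ "bone-bone (cross)"
  )
  cells$reported <- ifelse(cells$significant, cells$label, "no correlation")
  out <- cells |>
    dplyr::group_by(.data$block) |>
    dplyr::summarise(
      n_pairs = dplyr::n(),
      n_significant = sum(.data$significant),
      mean_r = mean(.data$r),
      verdict = if (sum(.data$significant) > 0 &&
                    mean(.data$r[.data$significant]) >= 0.7) "low WSV"
                else "substantial WSV",
      .groups = "drop")
  order_blocks <- c("muscle-muscle", "bone-bone (diaphyseal)",
                    "bone-bone (epiphyseal)", "bone-bone (cross)",
                    "muscle-bone")
  out[order(match(out$block, order_blocks)), ]
}
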
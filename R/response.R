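#' Euclidean distance between cell-cycle proportion vectors
#'
#' The phenotypic drug-response statistic `d`: the Euclidean (L2) distance
#' between the {2N, S, 4N, 8N+} proportion vectors (in percent) of a
#' control and a treated population. Ranges from 0 (identical class mixes)
#' to 100 * sqrt(2) (complete swap of two classes).
#'
#' @param p_control,p_treated Proportion vectors in percent over the same
#'   ordered classes, each summing to 100. If both are named they are
#'   matched by name.
#' @return Scalar distance `d`.
#' @examples
#' euclidean_response(c(60, 20, 15, 5), c(10, 5, 50, 35))  # sqrt(4850)
#' @export
euclidean_response <- function(p_control, p_treated) {
  if (length(p_control) != length(p_treated)) abort("mismatched class sets")
  if (!is.null(names(p_control)) && !is.null(names(p_treated))) {
    if (!setequal(names(p_control), names(p_treated))) {
      abort("mismatched class sets")
    }
    p_treated <- p_treated[names(p_control)]
  }
  for (p in list(p_control, p_treated)) {
    if (abs(sum(p) - 100) > 1e-6) abort("proportions must sum to 100 (percent)")
  }
  sqrt(sum((p_control - p_treated)^2))
}

#' Euclidean response profile over a dose grid
#'
#' Computes `d` at every dose of a population-summary table against the
#' summary at the reference dose (default 0), yielding the dose profile
#' whose area under the curve is the scalar sensitivity score.
#'
#' @param summaries A [summarise_population()] table for one cell line
#'   across doses (columns `dose`, `pct_2n`, `pct_s`, `pct_4n`, `pct_8n`).
#' @param reference_dose Dose of the control population (must be present).
#' @return Tibble of class `response_profile` with columns `dose`, `d`,
#'   sorted by dose; the profile AUC is stored in the `"auc"` attribute
#'   and returned by [profile_auc()].
#' @export
response_profile <- function(summaries, reference_dose = 0) {
  cols <- c("pct_2n", "pct_s", "pct_4n", "pct_8n")
  stopifnot(all(c("dose", cols) %in% names(summaries)))
  summaries <- dplyr::arrange(summaries, .data$dose)
  ref <- dplyr::filter(summaries, .data$dose == reference_dose)
  if (nrow(ref) != 1) abort("exactly one summary row at the reference dose is required")
  p_ref <- unlist(ref[cols])
  out <- summaries |>
    dplyr::rowwise() |>
    mutate(d = euclidean_response(p_ref, c(.data$pct_2n, .data$pct_s,
                                           .data$pct_4n, .data$pct_8n))) |>
    dplyr::ungroup() |>
    dplyr::select("dose", "d")
  class(out) <- c("response_profile", class(out))
  attr(out, "auc") <- profile_auc(out)
  out
}

#' Area under a Euclidean response profile
#'
#' Trapezoidal integral of `d` over the tested dose grid
#' (uM x distance units); the scalar per-cell-line sensitivity score.
#'
#' @param profile A [response_profile()] tibble, or any data frame with
#'   ascending `dose` and `d` columns.
#' @return Scalar AUC (>= 0 whenever d >= 0).
#' @examples
#' profile_auc(data.frame(dose = c(0, 1, 2), d = c(0, 100, 100)))  # 150
#' @export
profile_auc <- function(profile) {
  stopifnot(all(c("dose", "d") %in% names(profile)), nrow(profile) >= 2)
  if (is.unsorted(profile$dose, strictly = FALSE)) abort("doses must be ascending")
  pracma::trapz(profile$dose, profile$d)
}

#' Normality-gated two-group comparison with effect size
#'
#' The generic group-comparison used throughout the pipeline: Shapiro-Wilk
#' normality on both samples; if both pass at `alpha_normality`, an
#' unpaired two-tailed t-test, otherwise an unpaired two-tailed Wilcoxon
#' rank-sum test; Cohen's d with pooled (n-1) SD; optional
#' Benjamini-Hochberg adjustment of the p-value within a supplied family
#' of raw p-values.
#'
#' When both samples have zero variance no test applies and Cohen's d is
#' reported as 0 with `test = "none"`.
#'
#' @param a,b Numeric samples (n >= 3 each for testing).
#' @param family Optional numeric vector of the other raw p-values in the
#'   testing family; `p_adj` is then the BH-adjusted value of this
#'   comparison within `c(p, family)`. Without a family, `p_adj = p`.
#' @param alpha_normality Shapiro-Wilk gate level (default 0.05).
#' @return One-row tibble: `test`, `statistic`, `p`, `p_adj`, `cohens_d`,
#'   `shapiro_p_a`, `shapiro_p_b`, `n_a`, `n_b`.
#' @export
compare_groups <- function(a, b, family = NULL, alpha_normality = 0.05) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 3 || length(b) < 3) abort("each sample needs n >= 3")
  d <- cohens_d(a, b)
  if (sd(a) == 0 && sd(b) == 0) {
    return(tibble(test = "none", statistic = NA_real_, p = NA_real_,
                  p_adj = NA_real_, cohens_d = 0,
                  shapiro_p_a = NA_real_, shapiro_p_b = NA_real_,
                  n_a = length(a), n_b = length(b)))
  }
  sw_a <- if (sd(a) > 0) shapiro.test(a)$p.value else 0
  sw_b <- if (sd(b) > 0) shapiro.test(b)$p.value else 0
  if (sw_a >= alpha_normality && sw_b >= alpha_normality) {
    ht <- t.test(a, b, var.equal = FALSE)
    test <- "t"
  } else {
    ht <- suppressWarnings(wilcox.test(a, b, exact = FALSE))
    test <- "wilcoxon"
  }
  p <- ht$p.value
  p_adj <- if (is.null(family)) p else p.adjust(c(p, family), "BH")[1]
  tibble(test = test, statistic = unname(ht$statistic), p = p, p_adj = p_adj,
         cohens_d = d, shapiro_p_a = sw_a, shapiro_p_b = sw_b,
         n_a = length(a), n_b = length(b))
}

#' Cohen's d with pooled standard deviation
#'
#' `(mean(a) - mean(b)) / s_pooled` with the pooled SD using n-1
#' denominators. Returns 0 when both samples are constant.
#'
#' @param a,b Numeric samples.
#' @return Scalar effect size.
#' @export
cohens_d <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  if (sp2 == 0) return(0)
  (mean(a) - mean(b)) / sqrt(sp2)
}
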
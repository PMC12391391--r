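#' Scale an expression panel against a loading control
#'
#' Densitometry convention for Western-blot panels: each analyte is
#' divided by the per-sample loading control (e.g. GAPDH), then by the
#' per-analyte maximum so the highest value equals 1. Invariant to any
#' global multiplicative factor on the raw values.
#'
#' @param raw Expression panel (one row per sample/line, analytes in
#'   numeric columns).
#' @param loading_control Either the name of the loading-control column or
#'   a positive numeric vector, one value per row.
#' @param analytes Analyte columns to scale; defaults to all numeric
#'   columns except the loading control.
#' @return The panel with analyte columns scaled to max 1; the
#'   loading-control column (if present) is dropped.
#' @export
scale_expression <- function(raw, loading_control, analytes = NULL) {
  raw <- as_tibble(raw)
  if (is.character(loading_control) && length(loading_control) == 1) {
    ctrl_col <- loading_control
    stopifnot(ctrl_col %in% names(raw))
    ctrl <- raw[[ctrl_col]]
  } else {
    ctrl_col <- NULL
    ctrl <- loading_control
  }
  if (length(ctrl) != nrow(raw)) abort("one loading-control value per sample is required")
  if (any(!is.finite(ctrl)) || any(ctrl <= 0)) abort("loading control must be positive")
  if (is.null(analytes)) {
    analytes <- names(raw)[vapply(raw, is.numeric, TRUE)]
    analytes <- setdiff(analytes, ctrl_col)
  }
  out <- raw
  for (a in analytes) {
    v <- out[[a]] / ctrl
    out[[a]] <- v / max(v)
  }
  if (!is.null(ctrl_col)) out[[ctrl_col]] <- NULL
  out
}

#' Fit the GWL/B55-alpha expression-ratio sensitivity model
#'
#' Ordinary least squares (unweighted) regression of observed ED50 values
#' on the scalar predictor GWL/B55-alpha, the expression-ratio model of
#' sensitivity to Greatwall inhibition:
#' `*ED50 = gradient x GWL/B55a + intercept`. A two-covariate variant
#' (GWL and B55-alpha as separate terms) is available for exploration.
#'
#' @param panel Expression panel with columns `gwl`, `b55a` (> 0) and,
#'   unless `ed50` is supplied, `ed50` (uM).
#' @param ed50 Optional ED50 vector overriding `panel$ed50`.
#' @param form `"ratio"` (the published single-predictor form, default)
#'   or `"two_covariate"`.
#' @return An object of class `ratio_model`: gradient (uM per ratio
#'   unit), intercept (uM), `r_squared`, `pearson_r`, `p_value` (two-tailed
#'   t on the correlation), `n`, the underlying `lm` fit and the data.
#'   Supports [tidy()], [glance()], `predict()` and [ggplot2::autoplot()].
#' @examples
#' panel <- gen_expression_panel(n_lines = 12, noise_sd = 0.05, seed = 3)
#' fit <- fit_ratio_model(panel)
#' glance(fit)
#' @export
fit_ratio_model <- function(panel, ed50 = NULL, form = c("ratio", "two_covariate")) {
  form <- match.arg(form)
  panel <- as_tibble(panel)
  stopifnot(all(c("gwl", "b55a") %in% names(panel)))
  y <- ed50 %||% panel$ed50
  if (is.null(y)) abort("ed50 values are required (column or argument)")
  if (any(panel$b55a <= 0)) abort("b55a must be positive for the ratio predictor")
  if (length(y) < 3) abort("n >= 3 samples are required")
  ratio <- panel$gwl / panel$b55a
  if (sd(ratio) == 0) abort("zero-variance predictor")
  d <- tibble(ratio = ratio, gwl = panel$gwl, b55a = panel$b55a, ed50 = y)
  fit <- if (form == "ratio") lm(ed50 ~ ratio, data = d) else
    lm(ed50 ~ gwl + b55a, data = d)
  ct <- if (form == "ratio") cor.test(ratio, y) else NULL
  structure(list(
    form = form,
    gradient = if (form == "ratio") unname(coef(fit)[["ratio"]]) else NA_real_,
    intercept = unname(coef(fit)[[1]]),
    coefficients = coef(fit),
    r_squared = summary(fit)$r.squared,
    pearson_r = if (form == "ratio") unname(ct$estimate) else NA_real_,
    p_value = if (form == "ratio") ct$p.value else NA_real_,
    n = length(y), fit = fit, data = d
  ), class = "ratio_model")
}

#' @export
print.ratio_model <- function(x, ...) {
  cat("GWL/B55a expression-ratio sensitivity model (", x$form, " form)\n", sep = "")
  if (x$form == "ratio") {
    cat(sprintf("  *ED50 = %.3f x GWL/B55a + %.3f  (uM)\n", x$gradient, x$intercept))
    cat(sprintf("  R^2 %.3f  r %.3f  p %.3g  n %d\n",
                x$r_squared, x$pearson_r, x$p_value, x$n))
  } else {
    print(x$coefficients)
  }
  invisible(x)
}

#' @rdname fit_ratio_model
#' @param x A `ratio_model`.
#' @param ... Unused.
#' @method tidy ratio_model
#' @export
tidy.ratio_model <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble(term = rownames(s), estimate = s[, 1], std.error = s[, 2],
         statistic = s[, 3], p.value = s[, 4])
}

#' @rdname fit_ratio_model
#' @method glance ratio_model
#' @export
glance.ratio_model <- function(x, ...) {
  tibble(gradient = x$gradient, intercept = x$intercept,
         r_squared = x$r_squared, pearson_r = x$pearson_r,
         p_value = x$p_value, n = x$n)
}

#' Predict ED50 from GWL and B55-alpha expression
#'
#' Applies the ratio model `*ED50 = gradient x GWL/B55a + intercept` to an
#' expression panel. The default coefficients are the reference C-604
#' sensitivity model (gradient 0.399, intercept 0.406 uM) so predictions
#' can be made without refitting; pass a fitted [fit_ratio_model()] object
#' to use estimated coefficients. RNA panels (TPM/FPKM) enter the ratio
#' untransformed. Samples with `b55a = 0` receive `NA` and a warning.
#'
#' @param panel Panel with columns `gwl` and `b55a`.
#' @param model A `ratio_model`, or a named list/vector with `gradient`
#'   and `intercept` (uM). Defaults to the reference coefficients.
#' @return The panel with a `pred_ed50` column (uM) appended.
#' @examples
#' predict_ed50(tibble::tibble(gwl = 0.5, b55a = 1.0))  # 0.6055 uM
#' @export
predict_ed50 <- function(panel, model = list(gradient = 0.399, intercept = 0.406)) {
  panel <- as_tibble(panel)
  stopifnot(all(c("gwl", "b55a") %in% names(panel)))
  if (inherits(model, "ratio_model")) {
    if (model$form != "ratio") abort("predict_ed50 requires the ratio form")
    g <- model$gradient; i <- model$intercept
  } else {
    g <- model[["gradient"]]; i <- model[["intercept"]]
  }
  bad <- panel$b55a == 0
  if (any(bad)) warn(sprintf("%d sample(s) with b55a = 0: no prediction", sum(bad)))
  mutate(panel, pred_ed50 = ifelse(bad, NA_real_,
                                   g * .data$gwl / .data$b55a + i))
}

#' @export
predict.ratio_model <- function(object, newdata, ...) {
  predict_ed50(newdata, object)$pred_ed50
}

#' Flag the most sensitive predicted samples
#'
#' Flags the `ceiling(fraction * n)` samples with the lowest predicted
#' ED50 — the "top 5% most sensitive" convention for cohort
#' stratification. Ties are broken by stable input order (and noted with
#' a message). Invariant to strictly monotone transforms of predictions.
#'
#' @param predictions Numeric vector of predicted ED50s, or a data frame
#'   with a `pred_ed50` column.
#' @param fraction Fraction to flag, in (0, 1); default 0.05.
#' @return For a vector, a logical flag vector; for a data frame, the
#'   frame with a logical `flagged` column appended.
#' @export
rank_and_flag <- function(predictions, fraction = 0.05) {
  if (!(fraction > 0 && fraction < 1)) abort("fraction must be in (0, 1)")
  is_df <- is.data.frame(predictions)
  v <- if (is_df) predictions$pred_ed50 else predictions
  if (length(v) == 0) abort("empty input")
  k <- ceiling(fraction * length(v))
  ord <- order(v, na.last = TRUE)  # stable for ties: order() is stable in R
  cutoff_vals <- v[ord[seq_len(k)]]
  if (anyDuplicated(v[!is.na(v)]) && any(duplicated(cutoff_vals))) {
    inform("ties at the flag boundary broken by input order")
  }
  flags <- logical(length(v))
  flags[ord[seq_len(k)]] <- TRUE
  if (is_df) mutate(predictions, flagged = flags) else flags
}

#' Tumour-vs-normal median expression shifts per cancer group
#'
#' For each cancer group and gene: the difference between the median
#' tumour and median normal expression (T - N), an unpaired two-tailed
#' Wilcoxon rank-sum test, and Benjamini-Hochberg adjustment across all
#' determined comparisons. Groups lacking normal samples are marked
#' not-determined (`determined = FALSE`, the "nd" convention). The exact
#' Wilcoxon distribution is used when both arms have fewer than 25
#' samples, the normal approximation otherwise.
#'
#' @param cohort Long cohort table (see [gen_cohort_expression()]) with
#'   columns `group`, `gene`, `tissue` (tumour/normal), `fpkm`.
#' @return Tibble per group x gene: `n_tumour`, `n_normal`,
#'   `median_tumour`, `median_normal`, `median_shift`, `p`, `p_adj`,
#'   `determined`.
#' @export
cohort_median_shift <- function(cohort) {
  cohort <- as_tibble(cohort)
  stopifnot(all(c("group", "gene", "tissue", "fpkm") %in% names(cohort)))
  out <- cohort |>
    dplyr::group_by(.data$group, .data$gene) |>
    dplyr::reframe({
      tv <- .data$fpkm[.data$tissue == "tumour"]
      nv <- .data$fpkm[.data$tissue == "normal"]
      tibble(
        n_tumour = length(tv), n_normal = length(nv),
        median_tumour = if (length(tv)) median(tv) else NA_real_,
        median_normal = if (length(nv)) median(nv) else NA_real_,
        p = if (length(nv) == 0 || length(tv) == 0) NA_real_ else
          suppressWarnings(wilcox.test(
            tv, nv, exact = length(tv) < 25 && length(nv) < 25
          )$p.value)
      )
    }) |>
    mutate(median_shift = .data$median_tumour - .data$median_normal,
           determined = !is.na(.data$p),
           p_adj = {
             adj <- rep(NA_real_, dplyr::n())
             adj[.data$determined] <- p.adjust(.data$p[.data$determined], "BH")
             adj
           }) |>
    dplyr::relocate("median_shift", .after = "median_normal")
  out
}

#' Pearson correlation with a two-tailed t-test
#'
#' Thin, tidy wrapper around [stats::cor.test()] for the panel-level
#' correlations between ED50 and expression levels.
#'
#' @param x,y Numeric vectors (n >= 3, non-zero variance).
#' @return One-row tibble: `r`, `p`, `n`.
#' @export
correlate <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) abort("n >= 3 is required")
  if (sd(x) == 0 || sd(y) == 0) abort("zero-variance input")
  ct <- cor.test(x, y, method = "pearson")
  tibble(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}
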
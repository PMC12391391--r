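#' Plot a fitted dose-response curve
#'
#' Observed responses and the fitted 4PL curve on a log-dose axis; dose 0
#' is drawn at one quarter of the smallest positive dose and annotated as
#' the asymptote limit.
#'
#' @param object A `fourpl_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot fourpl_fit
#' @export
autoplot.fourpl_fit <- function(object, ...) {
  d <- object$data
  pos <- d$dose[d$dose > 0]
  pseudo0 <- min(pos) / 4
  grid <- exp(seq(log(pseudo0), log(max(pos)), length.out = 200))
  curve <- tibble(dose = grid,
                  response = fourpl(grid, object$slope, object$lower,
                                    object$upper, object$ed50))
  pts <- mutate(d, dose_plot = ifelse(.data$dose == 0, pseudo0, .data$dose))
  ggplot(curve, aes(x = .data$dose, y = .data$response)) +
    geom_line(colour = "firebrick") +
    geom_point(data = pts, aes(x = .data$dose_plot, y = .data$response),
               alpha = 0.7) +
    geom_vline(xintercept = object$ed50, linetype = "dashed",
               colour = "grey40") +
    scale_x_log10() +
    labs(x = "dose (uM, log scale)", y = "response",
         title = sprintf("4PL fit: ED50 = %.3g uM", object$ed50)) +
    theme_minimal()
}

#' Plot the expression-ratio sensitivity model
#'
#' Scatter of observed ED50 against the GWL/B55-alpha ratio with the
#' fitted regression line and the fit statistics in the title.
#'
#' @param object A `ratio_model`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ratio_model
#' @export
autoplot.ratio_model <- function(object, ...) {
  if (object$form != "ratio") abort("autoplot supports the ratio form")
  ggplot(object$data, aes(x = .data$ratio, y = .data$ed50)) +
    geom_point() +
    geom_abline(slope = object$gradient, intercept = object$intercept,
                colour = "firebrick") +
    labs(x = "GWL / B55a (scaled expression ratio)", y = "ED50 (uM)",
         title = sprintf("*ED50 = %.3f x ratio + %.3f   (R2 = %.2f, p = %.2g)",
                         object$gradient, object$intercept,
                         object$r_squared, object$p_value)) +
    theme_minimal()
}

#' Stacked cell-cycle composition across doses
#'
#' Stacked bars of the {2N, S, 4N, 8N+} percentages per dose — the
#' standard view of dose-dependent ploidy shifts.
#'
#' @param summary A [summarise_population()] table.
#' @return A ggplot.
#' @export
plot_population_summary <- function(summary) {
  long <- summary |>
    tidyr::pivot_longer(c("pct_2n", "pct_s", "pct_4n", "pct_8n"),
                        names_to = "class", values_to = "pct") |>
    mutate(class = factor(.data$class,
                          levels = c("pct_8n", "pct_4n", "pct_s", "pct_2n"),
                          labels = c("8N+", "4N", "S", "2N")))
  ggplot(long, aes(x = factor(.data$dose), y = .data$pct, fill = .data$class)) +
    geom_col() +
    scale_fill_brewer(palette = "RdYlBu", direction = -1) +
    labs(x = "dose (uM)", y = "cells (%)", fill = "class") +
    theme_minimal()
}

#' Euclidean response profile plot
#'
#' `d` versus dose with the AUC annotated.
#'
#' @param profile A [response_profile()] result.
#' @return A ggplot.
#' @export
plot_response_profile <- function(profile) {
  auc <- attr(profile, "auc")
  ggplot(profile, aes(x = .data$dose, y = .data$d)) +
    geom_area(fill = "firebrick", alpha = 0.2) +
    geom_line(colour = "firebrick") +
    geom_point() +
    labs(x = "dose (uM)", y = "Euclidean distance d",
         title = if (!is.null(auc)) sprintf("AUC = %.1f", auc) else NULL) +
    theme_minimal()
}

#' Phenotype embedding scatter
#'
#' 2D embedding coloured by condition; the view used to judge phenotypic
#' similarity between perturbations.
#'
#' @param object A [embed_conditions()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot phenotype_embedding
#' @export
autoplot.phenotype_embedding <- function(object, ...) {
  ggplot(object, aes(x = .data$umap1, y = .data$umap2,
                     colour = .data$condition)) +
    geom_point(alpha = 0.6, size = 0.8) +
    labs(x = "UMAP 1", y = "UMAP 2", colour = NULL) +
    theme_minimal()
}

#' Volcano plot of differential phosphosites
#'
#' log2 fold change against -log10 p, coloured by hit class.
#'
#' @param stats A [classify_hits()] table.
#' @return A ggplot.
#' @export
plot_volcano <- function(stats) {
  stopifnot(all(c("log2_fc", "p", "class") %in% names(stats)))
  ggplot(stats, aes(x = .data$log2_fc, y = -log10(.data$p),
                    colour = .data$class)) +
    geom_point(alpha = 0.6, size = 0.8) +
    scale_colour_manual(values = c("negative hit" = "steelblue",
                                   "positive hit" = "firebrick",
                                   "not significant" = "grey70")) +
    labs(x = "log2 fold change", y = "-log10 p", colour = NULL) +
    theme_minimal()
}
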
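#' Four-parameter log-logistic curve
#'
#' Evaluates the four-parameter log-logistic (4PL) function
#' \deqn{f(x) = lower + \frac{upper - lower}{1 + \exp\{slope\,(\log x - \log ed50)\}}}
#' the standard LL.4 parameterisation of sigmoidal dose-response curves.
#' With `slope > 0` the curve decreases with dose and `f(0)` equals the
#' upper asymptote; `f(ed50)` is always the midpoint `(lower + upper) / 2`.
#' Dose 0 is handled by the asymptote limit rather than a log-offset.
#'
#' @param x Dose (same units as `ed50`, typically uM). Non-negative.
#' @param slope Hill slope (unitless). Positive for responses that fall
#'   with dose.
#' @param lower,upper Lower and upper asymptotes (response units).
#' @param ed50 Midpoint dose (> 0); the EC50/ED50/IC50 depending on assay.
#' @return Numeric vector of responses, same length as `x`.
#' @examples
#' fourpl(c(0, 0.5, Inf), slope = 2, lower = 0, upper = 1, ed50 = 0.5)
#' @export
fourpl <- function(x, slope, lower, upper, ed50) {
  stopifnot(is.numeric(x), ed50 > 0)
  if (any(x < 0, na.rm = TRUE)) abort("doses must be non-negative")
  out <- numeric(length(x))
  pos <- x > 0
  out[pos] <- lower + (upper - lower) /
    (1 + exp(slope * (log(x[pos]) - log(ed50))))
  # x = 0: limit depends on the slope sign
  if (any(!pos)) {
    lim0 <- if (slope > 0) upper else if (slope < 0) lower else (lower + upper) / 2
    out[!pos] <- lim0
  }
  out
}

# Linear-in-asymptotes profile SSE for fixed (slope, ed50); used by the
# grid initialiser.  g is the logistic weight so response = lower + (upper-lower)*g.
fourpl_profile <- function(dose, response, slope, ed50) {
  g <- ifelse(dose > 0,
              1 / (1 + exp(slope * (log(dose) - log(ed50)))),
              if (slope > 0) 1 else if (slope < 0) 0 else 0.5)
  fit <- tryCatch(lm(response ~ g), error = function(e) NULL)
  if (is.null(fit) || anyNA(coef(fit))) {
    return(list(sse = Inf, lower = NA_real_, upper = NA_real_))
  }
  cf <- coef(fit)
  list(sse = sum(residuals(fit)^2), lower = unname(cf[1]),
       upper = unname(cf[1] + cf[2]))
}

#' Fit a four-parameter log-logistic dose-response model
#'
#' Least-squares fit of [fourpl()] to a dose-response table by
#' Levenberg-Marquardt (via \pkg{minpack.lm}) with a coarse grid of
#' starting values over the midpoint and slope. The midpoint is fitted on
#' the log scale and constrained to
#' `[min positive dose / 10, max dose * 10]` unless other bounds are given.
#' Asymptotes are unconstrained by default.
#'
#' @param data Data frame with columns `dose` (uM, >= 0) and `response`.
#'   At least 4 distinct doses are required.
#' @param init Optional named list of starting values
#'   (`slope`, `lower`, `upper`, `ed50`) to use instead of the grid.
#' @param bounds Optional named list with elements `ed50 = c(min, max)`
#'   overriding the default midpoint bounds.
#' @return An object of class `fourpl_fit`: a list with elements `slope`,
#'   `lower`, `upper`, `ed50`, `sse`, `converged`, `n`, the `data` used and
#'   the standard errors (`se`, via the curvature of the least-squares
#'   surface; `NA` where not estimable). Non-convergence is reported in the
#'   `converged` flag, never silently. Supports [tidy()], [glance()],
#'   `predict()` and [ggplot2::autoplot()].
#' @examples
#' d <- gen_dose_response(list(slope = 2, lower = 0, upper = 1, ed50 = 0.5),
#'                        doses = c(0, 0.1, 0.25, 0.5, 1, 2), replicates = 1,
#'                        noise_cv = 0, seed = 1)
#' fit <- fit_4pl(d)
#' tidy(fit)
#' @export
fit_4pl <- function(data, init = NULL, bounds = NULL) {
  data <- as_tibble(data)
  stopifnot(all(c("dose", "response") %in% names(data)))
  data <- dplyr::filter(data, is.finite(.data$dose), is.finite(.data$response))
  if (any(data$dose < 0)) abort("doses must be non-negative")
  if (dplyr::n_distinct(data$dose) < 4) {
    abort("at least 4 distinct doses are required to fit a 4PL model")
  }
  dose <- data$dose
  response <- data$response
  pos <- sort(unique(dose[dose > 0]))
  ed50_lim <- c(min(pos) / 10, max(dose) * 10)
  if (!is.null(bounds$ed50)) ed50_lim <- bounds$ed50

  if (is.null(init)) {
    grid <- expand.grid(
      slope = c(-4, -2, -1, -0.5, 0.5, 1, 2, 4),
      ed50  = exp(seq(log(min(pos) / 3), log(max(pos) * 3), length.out = 15))
    )
    prof <- purrr::pmap(grid, function(slope, ed50) {
      c(fourpl_profile(dose, response, slope, ed50),
        slope = slope, ed50 = ed50)
    })
    best <- prof[[which.min(purrr::map_dbl(prof, "sse"))]]
    start <- list(slope = best$slope, lower = best$lower,
                  upper = best$upper, log_ed50 = log(best$ed50))
  } else {
    start <- list(slope = init$slope, lower = init$lower,
                  upper = init$upper, log_ed50 = log(init$ed50))
  }

  fit <- tryCatch(
    minpack.lm::nlsLM(
      response ~ fourpl(dose, slope, lower, upper, exp(log_ed50)),
      data = list(dose = dose, response = response),
      start = start,
      lower = c(-Inf, -Inf, -Inf, log(ed50_lim[1])),
      upper = c(Inf, Inf, Inf, log(ed50_lim[2])),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )

  if (!is.null(fit)) {
    cf <- coef(fit)
    se <- tryCatch(sqrt(diag(stats::vcov(fit))), error = function(e) rep(NA_real_, 4))
    ed50_se <- unname(se["log_ed50"]) * exp(cf[["log_ed50"]])  # delta method
    out <- list(
      slope = cf[["slope"]], lower = cf[["lower"]], upper = cf[["upper"]],
      ed50 = exp(cf[["log_ed50"]]),
      se = c(slope = unname(se["slope"]), lower = unname(se["lower"]),
             upper = unname(se["upper"]), ed50 = ed50_se),
      sse = sum(residuals(fit)^2),
      converged = fit$convInfo$isConv %||% TRUE,
      n = length(dose), data = data
    )
  } else {
    # Levenberg-Marquardt failed outright; polish the grid optimum with
    # Nelder-Mead so a parameter estimate (flagged non-converged when the
    # optimiser says so) is still reported.
    obj <- function(p) {
      sum((response - fourpl(dose, p[1], p[2], p[3], exp(p[4])))^2)
    }
    om <- optim(unlist(start), obj, method = "Nelder-Mead",
                control = list(maxit = 2000))
    out <- list(
      slope = unname(om$par[1]), lower = unname(om$par[2]),
      upper = unname(om$par[3]), ed50 = unname(exp(om$par[4])),
      se = c(slope = NA_real_, lower = NA_real_, upper = NA_real_,
             ed50 = NA_real_),
      sse = om$value, converged = om$convergence == 0,
      n = length(dose), data = data
    )
  }
  # canonicalise the LL.4 sign symmetry f(x; b, c, d, e) = f(x; -b, d, c, e)
  # so `upper` is always the larger asymptote
  if (out$upper < out$lower) {
    tmp <- out$lower
    out$lower <- out$upper
    out$upper <- tmp
    out$slope <- -out$slope
    out$se[c("lower", "upper")] <- out$se[c("upper", "lower")]
  }
  # a midpoint pinned to its bound is not an interior optimum: the ED50 is
  # unidentified for these data, so the fit is reported as non-converged
  at_bound <- out$ed50 / ed50_lim[1] < 1 + 1e-6 ||
    ed50_lim[2] / out$ed50 < 1 + 1e-6
  if (at_bound) out$converged <- FALSE
  # A midpoint outside the tested dose window was never bracketed by an
  # observed half-maximal response: the estimate is an extrapolation and is
  # reported as such (the assay-window convention for ED50s, "> max dose").
  out$midpoint_bracketed <- out$ed50 >= min(pos) && out$ed50 <= max(pos)
  if (!out$converged) warn("4PL fit did not converge; inspect `converged`")
  structure(out, class = "fourpl_fit")
}

#' @export
print.fourpl_fit <- function(x, ...) {
  cat("Four-parameter log-logistic fit (", x$n, " points)\n", sep = "")
  cat(sprintf("  slope %.4g  lower %.4g  upper %.4g  ed50 %.4g\n",
              x$slope, x$lower, x$upper, x$ed50))
  cat(sprintf("  SSE %.4g  converged: %s\n", x$sse, x$converged))
  invisible(x)
}

#' @export
predict.fourpl_fit <- function(object, newdata = NULL, ...) {
  dose <- if (is.null(newdata)) object$data$dose else {
    if (is.data.frame(newdata)) newdata$dose else newdata
  }
  fourpl(dose, object$slope, object$lower, object$upper, object$ed50)
}

#' @rdname fit_4pl
#' @param x A `fourpl_fit` object.
#' @param ... Unused.
#' @method tidy fourpl_fit
#' @export
tidy.fourpl_fit <- function(x, ...) {
  tibble(
    term = c("slope", "lower", "upper", "ed50"),
    estimate = c(x$slope, x$lower, x$upper, x$ed50),
    std.error = unname(x$se[c("slope", "lower", "upper", "ed50")])
  )
}

#' @rdname fit_4pl
#' @method glance fourpl_fit
#' @export
glance.fourpl_fit <- function(x, ...) {
  tibble(ed50 = x$ed50, sse = x$sse, n = x$n, converged = x$converged)
}

#' Replicate-wise ED50 aggregation
#'
#' Fits one 4PL model per replicate series and reports the arithmetic mean
#' and sample standard deviation of the replicate midpoints, the convention
#' for colony-formation ED50s from independently fitted sigmoidal models.
#' Replicate fits that did not converge, or whose midpoint falls outside
#' the tested dose window (an extrapolated ED50, conventionally reported
#' as "> max dose" rather than averaged), are excluded with a warning.
#'
#' @param data Either a data frame with columns `dose`, `response`,
#'   `replicate`, or a list of `fourpl_fit` objects.
#' @param ... Passed on to [fit_4pl()] when `data` is a data frame.
#' @return A one-row tibble: `ed50_mean`, `ed50_sd`, `n_fits`,
#'   `n_converged`, plus a list-column `fits`.
#' @export
ed50_with_replicates <- function(data, ...) {
  fits <- if (is.data.frame(data)) {
    stopifnot("replicate" %in% names(data))
    data |>
      dplyr::group_split(.data$replicate) |>
      purrr::map(\(d) tryCatch(fit_4pl(d, ...), error = function(e) NULL))
  } else {
    data
  }
  fits <- purrr::compact(fits)
  if (length(fits) == 0) abort("all replicate 4PL fits failed")
  conv <- purrr::map_lgl(fits, "converged") &
    purrr::map_lgl(fits, \(f) f$midpoint_bracketed %||% TRUE)
  if (any(!conv)) {
    warn(sprintf("excluding %d non-converged or unbracketed replicate fit(s)",
                 sum(!conv)))
  }
  mids <- purrr::map_dbl(fits[conv], "ed50")
  if (length(mids) < 2) abort("fewer than 2 converged replicate fits")
  tibble(
    ed50_mean = mean(mids), ed50_sd = sd(mids),
    n_fits = length(fits), n_converged = sum(conv),
    fits = list(fits)
  )
}

#' Normalise a response series to its maximum
#'
#' Divides a series by its maximum so the largest value maps to 1, the
#' convention used for ENSA-P/ENSA ratios and proliferation counts before
#' curve fitting or AUC computation. Idempotent and invariant to positive
#' rescaling.
#'
#' @param values Numeric vector with a positive maximum.
#' @return `values / max(values)`.
#' @export
normalize_to_max <- function(values) {
  m <- max(values, na.rm = TRUE)
  if (!is.finite(m) || m <= 0) abort("maximum must be positive to normalise")
  values / m
}

#' Proliferation AUC over a dose grid
#'
#' Trapezoidal area under normalised cell counts as a function of dose
#' (uM x normalised-count units). Lower AUC means a stronger
#' anti-proliferative response.
#'
#' @param doses Ascending dose grid (uM).
#' @param normalised_counts Counts normalised to their maximum, same length.
#' @return Scalar AUC.
#' @export
proliferation_auc <- function(doses, normalised_counts) {
  stopifnot(length(doses) == length(normalised_counts), length(doses) >= 2)
  if (is.unsorted(doses, strictly = FALSE)) abort("doses must be ascending")
  pracma::trapz(doses, normalised_counts)
}
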
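test_that("expression scaling divides by loading control then analyte maximum", {
  panel <- tibble::tibble(line = c("a", "b", "c"),
                          gwl = c(2, 4, 8), gapdh = c(1, 1, 1))
  out <- scale_expression(panel, "gapdh")
  expect_equal(out$gwl, c(0.25, 0.5, 1))
  expect_false("gapdh" %in% names(out))

  # invariant to a global multiplicative factor on the raw values
  out2 <- scale_expression(dplyr::mutate(panel, gwl = gwl * 37.2), "gapdh")
  expect_equal(out2$gwl, out$gwl)
  expect_equal(max(out$gwl), 1)
  expect_error(scale_expression(dplyr::mutate(panel, gapdh = 0), "gapdh"),
               "positive")
})

test_that("ratio model fitting matches closed-form OLS and is exact when noiseless", {
  noiseless <- tibble::tibble(gwl = runif(8, 0.2, 1), b55a = runif(8, 0.2, 1))
  noiseless$ed50 <- 0.5 * noiseless$gwl / noiseless$b55a + 0.1
  fit <- fit_ratio_model(noiseless)
  expect_equal(fit$gradient, 0.5, tolerance = 1e-10)
  expect_equal(fit$intercept, 0.1, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)

  set.seed(40)
  p <- gen_expression_panel(n_lines = 15, noise_sd = 0.2, seed = 41)
  fit <- fit_ratio_model(p)
  hand <- ols_by_hand(p$ratio, p$ed50)
  expect_equal(fit$gradient, unname(hand["gradient"]), tolerance = 1e-10)
  expect_equal(fit$intercept, unname(hand["intercept"]), tolerance = 1e-10)
  expect_equal(fit$r_squared, fit$pearson_r^2, tolerance = 1e-10)

  expect_error(fit_ratio_model(noiseless[1:2, ]), "n >= 3")
  expect_error(fit_ratio_model(dplyr::mutate(noiseless, b55a = 0)), "positive")
  expect_error(
    fit_ratio_model(tibble::tibble(gwl = c(1, 2, 3), b55a = c(1, 2, 3),
                                   ed50 = 1:3)), "zero-variance")
})

test_that("coefficient estimates are unbiased over repeated panels", {
  fits <- purrr::map(1:200, function(s) {
    glance(fit_ratio_model(gen_expression_panel(
      n_lines = 12, noise_sd = 0.05, seed = 5000 + s)))
  }) |> purrr::list_rbind()
  # mean estimates within one single-fit standard error of the truth
  se_g <- sd(fits$gradient)
  se_i <- sd(fits$intercept)
  expect_lt(abs(mean(fits$gradient) - 0.399), se_g)
  expect_lt(abs(mean(fits$intercept) - 0.406), se_i)
})

test_that("predictions follow the reference formula", {
  expect_equal(predict_ed50(tibble::tibble(gwl = 0.5, b55a = 1.0))$pred_ed50,
               0.6055)
  expect_equal(predict_ed50(tibble::tibble(gwl = 0.7, b55a = 0.7))$pred_ed50,
               0.399 + 0.406)
  flat <- predict_ed50(tibble::tibble(gwl = c(0.2, 0.9), b55a = c(0.5, 0.5)),
                       model = list(gradient = 0, intercept = 0.3))
  expect_equal(flat$pred_ed50, c(0.3, 0.3))
  expect_warning(out <- predict_ed50(tibble::tibble(gwl = 1, b55a = 0)),
                 "b55a = 0")
  expect_true(is.na(out$pred_ed50))

  # predict on a fit reproduces the observed ED50s for noiseless data
  p0 <- gen_expression_panel(n_lines = 10, noise_sd = 0, seed = 42)
  fit <- fit_ratio_model(p0)
  expect_equal(predict(fit, p0), p0$ed50, tolerance = 1e-10)
})

test_that("flagging selects the ceiling-fraction lowest predictions", {
  set.seed(43)
  v <- runif(100)
  flags <- rank_and_flag(v, 0.05)
  expect_equal(sum(flags), 5)
  expect_setequal(which(flags), order(v)[1:5])          # full-sort oracle
  # invariant to strictly monotone transforms
  expect_identical(flags, rank_and_flag(exp(3 * v), 0.05))
  expect_equal(sum(rank_and_flag(runif(11), 0.05)), 1)  # ceiling rule
  df <- rank_and_flag(tibble::tibble(pred_ed50 = v), 0.1)
  expect_equal(sum(df$flagged), 10)
  expect_error(rank_and_flag(numeric(0)), "empty")
  expect_error(rank_and_flag(v, 1.5), "fraction")
})

test_that("cohort median shifts recover generative shifts and mark nd groups", {
  groups <- tibble::tibble(group = c("null", "shifted", "no_normals"),
                           n_tumour = c(40, 40, 20),
                           n_normal = c(40, 40, 0))
  sh <- tibble::tibble(group = "shifted", gene = c("B55A", "GWL"),
                       shift_log = c(0.5, -0.5))
  coh <- gen_cohort_expression(groups, sh, seed = 44)
  res <- cohort_median_shift(coh)

  nd <- res[res$group == "no_normals", ]
  expect_true(all(!nd$determined))
  expect_true(all(is.na(nd$p)))

  up <- res[res$group == "shifted" & res$gene == "B55A", ]
  expect_gt(up$median_shift, 0)
  expect_lt(up$p_adj, 0.05)
  dn <- res[res$group == "shifted" & res$gene == "GWL", ]
  expect_lt(dn$median_shift, 0)
  expect_lt(dn$p_adj, 0.05)

  # null group: shift near zero on the log scale, test not strongly significant
  nl <- res[res$group == "null", ]
  expect_true(all(abs(log(nl$median_tumour / nl$median_normal)) < 0.4))
  expect_true(all(nl$p > 0.001))
  expect_true(all(res$p_adj >= res$p, na.rm = TRUE))
})

test_that("a strong GWL-down/B55A-up group dominates the sensitivity flags", {
  groups <- tibble::tibble(group = c("plain", "sensitive"),
                           n_tumour = c(100, 100), n_normal = c(0, 0))
  sh <- tibble::tibble(group = "sensitive", gene = c("GWL", "B55A"),
                       shift_log = c(-1.5, 1.5))
  coh <- gen_cohort_expression(groups, sh, seed = 45)
  wide <- coh |>
    dplyr::select(group, gene, sample, fpkm) |>
    dplyr::mutate(sample = sub("_(B55A|GWL)_", "_", sample)) |>
    tidyr::pivot_wider(names_from = gene, values_from = fpkm) |>
    dplyr::rename(gwl = GWL, b55a = B55A)
  flagged <- wide |> predict_ed50() |> rank_and_flag(0.05)
  expect_true(all(flagged$group[flagged$flagged] == "sensitive"))
})

test_that("Pearson correlation matches the textbook formula", {
  x <- c(1, 2, 4, 5, 7)
  y <- c(2, 1, 5, 4, 8)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  out <- correlate(x, y)
  expect_equal(out$r, r_hand, tolerance = 1e-12)
  expect_equal(correlate(x, 2 * x)$r, 1)

  # null: p-values uniform over seeds (KS)
  ps <- vapply(1:200, function(s) {
    set.seed(s)
    correlate(rnorm(100), rnorm(100))$p
  }, numeric(1))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
  expect_error(correlate(c(1, 1, 1), c(1, 2, 3)), "zero-variance")
})
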
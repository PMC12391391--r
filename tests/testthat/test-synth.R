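test_that("generated class fractions match generative probabilities at dose 0", {
  n <- 10000
  spec <- population_spec(n_cells = n, dose = 0, intensity_gain = 1, seed = 42)
  cells <- gen_cell_population(spec)
  probs <- expected_class_probs(spec)
  frac <- table(cells$true_class)[names(probs)] / n
  for (cl in names(probs)) {
    sd_bin <- sqrt(probs[[cl]] * (1 - probs[[cl]]) / n)
    expect_lt(abs(frac[[cl]] - probs[[cl]]), 3 * sd_bin)
  }
})

test_that("generators are deterministic per seed", {
  spec <- population_spec(n_cells = 500, dose = 1,
                          effect_curve = list(ed50 = 0.5, hill = 2, max_shift = 0.8),
                          seed = 7)
  expect_identical(gen_cell_population(spec), gen_cell_population(spec))
  dr <- function() gen_dose_response(list(slope = 2, lower = 0, upper = 1, ed50 = 0.5),
                                     doses = c(0, 0.5, 1), seed = 3)
  expect_identical(dr(), dr())
  ph <- function() gen_phospho_dataset(n_sites = 50, seed = 5)
  expect_identical(ph(), ph())
})

test_that("a saturating effect curve empties the cycling classes", {
  spec <- population_spec(
    n_cells = 5000, dose = 1000,
    effect_curve = list(ed50 = 0.5, hill = 2, max_shift = 1), seed = 9)
  probs <- expected_class_probs(spec)
  expect_lt(probs[["2N"]] + probs[["S"]], 0.001)
  cells <- gen_cell_population(spec)
  expect_lt(mean(cells$true_class %in% c("2N", "S")), 0.005)
})

test_that("population spec validates its inputs", {
  expect_error(population_spec(n_cells = 0), "n_cells")
  expect_error(population_spec(baseline_class_probs = c(0.5, 0.5, 0.2, -0.2)),
               "probabilities")
  expect_error(population_spec(intensity_gain = 0), "positive")
})

test_that("dose-response generator reproduces the 4PL curve", {
  truth <- list(slope = 2, lower = 0.1, upper = 1, ed50 = 0.5)
  doses <- c(0, 0.125, 0.25, 0.5, 1, 2)
  noiseless <- gen_dose_response(truth, doses, replicates = 2, noise_cv = 0,
                                 seed = 1)
  expect_equal(noiseless$response,
               rep(fourpl(doses, truth$slope, truth$lower, truth$upper,
                          truth$ed50), 2),
               tolerance = 1e-12)
  expect_equal(noiseless$response[noiseless$dose == 0],
               rep(truth$upper, 2))

  # law of large numbers: replicate means converge to the curve
  big <- gen_dose_response(truth, doses, replicates = 1000, noise_cv = 0.1,
                           seed = 2)
  means <- tapply(big$response, big$dose, mean)
  mu <- fourpl(doses, truth$slope, truth$lower, truth$upper, truth$ed50)
  mc_sd <- mu * 0.1 / sqrt(1000)
  expect_true(all(abs(means[as.character(doses)] - mu) <=
                    pmax(3 * mc_sd, 1e-12)))
})

test_that("expression panel obeys the generative ratio model", {
  p0 <- gen_expression_panel(n_lines = 10, noise_sd = 0, seed = 4)
  fit <- fit_ratio_model(p0)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  expect_equal(fit$gradient, 0.399, tolerance = 1e-10)
  expect_equal(fit$intercept, 0.406, tolerance = 1e-10)

  flat <- gen_expression_panel(n_lines = 10, gradient = 0, intercept = 0.7,
                               noise_sd = 0, seed = 4)
  expect_equal(flat$ed50, rep(0.7, 10))

  # closed-form OLS oracle recovers the gradient within its standard error
  p <- gen_expression_panel(n_lines = 12, noise_sd = 0.1, seed = 6)
  hand <- ols_by_hand(p$ratio, p$ed50)
  fit <- fit_ratio_model(p)
  expect_equal(fit$gradient, unname(hand["gradient"]), tolerance = 1e-10)
  se <- tidy(fit)$std.error[2]
  expect_lt(abs(fit$gradient - 0.399), 2 * se)
})

test_that("phospho generator honours the +1 proline probabilities", {
  ph <- gen_phospho_dataset(n_sites = 500, frac_down = 0.2, frac_up = 0,
                            pro_plus1_hit = 1, pro_plus1_bg = 0, seed = 8)
  plus1 <- substr(ph$windows$window, 9, 9)
  down <- ph$truth$status == "down"
  expect_true(all(plus1[down] == "P"))
  expect_true(all(plus1[!down] != "P"))
  expect_true(all(substr(ph$windows$window, 8, 8) %in% c("S", "T")))
  expect_error(gen_phospho_dataset(frac_down = 0.8, frac_up = 0.5), "frac")
  expect_error(gen_phospho_dataset(n_per_group = 1), "replicates")
})

test_that("cohort generator supports missing normal arms and log shifts", {
  groups <- tibble::tibble(group = c("A", "B"), n_tumour = c(30, 25),
                           n_normal = c(30, 0))
  sh <- tibble::tibble(group = "A", gene = "GWL", shift_log = -1)
  coh <- gen_cohort_expression(groups, sh, seed = 12)
  expect_equal(sum(coh$group == "B" & coh$tissue == "normal"), 0)
  med <- with(subset(coh, group == "A" & gene == "GWL"),
              tapply(log(fpkm), tissue, median))
  expect_lt(med[["tumour"]], med[["normal"]])
})
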
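test_that("phospho preprocessing follows the stated normalisation chain", {
  raw <- tibble::tibble(
    site = c("s1", "s2", "s3", "s4"),
    a = c(100, 200, 0, 700),
    b = c(10, 20, 30, 40)
  )
  proc <- normalize_phospho(raw)
  expect_true(isTRUE(attr(proc, "processed")))

  # zero entries imputed as the sample's minimum log2 value minus 1
  # (median-centring subtracts a constant, so differences are preserved)
  obs_a <- proc$a[raw$a > 0]
  expect_equal(proc$a[raw$a == 0], min(obs_a) - 1)

  # invariant to per-sample multiplicative rescaling of the raw input
  proc2 <- normalize_phospho(dplyr::mutate(raw, a = a * 10))
  expect_equal(proc2$a, proc$a, tolerance = 1e-12)
  expect_equal(proc2$b, proc$b, tolerance = 1e-12)

  # per-sample medians are centred at zero
  expect_equal(median(proc$b), 0)
  expect_error(normalize_phospho(dplyr::mutate(raw, a = 0)), "positive total")
  expect_error(normalize_phospho(dplyr::mutate(raw, a = -a)), "non-negative")
})

test_that("moderated test reduces to the ordinary t-test at zero prior df", {
  ph <- gen_phospho_dataset(n_sites = 300, frac_down = 0.1, frac_up = 0.05,
                            effect_log2 = 1.5, frac_zero = 0, seed = 50)
  proc <- normalize_phospho(ph$intensities)
  stats <- moderated_test(proc, ph$design, contrast = c("control", "treated"),
                          prior_df = 0)
  m <- as.matrix(proc[-1])
  ctrl <- ph$design$sample[ph$design$group == "control"]
  trt <- ph$design$sample[ph$design$group == "treated"]
  oracle <- vapply(seq_len(nrow(m)), function(i) {
    tt <- t.test(m[i, trt], m[i, ctrl], var.equal = TRUE)
    c(tt$statistic, tt$p.value)
  }, numeric(2))
  expect_equal(stats$t, unname(oracle[1, ]), tolerance = 1e-10)
  expect_equal(stats$p, unname(oracle[2, ]), tolerance = 1e-10)
  expect_equal(stats$log2_fc,
               unname(rowMeans(m[, trt]) - rowMeans(m[, ctrl])),
               tolerance = 1e-12)
})

test_that("infinite prior df pools the variance completely", {
  ph <- gen_phospho_dataset(n_sites = 200, frac_down = 0, frac_up = 0,
                            frac_zero = 0, seed = 51)
  proc <- normalize_phospho(ph$intensities)
  stats <- moderated_test(proc, ph$design, contrast = c("control", "treated"),
                          prior_df = Inf)
  s0 <- attr(stats, "var_prior")
  expect_equal(stats$t, stats$log2_fc / sqrt(s0 * (2 / 3)), tolerance = 1e-12)
  expect_true(all(stats$df_total == Inf))
})

test_that("moderated statistics agree with the limma cross-check", {
  skip_if_not_installed("limma")
  ph <- gen_phospho_dataset(n_sites = 400, frac_down = 0.1, frac_up = 0.05,
                            effect_log2 = 1.5, frac_zero = 0.03, seed = 52)
  proc <- normalize_phospho(ph$intensities)
  stats <- moderated_test(proc, ph$design, contrast = c("control", "treated"))

  m <- as.matrix(proc[-1])
  grp <- ph$design$group[match(colnames(m), ph$design$sample)]
  design <- cbind(1, grp == "treated")
  fit <- limma::eBayes(limma::lmFit(m, design))
  expect_equal(attr(stats, "df_prior"), fit$df.prior, tolerance = 1e-6)
  expect_equal(stats$t, fit$t[, 2], tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(stats$p, fit$p.value[, 2], tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("type-I error is controlled on a 2000-site null with 3v3 replicates", {
  ph <- gen_phospho_dataset(n_sites = 2000, n_per_group = 3,
                            frac_down = 0, frac_up = 0, frac_zero = 0,
                            seed = 53)
  proc <- normalize_phospho(ph$intensities)
  stats <- moderated_test(proc, ph$design, contrast = c("control", "treated"))
  frac_sig <- mean(stats$p < 0.05)
  mc_sd <- sqrt(0.05 * 0.95 / 2000)
  expect_lt(abs(frac_sig - 0.05), 3 * mc_sd)
  # essentially no FDR-gated hits under the null
  hits <- classify_hits(stats)
  expect_lte(sum(hits$class != "not significant"), 2)
})

test_that("spiked differential sites are recovered with high power", {
  ph <- gen_phospho_dataset(n_sites = 1000, n_per_group = 3,
                            frac_down = 0.1, frac_up = 0, effect_log2 = 3,
                            frac_zero = 0, seed = 54)
  proc <- normalize_phospho(ph$intensities)
  hits <- classify_hits(moderated_test(proc, ph$design,
                                       contrast = c("control", "treated")))
  down_truth <- ph$truth$site[ph$truth$status == "down"]
  recovered <- hits$site[hits$class == "negative hit"]
  expect_gte(mean(down_truth %in% recovered), 0.8)
})

test_that("hit classification applies the p and FDR gates jointly", {
  stats <- tibble::tibble(
    site = paste0("s", 1:5),
    log2_fc = c(-1, 1, -1, 2, 0.5),
    p = c(0.01, 0.01, 0.5, 0.01, 0.04),
    fdr = c(0.05, 0.05, 0.05, 0.2, 0.09)
  )
  out <- classify_hits(stats)
  expect_equal(as.character(out$class),
               c("negative hit", "positive hit", "not significant",
                 "not significant", "positive hit"))
  counts <- attr(out, "counts")
  expect_equal(counts$n, c(1, 2, 2))

  # counts are monotone non-increasing under stricter thresholds
  strict <- classify_hits(stats, p_max = 0.02, fdr_max = 0.06)
  expect_lte(sum(strict$class != "not significant"),
             sum(out$class != "not significant"))
})

test_that("motif frequencies report the +1 proline enrichment", {
  set.seed(55)
  mk_window <- function(plus1) {
    w <- sample(strsplit("ACDEFGHIKLMNQRSTVWY", "")[[1]], 15, replace = TRUE)
    w[8] <- "S"; w[9] <- plus1
    paste(w, collapse = "")
  }
  hits <- vapply(1:200, function(i) mk_window(if (runif(1) < 0.6) "P" else "A"),
                 character(1))
  bg <- vapply(1:2000, function(i) mk_window(if (runif(1) < 0.2) "P" else "A"),
               character(1))
  res <- motif_frequencies(c(hits, bg),
                           c(rep("negative hit", 200),
                             rep("not significant", 2000)))
  enr <- res$plus1_proline[res$plus1_proline$class == "negative hit", ]
  # 2x2 oracle: OR = (p_hit/(1-p_hit)) / (p_bg/(1-p_bg)) = 6 at the
  # generative rates; the seeded draw must land near it and be overwhelming
  expect_gt(enr$odds_ratio, 4)
  expect_lt(enr$odds_ratio, 9)
  expect_lt(enr$p, 1e-10)
  ft <- fisher.test(matrix(c(enr$n_pro, enr$n - enr$n_pro,
                             sum(substr(bg, 9, 9) == "P"),
                             sum(substr(bg, 9, 9) != "P")), 2, byrow = TRUE))
  expect_equal(enr$p, ft$p.value, tolerance = 1e-12)

  all_p <- vapply(1:30, function(i) mk_window("P"), character(1))
  res2 <- motif_frequencies(c(all_p, bg[1:50]),
                            c(rep("positive hit", 30),
                              rep("not significant", 50)))
  f <- res2$frequencies
  expect_equal(f$freq[f$class == "positive hit" & f$position == 1 &
                        f$residue == "P"], 1)

  # 'X' padding excluded from denominators
  res3 <- motif_frequencies(c("XXXXXXXSPAAAAAA", "XXXXXXXSAAAAAAA"),
                            c("negative hit", "not significant"))
  f3 <- res3$frequencies
  expect_equal(nrow(f3[f3$position == -1, ]), 0)   # padding-only position
  expect_equal(res3$plus1_proline$freq_pro[
    res3$plus1_proline$class == "negative hit"], 1)
})

test_that("hit-set intersections match brute-force set algebra", {
  a <- paste0("s", 1:50)
  res <- intersect_hits(list(A = a, B = a, C = a))
  expect_equal(res$shared_fraction, 1)
  expect_equal(length(res$common), 50)

  res2 <- intersect_hits(list(A = paste0("s", 1:10), B = paste0("t", 1:10)))
  expect_equal(length(res2$common), 0)
  expect_equal(res2$shared_fraction, 0)

  set.seed(56)
  sets <- purrr::map(1:3, \(i) sample(paste0("s", 1:60), 30))
  names(sets) <- c("A", "B", "C")
  res3 <- intersect_hits(sets)
  expect_equal(sort(res3$common),
               sort(Reduce(intersect, sets)))
  expect_equal(res3$union_size, length(Reduce(union, sets)))
  only_a <- setdiff(sets$A, union(sets$B, sets$C))
  expect_equal(res3$partition$n[res3$partition$region == "A"],
               length(only_a))
  expect_equal(sum(res3$partition$n), res3$union_size)
  expect_error(intersect_hits(list(A = a)), "2 sets")
})
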
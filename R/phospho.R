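#' Normalise and transform a phosphopeptide intensity matrix
#'
#' The preprocessing chain for XIC-derived phosphosite intensities:
#' each sample (column) is divided by its total intensity so column sums
#' equal 1; intensities are log2-transformed; zero entries are imputed as
#' that sample's minimum observed log2 value minus 1; finally each sample
#' is median-centred. The processed matrix is invariant to per-sample
#' multiplicative rescaling of the raw intensities.
#'
#' The imputation step needs the post-log2 per-sample minimum, which fixes
#' the order of operations: sum-normalise, log2, impute, centre.
#'
#' @param x Wide tibble (`site` column plus one numeric column per
#'   sample) or a numeric matrix with site rownames. Intensities >= 0;
#'   every sample must have a positive total.
#' @return Wide tibble of processed log2 intensities (same shape), with
#'   attribute `processed = TRUE`.
#' @export
normalize_phospho <- function(x) {
  m <- phospho_matrix(x)
  if (any(m < 0, na.rm = TRUE)) abort("intensities must be non-negative")
  totals <- colSums(m, na.rm = TRUE)
  if (any(totals <= 0)) abort("every sample needs positive total intensity")
  m <- sweep(m, 2, totals, "/")
  lg <- log2(m)                              # zeros become -Inf, imputed next
  for (j in seq_len(ncol(lg))) {
    col <- lg[, j]
    obs <- col[is.finite(col)]
    if (length(obs) == 0) abort("all-zero sample after normalisation")
    col[!is.finite(col)] <- min(obs) - 1
    lg[, j] <- col - median(col)
  }
  out <- dplyr::bind_cols(tibble(site = rownames(lg)), as_tibble(lg))
  attr(out, "processed") <- TRUE
  out
}

phospho_matrix <- function(x) {
  if (is.matrix(x)) {
    if (is.null(rownames(x))) rownames(x) <- sprintf("site_%05d", seq_len(nrow(x)))
    return(x)
  }
  x <- as_tibble(x)
  stopifnot("site" %in% names(x))
  m <- as.matrix(x[setdiff(names(x), "site")])
  rownames(m) <- x$site
  m
}

# Newton solver for trigamma(x) = y (Smyth-style), vectorised over y.
trigamma_inverse <- function(y) {
  out <- y
  lo <- y < 1e-6; hi <- y > 1e7
  out[lo] <- 1 / y[lo]
  out[hi] <- 1 / sqrt(y[hi])
  mid <- !lo & !hi
  if (any(mid)) {
    x <- 0.5 + 1 / y[mid]
    for (i in 1:50) {
      tri <- trigamma(x)
      dif <- tri * (1 - tri / y[mid]) / psigamma(x, deriv = 2)
      x <- x + dif
      if (max(abs(dif / x)) < 1e-8) break
    }
    out[mid] <- x
  }
  out
}

# Method-of-moments fit of a scaled-F prior to sample variances (Smyth):
# returns prior df d0 and prior variance s0^2 from log residual variances.
fit_variance_prior <- function(s2, df) {
  ok <- is.finite(s2) & s2 > 0
  if (sum(ok) < 2) return(list(df_prior = 0, var_prior = mean(s2[ok])))
  z <- log(s2[ok])
  e <- z - digamma(df / 2) + log(df / 2)
  evar <- stats::var(e) - trigamma(df / 2)
  if (evar > 0) {
    df_prior <- 2 * trigamma_inverse(evar)
    var_prior <- exp(mean(e) + digamma(df_prior / 2) - log(df_prior / 2))
  } else {
    df_prior <- Inf
    var_prior <- exp(mean(e))
  }
  list(df_prior = df_prior, var_prior = var_prior)
}

#' Empirical-Bayes moderated two-group test per phosphosite
#'
#' For every site, the log2 fold change (treated minus reference group
#' mean on the processed scale) and a moderated t-statistic: per-site
#' pooled variances are shrunk toward a common prior estimated by the
#' method of moments on the log residual variances (a scaled-F
#' hierarchical model), and the moderated t is referred to a t
#' distribution with prior + residual degrees of freedom. Benjamini-
#' Hochberg FDR across all sites. With `prior_df = 0` the statistics
#' reduce to the ordinary two-sample pooled t-test; with `prior_df = Inf`
#' every site uses the common prior variance and the reference
#' distribution is normal.
#'
#' Sites whose residual variance is exactly zero receive the prior
#' variance.
#'
#' @param x Processed matrix/tibble from [normalize_phospho()].
#' @param design Tibble `sample`, `group` covering every sample column;
#'   exactly two groups, each with >= 2 replicates.
#' @param contrast Length-2 character: `c(reference, treatment)`. Default
#'   is the group order of `design`.
#' @param prior_df Optional override of the estimated prior degrees of
#'   freedom (0 = ordinary t; Inf = fully pooled variance).
#' @return Tibble `site`, `log2_fc`, `t`, `df_total`, `p`, `fdr`;
#'   attributes `df_prior` and `var_prior` record the estimated (or
#'   forced) prior.
#' @export
moderated_test <- function(x, design, contrast = NULL, prior_df = NULL) {
  m <- phospho_matrix(x)
  design <- as_tibble(design)
  stopifnot(all(c("sample", "group") %in% names(design)))
  if (!all(design$sample %in% colnames(m))) {
    abort("design names samples missing from the matrix")
  }
  groups <- unique(design$group)
  if (length(groups) != 2) abort("exactly two groups are required")
  contrast <- contrast %||% groups
  stopifnot(setequal(contrast, groups))
  ref_s <- design$sample[design$group == contrast[1]]
  trt_s <- design$sample[design$group == contrast[2]]
  n1 <- length(ref_s); n2 <- length(trt_s)
  if (n1 < 2 || n2 < 2) abort("at least 2 replicates per group are required")

  m1 <- rowMeans(m[, ref_s, drop = FALSE])
  m2 <- rowMeans(m[, trt_s, drop = FALSE])
  v1 <- apply(m[, ref_s, drop = FALSE], 1, stats::var)
  v2 <- apply(m[, trt_s, drop = FALSE], 1, stats::var)
  df <- n1 + n2 - 2
  if (df < 1) abort("zero residual degrees of freedom")
  s2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df

  prior <- fit_variance_prior(s2, df)
  d0 <- prior_df %||% prior$df_prior
  s0 <- prior$var_prior
  s2_post <- if (d0 == 0) s2 else if (is.infinite(d0)) rep(s0, length(s2)) else
    (d0 * s0 + df * s2) / (d0 + df)
  s2_post[s2 == 0 & d0 > 0] <- s0
  if (d0 == 0 && any(s2 == 0)) s2_post[s2 == 0] <- s0  # untestable otherwise

  fc <- unname(m2 - m1)
  tstat <- fc / sqrt(unname(s2_post) * (1 / n1 + 1 / n2))
  df_total <- df + d0
  p <- 2 * pt(-abs(tstat), df = df_total)
  out <- tibble(site = rownames(m), log2_fc = fc, t = tstat,
                df_total = df_total, p = p,
                fdr = p.adjust(p, "BH"))
  attr(out, "df_prior") <- d0
  attr(out, "var_prior") <- s0
  out
}

#' Classify phosphosites into hit classes
#'
#' A site is a negative hit if `p < p_max`, `FDR < fdr_max` and its log2
#' fold change is negative (dephosphorylated); a positive hit with the
#' same gates and a positive fold change; otherwise not significant.
#' Defaults are the standard gates p < 0.05 and FDR < 0.1.
#'
#' @param stats Output of [moderated_test()].
#' @param p_max,fdr_max Significance gates on raw p and BH FDR.
#' @return `stats` with a `class` factor column
#'   (levels: negative hit / positive hit / not significant); per-class
#'   counts in the `"counts"` attribute.
#' @export
classify_hits <- function(stats, p_max = 0.05, fdr_max = 0.1) {
  stopifnot(all(c("log2_fc", "p", "fdr") %in% names(stats)))
  out <- stats |>
    mutate(class = factor(
      dplyr::case_when(
        .data$p < p_max & .data$fdr < fdr_max & .data$log2_fc < 0 ~ "negative hit",
        .data$p < p_max & .data$fdr < fdr_max & .data$log2_fc > 0 ~ "positive hit",
        TRUE ~ "not significant"
      ),
      levels = c("negative hit", "positive hit", "not significant")
    ))
  attr(out, "counts") <- dplyr::count(out, .data$class, .drop = FALSE)
  out
}

#' Position-specific residue frequencies and +1-proline enrichment
#'
#' Computes, per hit class, the relative frequency of every residue at
#' window positions -7..+7 around the phosphoresidue ('X' padding is
#' excluded from denominators), and a two-sided Fisher exact test of
#' proline at the +1 position in each hit class (and in all hits
#' combined) against the not-significant background — the signature of
#' CDK-substrate involvement.
#'
#' @param windows Character vector of 15-mer sequence windows aligned on
#'   the phosphoresidue (position 0 at index 8).
#' @param labels Class labels parallel to `windows` (as from
#'   [classify_hits()]).
#' @return List with `frequencies` (tibble `class`, `position`, `residue`,
#'   `freq`, `n`) and `plus1_proline` (tibble `class`, `n`, `n_pro`,
#'   `freq_pro`, `odds_ratio`, `p` vs the not-significant background).
#' @export
motif_frequencies <- function(windows, labels) {
  stopifnot(length(windows) == length(labels))
  if (any(nchar(windows) != 15)) abort("windows must be 15-mers (use 'X' padding)")
  labels <- as.character(labels)
  aa_mat <- do.call(rbind, strsplit(windows, ""))
  positions <- -7:7

  freq <- purrr::map(unique(labels), function(cl) {
    rows <- aa_mat[labels == cl, , drop = FALSE]
    if (nrow(rows) == 0) abort(sprintf("no windows in class '%s'", cl))
    purrr::map(seq_along(positions), function(j) {
      col <- rows[, j]
      col <- col[col != "X"]
      if (length(col) == 0) return(NULL)
      tab <- table(col)
      tibble(class = cl, position = positions[j],
             residue = names(tab), freq = as.numeric(tab) / length(col),
             n = length(col))
    }) |> purrr::compact() |> list_rbind()
  }) |> list_rbind()

  ns_lab <- "not significant"
  plus1 <- function(rows) rows[, 9] == "P" & rows[, 9] != "X"
  bg_rows <- aa_mat[labels == ns_lab, , drop = FALSE]
  enr <- purrr::map(setdiff(unique(labels), ns_lab), function(cl) {
    plus1_table(aa_mat[labels == cl, , drop = FALSE], bg_rows, cl)
  })
  if (sum(labels != ns_lab) > 0 && nrow(bg_rows) > 0) {
    enr <- c(enr, list(plus1_table(aa_mat[labels != ns_lab, , drop = FALSE],
                                   bg_rows, "hits (all)")))
  }
  list(frequencies = freq, plus1_proline = list_rbind(enr))
}

plus1_table <- function(hit_rows, bg_rows, label) {
  hp <- hit_rows[, 9]; bp <- bg_rows[, 9]
  hp <- hp[hp != "X"]; bp <- bp[bp != "X"]
  tab <- matrix(c(sum(hp == "P"), sum(hp != "P"),
                  sum(bp == "P"), sum(bp != "P")), 2, byrow = TRUE)
  ft <- if (nrow(bg_rows) > 0 && length(hp) > 0)
    fisher.test(tab, alternative = "two.sided") else NULL
  tibble(class = label, n = length(hp), n_pro = sum(hp == "P"),
         freq_pro = if (length(hp)) mean(hp == "P") else NA_real_,
         odds_ratio = if (!is.null(ft)) unname(ft$estimate) else NA_real_,
         p = if (!is.null(ft)) ft$p.value else NA_real_)
}

#' Intersection structure of hit sets across cell lines
#'
#' Venn partition of two or more named site-id sets: the number of sites
#' falling in every exclusive region, the sites common to all sets, and
#' the shared fraction |common to all| / |union| — the cross-cell-line
#' consistency statistic.
#'
#' @param hit_sets Named list (>= 2) of character vectors of site ids.
#' @return List: `partition` (tibble `region`, `n`, with region names like
#'   `"A&B"` for sites in exactly A and B), `common` (character vector),
#'   `union_size`, `shared_fraction`.
#' @export
intersect_hits <- function(hit_sets) {
  if (length(hit_sets) < 2) abort("at least 2 sets are required")
  if (is.null(names(hit_sets)) || any(names(hit_sets) == "")) {
    names(hit_sets) <- LETTERS[seq_along(hit_sets)]
  }
  hit_sets <- purrr::map(hit_sets, unique)
  all_ids <- unique(unlist(hit_sets))
  membership <- vapply(hit_sets, function(s) all_ids %in% s,
                       logical(length(all_ids)))
  membership <- matrix(membership, nrow = length(all_ids),
                       dimnames = list(all_ids, names(hit_sets)))
  region <- apply(membership, 1, function(r) paste(names(hit_sets)[r], collapse = "&"))
  partition <- tibble(region = region) |>
    dplyr::count(.data$region, name = "n") |>
    dplyr::arrange(dplyr::desc(.data$n))
  common <- all_ids[rowSums(membership) == length(hit_sets)]
  list(partition = partition, common = common,
       union_size = length(all_ids),
       shared_fraction = if (length(all_ids)) length(common) / length(all_ids) else NA_real_)
}
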
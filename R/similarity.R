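#' Subsample cells uniformly without replacement
#'
#' Draws `n` cells uniformly at random; the fixed-size subsample that
#' precedes embedding so every condition contributes the same number of
#' points. If the population is smaller than `n` the whole table is
#' returned with a warning.
#'
#' @param table A per-cell feature table.
#' @param n Target number of cells (default 500).
#' @param seed Integer seed.
#' @return The subsampled tibble (attributes preserved).
#' @export
subsample_cells <- function(table, n = 500, seed = 1L) {
  if (nrow(table) == 0) abort("empty table")
  if (n < 1) abort("n must be >= 1")
  if (nrow(table) <= n) {
    if (nrow(table) < n) {
      warn(sprintf("population (%d) smaller than requested n = %d; returning all cells",
                   nrow(table), n))
    }
    return(table)
  }
  set.seed(as.integer(seed))
  idx <- sample.int(nrow(table), n)
  out <- table[idx, , drop = FALSE]
  attributes(out)[c("normalised", "norm_factors")] <-
    attributes(table)[c("normalised", "norm_factors")]
  out
}

#' Joint 2D embedding of per-cell features across conditions
#'
#' Pools the cells of all conditions, log-transforms the right-skewed
#' intensity channels (log1p on DNA, EdU, p21), z-scores each feature over
#' the pooled cells, and fits a single UMAP embedding so that coordinates
#' are comparable across conditions — a prerequisite for cross-condition
#' transport distances. The embedding is deterministic given the seed
#' (single-threaded).
#'
#' @param tables A single feature table with a `condition` column, or a
#'   named list of per-condition tables.
#' @param features Feature columns to embed (default the five-channel
#'   phenotype: DNA, EdU, p21, area, nuclear count).
#' @param seed Integer seed.
#' @param n_neighbors,min_dist UMAP hyperparameters (defaults 15 / 0.1).
#' @return Tibble of class `phenotype_embedding` with columns `condition`,
#'   `umap1`, `umap2` (one row per input cell, input order preserved
#'   within condition); seed and hyperparameters stored as attributes.
#' @export
embed_conditions <- function(tables,
                             features = c("dna", "edu", "p21", "area", "nuclei"),
                             seed = 1L, n_neighbors = 15, min_dist = 0.1) {
  cells <- if (is.data.frame(tables)) {
    as_tibble(tables)
  } else {
    purrr::imap(tables, \(t, nm) mutate(as_tibble(t), condition = nm)) |>
      list_rbind()
  }
  if (!"condition" %in% names(cells)) abort("a condition column is required")
  stopifnot(all(features %in% names(cells)))
  if (nrow(cells) < 20) abort("fewer than 20 pooled cells; embedding unreliable")

  x <- as.matrix(cells[features])
  for (f in intersect(features, c("dna", "edu", "p21"))) {
    x[, f] <- log1p(x[, f])
  }
  x <- scale(x)
  x[, attr(x, "scaled:scale") == 0] <- 0   # constant features carry no signal

  nn <- min(n_neighbors, nrow(cells) - 1)
  if (nn < n_neighbors) {
    warn(sprintf("n_neighbors reduced to %d for %d cells", nn, nrow(cells)))
  }
  set.seed(as.integer(seed))
  emb <- uwot::umap(x, n_neighbors = nn, min_dist = min_dist,
                    n_threads = 1, n_sgd_threads = 0, verbose = FALSE)
  out <- tibble(condition = cells$condition,
                umap1 = emb[, 1], umap2 = emb[, 2])
  class(out) <- c("phenotype_embedding", class(out))
  attr(out, "seed") <- as.integer(seed)
  attr(out, "params") <- list(n_neighbors = nn, min_dist = min_dist,
                              features = features)
  out
}

#' Exact 1-Wasserstein distance between 2D point clouds
#'
#' The earth mover's distance between two equal-size empirical measures
#' with Euclidean ground cost, solved exactly as a linear assignment
#' problem (for uniform weights and equal sizes the optimal transport plan
#' is a permutation, so W1 is the minimum mean assignment cost). Clouds of
#' unequal size are equalised by uniformly subsampling the larger.
#'
#' @param a,b Two-column matrices or data frames of 2D coordinates
#'   (e.g. `umap1`, `umap2`).
#' @param seed Seed for the equalising subsample when sizes differ.
#' @return Scalar W1 distance (embedding units). 0 for identical clouds;
#'   exactly `|v|` when `b` is `a` translated by `v`.
#' @export
wasserstein_2d <- function(a, b, seed = 1L) {
  a <- cloud_matrix(a); b <- cloud_matrix(b)
  if (nrow(a) == 0 || nrow(b) == 0) abort("empty point cloud")
  set.seed(as.integer(seed))
  if (nrow(a) > nrow(b)) a <- a[sample.int(nrow(a), nrow(b)), , drop = FALSE]
  if (nrow(b) > nrow(a)) b <- b[sample.int(nrow(b), nrow(a)), , drop = FALSE]
  n <- nrow(a)
  cost <- sqrt(outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2)
  sol <- clue::solve_LSAP(cost)
  mean(cost[cbind(seq_len(n), as.integer(sol))])
}

cloud_matrix <- function(x) {
  if (is.data.frame(x)) {
    cols <- intersect(c("umap1", "umap2"), names(x))
    x <- if (length(cols) == 2) x[cols] else x[vapply(x, is.numeric, TRUE)][1:2]
  }
  m <- as.matrix(x)
  stopifnot(ncol(m) == 2)
  m
}

#' Phenotypic similarity profile against a reference condition
#'
#' Scores every condition of a joint embedding by its Wasserstein distance
#' to a reference condition (e.g. control-siRNA cells treated with a high
#' inhibitor dose). Low distances mean the condition's phenotype
#' distribution resembles the reference. A baseline noise floor — the
#' distance between two disjoint halves of the reference cloud itself —
#' is reported as an extra row flagged `baseline`.
#'
#' @param embedding A [embed_conditions()] result.
#' @param reference Reference condition label (must be present).
#' @param seed Seed for size equalisation and the baseline split.
#' @return Tibble `condition`, `distance`, `n`, `baseline`, sorted by
#'   distance with the baseline row last.
#' @export
similarity_profile <- function(embedding, reference, seed = 1L) {
  stopifnot(all(c("condition", "umap1", "umap2") %in% names(embedding)))
  conds <- unique(embedding$condition)
  if (!reference %in% conds) {
    abort(sprintf("reference condition '%s' not present", reference))
  }
  ref <- dplyr::filter(embedding, .data$condition == reference)
  scores <- purrr::map(setdiff(conds, reference), function(cond) {
    pts <- dplyr::filter(embedding, .data$condition == cond)
    tibble(condition = cond,
           distance = wasserstein_2d(pts, ref, seed = seed),
           n = min(nrow(pts), nrow(ref)), baseline = FALSE)
  }) |> list_rbind()

  # noise floor: W1 between two disjoint halves of the reference cloud
  set.seed(as.integer(seed))
  half <- sample.int(nrow(ref), floor(nrow(ref) / 2))
  floor_d <- wasserstein_2d(ref[half, ], ref[-half, ][seq_along(half), ],
                            seed = seed)
  dplyr::bind_rows(
    dplyr::arrange(scores, .data$distance),
    tibble(condition = reference, distance = floor_d,
           n = length(half), baseline = TRUE)
  )
}
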
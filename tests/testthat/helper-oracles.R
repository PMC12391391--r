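# Independent oracles used across test files.

# All permutations of 1:n (n small), for the brute-force transport oracle.
all_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1)) {
    for (k in seq_len(n)) {
      out[[length(out) + 1]] <- append(p, n, after = k - 1)
    }
  }
  out
}

# Exact W1 between equal-size clouds by enumerating all assignments.
w1_brute <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  n <- nrow(a)
  cost <- sqrt(outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2)
  min(vapply(all_perms(n),
             function(p) mean(cost[cbind(seq_len(n), p)]), numeric(1)))
}

# Benjamini-Hochberg step-up computed from the definition.
bh_by_hand <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (i in rev(seq_len(m))) {
    prev <- min(prev, m / i * p[o[i]])
    adj[o[i]] <- prev
  }
  adj
}

# Closed-form simple OLS (sums formulation).
ols_by_hand <- function(x, y) {
  beta <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  c(intercept = mean(y) - beta * mean(x), gradient = beta)
}

# A small raw + reference population pair with ground truth.
make_gated_population <- function(n = 4000, dose = 1, gain = 1, cv = 0.08,
                                  seed = 11) {
  eff <- list(ed50 = 0.5, hill = 2, max_shift = 0.8)
  ref <- gen_cell_population(population_spec(
    n_cells = n, dose = 0, intensity_gain = gain, peak_cv = cv, seed = seed))
  trt <- gen_cell_population(population_spec(
    n_cells = n, dose = dose, effect_curve = eff, intensity_gain = gain,
    peak_cv = cv, seed = seed + 1))
  list(ref = ref, trt = trt)
}
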
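#' Specification of a synthetic cell population
#'
#' Bundles the parameters of the per-cell feature generator. The generator
#' emulates tables exported downstream of segmentation: integrated DNA
#' intensity, mean EdU and p21 intensities, cell area and nuclear count,
#' in arbitrary units with a global multiplicative gain so that the
#' first-peak normalisation stage has real work to do.
#'
#' The dose acts through a saturating Hill-type transfer curve
#' (`effect_curve`) that moves probability mass from the cycling classes
#' {2N, S} into {4N, 8N+}, emulating mitotic failure followed by
#' tetraploidisation and endoreduplication; shifted mass is split 2/3 to
#' 4N and 1/3 to 8N+.
#'
#' @param n_cells Number of cells to draw (> 0).
#' @param baseline_class_probs Named probabilities over
#'   `c("2N", "S", "4N", "8N+")`, summing to 1: the dose-0 class mix.
#' @param dose Drug concentration (uM).
#' @param effect_curve `NULL` (no dose effect) or a list
#'   `list(ed50 =, hill =, max_shift =)`: the fraction of {2N, S} mass
#'   shifted at `dose` is `max_shift / (1 + (ed50 / dose)^hill)` (0 at
#'   dose 0, `max_shift` at saturation).
#' @param p21_fraction,multinucleation_fraction Probability that a cell is
#'   p21-positive / multinucleated; either a scalar or a function of dose.
#' @param intensity_gain Positive arbitrary-unit gain applied to all three
#'   intensity channels.
#' @param peak_cv Coefficient of variation of the intensity peaks
#'   (lognormal shape).
#' @param condition Condition label stored with every cell.
#' @param seed Integer seed; generation is reproducible per seed.
#' @return A `population_spec` list, validated.
#' @export
population_spec <- function(n_cells = 5000,
                            baseline_class_probs = c("2N" = 0.55, "S" = 0.20,
                                                     "4N" = 0.20, "8N+" = 0.05),
                            dose = 0,
                            effect_curve = NULL,
                            p21_fraction = 0.05,
                            multinucleation_fraction = 0.03,
                            intensity_gain = 1,
                            peak_cv = 0.08,
                            condition = sprintf("dose_%g", dose),
                            seed = 1L) {
  if (!is.numeric(n_cells) || n_cells < 1) abort("n_cells must be >= 1")
  p <- baseline_class_probs
  if (length(p) != 4 || any(p < 0) || any(p > 1) || abs(sum(p) - 1) > 1e-8) {
    abort("baseline_class_probs must be 4 probabilities in [0,1] summing to 1")
  }
  if (is.null(names(p))) names(p) <- cc_classes
  if (!setequal(names(p), cc_classes)) {
    abort("baseline_class_probs must be named 2N, S, 4N, 8N+")
  }
  if (intensity_gain <= 0) abort("intensity_gain must be positive")
  if (dose < 0) abort("dose must be non-negative")
  if (peak_cv < 0) abort("peak_cv must be non-negative")
  structure(list(n_cells = as.integer(n_cells),
                 baseline_class_probs = p[cc_classes], dose = dose,
                 effect_curve = effect_curve, p21_fraction = p21_fraction,
                 multinucleation_fraction = multinucleation_fraction,
                 intensity_gain = intensity_gain, peak_cv = peak_cv,
                 condition = condition, seed = as.integer(seed)),
            class = "population_spec")
}

cc_classes <- c("2N", "S", "4N", "8N+")

# lognormal sdlog giving the requested coefficient of variation
cv_to_sdlog <- function(cv) sqrt(log1p(cv^2))

as_dose_fun <- function(x) if (is.function(x)) x else function(dose) x

#' Dose-adjusted class probabilities
#'
#' Closed-form expected class mix of [gen_cell_population()] at a dose:
#' a fraction `s` of the {2N, S} mass (given by the spec's effect curve)
#' moves into {4N, 8N+} in a 2:1 split.
#'
#' @param spec A [population_spec()].
#' @return Named probability vector over the four classes.
#' @export
expected_class_probs <- function(spec) {
  p <- spec$baseline_class_probs
  s <- shift_fraction(spec$effect_curve, spec$dose)
  moved <- s * (p[["2N"]] + p[["S"]])
  c("2N" = p[["2N"]] * (1 - s),
    "S"  = p[["S"]] * (1 - s),
    "4N" = p[["4N"]] + 2 / 3 * moved,
    "8N+" = p[["8N+"]] + 1 / 3 * moved)
}

shift_fraction <- function(effect_curve, dose) {
  if (is.null(effect_curve) || dose == 0) return(0)
  with(effect_curve, max_shift / (1 + (ed50 / dose)^hill))
}

#' Generate a synthetic per-cell feature table with ground truth
#'
#' Draws a per-cell feature table whose statistical structure matches what
#' the gating stage assumes: lognormal integrated DNA intensity with class
#' medians at gain x {1, 2, 4} genome-equivalents for 2N/4N/8N+ and
#' uniform between the 2N and 4N medians for S cells; bimodal EdU (high
#' component for S cells) and p21 (high component for p21+ cells)
#' intensities; nuclear counts of 2-4 for multinucleated cells; and
#' ploidy-scaled lognormal cell areas. Ground-truth labels travel with the
#' table in `true_*` columns (ignored by all analysis stages) and the
#' generative probabilities in the `"truth"` attribute.
#'
#' @param spec A [population_spec()].
#' @return A raw (un-normalised) tibble with columns `condition`, `dose`,
#'   `dna`, `edu`, `p21`, `area`, `nuclei`, `true_class`, `true_p21`,
#'   `true_multi`; attribute `truth` holds the expected class
#'   probabilities, p21/multinucleation fractions and the spec.
#' @examples
#' cells <- gen_cell_population(population_spec(n_cells = 1000, seed = 7))
#' dplyr::count(cells, true_class)
#' @export
gen_cell_population <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  set_gen_seed(spec$seed)
  n <- spec$n_cells
  gain <- spec$intensity_gain
  sdlog <- cv_to_sdlog(spec$peak_cv)
  probs <- expected_class_probs(spec)
  cls <- sample(cc_classes, n, replace = TRUE, prob = probs)

  p21_frac <- as_dose_fun(spec$p21_fraction)(spec$dose)
  multi_frac <- as_dose_fun(spec$multinucleation_fraction)(spec$dose)
  if (p21_frac < 0 || p21_frac > 1 || multi_frac < 0 || multi_frac > 1) {
    abort("p21 and multinucleation fractions must be probabilities")
  }
  p21_pos <- runif(n) < p21_frac
  multi <- runif(n) < multi_frac

  # S cells get a placeholder draw (keeps the RNG stream aligned) and are
  # then overwritten with the uniform inter-peak DNA content
  dna_median <- c("2N" = 1, "S" = 1, "4N" = 2, "8N+" = 4)[cls] * gain
  dna <- rlnorm(n, meanlog = log(dna_median), sdlog = sdlog)
  is_s <- cls == "S"
  dna[is_s] <- runif(sum(is_s), min = gain, max = 2 * gain)

  edu <- rlnorm(n, meanlog = log(gain), sdlog = sdlog)            # negative pop
  edu[is_s] <- rlnorm(sum(is_s), meanlog = log(6 * gain), sdlog = 0.35)
  p21 <- rlnorm(n, meanlog = log(gain), sdlog = sdlog)
  p21[p21_pos] <- rlnorm(sum(p21_pos), meanlog = log(6 * gain), sdlog = 0.35)

  nuclei <- rep(1L, n)
  nuclei[multi] <- sample(2:4, sum(multi), replace = TRUE)

  area_scale <- c("2N" = 1, "S" = 1.5, "4N" = 2, "8N+" = 4)[cls]
  area <- rlnorm(n, meanlog = log(400 * area_scale), sdlog = cv_to_sdlog(0.3))

  out <- tibble(
    condition = spec$condition, dose = spec$dose,
    dna = dna, edu = edu, p21 = p21, area = area, nuclei = nuclei,
    true_class = factor(cls, levels = cc_classes),
    true_p21 = p21_pos, true_multi = multi
  )
  attr(out, "truth") <- list(
    class_probs = probs, p21_fraction = p21_frac,
    multinucleation_fraction = multi_frac, spec = spec
  )
  out
}

#' Generate synthetic dose-response curves
#'
#' Draws replicate response series from a known 4PL curve with
#' multiplicative mean-one lognormal noise, emulating colony counts over a
#' dose grid; the expected value at every dose equals the generative curve.
#'
#' @param truth Named list of generative 4PL parameters
#'   (`slope`, `lower`, `upper`, `ed50`), see [fourpl()].
#' @param doses Non-negative dose grid (uM).
#' @param replicates Number of independent replicate series.
#' @param noise_cv Coefficient of variation of the multiplicative noise
#'   (>= 0; 0 gives noiseless curves).
#' @param seed Integer seed.
#' @return Tibble `dose`, `replicate`, `response` with the generative
#'   parameters in the `"truth"` attribute.
#' @export
gen_dose_response <- function(truth, doses, replicates = 3, noise_cv = 0.1,
                              seed = 1L) {
  stopifnot(all(c("slope", "lower", "upper", "ed50") %in% names(truth)))
  if (any(doses < 0)) abort("doses must be non-negative")
  if (noise_cv < 0) abort("noise_cv must be >= 0")
  set_gen_seed(seed)
  mu <- fourpl(doses, truth$slope, truth$lower, truth$upper, truth$ed50)
  sdlog <- cv_to_sdlog(noise_cv)
  out <- tidyr::expand_grid(replicate = seq_len(replicates), dose = doses) |>
    mutate(response = rep(mu, replicates) *
             rlnorm(dplyr::n(), meanlog = -sdlog^2 / 2, sdlog = sdlog)) |>
    dplyr::relocate("dose")
  attr(out, "truth") <- truth
  out
}

#' Generate a synthetic expression panel obeying the ratio model
#'
#' Draws scaled GWL and B55-alpha levels uniform on [0.2, 1] and ED50
#' values from the linear ratio model
#' `ed50 = gradient * GWL/B55a + intercept + N(0, noise_sd)`, truncated at
#' a 0.01 uM floor. Defaults are the reference C-604 sensitivity model
#' coefficients (gradient 0.399 uM per ratio unit, intercept 0.406 uM).
#'
#' @param n_lines Number of cell lines (>= 3).
#' @param gradient,intercept Generative model coefficients (uM).
#' @param noise_sd Gaussian noise SD on ED50 (uM).
#' @param seed Integer seed.
#' @return Tibble `line`, `gwl`, `b55a`, `ratio`, `ed50`; generative
#'   coefficients in the `"truth"` attribute.
#' @export
gen_expression_panel <- function(n_lines = 12, gradient = 0.399,
                                 intercept = 0.406, noise_sd = 0.05,
                                 seed = 1L) {
  if (n_lines < 3) abort("n_lines must be >= 3")
  set_gen_seed(seed)
  gwl <- runif(n_lines, 0.2, 1)
  b55a <- runif(n_lines, 0.2, 1)
  ratio <- gwl / b55a
  ed50 <- pmax(0.01, gradient * ratio + intercept + rnorm(n_lines, 0, noise_sd))
  out <- tibble(line = sprintf("line_%02d", seq_len(n_lines)),
                gwl = gwl, b55a = b55a, ratio = ratio, ed50 = ed50)
  attr(out, "truth") <- list(gradient = gradient, intercept = intercept,
                             noise_sd = noise_sd)
  out
}

#' Generate a synthetic phosphoproteomics dataset
#'
#' Builds a sites x samples intensity matrix for a two-group design
#' (control vs treated, `n_per_group` replicates each) with spiked
#' differential sites, a stated fraction of zero entries (to exercise
#' imputation), and +/-7-residue sequence windows whose +1 position
#' carries a proline bias in down-regulated sites — the hallmark of
#' CDK-substrate dephosphorylation after Greatwall inhibition.
#'
#' Per-site log2 intensities are Gaussian around a site-specific baseline;
#' differential sites carry a `+/- effect_log2` shift in the treated group.
#'
#' @param n_sites Number of phosphosites.
#' @param n_per_group Replicates per group (>= 2).
#' @param frac_down,frac_up Fractions of sites down-/up-regulated in the
#'   treated group (`frac_down + frac_up <= 1`).
#' @param effect_log2 Absolute log2 shift of differential sites.
#' @param pro_plus1_hit Probability of proline at +1 in down-regulated
#'   sites' windows.
#' @param pro_plus1_bg Same for all other sites.
#' @param frac_zero Fraction of matrix entries zeroed at random.
#' @param seed Integer seed.
#' @return List with `intensities` (wide tibble: `site` + one column per
#'   sample, raw non-negative intensities), `windows` (tibble `site`,
#'   `window` of 15-mers centred on the phosphoresidue), `design` (tibble
#'   `sample`, `group`) and `truth` (tibble `site`, `status`
#'   in {down, up, null}).
#' @export
gen_phospho_dataset <- function(n_sites = 2000, n_per_group = 3,
                                frac_down = 0.05, frac_up = 0.02,
                                effect_log2 = 2, pro_plus1_hit = 0.6,
                                pro_plus1_bg = 0.2, frac_zero = 0.05,
                                seed = 1L) {
  if (frac_down < 0 || frac_up < 0 || frac_down + frac_up > 1) {
    abort("frac_down + frac_up must lie in [0, 1]")
  }
  if (n_per_group < 2) abort("at least 2 replicates per group are required")
  set_gen_seed(seed)
  site <- sprintf("site_%05d", seq_len(n_sites))
  n_down <- round(frac_down * n_sites)
  n_up <- round(frac_up * n_sites)
  status <- rep("null", n_sites)
  status[seq_len(n_down)] <- "down"
  status[n_down + seq_len(n_up)] <- "up"
  status <- sample(status)   # scatter differential sites over the matrix

  samples <- c(sprintf("ctrl_%d", seq_len(n_per_group)),
               sprintf("trt_%d", seq_len(n_per_group)))
  design <- tibble(sample = samples,
                   group = rep(c("control", "treated"), each = n_per_group))

  baseline <- runif(n_sites, 14, 24)
  sigma <- runif(n_sites, 0.3, 0.8)
  shift <- c(down = -effect_log2, up = effect_log2, null = 0)[status]
  mu <- cbind(matrix(baseline, n_sites, n_per_group),
              matrix(baseline + shift, n_sites, n_per_group))
  log2_int <- mu + matrix(rnorm(n_sites * 2 * n_per_group, sd = sigma),
                          n_sites, 2 * n_per_group)
  raw <- 2^log2_int
  zero_mask <- matrix(runif(length(raw)) < frac_zero, n_sites)
  raw[zero_mask] <- 0
  colnames(raw) <- samples

  aa <- setdiff(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], character(0))
  centre <- sample(c("S", "T"), n_sites, replace = TRUE, prob = c(0.8, 0.2))
  p_pro <- ifelse(status == "down", pro_plus1_hit, pro_plus1_bg)
  windows <- vapply(seq_len(n_sites), function(i) {
    w <- sample(aa, 15, replace = TRUE)
    w[8] <- centre[i]
    w[9] <- if (runif(1) < p_pro[i]) "P" else sample(setdiff(aa, "P"), 1)
    paste(w, collapse = "")
  }, character(1))

  list(
    intensities = dplyr::bind_cols(tibble(site = site), as_tibble(raw)),
    windows = tibble(site = site, window = windows),
    design = design,
    truth = tibble(site = site, status = status,
                   effect_log2 = shift)
  )
}

#' Generate a synthetic tumour/normal expression cohort
#'
#' Draws lognormal FPKM-like values for the two model genes (B55-alpha and
#' GWL) in tumour and matched-normal arms across cancer groups, with
#' optional per-group, per-gene log-scale shifts in the tumour arm. Groups
#' with `n_normal = 0` emulate cohorts lacking matched normal tissue
#' ("nd" downstream).
#'
#' @param groups Tibble (or data frame) with columns `group`, `n_tumour`,
#'   `n_normal` (counts >= 0).
#' @param shift_log Optional tibble `group`, `gene`, `shift_log`: additive
#'   shift on the tumour arm's lognormal meanlog; missing pairs shift 0.
#' @param seed Integer seed.
#' @return Tibble `group`, `gene` in {B55A, GWL}, `tissue` in
#'   {tumour, normal}, `sample`, `fpkm`.
#' @export
gen_cohort_expression <- function(groups, shift_log = NULL, seed = 1L) {
  groups <- as_tibble(groups)
  stopifnot(all(c("group", "n_tumour", "n_normal") %in% names(groups)))
  if (any(groups$n_tumour < 0) || any(groups$n_normal < 0)) {
    abort("sample counts must be >= 0")
  }
  set_gen_seed(seed)
  base_meanlog <- c(B55A = 3, GWL = 2)
  if (is.null(shift_log)) {
    shift_log <- tibble(group = character(), gene = character(),
                        shift_log = numeric())
  }
  purrr::pmap(groups, function(group, n_tumour, n_normal, ...) {
    purrr::map(c("B55A", "GWL"), function(gene) {
      sh <- shift_log$shift_log[shift_log$group == group &
                                  shift_log$gene == gene]
      sh <- if (length(sh)) sh[1] else 0
      n <- n_tumour + n_normal
      tissue <- rep(c("tumour", "normal"), c(n_tumour, n_normal))
      meanlog <- base_meanlog[[gene]] + ifelse(tissue == "tumour", sh, 0)
      tibble(
        group = group, gene = gene, tissue = tissue,
        sample = sprintf("%s_%s_%s_%02d", group, gene,
                         substr(tissue, 1, 1), seq_len(n)),
        fpkm = rlnorm(n, meanlog = meanlog, sdlog = 0.5)
      )
    }) |> list_rbind()
  }) |> list_rbind()
}

set_gen_seed <- function(seed) {
  set.seed(as.integer(seed))
  invisible(seed)
}
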
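#' Locate the first peak of an intensity distribution
#'
#' Finds the lowest-location local maximum of a Gaussian kernel density
#' estimate whose height exceeds 10% of the global maximum. Used to anchor
#' per-channel normalisation: the first peak of an untreated population's
#' integrated DNA intensity is the 2N (one genome-equivalent) mode, and the
#' first peaks of EdU and p21 are the negative-population modes.
#'
#' @param values Non-negative, finite numeric sample; at least ~50 values
#'   are recommended for a stable estimate.
#' @param bw Kernel bandwidth rule passed to [stats::density()]
#'   (default Silverman's `"nrd0"`).
#' @param height_floor Minimum peak height as a fraction of the density
#'   maximum; bumps below it are ignored as noise.
#' @return Scalar peak location. A constant sample returns that constant.
#' @examples
#' set.seed(1)
#' x <- c(rnorm(500, 1, 0.05), rnorm(500, 2, 0.1))
#' find_first_peak(x)
#' @export
find_first_peak <- function(values, bw = "nrd0", height_floor = 0.1) {
  values <- values[is.finite(values)]
  if (length(values) == 0) abort("empty input")
  if (diff(range(values)) == 0) return(values[1])
  d <- density(values, bw = bw)
  y <- d$y
  n <- length(y)
  is_max <- c(y[1] > y[2],
              y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n],
              y[n] > y[n - 1])
  keep <- is_max & y >= height_floor * max(y)
  if (!any(keep)) keep <- is_max          # degenerate KDE; fall back
  min(d$x[keep])
}

#' Normalise a per-cell feature table against an untreated reference
#'
#' Divides the DNA, EdU and p21 intensity columns by the first-peak
#' locations of the corresponding distributions in an untreated reference
#' population of the same cell line, and the cell area by the reference
#' median area. After normalisation the reference 2N DNA peak sits at 1
#' genome-equivalent and the EdU/p21 negative modes at 1, so gates can be
#' expressed on a common scale regardless of acquisition gain. The result
#' is invariant to any global multiplicative gain applied to the raw
#' intensities (applied equally to table and reference).
#'
#' @param raw Raw feature table (columns `dna`, `edu`, `p21`, `area`, ...).
#' @param reference Untreated raw feature table of the same line; needs at
#'   least 50 cells for peak estimation.
#' @return The table with intensity columns rescaled; attribute
#'   `normalised = TRUE` and the normalisation factors in attribute
#'   `norm_factors`.
#' @export
normalize_population <- function(raw, reference) {
  needed <- c("dna", "edu", "p21", "area")
  if (!all(needed %in% names(raw)) || !all(needed %in% names(reference))) {
    abort("raw and reference must share columns dna, edu, p21, area")
  }
  if (nrow(reference) < 50) {
    abort("reference population too small for first-peak estimation (< 50 cells)")
  }
  factors <- c(
    dna = find_first_peak(reference$dna),
    edu = find_first_peak(reference$edu),
    p21 = find_first_peak(reference$p21),
    area = median(reference$area)
  )
  if (any(factors <= 0)) abort("normalisation factors must be positive")
  out <- raw |>
    mutate(dna = .data$dna / factors[["dna"]],
           edu = .data$edu / factors[["edu"]],
           p21 = .data$p21 / factors[["p21"]],
           area = .data$area / factors[["area"]])
  attr(out, "normalised") <- TRUE
  attr(out, "norm_factors") <- factors
  out
}

#' Gate configuration for cell-cycle classification
#'
#' Thresholds on normalised intensities. DNA gates default to 1.5 and 3.0
#' genome-equivalents — the midpoints between the 2N/4N and 4N/8N peaks on
#' the linear scale. EdU and p21 positivity default to 3x the normalised
#' negative-population mode (which sits at 1 after normalisation).
#' "2N" is relative ploidy: in aneuploid lines it denotes the first DNA
#' peak, not a literal diploid genome.
#'
#' @param t_2n4n,t_4n8n DNA-content gates (genome-equivalents);
#'   `1 < t_2n4n < t_4n8n`.
#' @param edu_pos,p21_pos EdU/p21 positivity thresholds (normalised units).
#' @param multi_min Minimum nuclear count for a multinucleated call.
#' @return A `gate_config` list.
#' @export
gate_config <- function(t_2n4n = 1.5, t_4n8n = 3.0,
                        edu_pos = 3.0, p21_pos = 3.0, multi_min = 2L) {
  if (!(1 < t_2n4n && t_2n4n < t_4n8n)) {
    abort("gates must satisfy 1 < t_2n4n < t_4n8n")
  }
  structure(list(t_2n4n = t_2n4n, t_4n8n = t_4n8n, edu_pos = edu_pos,
                 p21_pos = p21_pos, multi_min = as.integer(multi_min)),
            class = "gate_config")
}

#' Classify normalised cells into cell-cycle, p21 and multinucleation groups
#'
#' Labels every cell with exactly one of the relative-ploidy classes
#' {2N, S, 4N, 8N+}: S if EdU is at or above the positivity gate
#' (EdU incorporation takes precedence over DNA content, so replicating
#' cells with intermediate or high DNA are called S); otherwise 2N, 4N or
#' 8N+ by the DNA gates. Independent boolean flags mark p21-positive
#' (quiescent/senescent) and multinucleated cells.
#'
#' @param normalised A table produced by [normalize_population()] (or read
#'   back from disk with `assume_normalised = TRUE`).
#' @param gates A [gate_config()].
#' @param assume_normalised Set `TRUE` to accept a table whose
#'   normalisation flag was lost (e.g. after a CSV round-trip).
#' @return The table with columns `class` (factor 2N/S/4N/8N+),
#'   `p21_pos`, `multinucleated` added.
#' @export
classify_cells <- function(normalised, gates = gate_config(),
                           assume_normalised = FALSE) {
  if (!isTRUE(attr(normalised, "normalised")) && !assume_normalised) {
    abort(paste("input is not flagged as normalised;",
                "run normalize_population() first or set assume_normalised = TRUE"))
  }
  stopifnot(inherits(gates, "gate_config"))
  out <- normalised |>
    mutate(
      class = factor(
        dplyr::case_when(
          .data$edu >= gates$edu_pos ~ "S",
          .data$dna < gates$t_2n4n ~ "2N",
          .data$dna < gates$t_4n8n ~ "4N",
          TRUE ~ "8N+"
        ),
        levels = cc_classes
      ),
      p21_pos = .data$p21 >= gates$p21_pos,
      multinucleated = .data$nuclei >= gates$multi_min
    )
  attr(out, "normalised") <- TRUE
  attr(out, "gates") <- gates
  out
}

#' Summarise a labelled population
#'
#' Per condition x dose: cell-cycle class proportions (percent, summing to
#' 100), percentages of p21-positive and multinucleated cells, the median
#' normalised cell area and the cell count.
#'
#' @param labelled Output of [classify_cells()].
#' @param by Grouping columns (default condition and dose).
#' @return Tibble with columns `pct_2n`, `pct_s`, `pct_4n`, `pct_8n`,
#'   `pct_p21`, `pct_multi`, `median_area`, `n_cells` per group.
#' @export
summarise_population <- function(labelled, by = c("condition", "dose")) {
  if (nrow(labelled) == 0) abort("empty table")
  if (!"class" %in% names(labelled)) abort("cells are not labelled; run classify_cells()")
  labelled |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(
      pct_2n = 100 * mean(.data$class == "2N"),
      pct_s = 100 * mean(.data$class == "S"),
      pct_4n = 100 * mean(.data$class == "4N"),
      pct_8n = 100 * mean(.data$class == "8N+"),
      pct_p21 = 100 * mean(.data$p21_pos),
      pct_multi = 100 * mean(.data$multinucleated),
      median_area = median(.data$area),
      n_cells = dplyr::n(),
      .groups = "drop"
    )
}
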
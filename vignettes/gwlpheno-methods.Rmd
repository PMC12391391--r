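---
title: "Methods: models, parameters and design choices in gwlpheno"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in gwlpheno}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gwlpheno)
```

`gwlpheno` quantifies cellular responses to chemical inhibition of the
mitotic kinase Greatwall (GWL/MASTL). GWL keeps the PP2A-B55α
phosphatase repressed during mitosis via phosphorylated ENSA/ARPP19;
inhibiting GWL unleashes PP2A-B55α, destabilises the mitotic
phosphoproteome and produces a characteristic cellular phenotype:
failed divisions, tetraploidisation, polyploidy, p21 induction and
multinucleation. This vignette documents the statistical models the
package implements, the tunable parameters that matter, what the
synthetic generators do and do not emulate, and the design decisions
taken where the design was genuinely open.

## Cell-cycle phenotyping

### First-peak normalisation

Raw high-content intensities are in arbitrary units that vary with
acquisition settings. `normalize_population()` rescales each intensity
channel by the location of the *first peak* of its distribution in an
untreated reference population of the same line:

- integrated DNA intensity — the first peak is the G1 (2N) mode, so
  normalised DNA is in genome-equivalents and the reference G1 peak
  sits at 1;
- mean EdU and p21 intensities — the first peak is the negative
  population's mode, so positivity can be gated as a fold-over-mode;
- cell area — divided by the reference median.

The peak finder (`find_first_peak()`) takes the lowest-location local
maximum of a Gaussian KDE (Silverman's rule bandwidth) whose height
exceeds 10% of the density maximum; the floor ignores noise bumps in
the tail. A constant sample returns that constant. Because the KDE grid,
bandwidth and maxima are all scale-equivariant, normalisation is exactly
invariant to any global multiplicative gain applied to the raw
intensities — a property the tests verify bitwise with paired
generator runs at gain 1 and gain 2.

"2N" is *relative* ploidy throughout: in aneuploid (e.g. near-triploid)
lines the first DNA peak is still the reference state, so the classes
read as "modal content", "replicating", "doubled" and "more than
doubled".

### Gating

`classify_cells()` assigns exactly one class per cell:

1. **S** if normalised EdU ≥ the EdU gate (default 3× the negative
   mode). EdU incorporation takes precedence over DNA content, so a
   replicating cell with intermediate or even >4N DNA is called S. The
   precedence rule is a package decision — replication is directly
   observed while DNA content only implies it; it also keeps the
   S-phase DNA continuum from contaminating the 2N/4N gates.
2. otherwise **2N** / **4N** / **8N+** by the DNA gates, defaults 1.5
   and 3.0 genome-equivalents — the linear-scale midpoints between the
   1/2 and 2/4 peak positions.

p21 positivity (default gate 3× mode) and multinucleation (nuclear
count ≥ 2) are independent boolean flags. All thresholds live in
`gate_config()` because no universal values exist; the defaults are
calibrated to the generator's peak geometry and recover ≥ 95% of
generative labels at 10% peak CV.

## The Euclidean response statistic

For proportion vectors (percent) over the ordered classes
{2N, S, 4N, 8N+}, `euclidean_response()` returns
d = ‖p_ctrl − p_dose‖₂ ∈ [0, 100√2]. Proportions are kept in percent
(0–100) as the canonical scale. `response_profile()` evaluates d at
every tested dose against the reference dose and `profile_auc()`
integrates it with the trapezoid rule **on the actually tested dose
grid** — no interpolation onto a finer grid, because the discrete doses
are the experiment. d is a metric (property-tested), and the AUC is
monotone under pointwise increases of d.

`compare_groups()` carries the generic two-sample convention used
throughout: Shapiro-Wilk on both samples at α = 0.05; unpaired
two-tailed Welch t-test if both pass, otherwise the unpaired two-tailed
Wilcoxon rank-sum; Cohen's d with pooled (n−1) SD; optional BH
adjustment within a caller-supplied family of p-values. The rank-sum
(not signed-rank) variant is used because the designs compared here are
unpaired; a signed-rank test would require paired observations.

## Phenotypic similarity and off-target scoring

The off-target question — "does perturbation X produce the same
phenotype as the inhibitor?" — is answered distributionally:

1. `subsample_cells()` draws a fixed number of cells (default 500) per
   condition, so conditions contribute equal weight.
2. `embed_conditions()` pools all conditions, log1p-transforms the
   right-skewed intensity channels, z-scores the five features over the
   pooled cells and fits **one joint UMAP** (defaults: 15 neighbours,
   min-dist 0.1, fixed seed, single-threaded for bit-reproducibility).
   A joint embedding is required: per-condition embeddings have
   incomparable coordinates, and cross-condition transport distances
   would be meaningless.
3. `wasserstein_2d()` computes the exact 1-Wasserstein distance with
   Euclidean ground cost. For equal-size uniform empirical measures the
   optimal transport plan is a permutation, so W1 is solved exactly as
   a linear assignment problem (Hungarian algorithm); unequal clouds
   are equalised by subsampling the larger. At n = 500 the assignment
   solve takes well under a second.
4. `similarity_profile()` scores every condition against the reference
   and reports, as a noise floor, the distance between two disjoint
   halves of the reference cloud itself. Because the floor uses
   half-size clouds, it sits slightly above the distance between two
   independent full-size draws of the same distribution; it is a
   conservative "indistinguishable" bar.

UMAP hyperparameters are config-exposed since no published values
exist for this assay. Whether transport should be computed on the 2D
embedding or per-axis was open; the 2D exact solution was chosen as it
respects the embedding's geometry.

## Dose-response fitting

`fourpl()` is the LL.4 log-logistic
f(x) = c + (d − c)/(1 + exp(b(log x − log e))), with dose 0 mapped to
the asymptote limit (upper for b > 0) rather than handled by a log
offset — the zero dose is a genuine control, not a small dose.
`fit_4pl()` minimises least squares with Levenberg-Marquardt from a
coarse grid of starting values: slopes {±0.5, ±1, ±2, ±4} crossed with
15 log-spaced midpoints, with the two asymptotes profiled out by linear
regression at each grid point (the model is linear in (c, d) once b and
e are fixed). The midpoint is optimised on the log scale within
[min positive dose/10, max dose × 10]; asymptotes are unconstrained by
default (whether the original fits constrained them is unknown, so the
package does not).

Three estimator-hygiene rules:

- the LL.4 sign symmetry f(x; b, c, d, e) = f(x; −b, d, c, e) is
  canonicalised so `upper ≥ lower`;
- a midpoint pinned to its optimisation bound is not an interior
  optimum — the ED50 is unidentified for those data — and the fit is
  flagged non-converged (never silently);
- `ed50_with_replicates()` fits **per replicate** and reports the
  arithmetic mean ± SD of replicate midpoints (matching the
  independent-replicate-fits convention), excluding non-converged fits
  and fits whose midpoint falls outside the tested dose window. The
  latter is the standard assay-window convention: an ED50 beyond the
  largest tested dose is an extrapolation, reported as "> max dose",
  not a number to average. On noisy synthetic curves this exclusion
  removes a heavy right tail (roughly 1% of replicate fits) that would
  otherwise bias the replicate mean upward by ~20%.

`normalize_to_max()` and `proliferation_auc()` implement the
normalised-count AUC used for proliferation readouts; lower AUC means
a more sensitive line.

## The GWL/B55α expression-ratio biomarker

The sensitivity model is a single-predictor OLS regression (unweighted)
of ED50 on the scalar ratio GWL/B55α of scaled expression values:

\*ED50 = gradient × GWL/B55α + intercept,

with reference coefficients 0.399 µM per ratio unit and 0.406 µM. The
ratio form is used — not a two-covariate regression — because the ratio
is the mechanistically meaningful quantity (kinase over phosphatase
capacity); a two-covariate variant is available behind
`form = "two_covariate"` for exploration. Protein panels are scaled by
`scale_expression()` (loading control, then per-analyte max = 1); RNA
panels (TPM/FPKM) enter the ratio untransformed. Panel-level values are
means over replicates (the mean-per-line convention). Predictions below
zero are not truncated by `predict_ed50()`; the generator's ED50 floor
(0.01 µM) applies only to synthesis.

`rank_and_flag()` flags the ⌈fraction × n⌉ lowest predictions (default
5%), with ties broken by stable input order and noted.
`cohort_median_shift()` computes per-group tumour-minus-normal median
differences with unpaired two-tailed Wilcoxon tests (exact distribution
when both arms < 25, normal approximation otherwise) and BH adjustment
across all determined comparisons; groups without normal samples are
"nd", never zero-filled.

## Phosphoproteomics statistics

`normalize_phospho()` fixes the order of the preprocessing chain as
sum-normalise → log2 → impute → median-centre, per sample. The order is
forced by the imputation rule itself: a zero intensity is replaced by
*that sample's minimum observed log2 value minus 1*, which only exists
after the log transform; and centring must come last or the "minimum
minus one" anchor would shift. Centring is per-sample (median), chosen
over per-feature centring because it preserves per-site fold changes
while removing residual sample-level offsets. The processed matrix is
exactly invariant to per-sample rescaling of the raw intensities.

`moderated_test()` implements the empirical-Bayes moderated t: per-site
pooled two-group variances s² with df = n₁+n₂−2 are shrunk toward a
prior (d₀, s₀²) estimated by the method of moments on log s² (the
scaled-F hierarchical model, including a Newton trigamma-inverse
solver); the posterior variance (d₀s₀² + df·s²)/(d₀+df) feeds a t
statistic on df + d₀ degrees of freedom, and BH gives the FDR. Sites
with exactly zero residual variance receive the prior variance. The
`prior_df` argument can force the two limits — 0 recovers the ordinary
pooled t-test exactly, ∞ pools the variance completely with a normal
reference — and the default estimate agrees with the independent
`limma::eBayes` cross-check to 8 decimal places in the tests. Type-I
error on a 2,000-site null with 3v3 replicates lands within Monte-Carlo
error of the nominal 5%.

`classify_hits()` applies the joint gate p < 0.05 **and** FDR < 0.1,
split by fold-change sign into negative/positive hits.
`motif_frequencies()` computes position × residue frequencies over the
±7-residue windows ('X' padding excluded from denominators) and a
two-sided Fisher exact test of proline at +1 in hits versus the
not-significant background — the +1 proline bias is the minimal CDK
consensus, so its enrichment among dephosphorylated sites is the
expected signature of PP2A-B55α de-repression. `intersect_hits()`
returns the full Venn partition and the shared fraction
|common|/|union| across cell lines.

## Synthetic data: what it emulates, and what it does not

The generators produce every input the pipeline consumes, each with
stored ground truth sufficient to compute expected values of the
downstream statistics:

- `gen_cell_population()` — multimodal DNA content with class medians
  at gain × {1, 2, 4} and uniform S-phase content between the 2N and 4N
  medians; bimodal EdU and p21 (high components at 6× the negative
  mode); ploidy-scaled lognormal areas; nuclear counts 2–4 for
  multinucleated cells. The dose acts through a saturating Hill curve
  moving {2N, S} mass into {4N, 8N+} with a 2/3 : 1/3 split —
  tetraploidisation is the first consequence of mitotic failure,
  re-replication to 8N+ the rarer second round. Because the shift is an
  analytic function of dose, the expected Euclidean-d profile has a
  closed form the quadrature tests use. The intensity gain is a free
  positive scalar precisely so the normalisation stage has real work.
- `gen_dose_response()` — 4PL values times *mean-one* multiplicative
  lognormal noise, so replicate means converge to the generative curve
  (verified by a 1,000-replicate law-of-large-numbers test).
- `gen_expression_panel()` — scaled GWL and B55α uniform on [0.2, 1]
  (the range where densitometry is reliably quantitative), ED50 from
  the linear ratio model plus Gaussian noise, floored at 0.01 µM.
- `gen_phospho_dataset()` — Gaussian log2 intensities per site
  (baselines U(14, 24), within-site SD U(0.3, 0.8)), ± effect shifts in
  a chosen fraction of sites, a stated fraction of zeroed entries to
  exercise imputation, and windows whose +1 proline probability is
  elevated in down-regulated sites.
- `gen_cohort_expression()` — lognormal FPKM-like values per gene with
  per-group tumour shifts; groups may lack normal arms ("nd").

Baseline class fractions (55/20/20/5) are free parameters chosen as a
plausible mix for an unperturbed transformed line; no published
per-line baseline exists to calibrate against. What the generators do
**not** emulate: segmentation artefacts, spatial or batch effects,
intensity saturation, heavy-tailed outlier cells, peptide-level
missingness structure (zeros are missing-completely-at-random here),
and correlations between phosphosites on the same protein. Passing
tests therefore demonstrate correctness of the statistical machinery
under the stated generative assumptions, not robustness to every
artefact of real screens.

All generators take explicit integer seeds — never global state — and
identical seeds reproduce outputs bitwise; `run_pipeline()` extends
that contract to byte-identical output files for an identical
configuration and seed (its manifest hash deliberately excludes the
output directory).

## Problem sizes and runtime choices

The test-suite and acceptance simulations use desk-scale sizes chosen
so the full suite runs in about a minute: populations of 3,000–10,000
cells, 120–200 cells per condition in embeddings, 50-seed × 3-replicate
dose-response recoveries, 200-seed panel recoveries, and 2,000-site
null matrices. These sizes keep Monte-Carlo error comfortably inside
the asserted tolerances (binomial/3-SD bounds are computed in the tests
rather than hard-coded).

## Known limitations

- The Shapiro-Wilk gate in `compare_groups()` is itself a test; at
  n = 3 replicates its power is low and the t-branch is chosen almost
  always, which mirrors common practice but should be read accordingly.
- Exact W1 scales as O(n³) in the assignment solve; beyond a few
  thousand points per cloud a sliced or entropic approximation would be
  needed (not currently implemented — at the pipeline's n = 500 the
  exact solve is fast).
- The moderated test assumes exchangeable site variances after the
  scaled-F prior; gross variance structure (e.g. intensity-dependent
  variance) is not modelled.
- `fit_4pl()` reports, but does not resolve, non-identifiability: flat
  responses or unbracketed midpoints yield flagged fits that
  `ed50_with_replicates()` excludes rather than repairs.
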
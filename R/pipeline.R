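#' Read and write per-cell feature tables
#'
#' CSV round-trip for the documented feature-table schema (`condition`,
#' `dose`, `dna`, `edu`, `p21`, `area`, `nuclei`, optional `true_*`
#' ground-truth columns). Because CSV cannot carry R attributes, the
#' normalisation state is declared explicitly on read.
#'
#' @param path File path.
#' @param normalised Whether the stored table holds normalised
#'   genome-equivalent / fold-over-mode values.
#' @return `read_cell_features()`: a tibble flagged accordingly.
#' @export
read_cell_features <- function(path, normalised = FALSE) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  attr(out, "normalised") <- isTRUE(normalised)
  out
}

#' @rdname read_cell_features
#' @param x Feature table to write.
#' @export
write_cell_features <- function(x, path) {
  readr::write_csv(x, path)
  invisible(path)
}

#' Build a validated pipeline run configuration
#'
#' Collects everything a full synthetic run needs: generator settings,
#' gates, embedding and transport parameters, model coefficients and
#' statistical thresholds, a global seed and the output directory.
#' Configurations are plain lists and can be loaded from YAML with
#' [read_run_config()].
#'
#' @param outdir Output directory (created if missing).
#' @param seed Global integer seed; every stage derives its seed from it.
#' @param doses Dose grid (uM) for the synthetic populations; must
#'   include the reference dose.
#' @param reference_dose Dose of the control population.
#' @param n_cells Cells per synthetic population.
#' @param gates A [gate_config()] or list of its arguments.
#' @param effect_curve Dose-to-class-shift transfer curve, see
#'   [population_spec()].
#' @param subsample_n Cells per condition entering the embedding.
#' @param n_neighbors,min_dist Embedding hyperparameters.
#' @param dose_truth Generative 4PL parameters for the dose-response stage.
#' @param n_lines,panel_noise_sd Expression-panel settings.
#' @param model Ratio-model coefficients used for prediction
#'   (list with `gradient`, `intercept`, uM).
#' @param flag_fraction Fraction of samples flagged most sensitive.
#' @param phospho List of [gen_phospho_dataset()] arguments.
#' @param p_max,fdr_max Hit-classification gates.
#' @return A `run_config` list, validated.
#' @export
run_config <- function(outdir,
                       seed = 1L,
                       doses = c(0, 0.25, 0.5, 1, 2),
                       reference_dose = 0,
                       n_cells = 3000,
                       gates = gate_config(),
                       effect_curve = list(ed50 = 0.5, hill = 2, max_shift = 0.8),
                       subsample_n = 200,
                       n_neighbors = 15, min_dist = 0.1,
                       dose_truth = list(slope = 2, lower = 0, upper = 1, ed50 = 0.5),
                       n_lines = 12, panel_noise_sd = 0.05,
                       model = list(gradient = 0.399, intercept = 0.406),
                       flag_fraction = 0.05,
                       phospho = list(n_sites = 1000, n_per_group = 3,
                                      frac_down = 0.05, frac_up = 0.02,
                                      effect_log2 = 2),
                       p_max = 0.05, fdr_max = 0.1) {
  if (is.list(gates) && !inherits(gates, "gate_config")) {
    gates <- do.call(gate_config, gates)
  }
  cfg <- list(outdir = outdir, seed = as.integer(seed), doses = doses,
              reference_dose = reference_dose, n_cells = n_cells,
              gates = gates, effect_curve = effect_curve,
              subsample_n = subsample_n, n_neighbors = n_neighbors,
              min_dist = min_dist, dose_truth = dose_truth,
              n_lines = n_lines, panel_noise_sd = panel_noise_sd,
              model = model, flag_fraction = flag_fraction,
              phospho = phospho, p_max = p_max, fdr_max = fdr_max)
  validate_run_config(cfg)
  structure(cfg, class = "run_config")
}

validate_run_config <- function(cfg) {
  required <- c("outdir", "seed", "doses", "reference_dose", "n_cells",
                "gates", "model")
  missing <- setdiff(required, names(cfg))
  if (length(missing)) {
    abort(sprintf("config is missing field(s): %s", paste(missing, collapse = ", ")))
  }
  if (!cfg$reference_dose %in% cfg$doses) {
    abort("config field 'reference_dose' must be one of 'doses'")
  }
  if (!all(c("gradient", "intercept") %in% names(cfg$model))) {
    abort("config field 'model' needs 'gradient' and 'intercept'")
  }
  invisible(cfg)
}

#' @rdname run_config
#' @param path YAML file with `run_config()` arguments.
#' @export
read_run_config <- function(path) {
  args <- yaml::read_yaml(path)
  do.call(run_config, args)
}

pipeline_stages <- c("simulate", "gate", "respond", "similarity",
                     "fitdose", "biomarker", "phospho")

stage_deps <- list(
  simulate = character(), gate = "simulate", respond = "gate",
  similarity = "gate", fitdose = "simulate", biomarker = "simulate",
  phospho = "simulate"
)

#' Run the full synthetic pipeline
#'
#' Executes the requested stages in dependency order on synthetic inputs:
#' `simulate` (all generators), `gate` (normalise against the
#' reference-dose population, classify, summarise), `respond` (Euclidean
#' profile and AUC), `similarity` (subsample, joint embedding,
#' Wasserstein profile), `fitdose` (replicate-wise 4PL and ED50),
#' `biomarker` (ratio-model fit, predictions, flags) and `phospho`
#' (normalisation, moderated test, hit classes, motif summary). Each
#' stage writes tidy CSV outputs into `outdir` and a JSON run manifest
#' records the seed, configuration hash and package version, so identical
#' config + seed reruns are byte-identical. A failed stage halts only its
#' dependents.
#'
#' @param config A [run_config()] (or path to a YAML config).
#' @param stages Subset of stages to run (dependencies are added
#'   automatically).
#' @return Invisibly, a named list with each stage's in-memory results
#'   plus `manifest`.
#' @export
run_pipeline <- function(config, stages = pipeline_stages) {
  if (is.character(config)) config <- read_run_config(config)
  validate_run_config(config)
  stages <- match.arg(stages, pipeline_stages, several.ok = TRUE)
  # close over dependencies
  need <- stages
  repeat {
    more <- unique(unlist(stage_deps[need]))
    if (all(more %in% need)) break
    need <- union(need, more)
  }
  stages <- intersect(pipeline_stages, need)

  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  res <- list()
  failed <- character()
  for (st in stages) {
    if (any(stage_deps[[st]] %in% failed)) {
      warn(sprintf("skipping stage '%s': dependency failed", st))
      failed <- c(failed, st)
      next
    }
    res[[st]] <- tryCatch(
      run_stage(st, config, res),
      error = function(e) {
        warn(sprintf("stage '%s' failed: %s", st, conditionMessage(e)))
        failed <<- c(failed, st)
        NULL
      }
    )
  }

  manifest <- list(
    seed = config$seed,
    config_hash = rlang::hash(unclass(config)[setdiff(names(config), "outdir")]),
    package_version = as.character(utils::packageVersion("gwlpheno")),
    stages_run = setdiff(stages, failed),
    stages_failed = failed
  )
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  res$manifest <- manifest
  invisible(res)
}

run_stage <- function(stage, cfg, res) {
  out <- cfg$outdir
  seed <- cfg$seed
  switch(stage,
    simulate = {
      pops <- purrr::map(seq_along(cfg$doses), function(i) {
        gen_cell_population(population_spec(
          n_cells = cfg$n_cells, dose = cfg$doses[i],
          effect_curve = cfg$effect_curve,
          p21_fraction = function(d) min(0.05 + 0.1 * d, 1),
          multinucleation_fraction = function(d) min(0.03 + 0.08 * d, 1),
          seed = seed + i
        ))
      })
      cells <- list_rbind(pops)
      write_cell_features(cells, file.path(out, "cells_raw.csv"))
      dr <- gen_dose_response(cfg$dose_truth,
                              doses = c(0, 0.0625, 0.125, 0.25, 0.5, 1, 2),
                              replicates = 3, noise_cv = 0.1, seed = seed + 101)
      readr::write_csv(dr, file.path(out, "dose_response.csv"))
      panel <- gen_expression_panel(n_lines = cfg$n_lines,
                                    gradient = cfg$model$gradient,
                                    intercept = cfg$model$intercept,
                                    noise_sd = cfg$panel_noise_sd,
                                    seed = seed + 202)
      readr::write_csv(panel, file.path(out, "expression_panel.csv"))
      ph <- do.call(gen_phospho_dataset, c(cfg$phospho, list(seed = seed + 303)))
      readr::write_csv(ph$intensities, file.path(out, "phospho_intensities.csv"))
      readr::write_csv(ph$design, file.path(out, "phospho_design.csv"))
      readr::write_csv(ph$windows, file.path(out, "phospho_windows.csv"))
      readr::write_csv(ph$truth, file.path(out, "phospho_truth.csv"))
      list(cells = cells, pops = pops, dose_response = dr,
           panel = panel, phospho = ph)
    },
    gate = {
      cells <- res$simulate$cells
      reference <- dplyr::filter(cells, .data$dose == cfg$reference_dose)
      norm <- normalize_population(cells, reference)
      labelled <- classify_cells(norm, cfg$gates)
      summary <- summarise_population(labelled)
      readr::write_csv(summary, file.path(out, "population_summary.csv"))
      list(labelled = labelled, summary = summary)
    },
    respond = {
      prof <- response_profile(res$gate$summary,
                               reference_dose = cfg$reference_dose)
      readr::write_csv(
        mutate(as_tibble(prof), auc = attr(prof, "auc")),
        file.path(out, "response_profile.csv"))
      prof
    },
    similarity = {
      labelled <- res$gate$labelled
      sub <- labelled |>
        dplyr::group_split(.data$condition) |>
        purrr::imap(\(t, i) subsample_cells(t, n = cfg$subsample_n,
                                            seed = seed + 400 + i)) |>
        list_rbind()
      emb <- embed_conditions(sub, seed = seed + 410,
                              n_neighbors = cfg$n_neighbors,
                              min_dist = cfg$min_dist)
      ref_cond <- unique(labelled$condition[labelled$dose ==
                                              max(labelled$dose)])[1]
      sim <- similarity_profile(emb, reference = ref_cond, seed = seed + 420)
      readr::write_csv(as_tibble(emb), file.path(out, "embedding.csv"))
      readr::write_csv(sim, file.path(out, "similarity.csv"))
      list(embedding = emb, similarity = sim)
    },
    fitdose = {
      agg <- ed50_with_replicates(res$simulate$dose_response)
      readr::write_csv(dplyr::select(agg, -"fits"),
                       file.path(out, "ed50_fits.csv"))
      agg
    },
    biomarker = {
      panel <- res$simulate$panel
      fit <- fit_ratio_model(panel)
      preds <- predict_ed50(panel, cfg$model) |>
        rank_and_flag(fraction = cfg$flag_fraction)
      readr::write_csv(glance(fit), file.path(out, "ratio_model.csv"))
      readr::write_csv(preds, file.path(out, "predictions.csv"))
      list(fit = fit, predictions = preds)
    },
    phospho = {
      ph <- res$simulate$phospho
      proc <- normalize_phospho(ph$intensities)
      stats <- moderated_test(proc, ph$design,
                              contrast = c("control", "treated"))
      hits <- classify_hits(stats, p_max = cfg$p_max, fdr_max = cfg$fdr_max)
      motifs <- motif_frequencies(ph$windows$window,
                                  hits$class[match(ph$windows$site, hits$site)])
      readr::write_csv(hits, file.path(out, "phospho_stats.csv"))
      readr::write_csv(motifs$plus1_proline,
                       file.path(out, "motif_plus1_proline.csv"))
      list(stats = hits, motifs = motifs)
    }
  )
}
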
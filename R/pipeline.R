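#' Pipeline run configuration
#'
#' Collects the tunable parameters of the whole pipeline with their
#' defaults: abundance cutoff 0.001% (strict), prevalence floor 0.5,
#' coupling factor 400 with zero slack, community biomass bounds 0.4-1
#' mmol/day, producer threshold 0.01 mmol/day, responder threshold 1
#' mmol/day, genus-level reporting.
#'
#' @param cutoff abundance fraction cutoff.
#' @param prevalence shared-model prevalence floor.
#' @param coupling_c,coupling_u coupling factor and slack.
#' @param biomass_bounds community biomass bounds (mmol/day).
#' @param producer_threshold,responder_threshold calling thresholds
#'   (mmol/day).
#' @param rank taxonomic rank for contribution reports.
#' @param convention net-flux convention (see [net_exchange_fluxes()]).
#' @param targets metabolites for contribution analysis.
#' @param seed integer seed recorded in manifests.
#' @return a named list of class `run_config`.
#' @export
run_config <- function(cutoff = 1e-5, prevalence = 0.5,
                       coupling_c = 400, coupling_u = 0,
                       biomass_bounds = c(0.4, 1),
                       producer_threshold = 0.01,
                       responder_threshold = 1,
                       rank = "genus", convention = "signed",
                       targets = c("ac", "ppa", "but", "isobut"),
                       seed = 1L) {
  stopifnot(cutoff >= 0, prevalence >= 0, prevalence <= 1,
            coupling_c > 0, coupling_u >= 0,
            biomass_bounds[1] >= 0, biomass_bounds[1] <= biomass_bounds[2],
            producer_threshold >= 0, responder_threshold >= 0)
  structure(list(cutoff = cutoff, prevalence = prevalence,
                 coupling_c = coupling_c, coupling_u = coupling_u,
                 biomass_bounds = biomass_bounds,
                 producer_threshold = producer_threshold,
                 responder_threshold = responder_threshold,
                 rank = rank, convention = convention, targets = targets,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Write synthetic pipeline inputs to a directory
#'
#' Generates the full set of synthetic inputs -- taxon models (JSON),
#' cohort coverage table, taxonomy table, intake and composition tables,
#' molecular weights and reference ranges -- plus a manifest recording
#' seeds and the generation ground truth.
#'
#' @param out_dir output directory (created if needed).
#' @param n_samples cohort size.
#' @param seed integer seed.
#' @return `out_dir`, invisibly.
#' @export
run_synth <- function(out_dir, n_samples = 10, seed = 1L) {
  dir.create(file.path(out_dir, "models"), recursive = TRUE,
             showWarnings = FALSE)
  tt <- taxon_templates()
  for (i in seq_len(nrow(tt)))
    save_model(make_taxon_model(tt[i, ], seed = seed),
               file.path(out_dir, "models", paste0(tt$model_id[i], ".json")))
  cohort <- make_cohort(n_samples = n_samples, templates = tt, seed = seed)
  readr::write_tsv(cohort$coverage, file.path(out_dir, "coverage.tsv"))
  readr::write_tsv(cohort$taxonomy, file.path(out_dir, "taxonomy.tsv"))
  db <- make_food_db(seed = seed)
  readr::write_tsv(db$intake, file.path(out_dir, "intake.tsv"))
  readr::write_tsv(db$composition$nutrients,
                   file.path(out_dir, "composition_nutrients.tsv"))
  readr::write_tsv(db$composition$macros,
                   file.path(out_dir, "composition_macros.tsv"))
  readr::write_tsv(tibble::enframe(db$molecular_weights,
                                   name = "metabolite", value = "g_per_mol"),
                   file.path(out_dir, "molecular_weights.tsv"))
  readr::write_tsv(db$dri, file.path(out_dir, "dri.tsv"))
  readr::write_tsv(cohort$ground_truth$abundances,
                   file.path(out_dir, "ground_truth_abundances.tsv"))
  yaml::write_yaml(list(seed = as.integer(seed), n_samples = n_samples,
                        templates = tt$template),
                   file.path(out_dir, "manifest.yaml"))
  invisible(out_dir)
}

#' Build diet files from intake and composition tables
#'
#' Reads the intake and composition tables, writes the diet flux TSV, the
#' macronutrient profile, and the reference-intake report. Optional
#' supplements (named g/day vector) produce a supplemented diet instead.
#'
#' @param intake_path intake TSV (`food`, `g_per_day`, ...).
#' @param nutrients_path,macros_path composition TSVs.
#' @param mw_path molecular-weight TSV (`metabolite`, `g_per_mol`).
#' @param out_dir output directory.
#' @param supplement optional named numeric vector, g/day.
#' @param name diet name.
#' @return list with `diet`, `profile`, `dri_report` (also written to
#'   `out_dir`).
#' @export
run_build_diet <- function(intake_path, nutrients_path, macros_path, mw_path,
                           out_dir, supplement = NULL, name = "diet") {
  for (p in c(intake_path, nutrients_path, macros_path, mw_path))
    if (!file.exists(p)) stop("missing input file: ", p, call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  intake <- readr::read_tsv(intake_path, show_col_types = FALSE)
  comp <- food_composition(
    readr::read_tsv(nutrients_path, show_col_types = FALSE),
    readr::read_tsv(macros_path, show_col_types = FALSE))
  mw_tbl <- readr::read_tsv(mw_path, show_col_types = FALSE)
  mw <- stats::setNames(mw_tbl$g_per_mol, mw_tbl$metabolite)
  diet <- suppressWarnings(
    build_diet_fluxes(intake, comp, mw, name = name))
  if (!is.null(supplement))
    diet <- add_supplement(diet, supplement, comp, mw, name = name)
  profile <- macronutrient_profile(intake, comp)
  report <- validate_dri(profile)
  write_diet(diet, file.path(out_dir, paste0(name, ".tsv")))
  readr::write_tsv(profile, file.path(out_dir, "macro_profile.tsv"))
  readr::write_tsv(report, file.path(out_dir, "dri_report.tsv"))
  list(diet = diet, profile = profile, dri_report = report)
}

#' Simulate every sample of a cohort
#'
#' Normalizes the coverage table, builds and simulates one community model
#' per sample under the given diet, and writes per-sample FVA and net-flux
#' tables plus a manifest. Per-sample failures (e.g. infeasibility) are
#' recorded and do not stop the run.
#'
#' @param models_dir directory of taxon model JSON files named
#'   `<model_id>.json`.
#' @param coverage_path coverage TSV.
#' @param diet_path diet TSV.
#' @param out_dir output directory (one subdirectory per sample).
#' @param config a [run_config()].
#' @return tibble summary: `sample`, `status`.
#' @export
run_simulate <- function(models_dir, coverage_path, diet_path, out_dir,
                         config = run_config()) {
  cov <- readr::read_tsv(coverage_path, show_col_types = FALSE)
  diet <- read_diet(diet_path)
  prof <- normalize_coverage(cov, cutoff = config$cutoff)
  models <- load_model_dir(models_dir)
  coupling <- coupling_config(config$coupling_c, config$coupling_u)
  summary <- purrr::map_dfr(unique(prof$sample), function(s) {
    sub <- prof[prof$sample == s, ]
    ab <- stats::setNames(sub$abundance, sub$model_id)
    res <- tryCatch({
      sim <- simulate_sample(models[names(ab)], ab, diet,
                             coupling = coupling,
                             biomass_bounds = config$biomass_bounds,
                             convention = config$convention)
      sdir <- file.path(out_dir, s)
      dir.create(sdir, recursive = TRUE, showWarnings = FALSE)
      write_flux_table(sim$fva, file.path(sdir, "fva.tsv"))
      write_flux_table(sim$net_fluxes, file.path(sdir, "net_fluxes.tsv"))
      yaml::write_yaml(sim$manifest, file.path(sdir, "manifest.yaml"))
      "ok"
    }, error = function(e) paste0("failed: ", conditionMessage(e)))
    tibble::tibble(sample = s, status = res)
  })
  readr::write_tsv(summary, file.path(out_dir, "summary.tsv"))
  summary
}

#' Contribution analysis over a cohort
#'
#' Rebuilds each sample's diet-constrained community model, computes
#' per-taxon contribution ranges for the target metabolites, aggregates at
#' the configured rank, and writes the producer ranking and (when a
#' substrate is given) the responder report.
#'
#' @inheritParams run_simulate
#' @param taxonomy_path taxonomy TSV.
#' @param substrate optional supplement metabolite for responder calling.
#' @return list: `contributions`, `producers`, `responders` (or `NULL`).
#' @export
run_contributions <- function(models_dir, coverage_path, diet_path,
                              taxonomy_path, out_dir,
                              config = run_config(), substrate = NULL) {
  cov <- readr::read_tsv(coverage_path, show_col_types = FALSE)
  diet <- read_diet(diet_path)
  taxonomy <- readr::read_tsv(taxonomy_path, show_col_types = FALSE)
  prof <- normalize_coverage(cov, cutoff = config$cutoff)
  models <- load_model_dir(models_dir)
  coupling <- coupling_config(config$coupling_c, config$coupling_u)
  targets <- unique(c(config$targets, substrate))
  contrib <- cohort_contributions(models, prof, diet, targets,
                                  coupling = coupling,
                                  biomass_bounds = config$biomass_bounds)
  ranked <- aggregate_by_rank(contrib, taxonomy, rank = config$rank)
  producers <- identify_producers(
    dplyr::filter(ranked, metabolite %in% config$targets),
    threshold = config$producer_threshold)
  responders <- if (!is.null(substrate))
    identify_responders(ranked, substrate,
                        threshold = config$responder_threshold) else NULL
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(tibble::as_tibble(ranked),
                   file.path(out_dir, "contributions.tsv"))
  readr::write_tsv(producers, file.path(out_dir, "producers.tsv"))
  if (!is.null(responders))
    readr::write_tsv(responders, file.path(out_dir, "responders.tsv"))
  list(contributions = ranked, producers = producers,
       responders = responders)
}

#' Contribution tables for every sample of a cohort
#'
#' @param models named list of `taxon_model`s.
#' @param profile an `abundance_profile`.
#' @param diet a `diet_spec`.
#' @param targets lumen metabolite base ids.
#' @param coupling a [coupling_config()].
#' @param biomass_bounds community biomass bounds.
#' @return a `contribution_table` spanning all samples.
#' @export
cohort_contributions <- function(models, profile, diet, targets,
                                 coupling = coupling_config(),
                                 biomass_bounds = c(0.4, 1)) {
  rows <- purrr::map_dfr(unique(profile$sample), function(s) {
    sub <- profile[profile$sample == s, ]
    ab <- stats::setNames(sub$abundance, sub$model_id)
    cm <- build_community(models[names(ab)], ab, coupling = coupling,
                          biomass_bounds = biomass_bounds)
    cm <- apply_diet(cm, diet)
    compute_contributions(cm, targets, sample = s)
  })
  new_contribution_table(rows)
}

load_model_dir <- function(models_dir) {
  paths <- list.files(models_dir, pattern = "\\.json$", full.names = TRUE)
  if (length(paths) == 0L)
    stop("no model JSON files in ", models_dir, call. = FALSE)
  models <- purrr::map(paths, load_model)
  stats::setNames(models, purrr::map_chr(models, "model_id"))
}
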
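#' Per-taxon flux contributions to target metabolites
#'
#' Runs flux variability analysis over each member taxon's lumen-transfer
#' reaction for every target metabolite, under the full community
#' constraints (diet, coupling, community biomass bounds). Each member's
#' transfer is optimized independently; joint optimality across members is
#' not enforced. Positive fluxes are secretion into the lumen, negative
#' uptake from it. Members without a transfer for a target contribute the
#' degenerate range (0, 0).
#'
#' @param model a diet-constrained `community_model`.
#' @param targets character vector of lumen metabolite base ids (e.g.
#'   `"ac"`, `"mos"`).
#' @param sample sample label attached to the rows (default `"sample1"`).
#' @return a `contribution_table` tibble: `sample`, `model_id`, `taxon`
#'   (genus), `metabolite`, `minimum`, `maximum` (mmol/day).
#' @export
compute_contributions <- function(model, targets, sample = "sample1") {
  lumen <- sub("__u$", "", model$metabolites$id[
    model$metabolites$compartment == "u"])
  absent <- setdiff(targets, lumen)
  if (length(absent)) {
    warning("target(s) absent from the lumen, skipped: ",
            paste(absent, collapse = ", "), call. = FALSE)
    targets <- intersect(targets, lumen)
  }
  if (length(targets) == 0L)
    return(new_contribution_table(tibble::tibble(
      sample = character(), model_id = character(), taxon = character(),
      metabolite = character(), minimum = numeric(), maximum = numeric())))

  st <- model_lp_state(model)
  rxn_ids <- model$reactions$id
  grid <- tidyr::expand_grid(tag = model$members$tag, metabolite = targets)
  rows <- purrr::pmap_dfr(grid, function(tag, metabolite) {
    rid <- paste0(tag, "__IEX_", metabolite)
    mem <- model$members[model$members$tag == tag, ]
    if (!rid %in% rxn_ids) {
      return(tibble::tibble(sample = sample, model_id = mem$model_id,
                            taxon = mem$genus, metabolite = metabolite,
                            minimum = 0, maximum = 0))
    }
    obj <- as.numeric(rxn_ids == rid)
    lo <- lp_optimize(st, obj, maximize = FALSE)
    hi <- lp_optimize(st, obj, maximize = TRUE)
    if (lo$status == "infeasible" || hi$status == "infeasible")
      stop("community model infeasible during contribution analysis",
           call. = FALSE)
    cl <- function(v) if (abs(v) < 1e-9) 0 else v
    tibble::tibble(sample = sample, model_id = mem$model_id,
                   taxon = mem$genus, metabolite = metabolite,
                   minimum = cl(lo$objective), maximum = cl(hi$objective))
  })
  new_contribution_table(rows)
}

new_contribution_table <- function(x) {
  structure(x, class = c("contribution_table", class(x)))
}

#' Aggregate contributions at a taxonomic rank
#'
#' Sums contribution ranges (interval addition: minima with minima, maxima
#' with maxima) within the requested rank, per sample and metabolite.
#'
#' @param contributions a `contribution_table` with a `model_id` column.
#' @param taxonomy tibble with `model_id` and rank columns.
#' @param rank `"genus"`, `"species"`, `"family"` or `"phylum"`.
#' @return a rank-level `contribution_table` (`taxon` holds the rank
#'   labels).
#' @export
aggregate_by_rank <- function(contributions, taxonomy,
                              rank = c("genus", "species", "family",
                                       "phylum")) {
  rank <- match.arg(rank)
  unresolved <- setdiff(unique(contributions$model_id), taxonomy$model_id)
  if (length(unresolved))
    stop("model id(s) missing from taxonomy table: ",
         paste(unresolved, collapse = ", "), call. = FALSE)
  out <- contributions |>
    dplyr::select(-dplyr::any_of("taxon")) |>
    dplyr::left_join(taxonomy[, c("model_id", rank)], by = "model_id") |>
    dplyr::rename(taxon = dplyr::all_of(rank)) |>
    dplyr::group_by(sample, taxon, metabolite) |>
    dplyr::summarise(minimum = sum(minimum), maximum = sum(maximum),
                     .groups = "drop")
  new_contribution_table(out)
}

#' Call metabolite producers from a contribution table
#'
#' A taxon qualifies as a producer when its mean secretion-side
#' contribution across samples (per-sample FVA maxima, truncated at zero;
#' samples where the taxon is absent count as zero) is at least `threshold`
#' for at least one target metabolite. Producers are ranked by their total
#' mean secretion across all targets.
#'
#' @param contributions a `contribution_table` (any taxonomic level; the
#'   `taxon` column is used).
#' @param threshold qualification threshold in mmol/day (default 0.01).
#' @return tibble of producers: `taxon`, `total_mean_secretion`, `rank`,
#'   with the per-metabolite means in attribute `"detail"`.
#' @export
identify_producers <- function(contributions, threshold = 0.01) {
  n_samples <- dplyr::n_distinct(contributions$sample)
  stopifnot(n_samples >= 1L)
  detail <- contributions |>
    dplyr::group_by(taxon, metabolite) |>
    dplyr::summarise(mean_secretion = sum(pmax(maximum, 0)) / n_samples,
                     .groups = "drop")
  producers <- detail |>
    dplyr::group_by(taxon) |>
    dplyr::summarise(qualifies = any(mean_secretion >= threshold),
                     total_mean_secretion = sum(mean_secretion),
                     .groups = "drop") |>
    dplyr::filter(qualifies) |>
    dplyr::arrange(dplyr::desc(total_mean_secretion)) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::select(taxon, total_mean_secretion, rank)
  structure(producers, detail = detail, threshold = threshold)
}

#' Call prebiotic responders from a contribution table
#'
#' A taxon responds to a supplemented substrate when its mean uptake-side
#' flux of that substrate across samples (absolute value of per-sample FVA
#' minima truncated at zero from below; absent samples count as zero) is
#' at least `threshold`. The report carries mean, population standard
#' deviation, and the min-max range of the per-sample uptake fluxes.
#'
#' @param contributions a `contribution_table` computed under the
#'   supplemented diet.
#' @param substrate lumen metabolite base id of the supplement.
#' @param threshold mean uptake threshold in mmol/day (default 1).
#' @param diet optional `diet_spec` used for the simulation; when
#'   provided, the substrate must appear in it (a responder analysis
#'   without the substrate in the diet is meaningless).
#' @return tibble: `taxon`, `mean_uptake`, `sd_uptake`, `min_uptake`,
#'   `max_uptake`, `qualifies`, `threshold` -- one row per taxon with any
#'   nonzero uptake, qualifying rows first.
#' @export
identify_responders <- function(contributions, substrate, threshold = 1,
                                diet = NULL) {
  if (!is.null(diet) && !substrate %in% diet$metabolite)
    stop("substrate '", substrate, "' is not part of the supplied diet; ",
         "responder analysis is meaningless", call. = FALSE)
  n_samples <- dplyr::n_distinct(contributions$sample)
  sub <- contributions |>
    dplyr::filter(metabolite == substrate) |>
    dplyr::mutate(uptake = pmax(-minimum, 0))
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  report <- sub |>
    dplyr::group_by(taxon) |>
    dplyr::summarise(
      mean_uptake = sum(uptake) / n_samples,
      sd_uptake = pop_sd(c(uptake, rep(0, n_samples - dplyr::n()))),
      min_uptake = if (dplyr::n() < n_samples) 0 else min(uptake),
      max_uptake = max(uptake),
      .groups = "drop") |>
    dplyr::mutate(qualifies = mean_uptake >= threshold,
                  threshold = threshold) |>
    dplyr::filter(max_uptake > 0) |>
    dplyr::arrange(dplyr::desc(qualifies), dplyr::desc(mean_uptake))
  report
}
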
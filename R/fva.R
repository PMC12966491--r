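#' Flux variability analysis
#'
#' For each requested reaction, minimizes and maximizes its flux over the
#' constrained flux polytope (steady state, bounds, coupling rows, and the
#' community biomass bounds, which stay active rather than being fixed at
#' an optimum). Every min/max is an independent linear program; the
#' feasibility phase of the underlying solver is shared across objectives,
#' so results do not depend on the order in which reactions are listed.
#'
#' @param model a `taxon_model` or `community_model`.
#' @param reactions reaction ids to analyze; default: all exchange
#'   reactions.
#' @param fix_biomass optional fraction; when given, the model's biomass
#'   objective is first maximized and then fixed at `fix_biomass * optimum`
#'   before the variability analysis (a fix-at-fraction-of-optimum mode
#'   offered for comparison).
#' @param clamp absolute fluxes below this are reported as 0 in
#'   `minimum`/`maximum` for readability (default 1e-9); the raw solver
#'   values are kept in `raw_minimum`/`raw_maximum`.
#' @return an `fva_result` tibble: `reaction`, `minimum`, `maximum`,
#'   `raw_minimum`, `raw_maximum`, `unbounded_min`, `unbounded_max`
#'   (flux magnitude hit the open +/-1e6 bound). Fluxes in mmol/day.
#' @export
run_fva <- function(model, reactions = NULL, fix_biomass = NULL,
                    clamp = 1e-9) {
  rxn <- model$reactions
  if (is.null(reactions))
    reactions <- rxn$id[rxn$kind == "exchange"]
  missing_rxn <- setdiff(reactions, rxn$id)
  if (length(missing_rxn))
    stop("unknown reaction id(s): ", paste(missing_rxn, collapse = ", "),
         call. = FALSE)

  if (!is.null(fix_biomass)) {
    opt <- solve_lp(model, model$biomass_reaction_id, "max")
    if (opt$status != "optimal")
      stop("cannot fix biomass: solver status '", opt$status, "'",
           call. = FALSE)
    i <- match(model$biomass_reaction_id, rxn$id)
    model$reactions$lower_bound[i] <- fix_biomass * opt$objective_value
    model$reactions$upper_bound[i] <- fix_biomass * opt$objective_value
    rxn <- model$reactions
  }

  st <- model_lp_state(model)
  n <- nrow(rxn)
  res <- purrr::map_dfr(reactions, function(rid) {
    obj <- as.numeric(rxn$id == rid)
    lo <- lp_optimize(st, obj, maximize = FALSE)
    hi <- lp_optimize(st, obj, maximize = TRUE)
    if (lo$status == "infeasible" || hi$status == "infeasible")
      stop("model infeasible under the current constraints (solver status: ",
           "infeasible)", call. = FALSE)
    vmin <- if (lo$status == "optimal") lo$objective else -1e6
    vmax <- if (hi$status == "optimal") hi$objective else 1e6
    tibble::tibble(reaction = rid,
                   raw_minimum = vmin, raw_maximum = vmax,
                   unbounded_min = lo$status == "unbounded" ||
                     vmin <= -1e6 + 1e-6,
                   unbounded_max = hi$status == "unbounded" ||
                     vmax >= 1e6 - 1e-6)
  })
  res <- res |>
    dplyr::mutate(minimum = ifelse(abs(raw_minimum) < clamp, 0, raw_minimum),
                  maximum = ifelse(abs(raw_maximum) < clamp, 0, raw_maximum)) |>
    dplyr::select(reaction, minimum, maximum, raw_minimum, raw_maximum,
                  unbounded_min, unbounded_max)
  structure(res, class = c("fva_result", class(res)),
            fix_biomass = fix_biomass)
}

#' Net secretion and net uptake per metabolite
#'
#' Combines the variability ranges of each lumen metabolite's diet and
#' fecal exchanges into net fluxes. Under the default signed convention
#' (exchange flux positive = export):
#' `net_secretion(m) = maxFVA(fecal_m) + minFVA(diet_m)` and
#' `net_uptake(m) = maxFVA(diet_m) + minFVA(fecal_m)`, so a metabolite that
#' merely passes through (importable and re-exportable, never transformed)
#' nets to zero secretion. The `"magnitude"` convention instead reports
#' positive magnitudes: `net_secretion = maxFVA(fecal) - maxFVA(diet)`,
#' `net_uptake = -minFVA(diet) + minFVA(fecal)`. Metabolites lacking one of
#' the two exchanges contribute 0 for the missing term.
#'
#' @param fva an `fva_result` covering the diet and fecal exchanges.
#' @param model the `community_model` the FVA was run on.
#' @param convention `"signed"` (default) or `"magnitude"`.
#' @return tibble: `metabolite`, `net_secretion`, `net_uptake` (mmol/day).
#' @export
net_exchange_fluxes <- function(fva, model,
                                convention = c("signed", "magnitude")) {
  convention <- match.arg(convention)
  rxn <- model$reactions
  ex <- rxn$id[rxn$kind == "exchange"]
  diet_ids <- ex[grepl("__d$", ex)]
  fecal_ids <- ex[grepl("__fe$", ex)]
  base <- union(sub("^EX_(.*)__d$", "\\1", diet_ids),
                sub("^EX_(.*)__fe$", "\\1", fecal_ids))
  get <- function(rid, what) {
    i <- match(rid, fva$reaction)
    if (is.na(i)) 0 else fva[[what]][i]
  }
  purrr::map_dfr(sort(base), function(b) {
    d <- paste0("EX_", b, "__d")
    f <- paste0("EX_", b, "__fe")
    if (convention == "signed") {
      ns <- get(f, "maximum") + get(d, "minimum")
      nu <- get(d, "maximum") + get(f, "minimum")
    } else {
      ns <- get(f, "maximum") - get(d, "maximum")
      nu <- -get(d, "minimum") + get(f, "minimum")
    }
    tibble::tibble(metabolite = b, net_secretion = ns, net_uptake = nu)
  })
}

#' Simulate one sample end to end
#'
#' Deterministic composition of the pipeline stages for a single sample:
#' community assembly with abundance-weighted biomass and coupling, diet
#' application, flux variability analysis over the boundary exchanges, and
#' net-flux computation.
#'
#' @param models list of `taxon_model`s present in the sample.
#' @param abundances named abundance vector (sums to 1).
#' @param diet a `diet_spec`.
#' @param coupling a [coupling_config()].
#' @param biomass_bounds community biomass bounds, mmol/day.
#' @param gap_fill,trace passed to [apply_diet()].
#' @param reactions optional restriction of the FVA reaction set.
#' @param convention net-flux convention, see [net_exchange_fluxes()].
#' @return list with `fva` (an `fva_result`), `net_fluxes`, `model`, and a
#'   `manifest` recording the configuration.
#' @export
simulate_sample <- function(models, abundances, diet,
                            coupling = coupling_config(),
                            biomass_bounds = c(0.4, 1),
                            gap_fill = NULL, trace = 0.1,
                            reactions = NULL,
                            convention = "signed") {
  cm <- build_community(models, abundances, coupling = coupling,
                        biomass_bounds = biomass_bounds)
  cm <- apply_diet(cm, diet, gap_fill = gap_fill, trace = trace)
  fva <- run_fva(cm, reactions = reactions)
  nf <- net_exchange_fluxes(fva, cm, convention = convention)
  manifest <- list(
    diet = attr(diet, "diet_name") %||% "diet",
    taxa = cm$members$model_id,
    abundances = as.list(stats::setNames(cm$members$abundance,
                                         cm$members$model_id)),
    coupling = coupling,
    biomass_bounds = biomass_bounds,
    gap_fill = gap_fill,
    convention = convention,
    package_version = as.character(utils::packageVersion("gutflux")))
  list(fva = fva, net_fluxes = nf, model = cm, manifest = manifest)
}

#' Write an FVA or net-flux table as TSV
#'
#' @param x an `fva_result` or net-flux tibble.
#' @param path output file.
#' @export
write_flux_table <- function(x, path) {
  readr::write_tsv(tibble::as_tibble(x), path)
  invisible(path)
}
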
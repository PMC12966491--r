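#' Create a metabolite table
#'
#' Metabolites are rows of a tibble; `compartment` is a short label such as
#' `"c"` (cytosol), `"e"` (extracellular), `"u"` (lumen), `"d"` (diet) or
#' `"fe"` (fecal). `molecular_weight` (g/mol) is only consulted when diet
#' masses are converted to fluxes.
#'
#' @param id unique metabolite identifier(s).
#' @param name human-readable name(s); defaults to `id`.
#' @param compartment compartment label(s).
#' @param molecular_weight optional molecular weight(s) in g/mol.
#' @return a tibble with one row per metabolite.
#' @export
#' @examples
#' metabolite(c("glc__e", "ac__e"), compartment = "e")
metabolite <- function(id, name = id, compartment = "c",
                       molecular_weight = NA_real_) {
  tibble::tibble(id = as.character(id), name = as.character(name),
                 compartment = as.character(compartment),
                 molecular_weight = as.numeric(molecular_weight))
}

#' Create a reaction table
#'
#' A reaction is defined by its signed stoichiometry (negative coefficients
#' consume, positive produce) and flux bounds in mmol/day. Exchange
#' reactions follow the export-positive convention: they are written
#' `metabolite -> (nothing)`, so positive flux leaves the system and
#' negative flux is import.
#'
#' @param id reaction identifier.
#' @param stoichiometry named numeric vector, metabolite id -> coefficient.
#' @param lower_bound,upper_bound flux bounds in mmol/day; the defaults
#'   `c(-1e6, 1e6)` are effectively unconstrained while keeping every
#'   linear program bounded.
#' @param kind one of `"internal"`, `"transport"`, `"exchange"`,
#'   `"biomass"`, `"community_biomass"`.
#' @return a one-row tibble with a list-column `stoichiometry`.
#' @export
#' @examples
#' reaction("FERM", c(glc__e = -1, ac__e = 2), 0, 1e6)
reaction <- function(id, stoichiometry, lower_bound = -1e6,
                     upper_bound = 1e6, kind = "internal") {
  stopifnot(is.numeric(stoichiometry), !is.null(names(stoichiometry)))
  kind <- match.arg(kind, c("internal", "transport", "exchange",
                            "biomass", "community_biomass"))
  tibble::tibble(id = as.character(id),
                 stoichiometry = list(stoichiometry),
                 lower_bound = as.numeric(lower_bound),
                 upper_bound = as.numeric(upper_bound),
                 kind = kind)
}

#' Assemble a per-taxon metabolic model
#'
#' Bundles metabolite and reaction tables into a genome-scale-model-like
#' object for a single organism. The `model_id` plays the role of a model
#' repository identifier; `taxonomy` records the lineage used later when
#' contributions are aggregated by rank.
#'
#' @param model_id model identifier string.
#' @param metabolites tibble from [metabolite()] (rows may be bound together).
#' @param reactions tibble from [reaction()] rows.
#' @param biomass_reaction_id id of the reaction of kind `"biomass"`.
#' @param taxonomy named list or character with entries `phylum`, `family`,
#'   `genus`, `species`.
#' @param check validate on construction (default `TRUE`).
#' @return an object of class `taxon_model`.
#' @export
taxon_model <- function(model_id, metabolites, reactions, biomass_reaction_id,
                        taxonomy = list(phylum = NA_character_,
                                        family = NA_character_,
                                        genus = NA_character_,
                                        species = NA_character_),
                        check = TRUE) {
  m <- structure(
    list(model_id = model_id,
         taxonomy = as.list(taxonomy),
         metabolites = metabolites,
         reactions = reactions,
         biomass_reaction_id = biomass_reaction_id),
    class = "taxon_model")
  if (check) assert_valid_model(m)
  m
}

#' @export
print.taxon_model <- function(x, ...) {
  cat("<taxon_model> ", x$model_id, "\n",
      "  metabolites: ", nrow(x$metabolites),
      "  reactions: ", nrow(x$reactions),
      "  biomass: ", x$biomass_reaction_id, "\n", sep = "")
  invisible(x)
}

#' Validate a metabolic model
#'
#' Checks the structural invariants every model must satisfy: unique
#' nonempty ids, consistent bounds, referential integrity of stoichiometry,
#' single-metabolite exchanges, and a biomass reaction that produces exactly
#' one biomass metabolite.
#'
#' @param model a `taxon_model` or `community_model`.
#' @return a tibble of violations with columns `check`, `object`,
#'   `message`; zero rows means the model is valid.
#' @export
validate_model <- function(model) {
  v <- list()
  add <- function(check, object, message) {
    v[[length(v) + 1L]] <<- tibble::tibble(check = check, object = object,
                                           message = message)
  }
  met <- model$metabolites
  rxn <- model$reactions
  if (any(!nzchar(met$id)) || anyNA(met$id))
    add("metabolite_id", "<empty>", "empty or missing metabolite id")
  dup <- unique(met$id[duplicated(met$id)])
  for (d in dup) add("metabolite_id_unique", d, "duplicated metabolite id")
  dupr <- unique(rxn$id[duplicated(rxn$id)])
  for (d in dupr) add("reaction_id_unique", d, "duplicated reaction id")
  bad_b <- rxn$id[rxn$lower_bound > rxn$upper_bound]
  for (d in bad_b) add("bounds", d, "lower_bound exceeds upper_bound")
  known <- met$id
  for (i in seq_len(nrow(rxn))) {
    s <- rxn$stoichiometry[[i]]
    missing_met <- setdiff(names(s), known)
    if (length(missing_met))
      add("stoichiometry_refs", rxn$id[i],
          paste0("undeclared metabolite(s): ",
                 paste(missing_met, collapse = ", ")))
    if (rxn$kind[i] == "exchange" && length(s) != 1L)
      add("exchange_arity", rxn$id[i],
          "exchange reaction must touch exactly one metabolite")
    if (rxn$kind[i] == "biomass" && sum(s > 0) != 1L)
      add("biomass_product", rxn$id[i],
          "biomass reaction must produce exactly one biomass metabolite")
  }
  if (!is.null(model$biomass_reaction_id)) {
    hit <- rxn$kind[match(model$biomass_reaction_id, rxn$id)]
    if (is.na(hit))
      add("biomass_reaction", model$biomass_reaction_id %||% "<missing>",
          "biomass_reaction_id not found among reactions")
    else if (!hit %in% c("biomass", "community_biomass"))
      add("biomass_reaction", model$biomass_reaction_id,
          "biomass_reaction_id does not have kind 'biomass'")
  } else {
    add("biomass_reaction", "<missing>", "no biomass_reaction_id declared")
  }
  if (length(v)) dplyr::bind_rows(v) else
    tibble::tibble(check = character(), object = character(),
                   message = character())
}

assert_valid_model <- function(model) {
  v <- validate_model(model)
  if (nrow(v) > 0L) {
    stop("invalid model '", model$model_id, "':\n  ",
         paste(v$check, v$object, v$message, sep = ": ", collapse = "\n  "),
         call. = FALSE)
  }
  invisible(model)
}

## dense stoichiometric matrix, metabolites x reactions
model_smatrix <- function(model) {
  met_ids <- model$metabolites$id
  rxn <- model$reactions
  S <- matrix(0, length(met_ids), nrow(rxn),
              dimnames = list(met_ids, rxn$id))
  for (j in seq_len(nrow(rxn))) {
    s <- rxn$stoichiometry[[j]]
    S[names(s), j] <- S[names(s), j] + unname(s)
  }
  S
}

## Build the LP state (steady state + bounds + coupling rows) for a model.
## Coupling rows come from model$coupling: |v_r| <= c * v_bio + u, written
## as two "<=" rows per coupled reaction.
model_lp_state <- function(model) {
  S <- model_smatrix(model)
  rxn <- model$reactions
  ub_rows <- coupling_rows(model)
  st <- lp_build(S, rep(0, nrow(S)), ub_rows$A, ub_rows$b,
                 rxn$lower_bound, rxn$upper_bound)
  attr(st, "reaction_ids") <- rxn$id
  st
}

#' Optimize a flux through a model
#'
#' Solves the flux balance linear program: steady state (`S v = 0`), flux
#' bounds, and, for community models, the biomass coupling rows, optimizing
#' the named reaction. Infeasibility and unboundedness are reported in the
#' returned status, never silently repaired.
#'
#' @param model a `taxon_model` or `community_model`.
#' @param objective reaction id to optimize.
#' @param sense `"max"` or `"min"`.
#' @param extra_constraints optional list of extra rows, each a list with
#'   `coefs` (named numeric over reaction ids), `dir` (`"<="`, `">="` or
#'   `"=="`) and `rhs`.
#' @return list with `status` (`optimal`, `infeasible`, `unbounded`),
#'   `objective_value` (mmol/day) and `fluxes` (named vector, mmol/day).
#' @export
solve_lp <- function(model, objective, sense = c("max", "min"),
                     extra_constraints = NULL) {
  sense <- match.arg(sense)
  rxn <- model$reactions
  if (!objective %in% rxn$id)
    stop("objective reaction '", objective, "' not in model", call. = FALSE)
  S <- model_smatrix(model)
  n <- nrow(rxn)
  A_eq <- S
  b_eq <- rep(0, nrow(S))
  ub_rows <- coupling_rows(model)
  A_ub <- ub_rows$A; b_ub <- ub_rows$b
  if (!is.null(extra_constraints)) {
    for (ec in extra_constraints) {
      row <- numeric(n); names(row) <- rxn$id
      row[names(ec$coefs)] <- ec$coefs
      if (ec$dir == "<=") {
        A_ub <- rbind(A_ub, row); b_ub <- c(b_ub, ec$rhs)
      } else if (ec$dir == ">=") {
        A_ub <- rbind(A_ub, -row); b_ub <- c(b_ub, -ec$rhs)
      } else {
        A_eq <- rbind(A_eq, row); b_eq <- c(b_eq, ec$rhs)
      }
    }
  }
  obj <- as.numeric(rxn$id == objective)
  res <- lp_solve_dense(obj, A_eq, b_eq, A_ub, b_ub,
                        rxn$lower_bound, rxn$upper_bound,
                        maximize = sense == "max")
  lp_as_solution(res, rxn$id)
}

## the two "<=" rows per coupled reaction: v_r - c v_bio <= u, -v_r - c v_bio <= u
coupling_rows <- function(model) {
  cp <- model$coupling
  rxn <- model$reactions
  if (is.null(cp) || nrow(cp) == 0L) return(list(A = NULL, b = NULL))
  n <- nrow(rxn)
  idx_r <- match(cp$reaction_id, rxn$id)
  idx_b <- match(cp$biomass_reaction_id, rxn$id)
  A <- matrix(0, 2L * nrow(cp), n)
  b <- numeric(2L * nrow(cp))
  for (i in seq_len(nrow(cp))) {
    A[2 * i - 1, idx_r[i]] <- 1
    A[2 * i - 1, idx_b[i]] <- A[2 * i - 1, idx_b[i]] - cp$c[i]
    A[2 * i, idx_r[i]] <- -1
    A[2 * i, idx_b[i]] <- A[2 * i, idx_b[i]] - cp$c[i]
    b[c(2 * i - 1, 2 * i)] <- cp$u[i]
  }
  list(A = A, b = b)
}

lp_as_solution <- function(res, reaction_ids, extra = NULL) {
  fluxes <- if (!is.null(res$x)) stats::setNames(res$x[seq_along(reaction_ids)],
                                                 reaction_ids) else NULL
  list(status = res$status, objective_value = res$objective, fluxes = fluxes)
}

#' Maximize growth of a model
#'
#' Convenience wrapper for [solve_lp()] with the model's biomass reaction as
#' objective.
#'
#' @inheritParams solve_lp
#' @export
fba <- function(model, sense = "max") {
  solve_lp(model, model$biomass_reaction_id, sense = sense)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
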
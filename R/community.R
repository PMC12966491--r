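#' Coupling configuration
#'
#' Parameters of the biomass coupling constraints that tie every member
#' reaction's flux to its taxon's growth:
#' `|v_r| <= c * v_biomass + u`. The default `c = 400`, `u = 0` is the
#' established community-modeling convention; the slack `u` (mmol/day)
#' admits growth-free flux when positive.
#'
#' @param c dimensionless coupling factor (> 0).
#' @param u slack in mmol/day (>= 0).
#' @export
coupling_config <- function(c = 400, u = 0) {
  stopifnot(c > 0, u >= 0)
  list(c = c, u = u)
}

#' Namespace a taxon model for community assembly
#'
#' Prefixes every metabolite and reaction id with `tag__`, leaving
#' stoichiometry, bounds and kinds untouched. Lumen transfer reactions are
#' created later, at community build time.
#'
#' @param model a `taxon_model`.
#' @param tag nonempty tag, unique within the community.
#' @return the tagged `taxon_model`.
#' @export
tag_taxon_model <- function(model, tag) {
  stopifnot(is.character(tag), length(tag) == 1L, nzchar(tag))
  pre <- function(x) paste0(tag, "__", x)
  m <- model
  m$metabolites$id <- pre(m$metabolites$id)
  m$reactions$id <- pre(m$reactions$id)
  m$reactions$stoichiometry <- purrr::map(m$reactions$stoichiometry,
                                          function(s) {
                                            names(s) <- pre(names(s))
                                            s
                                          })
  m$biomass_reaction_id <- pre(m$biomass_reaction_id)
  m$tag <- tag
  m
}

#' Assemble a community-scale model from taxon models
#'
#' Joins per-taxon models through a shared lumen: each member is
#' namespaced by its tag, its standalone exchange reactions are removed,
#' every extracellular metabolite is linked to a lumen metabolite by a
#' reversible transfer reaction, and each lumen metabolite receives a diet
#' exchange (import side, closed until [apply_diet()] opens it) and a fecal
#' exchange (export only). A community biomass reaction consumes `a_k`
#' units of each taxon's biomass metabolite -- the relative abundances act
#' as stoichiometric coefficients -- and its exchange is bounded to
#' `biomass_bounds` mmol/day (default `[0.4, 1]`, fecal emptying between
#' every three days and daily). Coupling rows are added for every member
#' reaction via [apply_coupling()].
#'
#' @param models list of `taxon_model` objects.
#' @param abundances named numeric vector (model id -> relative abundance);
#'   must sum to 1 within 1e-9, all entries positive.
#' @param coupling a [coupling_config()].
#' @param biomass_bounds community biomass exchange bounds, mmol/day.
#' @param lumen_compartment member compartment linked to the lumen
#'   (default `"e"`).
#' @return a `community_model` (inherits `taxon_model`), with fields
#'   `members` (tibble: tag, model_id, abundance, biomass_reaction_id,
#'   taxonomy columns) and `coupling` (constraint rows).
#' @export
build_community <- function(models, abundances,
                            coupling = coupling_config(),
                            biomass_bounds = c(0.4, 1),
                            lumen_compartment = "e") {
  if (length(models) == 0L) stop("no member models", call. = FALSE)
  ids <- purrr::map_chr(models, "model_id")
  if (anyDuplicated(ids)) stop("duplicate member tag/model id: ",
                               paste(unique(ids[duplicated(ids)]),
                                     collapse = ", "), call. = FALSE)
  if (!setequal(names(abundances), ids))
    stop("abundance names do not match the member model ids", call. = FALSE)
  abundances <- abundances[ids]
  if (any(abundances <= 0)) stop("all abundances must be positive",
                                 call. = FALSE)
  if (abs(sum(abundances) - 1) > 1e-9)
    stop("abundances must sum to 1 (got ", format(sum(abundances)), ")",
         call. = FALSE)

  mets <- list(); rxns <- list(); members <- list()
  transfers <- list()
  lumen_base <- character(0)

  for (k in seq_along(models)) {
    tg <- ids[k]
    tm <- tag_taxon_model(models[[k]], tg)
    keep <- tm$reactions$kind != "exchange"
    mem_rxns <- tm$reactions[keep, ]
    mets[[k]] <- tm$metabolites
    rxns[[k]] <- mem_rxns
    ext <- tm$metabolites[tm$metabolites$compartment == lumen_compartment, ]
    base <- sub(paste0("^", tg, "__"), "", ext$id)
    base <- sub(paste0("__", lumen_compartment, "$"), "", base)
    lumen_base <- union(lumen_base, base)
    transfers[[k]] <- purrr::map2_dfr(ext$id, base, function(mid, b)
      reaction(paste0(tg, "__IEX_", b),
               stats::setNames(c(-1, 1), c(mid, paste0(b, "__u"))),
               -1e6, 1e6, kind = "transport"))
    bio_s <- mem_rxns$stoichiometry[[match(tm$biomass_reaction_id,
                                           mem_rxns$id)]]
    bm_met <- names(bio_s)[bio_s > 0]
    tax <- models[[k]]$taxonomy
    members[[k]] <- tibble::tibble(
      tag = tg, model_id = ids[k], abundance = unname(abundances[k]),
      biomass_reaction_id = tm$biomass_reaction_id,
      biomass_metabolite = bm_met,
      phylum = tax$phylum %||% NA_character_,
      family = tax$family %||% NA_character_,
      genus = tax$genus %||% NA_character_,
      species = tax$species %||% NA_character_)
  }
  members <- dplyr::bind_rows(members)

  lumen_base <- sort(lumen_base)
  lumen_mets <- metabolite(paste0(lumen_base, "__u"), lumen_base, "u")
  diet_ex <- purrr::map_dfr(lumen_base, function(b)
    reaction(paste0("EX_", b, "__d"),
             stats::setNames(-1, paste0(b, "__u")),
             0, 0, kind = "exchange"))
  fecal_ex <- purrr::map_dfr(lumen_base, function(b)
    reaction(paste0("EX_", b, "__fe"),
             stats::setNames(-1, paste0(b, "__u")),
             0, 1e6, kind = "exchange"))

  cb_met <- metabolite("community_biomass", "community biomass", "u")
  cb_stoich <- stats::setNames(c(-members$abundance, 1),
                               c(members$biomass_metabolite,
                                 "community_biomass"))
  cb_rxn <- reaction("community_biomass", cb_stoich, 0, 1e6,
                     kind = "community_biomass")
  cb_ex <- reaction("EX_community_biomass",
                    c(community_biomass = -1),
                    biomass_bounds[1], biomass_bounds[2], kind = "exchange")

  model <- structure(
    list(model_id = "community",
         taxonomy = list(phylum = NA_character_, family = NA_character_,
                         genus = NA_character_, species = NA_character_),
         metabolites = dplyr::bind_rows(mets, lumen_mets, cb_met),
         reactions = dplyr::bind_rows(rxns, transfers, diet_ex, fecal_ex,
                                      cb_rxn, cb_ex),
         biomass_reaction_id = "community_biomass",
         members = members,
         diet_name = NULL,
         coupling = NULL),
    class = c("community_model", "taxon_model"))
  model <- apply_coupling(model, coupling)
  assert_valid_model(model)
  model
}

#' @export
print.community_model <- function(x, ...) {
  cat("<community_model> ", nrow(x$members), " member taxa, ",
      nrow(x$metabolites), " metabolites, ", nrow(x$reactions),
      " reactions\n", sep = "")
  cat("  diet: ", x$diet_name %||% "<none applied>", "\n", sep = "")
  invisible(x)
}

#' (Re)build the biomass coupling constraint set
#'
#' For every member reaction `r` of taxon `k` other than its biomass
#' reaction, adds the pair of rows `v_r <= c * v_bio_k + u` and
#' `v_r >= -c * v_bio_k - u` to the model's explicit constraint block.
#'
#' @param model a `community_model`.
#' @param coupling a [coupling_config()].
#' @return the model with its `coupling` field replaced.
#' @export
apply_coupling <- function(model, coupling = coupling_config()) {
  members <- model$members
  rows <- purrr::pmap_dfr(members[, c("tag", "biomass_reaction_id")],
                          function(tag, biomass_reaction_id) {
    rid <- model$reactions$id
    own <- rid[startsWith(rid, paste0(tag, "__")) &
                 rid != biomass_reaction_id]
    tibble::tibble(reaction_id = own,
                   biomass_reaction_id = biomass_reaction_id,
                   c = coupling$c, u = coupling$u)
  })
  model$coupling <- rows
  model$coupling_config <- coupling
  model
}

#' Constrain a community model with a diet
#'
#' Opens each diet metabolite's diet exchange to import at the diet's flux
#' (`lb = -flux`, `ub = 0` under the export-positive convention). Diet
#' exchanges of metabolites absent from the diet stay closed to import
#' unless `gap_fill` supplies a trace set. Fecal exchanges remain
#' export-only. Diet entries with no matching lumen metabolite are
#' reported with a warning, not an error.
#'
#' @param model a `community_model`.
#' @param diet a `diet_spec` (columns `metabolite`, `mmol_per_day`).
#' @param gap_fill optional character vector of metabolite ids admitted at
#'   a trace import bound even when absent from the diet.
#' @param trace trace import bound in mmol/day for gap-filled metabolites
#'   (default 0.1).
#' @return the diet-constrained `community_model`.
#' @export
apply_diet <- function(model, diet, gap_fill = NULL, trace = 0.1) {
  rxn <- model$reactions
  diet_idx <- which(rxn$kind == "exchange" & grepl("__d$", rxn$id))
  base_of <- sub("__d$", "", sub("^EX_", "", rxn$id[diet_idx]))
  fx <- stats::setNames(diet$mmol_per_day, diet$metabolite)
  unresolved <- setdiff(names(fx), base_of)
  if (length(unresolved))
    warning("diet metabolite(s) without a lumen exchange: ",
            paste(unresolved, collapse = ", "), call. = FALSE)
  lb <- rep(0, length(diet_idx))
  hit <- base_of %in% names(fx)
  lb[hit] <- -unname(fx[base_of[hit]])
  gap <- !hit & base_of %in% gap_fill
  lb[gap] <- -trace
  model$reactions$lower_bound[diet_idx] <- lb
  model$reactions$upper_bound[diet_idx] <- 0
  model$diet_name <- attr(diet, "diet_name") %||% "diet"
  model
}

## JSON (de)serialization helpers for the community-specific fields
community_fields_to_json <- function(model, d) {
  d$members <- purrr::pmap(model$members, function(...) list(...))
  d$coupling <- purrr::pmap(model$coupling, function(...) list(...))
  d$diet_name <- model$diet_name
  d$community <- TRUE
  d
}

community_fields_from_json <- function(model, d) {
  model$members <- purrr::map_dfr(d$members, tibble::as_tibble)
  model$coupling <- purrr::map_dfr(d$coupling, tibble::as_tibble)
  model$diet_name <- d$diet_name
  class(model) <- c("community_model", class(model))
  model
}
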
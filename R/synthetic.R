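#' Toy fermenter templates
#'
#' Six small taxon templates with known substrate -> product stoichiometry,
#' designed so every pipeline stage has a ground truth: an acetogen, a
#' propionogen, a butyrogen that also cross-feeds on lumen acetate, an
#' isobutyrate producer fermenting the branched-chain amino acid valine, a
#' manno-oligosaccharide (MOS) utilizer, and a generalist that additionally
#' degrades maltodextrin. All grow on glucose; the taxonomy assignments are
#' synthetic lineages chosen to exercise rank aggregation.
#'
#' @return tibble: `template`, `model_id`, taxonomy columns, and a
#'   list-column `spec` holding the fermentation pathways
#'   (`list(substrates, products, yields)`) and the growth yield.
#' @export
taxon_templates <- function() {
  tpl <- function(template, genus, species, family, phylum, ferm,
                  growth_sub = "glc", gamma = 1) {
    tibble::tibble(template = template,
                   model_id = paste0("syn_", template),
                   phylum = phylum, family = family, genus = genus,
                   species = paste(genus, species),
                   spec = list(list(ferm = ferm, growth_sub = growth_sub,
                                    gamma = gamma)))
  }
  dplyr::bind_rows(
    tpl("acetogen", "Acetifaber", "simplex", "Lachnospiraceae", "Bacillota",
        list(list(id = "FERM_ac", sub = c(glc = 1), prod = c(ac = 2)))),
    tpl("propionogen", "Propionifaber", "communis", "Bacteroidaceae",
        "Bacteroidota",
        list(list(id = "FERM_ppa", sub = c(glc = 1), prod = c(ppa = 1.5)))),
    tpl("butyrogen", "Butyrifaber", "crossalimentus", "Lachnospiraceae",
        "Bacillota",
        list(list(id = "FERM_but", sub = c(glc = 1), prod = c(but = 1)),
             list(id = "FERM_but_ac", sub = c(glc = 1, ac = 1),
                  prod = c(but = 2.5)))),
    tpl("isobutyrogen", "Isobutyrifaber", "valivorans", "Bacteroidaceae",
        "Bacteroidota",
        list(list(id = "FERM_isobut", sub = c(val = 1),
                  prod = c(isobut = 1)))),
    tpl("mos_utilizer", "Mannovorax", "praebioticus", "Bifidobacteriaceae",
        "Actinomycetota",
        list(list(id = "FERM_mos", sub = c(mos = 1), prod = c(ac = 3)))),
    tpl("generalist", "Omnivorax", "vulgaris", "Oscillospiraceae",
        "Bacillota",
        list(list(id = "FERM_mix", sub = c(glc = 1),
                  prod = c(ac = 1, ppa = 0.5)),
             list(id = "DEGR_mdx", sub = c(mdx = 1), prod = c(glc = 3)))))
}

#' Molecular weights of the fixture metabolites
#'
#' g/mol values used by the diet conversion for the synthetic food
#' database: glucose, valine, the SCFAs, mannotriose (the MOS unit) and a
#' maltodextrin triose-equivalent.
#'
#' @return named numeric vector, metabolite id -> g/mol.
#' @export
fixture_molecular_weights <- function() {
  c(glc = 180.16, val = 117.15, ac = 60.05, ppa = 74.08,
    but = 88.11, isobut = 88.11, mos = 504.44, mdx = 504.44)
}

#' Build a taxon model from a template
#'
#' Expands a row of [taxon_templates()] into a full `taxon_model`:
#' one extracellular metabolite per substrate/product, a fermentation
#' reaction per pathway, a biomass reaction consuming the growth substrate,
#' a biomass demand exchange, and an exchange reaction per extracellular
#' metabolite. The construction is deterministic for a given template and
#' seed (the seed is recorded on the model for provenance).
#'
#' @param template one row of [taxon_templates()] (or a template name).
#' @param seed integer recorded on the model.
#' @return a validated `taxon_model`.
#' @export
make_taxon_model <- function(template, seed = 1L) {
  if (is.character(template)) {
    tt <- taxon_templates()
    template <- tt[tt$template == template, ]
    if (nrow(template) != 1L)
      stop("unknown template name", call. = FALSE)
  }
  sp <- template$spec[[1]]
  emets <- unique(c(unlist(purrr::map(sp$ferm, function(f)
    c(names(f$sub), names(f$prod)))), sp$growth_sub))
  mw <- fixture_molecular_weights()
  mets <- dplyr::bind_rows(
    metabolite(paste0(emets, "__e"), emets, "e",
               molecular_weight = unname(mw[emets])),
    metabolite("bm__c", "biomass", "c"))
  ferm <- purrr::map_dfr(sp$ferm, function(f)
    reaction(f$id,
             stats::setNames(c(-unname(f$sub), unname(f$prod)),
                             paste0(c(names(f$sub), names(f$prod)), "__e")),
             0, 1e6, kind = "internal"))
  growth <- reaction("BIOMASS",
                     stats::setNames(c(-sp$gamma, 1),
                                     c(paste0(sp$growth_sub, "__e"), "bm__c")),
                     0, 1e6, kind = "biomass")
  dm_bm <- reaction("DM_bm", c(bm__c = -1), 0, 1e6, kind = "exchange")
  ex <- purrr::map_dfr(emets, function(m)
    reaction(paste0("EX_", m, "__e"),
             stats::setNames(-1, paste0(m, "__e")),
             -1e6, 1e6, kind = "exchange"))
  m <- taxon_model(template$model_id, mets,
                   dplyr::bind_rows(ferm, growth, dm_bm, ex),
                   "BIOMASS",
                   taxonomy = list(phylum = template$phylum,
                                   family = template$family,
                                   genus = template$genus,
                                   species = template$species))
  m$seed <- as.integer(seed)
  m
}

#' Constrain a standalone model's exchanges with a diet
#'
#' Sets each exchange's import bound from the diet (`lb = -flux`) and
#' closes import for exchanges of metabolites absent from the diet; export
#' stays open. Used for standalone growth and capability checks.
#'
#' @param model a `taxon_model` with exchange reactions.
#' @param diet a `diet_spec` (base metabolite ids).
#' @return the constrained model.
#' @export
constrain_exchanges <- function(model, diet) {
  fx <- stats::setNames(diet$mmol_per_day, diet$metabolite)
  idx <- which(model$reactions$kind == "exchange")
  for (i in idx) {
    s <- model$reactions$stoichiometry[[i]]
    base <- sub("__e$", "", names(s)[1])
    if (names(s)[1] == "bm__c") next          # biomass demand stays open
    model$reactions$lower_bound[i] <-
      if (base %in% names(fx)) -unname(fx[base]) else 0
  }
  model
}

#' Ground-truth capability matrix for a template set
#'
#' For each template and each metabolite of interest, runs standalone flux
#' balance analysis under the given diet: a taxon *can produce* a
#' metabolite when its maximal export is positive, and *can consume* it
#' when its maximal import magnitude is positive.
#'
#' @param templates tibble from [taxon_templates()] (possibly subset).
#' @param diet a `diet_spec`.
#' @param metabolites base metabolite ids to probe; default: all fixture
#'   metabolites.
#' @return tibble: `model_id`, `genus`, `metabolite`, `can_produce`,
#'   `can_consume`.
#' @export
template_capabilities <- function(templates, diet,
                                  metabolites = names(fixture_molecular_weights())) {
  purrr::map_dfr(seq_len(nrow(templates)), function(i) {
    m <- constrain_exchanges(make_taxon_model(templates[i, ]), diet)
    purrr::map_dfr(metabolites, function(b) {
      ex <- paste0("EX_", b, "__e")
      if (!ex %in% m$reactions$id)
        return(tibble::tibble(model_id = m$model_id,
                              genus = templates$genus[i], metabolite = b,
                              can_produce = FALSE, can_consume = FALSE))
      hi <- solve_lp(m, ex, "max")
      lo <- solve_lp(m, ex, "min")
      tibble::tibble(
        model_id = m$model_id, genus = templates$genus[i], metabolite = b,
        can_produce = hi$status == "optimal" && hi$objective_value > 1e-6,
        can_consume = lo$status == "optimal" && lo$objective_value < -1e-6)
    })
  })
}

#' Generate a synthetic cohort
#'
#' Draws per-sample relative abundances over the templates from a
#' symmetric Dirichlet distribution and converts them to synthetic genome
#' coverages with multiplicative lognormal noise (sd 0.1 by default) and a
#' lognormal per-sample sequencing depth. The seed fully determines the
#' output.
#'
#' @param n_samples number of samples (>= 1).
#' @param templates tibble from [taxon_templates()].
#' @param dirichlet_alpha symmetric Dirichlet concentration (default 5,
#'   moderately even communities in which every template is comfortably
#'   above the abundance cutoff).
#' @param seed integer seed.
#' @param noise_sd sd of the lognormal coverage noise (default 0.1).
#' @return list with `coverage` (long tibble: `sample`, `model_id`,
#'   `coverage`), `taxonomy` (model_id -> lineage), and `ground_truth`
#'   (list: `abundances` tibble, `seed`, `dirichlet_alpha`, `noise_sd`).
#' @export
make_cohort <- function(n_samples = 10, templates = taxon_templates(),
                        dirichlet_alpha = 5, seed = 1L, noise_sd = 0.1) {
  stopifnot(n_samples >= 1L, dirichlet_alpha > 0)
  k <- nrow(templates)
  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    code
  }
  out <- withr_seed({
    samples <- sprintf("S%02d", seq_len(n_samples))
    ab <- purrr::map_dfr(samples, function(s) {
      g <- stats::rgamma(k, shape = dirichlet_alpha, rate = 1)
      tibble::tibble(sample = s, model_id = templates$model_id,
                     abundance = g / sum(g))
    })
    depth <- stats::rlnorm(n_samples, meanlog = log(100), sdlog = 0.2)
    cov <- ab |>
      dplyr::group_by(sample) |>
      dplyr::mutate(coverage = abundance *
                      depth[match(sample[1], samples)] *
                      stats::rlnorm(dplyr::n(), 0, noise_sd)) |>
      dplyr::ungroup() |>
      dplyr::select(sample, model_id, coverage)
    list(ab = ab, cov = cov)
  })
  taxonomy <- templates[, c("model_id", "phylum", "family", "genus",
                            "species")]
  list(coverage = out$cov,
       taxonomy = taxonomy,
       ground_truth = list(abundances = out$ab, seed = as.integer(seed),
                           dirichlet_alpha = dirichlet_alpha,
                           noise_sd = noise_sd))
}

#' Synthetic food database fixture
#'
#' Bundles the transcribed national food-intake table (grams/day for the
#' most consumed food items, with the matched/unmatched composition-source
#' flag) with a synthetic composition database covering every template
#' substrate, the fixture molecular weights, and the dietary reference
#' ranges. Matched foods draw their composition from the primary database;
#' a manual database covers several traditional foods without a primary
#' entry. The composition values are fixed fixtures; `seed` is recorded
#' for interface uniformity with the other generators.
#'
#' @param seed integer recorded in the output.
#' @return list: `intake`, `composition` (a [food_composition()]),
#'   `molecular_weights`, `dri`, `seed`.
#' @export
make_food_db <- function(seed = 1L) {
  intake <- readr::read_tsv(
    system.file("extdata", "thai_food_intake.tsv", package = "gutflux"),
    show_col_types = FALSE)
  macros <- fixture_macros()
  nutrients <- fixture_nutrients(macros)
  list(intake = intake,
       composition = food_composition(nutrients, macros),
       molecular_weights = fixture_molecular_weights(),
       dri = dri_reference(),
       seed = as.integer(seed))
}

## plausible g per 100 g edible portion; "manual" rows stand in for a
## locally curated composition source for foods absent from the primary db
fixture_macros <- function() {
  tibble::tribble(
    ~food,                          ~carbohydrate, ~fat, ~protein, ~alcohol, ~source,
    "Rice",                          28.0,  0.3,  2.7, 0, "primary",
    "Sandwich",                      35.0, 10.0, 10.0, 0, "primary",
    "Sweet potato",                  20.0,  0.1,  1.6, 0, "primary",
    "Peanuts",                       16.0, 49.0, 26.0, 0, "primary",
    "Cowpeas",                       21.0,  0.5,  8.0, 0, "primary",
    "Mushrooms",                      3.3,  0.3,  3.1, 0, "primary",
    "Pickled cabbage",                4.0,  0.1,  1.2, 0, "primary",
    "Watermelon",                     7.6,  0.2,  0.6, 0, "primary",
    "Snacks, banana chips",          50.0, 20.0,  2.3, 0, "primary",
    "Egg",                            1.1,  9.5, 12.6, 0, "primary",
    "Pork",                           0.0, 14.0, 27.0, 0, "primary",
    "Fish, tilapia",                  0.0,  1.7, 20.0, 0, "primary",
    "Fish, mackerel",                 0.0, 13.9, 19.0, 0, "primary",
    "Milk",                           4.8,  3.3,  3.2, 0, "primary",
    "Ice cream",                     24.0, 11.0,  3.5, 0, "primary",
    "Beer",                           3.6,  0.0,  0.5, 3.9, "primary",
    "Snacks, potato chips",          50.0, 30.0,  7.0, 0, "primary",
    "Sugar",                        100.0,  0.0,  0.0, 0, "primary",
    "Oil, palm",                      0.0,100.0,  0.0, 0, "primary",
    "Pork meatball",                  3.8, 10.0,  8.8, 0, "manual",
    "Insect, cricket",                5.0,  5.5, 20.0, 0, "manual",
    "Thai dessert (Khao Tom Mud)",   20.0,  4.0,  3.0, 0, "manual",
    "Fish sauce",                     3.6,  0.0,  5.0, 0, "manual",
    "Chicken essence",                0.5,  0.0,  8.0, 0, "manual")
}

## metabolite mg per 100 g: glucose-equivalents as 90% of carbohydrate,
## valine as 6% of protein -- toy allocations covering every template
## substrate so that synthetic communities are feasible on the fixture diet
fixture_nutrients <- function(macros) {
  macros |>
    dplyr::rowwise() |>
    dplyr::reframe(tibble::tibble(
      food = food,
      metabolite = c("glc", "val"),
      mg_per_100g = c(carbohydrate * 1000 * 0.9, protein * 1000 * 0.06),
      source = source)) |>
    dplyr::filter(mg_per_100g > 0)
}

#' The fixture diet and its supplement arms
#'
#' Builds the base diet from the bundled intake and composition fixtures
#' and, mirroring the intervention design, a placebo arm (base + 10 g/day
#' maltodextrin) and a prebiotic arm (base + 5 g/day MOS + 5 g/day
#' maltodextrin).
#'
#' @param db a [make_food_db()] result.
#' @return named list of three `diet_spec`s: `base`, `placebo`,
#'   `prebiotic`.
#' @export
fixture_diets <- function(db = make_food_db()) {
  base <- suppressWarnings(
    build_diet_fluxes(db$intake, db$composition, db$molecular_weights,
                      name = "thai_fixture"))
  placebo <- add_supplement(base, c(mdx = 10),
                            molecular_weights = db$molecular_weights,
                            name = "placebo")
  prebiotic <- add_supplement(base, c(mos = 5, mdx = 5),
                              molecular_weights = db$molecular_weights,
                              name = "prebiotic")
  list(base = base, placebo = placebo, prebiotic = prebiotic)
}
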
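# Shared fixtures: hand-built toy communities with closed-form optima, and
# the standard synthetic cohort setup.

# 8-reaction single-taxon chain community: glucose import (<= 10 mmol/day),
# fermentation glc -> 2 ac, growth 0.1 glc -> biomass, acetate fecal export,
# community biomass in [bio_lb, bio_ub], coupling on member reactions.
toy_chain_community <- function(c_factor = 400, u_slack = 0,
                                bio_lb = 0.4, bio_ub = 1,
                                glc_import = 10) {
  mets <- metabolite(
    c("glc__u", "ac__u", "t1__glc__e", "t1__ac__e", "t1__bm__c",
      "community_biomass"),
    compartment = c("u", "u", "e", "e", "c", "u"))
  rxns <- dplyr::bind_rows(
    reaction("EX_glc__d", c(glc__u = -1), -glc_import, 0, "exchange"),
    reaction("t1__IEX_glc", c(t1__glc__e = -1, glc__u = 1), -1e6, 1e6,
             "transport"),
    reaction("t1__FERM", c(t1__glc__e = -1, t1__ac__e = 2), 0, 1e6),
    reaction("t1__BIO", c(t1__glc__e = -0.1, t1__bm__c = 1), 0, 1e6,
             "biomass"),
    reaction("t1__IEX_ac", c(t1__ac__e = -1, ac__u = 1), -1e6, 1e6,
             "transport"),
    reaction("EX_ac__fe", c(ac__u = -1), 0, 1e6, "exchange"),
    reaction("community_biomass", c(t1__bm__c = -1, community_biomass = 1),
             0, 1e6, "community_biomass"),
    reaction("EX_community_biomass", c(community_biomass = -1),
             bio_lb, bio_ub, "exchange"))
  structure(
    list(model_id = "toy_chain",
         taxonomy = list(phylum = NA, family = NA, genus = NA, species = NA),
         metabolites = mets, reactions = rxns,
         biomass_reaction_id = "community_biomass",
         members = tibble::tibble(
           tag = "t1", model_id = "t1", abundance = 1,
           biomass_reaction_id = "t1__BIO", biomass_metabolite = "t1__bm__c",
           phylum = NA_character_, family = NA_character_,
           genus = "Toyella", species = "Toyella unica"),
         diet_name = "toy",
         coupling = tibble::tibble(
           reaction_id = c("t1__IEX_glc", "t1__FERM", "t1__IEX_ac"),
           biomass_reaction_id = "t1__BIO", c = c_factor, u = u_slack)),
    class = c("community_model", "taxon_model"))
}

# 7-reaction couplings-free toy with two alternative fermentation routes and
# a glucose pass-through path (degenerate optima on purpose)
toy_tworoute_model <- function(glc_import = 10) {
  mets <- metabolite(c("glc__u", "ac__u", "glc__e", "ac__e"),
                     compartment = c("u", "u", "e", "e"))
  rxns <- dplyr::bind_rows(
    reaction("EX_glc__d", c(glc__u = -1), -glc_import, 0, "exchange"),
    reaction("IEX_glc", c(glc__e = -1, glc__u = 1), -1e6, 1e6, "transport"),
    reaction("FERM1", c(glc__e = -1, ac__e = 2), 0, 1e6),
    reaction("FERM2", c(glc__e = -1, ac__e = 1.5), 0, 1e6),
    reaction("IEX_ac", c(ac__e = -1, ac__u = 1), -1e6, 1e6, "transport"),
    reaction("EX_ac__fe", c(ac__u = -1), 0, 1e6, "exchange"),
    reaction("EX_glc__fe", c(glc__u = -1), 0, 1e6, "exchange"))
  structure(
    list(model_id = "toy_tworoute",
         taxonomy = list(phylum = NA, family = NA, genus = NA, species = NA),
         metabolites = mets, reactions = rxns,
         biomass_reaction_id = NULL, coupling = NULL),
    class = "taxon_model")
}

# Pass-through toy: growth consumes a dedicated amino-acid precursor so the
# fermentation substrate passes through untouched by biomass demands.
# Hand LP: fecal ac max = 2 * glc import; glc nets to zero secretion.
toy_passthrough_community <- function(glc_import = 10, aa_import = 1,
                                      c_factor = 400, u_slack = 0) {
  tm <- taxon_model(
    "pass1",
    dplyr::bind_rows(
      metabolite(c("glc__e", "ac__e", "aa__e"), compartment = "e"),
      metabolite("bm__c", compartment = "c")),
    dplyr::bind_rows(
      reaction("FERM", c(glc__e = -1, ac__e = 2), 0, 1e6),
      reaction("BIOMASS", c(aa__e = -1, bm__c = 1), 0, 1e6, "biomass"),
      reaction("DM_bm", c(bm__c = -1), 0, 1e6, "exchange"),
      reaction("EX_glc__e", c(glc__e = -1), -1e6, 1e6, "exchange"),
      reaction("EX_ac__e", c(ac__e = -1), -1e6, 1e6, "exchange"),
      reaction("EX_aa__e", c(aa__e = -1), -1e6, 1e6, "exchange")),
    "BIOMASS",
    taxonomy = list(phylum = "P", family = "F", genus = "Passerella",
                    species = "Passerella sola"))
  cm <- build_community(list(tm), c(pass1 = 1),
                        coupling = coupling_config(c_factor, u_slack))
  diet <- structure(tibble::tibble(metabolite = c("glc", "aa"),
                                   mmol_per_day = c(glc_import, aa_import)),
                    diet_name = "passthrough",
                    class = c("diet_spec", "tbl_df", "tbl", "data.frame"))
  apply_diet(cm, diet)
}

# standard synthetic setup used across tests
fixture_models <- function() {
  tt <- taxon_templates()
  models <- lapply(seq_len(nrow(tt)), function(i) make_taxon_model(tt[i, ]))
  stats::setNames(models, tt$model_id)
}

fixture_community <- function(diet = NULL, models = fixture_models(),
                              ...) {
  ab <- stats::setNames(rep(1 / length(models), length(models)),
                        names(models))
  cm <- build_community(models, ab, ...)
  if (!is.null(diet)) cm <- apply_diet(cm, diet)
  cm
}
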
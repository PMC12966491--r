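# two exchange-free 4-reaction toys sharing 2 extracellular metabolites
four_rxn_member <- function(id, genus = "G") {
  taxon_model(
    id,
    dplyr::bind_rows(metabolite(c("glc__e", "ac__e"), compartment = "e"),
                     metabolite(c("x__c", "bm__c"), compartment = "c")),
    dplyr::bind_rows(
      reaction("UPT", c(glc__e = -1, x__c = 1), 0, 1e6),
      reaction("FERM", c(x__c = -1, ac__e = 2), 0, 1e6),
      reaction("MAINT", c(x__c = -0.1), 0, 1e6),
      reaction("BIOMASS", c(x__c = -1, bm__c = 1), 0, 1e6, "biomass")),
    "BIOMASS",
    taxonomy = list(phylum = "P", family = "F", genus = genus,
                    species = paste(genus, "sp")))
}

test_that("tagging namespaces ids exactly once and collisions error", {
  m <- four_rxn_member("t1")
  tagged <- tag_taxon_model(m, "t1")
  expect_true(all(startsWith(tagged$reactions$id, "t1__")))
  expect_true(all(startsWith(tagged$metabolites$id, "t1__")))
  expect_equal(nrow(tagged$reactions), 4)

  t2 <- tag_taxon_model(m, "t2")
  expect_length(intersect(tagged$reactions$id, t2$reactions$id), 0)

  expect_error(build_community(list(four_rxn_member("a"),
                                    four_rxn_member("a")),
                               c(a = 0.5, a = 0.5)),
               "duplicate")
})

test_that("community biomass uses abundances as stoichiometric weights", {
  single <- build_community(list(four_rxn_member("solo")), c(solo = 1))
  s <- single$reactions$stoichiometry[[
    match("community_biomass", single$reactions$id)]]
  expect_equal(s[["solo__bm__c"]], -1)

  duo <- build_community(list(four_rxn_member("a"), four_rxn_member("b")),
                         c(a = 0.7, b = 0.3))
  s2 <- duo$reactions$stoichiometry[[
    match("community_biomass", duo$reactions$id)]]
  expect_equal(s2[["a__bm__c"]], -0.7)
  expect_equal(s2[["b__bm__c"]], -0.3)
  expect_equal(sum(duo$members$abundance), 1)

  # bad abundance vectors are rejected
  expect_error(build_community(list(four_rxn_member("a")), c(a = 0.5)),
               "sum to 1")
  expect_error(build_community(list(four_rxn_member("a"),
                                    four_rxn_member("b")),
                               c(a = 1.2, b = -0.2)),
               "positive")
  expect_error(build_community(list(), numeric(0)), "no member")
})

test_that("the scaffold has the expected reaction count and conserves mass", {
  duo <- build_community(list(four_rxn_member("a"), four_rxn_member("b")),
                         c(a = 0.5, b = 0.5))
  # 8 tagged + 2 transfers/taxon (2 shared e-metabolites) + 2 diet + 2 fecal
  # + community biomass + its exchange = 18
  expect_equal(nrow(duo$reactions), 8 + 4 + 2 + 2 + 1 + 1)
  expect_equal(nrow(validate_model(duo)), 0)

  # transfer/diet/fecal reactions conserve their metabolite 1:1
  scaffold <- duo$reactions[grepl("IEX|EX_", duo$reactions$id), ]
  for (s in scaffold$stoichiometry)
    expect_true(all(abs(s) == 1) ||
                  identical(names(s), "community_biomass"))

  # community biomass bounds default to [0.4, 1] on the exchange
  i <- match("EX_community_biomass", duo$reactions$id)
  expect_equal(duo$reactions$lower_bound[i], 0.4)
  expect_equal(duo$reactions$upper_bound[i], 1)
})

test_that("coupling rows bound member fluxes by c * biomass + u", {
  toy <- toy_chain_community(c_factor = 400, u_slack = 0)
  # fix the member biomass at 0.5 -> |v| <= 200 for coupled reactions
  i <- match("EX_community_biomass", toy$reactions$id)
  toy$reactions$lower_bound[i] <- 0.5
  toy$reactions$upper_bound[i] <- 0.5
  toy$reactions$lower_bound[match("EX_glc__d", toy$reactions$id)] <- -1e6
  fva <- run_fva(toy, c("t1__IEX_ac", "t1__FERM"))
  # the acetate transfer hits its own cap c * v_bio = 200 exactly; the
  # fermentation flux is then held at 100 by the 1:2 stoichiometry
  expect_equal(fva$maximum[1], 200, tolerance = 1e-6)
  expect_equal(fva$maximum[2], 100, tolerance = 1e-6)
  expect_true(all(abs(fva$minimum) <= 200 + 1e-6))

  # slack-only regime: biomass forced to 0, u = 5 -> |v| <= 5; the
  # acetate transfer binds at 5, capping fermentation at 2.5
  slack <- toy_chain_community(u_slack = 5, bio_lb = 0, bio_ub = 0)
  fva_s <- run_fva(slack, c("t1__IEX_ac", "t1__FERM"))
  expect_equal(fva_s$maximum[1], 5, tolerance = 1e-6)
  expect_equal(fva_s$maximum[2], 2.5, tolerance = 1e-6)
  expect_gte(min(fva_s$minimum), -5 - 1e-6)
})

test_that("zero growth with zero slack collapses all member fluxes", {
  collapsed <- toy_chain_community(u_slack = 0, bio_lb = 0, bio_ub = 0)
  fva <- run_fva(collapsed, collapsed$reactions$id)
  member <- grepl("^t1__", fva$reaction)
  expect_true(all(abs(fva$minimum[member]) < 1e-6))
  expect_true(all(abs(fva$maximum[member]) < 1e-6))
})

test_that("diet application maps fluxes onto import bounds", {
  cm <- fixture_community()
  diet <- gutflux:::new_diet_spec(
    tibble::tibble(metabolite = c("glc", "ghost"),
                   mmol_per_day = c(10, 1)), name = "t")
  expect_warning(cm2 <- apply_diet(cm, diet), "ghost")
  i <- match("EX_glc__d", cm2$reactions$id)
  expect_equal(cm2$reactions$lower_bound[i], -10)
  expect_equal(cm2$reactions$upper_bound[i], 0)
  # metabolites absent from the diet stay closed on the import side
  j <- match("EX_but__d", cm2$reactions$id)
  expect_equal(cm2$reactions$lower_bound[j], 0)
  # unless gap-filled at the trace bound
  cm3 <- suppressWarnings(apply_diet(cm, diet, gap_fill = "val",
                                     trace = 0.25))
  expect_equal(cm3$reactions$lower_bound[
    match("EX_val__d", cm3$reactions$id)], -0.25)
  # fecal exchanges remain export-only
  fe <- grepl("__fe$", cm2$reactions$id)
  expect_true(all(cm2$reactions$lower_bound[fe] == 0))

  # starvation: empty diet + biomass requirement is infeasible, reported
  starved <- apply_diet(cm, gutflux:::new_diet_spec(
    tibble::tibble(metabolite = character(), mmol_per_day = numeric()),
    name = "empty"))
  expect_error(run_fva(starved, "EX_ac__fe"), "infeasible")
})

test_that("a single-taxon community mirrors the standalone optimum", {
  # member alone (diet-constrained): max acetate export = 2 * (glc - growth)
  tm <- four_rxn_member("solo")
  cm <- build_community(list(tm), c(solo = 1))
  diet <- gutflux:::new_diet_spec(
    tibble::tibble(metabolite = "glc", mmol_per_day = 10), name = "g")
  cm <- apply_diet(cm, diet)
  fva <- run_fva(cm, "EX_ac__fe")
  # glucose left after the mandatory minimum growth (0.4 * 1 biomass unit)
  expect_equal(fva$maximum, 2 * (10 - 0.4), tolerance = 1e-6)
})
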
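make_chain_model <- function(glc_lb = -10) {
  taxon_model(
    "chain",
    dplyr::bind_rows(metabolite("glc__e", compartment = "e"),
                     metabolite("ac__e", compartment = "e"),
                     metabolite("bm__c", compartment = "c")),
    dplyr::bind_rows(
      reaction("EX_glc__e", c(glc__e = -1), glc_lb, 1e6, "exchange"),
      reaction("v1", c(glc__e = -1, ac__e = 2), 0, 1e6),
      reaction("EX_ac__e", c(ac__e = -1), 0, 1e6, "exchange"),
      reaction("BIOMASS", c(glc__e = -0.01, bm__c = 1), 0, 1e6, "biomass"),
      reaction("DM_bm", c(bm__c = -1), 0, 1e6, "exchange")),
    "BIOMASS")
}

test_that("validation reports each violated invariant and only those", {
  expect_equal(nrow(validate_model(make_chain_model())), 0)

  bad_bounds <- make_chain_model()
  bad_bounds$reactions$lower_bound[2] <- 5
  bad_bounds$reactions$upper_bound[2] <- 1
  v <- validate_model(bad_bounds)
  expect_equal(v$check, "bounds")
  expect_equal(v$object, "v1")

  dup <- make_chain_model()
  dup$reactions <- dplyr::bind_rows(dup$reactions, dup$reactions[2, ])
  expect_equal(sum(validate_model(dup)$check == "reaction_id_unique"), 1)

  ghost <- make_chain_model()
  ghost$reactions$stoichiometry[[2]] <- c(glc__e = -1, phantom__c = 1)
  expect_equal(validate_model(ghost)$check, "stoichiometry_refs")

  fat_exchange <- make_chain_model()
  fat_exchange$reactions$stoichiometry[[1]] <- c(glc__e = -1, ac__e = 1)
  expect_equal(validate_model(fat_exchange)$check, "exchange_arity")

  no_bio <- make_chain_model()
  no_bio$biomass_reaction_id <- "nope"
  expect_equal(validate_model(no_bio)$check, "biomass_reaction")
})

test_that("flux balance optima match hand-derived values on the chain", {
  m <- make_chain_model(glc_lb = -10)
  # all glucose fermented: v_EX_ac = 2 * uptake = 20
  r <- solve_lp(m, "EX_ac__e", "max")
  expect_equal(r$status, "optimal")
  expect_equal(r$objective_value, 20, tolerance = 1e-6)
  # steady state and bounds hold at the optimum
  S <- gutflux:::model_smatrix(m)
  expect_lt(max(abs(S %*% r$fluxes)), 1e-6)
  expect_true(all(r$fluxes >= m$reactions$lower_bound - 1e-6))
  expect_true(all(r$fluxes <= m$reactions$upper_bound + 1e-6))

  # closing the import forces zero product
  r0 <- solve_lp(make_chain_model(glc_lb = 0), "EX_ac__e", "max")
  expect_equal(r0$objective_value, 0, tolerance = 1e-9)

  # forced export of a sourceless metabolite is infeasible
  stuck <- make_chain_model(glc_lb = 0)
  stuck$reactions$lower_bound[3] <- 1
  stuck$reactions$upper_bound[3] <- 2
  expect_equal(solve_lp(stuck, "EX_ac__e", "max")$status, "infeasible")

  # extra constraints are honored
  capped <- solve_lp(m, "EX_ac__e", "max",
                     extra_constraints = list(
                       list(coefs = c(v1 = 1), dir = "<=", rhs = 3)))
  expect_equal(capped$objective_value, 6, tolerance = 1e-6)
})

test_that("JSON and SBML round trips preserve the model exactly", {
  m <- make_taxon_model("butyrogen")
  m$metabolites$name[1] <- "glucose (α-D) 中"   # unicode survives
  j <- withr::local_tempfile(fileext = ".json")
  x <- withr::local_tempfile(fileext = ".xml")
  j2 <- withr::local_tempfile(fileext = ".json")

  save_model(m, j)
  mj <- load_model(j)
  expect_equal(mj$reactions$stoichiometry, m$reactions$stoichiometry)
  expect_equal(mj$reactions$lower_bound, m$reactions$lower_bound)
  expect_equal(mj$metabolites$name, m$metabolites$name)
  expect_equal(mj$taxonomy, m$taxonomy)

  save_model(mj, x, format = "sbml")
  mx <- load_model(x)
  expect_equal(mx$reactions$kind, m$reactions$kind)
  expect_equal(mx$biomass_reaction_id, m$biomass_reaction_id)
  save_model(mx, j2)
  mj2 <- load_model(j2)
  expect_equal(mj2$reactions$lower_bound, m$reactions$lower_bound)
  expect_equal(mj2$reactions$upper_bound, m$reactions$upper_bound)
  # stoichiometry is a map: compare it independent of entry order
  norm <- function(s) lapply(s, function(x) x[order(names(x))])
  expect_equal(norm(mj2$reactions$stoichiometry),
               norm(m$reactions$stoichiometry))
})

test_that("loader errors name the offending element", {
  p <- withr::local_tempfile(fileext = ".json")
  writeLines("{not json", p)
  expect_error(load_model(p), "cannot parse")

  writeLines(jsonlite::toJSON(list(model_id = "x"), auto_unbox = TRUE), p)
  expect_error(load_model(p), "metabolites")

  # reaction citing an undeclared metabolite fails validation
  writeLines(jsonlite::toJSON(list(
    model_id = "x",
    metabolites = list(list(id = "a__c", compartment = "c")),
    reactions = list(list(id = "r1", stoichiometry = list(ghost__c = 1),
                          lower_bound = 0, upper_bound = 1,
                          kind = "biomass")),
    biomass_reaction_id = "r1"), auto_unbox = TRUE), p)
  expect_error(load_model(p), "undeclared metabolite")

  expect_error(load_model("/nonexistent/file.json"), "no such file")

  # minimal valid model: 1 metabolite, 1 exchange, 1 biomass
  writeLines(jsonlite::toJSON(list(
    model_id = "mini",
    metabolites = list(list(id = "x__c", compartment = "c")),
    reactions = list(
      list(id = "BIO", stoichiometry = list(x__c = 1),
           lower_bound = 0, upper_bound = 10, kind = "biomass"),
      list(id = "EX_x", stoichiometry = list(x__c = -1), kind = "exchange")),
    biomass_reaction_id = "BIO"), auto_unbox = TRUE), p)
  mini <- load_model(p)
  expect_equal(nrow(mini$reactions), 2)
  # bounds absent from the file default to +/- 1e6
  expect_equal(mini$reactions$lower_bound[2], -1e6)
  expect_equal(mini$reactions$upper_bound[2], 1e6)
})
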
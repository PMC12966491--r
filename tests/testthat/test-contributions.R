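contrib_setup <- function(diet_name = "prebiotic") {
  models <- fixture_models()
  diets <- fixture_diets()
  cm <- fixture_community(diets[[diet_name]], models)
  list(models = models, diets = diets, cm = cm)
}

test_that("contribution ranges have the right signs and supports", {
  s <- contrib_setup("base")
  ct <- compute_contributions(s$cm, c("ac", "but", "isobut", "mos"))
  # a taxon without the pathway contributes the degenerate (0, 0) range
  no_path <- ct[ct$model_id == "syn_propionogen" & ct$metabolite == "but", ]
  expect_equal(no_path$minimum, 0)
  expect_equal(no_path$maximum, 0)
  # the isobutyrate producer is the only taxon with a positive maximum
  iso <- ct[ct$metabolite == "isobut", ]
  expect_true(all(iso$maximum[iso$model_id != "syn_isobutyrogen"] < 1e-9))
  expect_gt(iso$maximum[iso$model_id == "syn_isobutyrogen"], 0.01)
  # on a MOS-free diet nothing moves MOS
  expect_true(all(abs(ct$maximum[ct$metabolite == "mos"]) < 1e-9))

  # unknown targets are skipped with a warning
  expect_warning(ct2 <- compute_contributions(s$cm, c("ac", "ghost")),
                 "ghost")
  expect_setequal(unique(ct2$metabolite), "ac")
})

test_that("a sole producer's maximum equals the community secretion max", {
  # single-producer community: only the butyrogen can make butyrate
  models <- fixture_models()[c("syn_acetogen", "syn_butyrogen")]
  diets <- fixture_diets()
  cm <- build_community(models, c(syn_acetogen = 0.5, syn_butyrogen = 0.5))
  cm <- suppressWarnings(apply_diet(cm, diets$base))
  ct <- compute_contributions(cm, "but")
  community_max <- run_fva(cm, "EX_but__fe")$maximum
  expect_equal(ct$maximum[ct$model_id == "syn_butyrogen"], community_max,
               tolerance = 1e-6)
  expect_equal(ct$maximum[ct$model_id == "syn_acetogen"], 0)
})

test_that("identical producers at equal abundance contribute symmetrically", {
  m1 <- make_taxon_model("acetogen")
  m2 <- make_taxon_model("acetogen")
  m2$model_id <- "syn_acetogen_b"
  diets <- fixture_diets()
  cm <- build_community(list(m1, m2),
                        c(syn_acetogen = 0.5, syn_acetogen_b = 0.5))
  cm <- suppressWarnings(apply_diet(cm, diets$base))
  ct <- compute_contributions(cm, "ac")
  expect_equal(ct$maximum[1], ct$maximum[2], tolerance = 1e-6)
})

test_that("member secretion maxima bound the community maximum", {
  s <- contrib_setup("base")
  ct <- compute_contributions(s$cm, c("ac", "ppa", "but"))
  for (b in unique(ct$metabolite)) {
    member_sum <- sum(pmax(ct$maximum[ct$metabolite == b], 0))
    comm <- run_fva(s$cm, paste0("EX_", b, "__fe"))$maximum
    expect_gte(member_sum + 1e-6, comm)
  }
})

test_that("shared-substrate uptake respects the community import bound", {
  # two MOS utilizers competing for one MOS pool
  m1 <- make_taxon_model("mos_utilizer")
  m2 <- make_taxon_model("mos_utilizer")
  m2$model_id <- "syn_mos_b"
  diets <- fixture_diets()
  cm <- build_community(list(m1, m2),
                        c(syn_mos_utilizer = 0.5, syn_mos_b = 0.5))
  cm <- suppressWarnings(apply_diet(cm, diets$prebiotic))
  ct <- compute_contributions(cm, "mos")
  mos_bound <- 5000 / 504.44
  # each alone can take (almost) the whole pool, but any feasible joint
  # assignment is capped by the import bound; the FVA minima certify each
  # member's individual uptake never exceeds the pool
  expect_true(all(-ct$minimum <= mos_bound + 1e-6))
  expect_gt(sum(-ct$minimum), 0)
})

test_that("producer calls recover the per-sample boundary arithmetic", {
  mk <- function(sample, taxon, max) tibble::tibble(
    sample = sample, model_id = taxon, taxon = taxon, metabolite = "ac",
    minimum = 0, maximum = max)
  # present in half the samples at twice the threshold -> mean == threshold
  ct <- gutflux:::new_contribution_table(dplyr::bind_rows(
    mk("s1", "GX", 0.02), mk("s2", "GX", 0)))
  p <- identify_producers(ct, threshold = 0.01)
  expect_true("GX" %in% p$taxon)
  # threshold above every mean -> empty set
  p2 <- identify_producers(ct, threshold = 0.05)
  expect_equal(nrow(p2), 0)
  # ordering of rows must not matter
  ct_rev <- gutflux:::new_contribution_table(
    dplyr::arrange(ct, dplyr::desc(sample)))
  expect_equal(identify_producers(ct_rev, threshold = 0.01)$taxon, p$taxon)
})

test_that("responder reports carry mean/sd/min-max and need the substrate", {
  s <- contrib_setup("prebiotic")
  ct <- compute_contributions(s$cm, "mos")
  ranked <- aggregate_by_rank(ct, tibble::tibble(
    model_id = s$cm$members$model_id, genus = s$cm$members$genus,
    species = s$cm$members$species, family = s$cm$members$family,
    phylum = s$cm$members$phylum), "genus")
  rep <- identify_responders(ranked, "mos", diet = s$diets$prebiotic)
  expect_equal(rep$taxon, "Mannovorax")
  expect_equal(rep$mean_uptake, 5000 / 504.44, tolerance = 1e-6)
  expect_equal(rep$sd_uptake, 0, tolerance = 1e-9)
  expect_true(rep$qualifies)

  # substrate missing from the provided diet is a hard error
  expect_error(identify_responders(ranked, "mos", diet = s$diets$base),
               "not part of the supplied diet")

  # placebo arm: no MOS import, empty responder table
  cmp <- fixture_community(s$diets$placebo, s$models)
  ctp <- compute_contributions(cmp, "mos")
  repp <- identify_responders(ctp, "mos")
  expect_equal(nrow(repp), 0)
})

test_that("rank aggregation adds contribution intervals", {
  ct <- gutflux:::new_contribution_table(tibble::tibble(
    sample = "s1",
    model_id = c("m1", "m2", "m3"),
    taxon = NA_character_,
    metabolite = "ac",
    minimum = c(-1, 0, 0),
    maximum = c(3, 2, 1)))
  tax <- tibble::tibble(model_id = c("m1", "m2", "m3"),
                        genus = c("G1", "G1", "G2"))
  agg <- aggregate_by_rank(ct, tax, "genus")
  expect_equal(agg$maximum[agg$taxon == "G1"], 5)
  expect_equal(agg$minimum[agg$taxon == "G1"], -1)
  expect_equal(agg$maximum[agg$taxon == "G2"], 1)
  expect_error(aggregate_by_rank(ct, tax[1:2, ], "genus"), "m3")
})
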
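toy_composition <- function() {
  food_composition(
    nutrients = tibble::tribble(
      ~food,     ~metabolite, ~mg_per_100g, ~source,
      "RiceToy", "glc",        18016,       "primary",
      "RiceToy", "val",        100,         "primary",
      "FishToy", "val",        2343,        "manual"),
    macros = tibble::tribble(
      ~food,     ~carbohydrate, ~fat, ~protein, ~alcohol,
      "RiceToy",  100,           10,   20,       0,
      "FishToy",  0,             5,    20,       0))
}

toy_mw <- c(glc = 180.16, val = 117.15, mos = 504.44, mdx = 504.44)

test_that("mass-to-flux conversion matches hand unit arithmetic", {
  intake <- tibble::tibble(food = "RiceToy", g_per_day = 100)
  d <- build_diet_fluxes(intake, toy_composition(), toy_mw)
  # 100 g/day * 18016 mg/100g = 18.016 g/day; / 180.16 g/mol * 1000 = 100
  expect_equal(d$mmol_per_day[d$metabolite == "glc"], 100, tolerance = 1e-12)
  expect_equal(attr(d, "provenance")$composition_source, "primary_db")

  empty <- build_diet_fluxes(tibble::tibble(food = character(),
                                            g_per_day = numeric()),
                             toy_composition(), toy_mw)
  expect_equal(nrow(empty), 0)

  # manual and primary sources combine by summation
  both <- build_diet_fluxes(
    tibble::tibble(food = c("RiceToy", "FishToy"), g_per_day = c(100, 50)),
    toy_composition(), toy_mw)
  expect_equal(both$mmol_per_day[both$metabolite == "val"],
               100 * 1 / 117.15 + 50 * 23.43 / 117.15, tolerance = 1e-12)

  expect_error(
    build_diet_fluxes(intake, toy_composition(), c(val = 117.15)),
    "molecular weight.*glc")
  expect_warning(
    build_diet_fluxes(tibble::tibble(food = "Mystery", g_per_day = 10),
                      toy_composition(), toy_mw),
    "Mystery")
})

test_that("diet conversion is linear and additive over intake tables", {
  comp <- toy_composition()
  i1 <- tibble::tibble(food = c("RiceToy", "FishToy"),
                       g_per_day = c(120, 40))
  i2 <- tibble::tibble(food = c("RiceToy"), g_per_day = c(33))
  d1 <- build_diet_fluxes(i1, comp, toy_mw)
  # scaling all intakes by k scales every flux by k
  k <- 2.5
  dk <- build_diet_fluxes(dplyr::mutate(i1, g_per_day = g_per_day * k),
                          comp, toy_mw)
  expect_equal(dk$mmol_per_day, k * d1$mmol_per_day, tolerance = 1e-12)
  # converting merged tables equals summing separate conversions
  d2 <- build_diet_fluxes(i2, comp, toy_mw)
  dm <- build_diet_fluxes(dplyr::bind_rows(i1, i2), comp, toy_mw)
  merged <- dplyr::full_join(tibble::as_tibble(d1), tibble::as_tibble(d2),
                             by = "metabolite") |>
    dplyr::mutate(total = dplyr::coalesce(mmol_per_day.x, 0) +
                    dplyr::coalesce(mmol_per_day.y, 0)) |>
    dplyr::arrange(metabolite)
  expect_equal(dm$mmol_per_day, merged$total, tolerance = 1e-12)
})

test_that("macronutrient profile reproduces hand arithmetic and scales", {
  intake <- tibble::tibble(food = "RiceToy", g_per_day = 100)
  p <- macronutrient_profile(intake, toy_composition())
  # 100 g C + 10 g F + 20 g P -> 400 + 90 + 80 = 570 kcal
  expect_equal(p$energy_kcal, 570)
  expect_equal(p$pct_carbohydrate, 100 * 400 / 570, tolerance = 1e-12)
  expect_equal(p$pct_carbohydrate + p$pct_fat + p$pct_protein +
                 p$pct_alcohol, 100, tolerance = 1e-9)

  doubled <- macronutrient_profile(
    dplyr::mutate(intake, g_per_day = g_per_day * 2), toy_composition())
  expect_equal(doubled$energy_kcal, 2 * p$energy_kcal)
  expect_equal(doubled$pct_fat, p$pct_fat, tolerance = 1e-12)

  expect_error(
    macronutrient_profile(tibble::tibble(food = "RiceToy", g_per_day = 0),
                          toy_composition()),
    "undefined")
})

test_that("reference-intake verdicts are pure arithmetic on (value, range)", {
  mk <- function(e, c, f, p) tibble::tibble(
    energy_kcal = e, pct_carbohydrate = c, pct_fat = f, pct_protein = p,
    pct_alcohol = 100 - c - f - p)
  v <- function(rep, chk) rep$verdict[rep$check == chk]

  rep <- validate_dri(mk(2295, 54.65, 23.66, 21.69))
  expect_equal(v(rep, "energy_kcal"), "within")
  expect_equal(v(rep, "pct_carbohydrate"), "within")
  expect_equal(v(rep, "pct_fat"), "within")
  expect_equal(v(rep, "pct_protein"), "above-but-below-caution")

  expect_equal(v(validate_dri(mk(1000, 50, 25, 12)), "energy_kcal"), "below")
  expect_equal(v(validate_dri(mk(2000, 50, 25, 12)), "pct_protein"),
               "within")
  expect_equal(v(validate_dri(mk(2000, 50, 25, 35)), "pct_protein"),
               "above")

  # property: verdict consistent with arithmetic for random profiles
  set.seed(3)
  ref <- dri_reference()
  for (i in 1:50) {
    prof <- mk(runif(1, 800, 3200), runif(1, 20, 80), runif(1, 5, 50),
               runif(1, 5, 40))
    rp <- validate_dri(prof)
    for (j in seq_len(nrow(rp))) {
      x <- rp$observed[j]
      expected <- if (x < rp$lower[j]) "below"
      else if (x <= rp$upper[j]) "within"
      else if (!is.na(rp$caution[j]) && x < rp$caution[j])
        "above-but-below-caution"
      else "above"
      expect_equal(rp$verdict[j], expected)
    }
  }
})

test_that("supplements convert g/day to mmol/day on top of the base diet", {
  base <- build_diet_fluxes(tibble::tibble(food = "RiceToy",
                                           g_per_day = 100),
                            toy_composition(), toy_mw)
  expect_equal(nrow(add_supplement(base, c(mos = 0),
                                   molecular_weights = toy_mw)),
               nrow(base))

  plus <- add_supplement(base, c(mos = 5), molecular_weights = toy_mw)
  expect_equal(plus$mmol_per_day[plus$metabolite == "mos"],
               5000 / 504.44, tolerance = 1e-9)
  # base untouched
  expect_false("mos" %in% base$metabolite)

  placebo <- add_supplement(base, c(mdx = 10), molecular_weights = toy_mw,
                            name = "placebo")
  prebiotic <- add_supplement(base, c(mos = 5, mdx = 5),
                              molecular_weights = toy_mw, name = "prebiotic")
  diffs <- compare_diets(list(placebo = placebo, prebiotic = prebiotic))
  changed <- diffs$metabolite[diffs$placebo != diffs$prebiotic]
  expect_setequal(changed, c("mos", "mdx"))

  expect_error(add_supplement(base, c(unobtainium = 1),
                              molecular_weights = toy_mw),
               "unknown supplement")
})

test_that("diet comparison reports shared and above-threshold sets", {
  mk_diet <- function(name, ...) {
    fx <- c(...)
    gutflux:::new_diet_spec(
      tibble::tibble(metabolite = names(fx), mmol_per_day = unname(fx)),
      name = name)
  }
  d1 <- mk_diet("d1", A = 2, B = 0.5, C = 3)
  d2 <- mk_diet("d2", B = 2, C = 4, D = 1)

  self <- compare_diets(list(a = d1, b = d1))
  expect_true(all(self$shared))

  cmp <- compare_diets(list(d1 = d1, d2 = d2))
  expect_setequal(cmp$metabolite[cmp$shared], c("B", "C"))
  expect_equal(sum(cmp$shared), 2)
  expect_setequal(cmp$metabolite[cmp$exceeds_everywhere], "C")

  d3 <- mk_diet("d3", B = 1.2, C = 9)
  cmp3 <- compare_diets(list(d1, d2, d3))
  expect_setequal(cmp3$metabolite[cmp3$exceeds_everywhere], "C")
})
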
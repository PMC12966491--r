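#' Convert food intakes into metabolite uptake fluxes
#'
#' Implements the diet-to-flux translation at the head of the pipeline:
#' each food's daily intake (g/day) is combined with its composition
#' (mg of metabolite per 100 g edible portion) and the metabolite's
#' molecular weight to yield an uptake flux in mmol/day:
#' `flux(m) = sum_foods intake * (mg_per_100g / 100) / MW`.
#' Contributions from the primary and the manual composition sources are
#' summed. Foods with positive intake but no composition entry are retained
#' in the provenance attribute with zero contribution and flagged with a
#' warning.
#'
#' @param intake tibble with columns `food`, `g_per_day` (and optionally
#'   `sd_g_per_day`, `vmh_status`).
#' @param composition a [food_composition()] object.
#' @param molecular_weights named numeric vector, metabolite id -> g/mol.
#' @param name name given to the resulting diet.
#' @return a `diet_spec`: tibble with columns `metabolite`, `mmol_per_day`,
#'   carrying attributes `diet_name` and `provenance` (per-food source).
#' @export
build_diet_fluxes <- function(intake, composition, molecular_weights,
                              name = "diet") {
  stopifnot(all(c("food", "g_per_day") %in% names(intake)))
  if (any(intake$g_per_day < 0))
    stop("negative intake in foods: ",
         paste(intake$food[intake$g_per_day < 0], collapse = ", "),
         call. = FALSE)
  nutr <- composition$nutrients
  prov <- dplyr::mutate(
    intake[, c("food", "g_per_day")],
    composition_source = dplyr::case_when(
      food %in% nutr$food[nutr$source == "primary"] ~ "primary_db",
      food %in% nutr$food[nutr$source == "manual"] ~ "manual_db",
      TRUE ~ "unmatched"))
  unmatched <- prov$food[prov$composition_source == "unmatched" &
                           prov$g_per_day > 0]
  if (length(unmatched))
    warning("foods without composition data excluded from fluxes: ",
            paste(unmatched, collapse = ", "), call. = FALSE)

  joined <- dplyr::inner_join(intake[, c("food", "g_per_day")], nutr,
                              by = "food",
                              relationship = "many-to-many")
  fx <- if (nrow(joined) == 0L) {
    tibble::tibble(metabolite = character(), mmol_per_day = numeric())
  } else {
    miss_mw <- setdiff(unique(joined$metabolite), names(molecular_weights))
    if (length(miss_mw))
      stop("no molecular weight for metabolite(s): ",
           paste(miss_mw, collapse = ", "), call. = FALSE)
    joined |>
      dplyr::mutate(
        mmol = g_per_day * (mg_per_100g / 100) /
          molecular_weights[metabolite]) |>
      dplyr::group_by(metabolite) |>
      dplyr::summarise(mmol_per_day = sum(mmol), .groups = "drop") |>
      dplyr::filter(mmol_per_day > 0) |>
      dplyr::arrange(metabolite)
  }
  new_diet_spec(fx, name = name, provenance = prov)
}

new_diet_spec <- function(fluxes, name, provenance = NULL) {
  stopifnot(all(fluxes$mmol_per_day >= 0))
  structure(fluxes, diet_name = name, provenance = provenance,
            class = c("diet_spec", class(fluxes)))
}

#' Read / write a diet as two-column TSV
#'
#' The on-disk format is the one the simulation stage consumes: columns
#' `metabolite` and `mmol_per_day`.
#'
#' @param diet a `diet_spec`.
#' @param path file path.
#' @param name diet name used when reading.
#' @export
write_diet <- function(diet, path) {
  readr::write_tsv(tibble::as_tibble(diet)[, c("metabolite", "mmol_per_day")],
                   path)
  invisible(path)
}

#' @rdname write_diet
#' @export
read_diet <- function(path, name = basename(path)) {
  d <- readr::read_tsv(path, show_col_types = FALSE,
                       col_types = readr::cols(
                         metabolite = readr::col_character(),
                         mmol_per_day = readr::col_double()))
  new_diet_spec(d, name = name)
}

#' Energy and macronutrient profile of an intake table
#'
#' Computes total energy (kcal/day) and the percentage of energy from
#' carbohydrate, fat, protein and alcohol using per-gram energy factors
#' (Atwater 4/9/4 kcal/g with 7 kcal/g for alcohol by default).
#'
#' @inheritParams build_diet_fluxes
#' @param energy_factors named vector of kcal/g for `carbohydrate`, `fat`,
#'   `protein`, `alcohol`.
#' @return one-row tibble: `energy_kcal`, `pct_carbohydrate`, `pct_fat`,
#'   `pct_protein`, `pct_alcohol`.
#' @export
macronutrient_profile <- function(intake, composition,
                                  energy_factors = c(carbohydrate = 4,
                                                     fat = 9, protein = 4,
                                                     alcohol = 7)) {
  macros <- composition$macros
  j <- dplyr::inner_join(intake[, c("food", "g_per_day")], macros,
                         by = "food")
  grams <- vapply(names(energy_factors), function(m)
    sum(j[[m]] * j$g_per_day / 100), numeric(1))
  kcal <- grams * energy_factors
  total <- sum(kcal)
  if (total <= 0)
    stop("total energy is zero; macronutrient percentages are undefined",
         call. = FALSE)
  tibble::tibble(energy_kcal = total,
                 pct_carbohydrate = 100 * kcal[["carbohydrate"]] / total,
                 pct_fat = 100 * kcal[["fat"]] / total,
                 pct_protein = 100 * kcal[["protein"]] / total,
                 pct_alcohol = 100 * kcal[["alcohol"]] / total)
}

#' Default dietary reference intake ranges
#'
#' Reference ranges for daily energy and macronutrient energy shares used
#' by [validate_dri()]: energy 1500-2400 kcal/day, carbohydrate 45-65% of
#' energy, fat 20-35%, protein 10-15% with a 30% cautionary ceiling.
#'
#' @return tibble with columns `check`, `lower`, `upper`, `caution`.
#' @export
dri_reference <- function() {
  tibble::tibble(
    check = c("energy_kcal", "pct_carbohydrate", "pct_fat", "pct_protein"),
    lower = c(1500, 45, 20, 10),
    upper = c(2400, 65, 35, 15),
    caution = c(NA, NA, NA, 30))
}

#' Check a macronutrient profile against reference intake ranges
#'
#' Each quantity is compared to its reference range by plain arithmetic.
#' Checks with a cautionary ceiling (protein by default) get a three-way
#' verdict: values above the range but below the ceiling are flagged
#' `"above-but-below-caution"` rather than `"above"`.
#'
#' @param profile one-row tibble from [macronutrient_profile()].
#' @param reference tibble like [dri_reference()].
#' @return tibble with columns `check`, `observed`, `lower`, `upper`,
#'   `caution`, `verdict`.
#' @export
validate_dri <- function(profile, reference = dri_reference()) {
  stopifnot(all(reference$lower <= reference$upper))
  reference |>
    dplyr::mutate(
      observed = vapply(check, function(k) profile[[k]], numeric(1)),
      verdict = dplyr::case_when(
        observed < lower ~ "below",
        observed <= upper ~ "within",
        !is.na(caution) & observed < caution ~ "above-but-below-caution",
        TRUE ~ "above")) |>
    dplyr::select(check, observed, lower, upper, caution, verdict)
}

#' Add a supplement to a diet
#'
#' Converts a supplement dose in g/day into mmol/day using the metabolite's
#' molecular weight and adds it onto the base diet's fluxes. The supplement
#' is given either as a metabolite id (resolved against
#' `molecular_weights`) or as a food name (resolved through the composition
#' database). The base diet is not modified.
#'
#' @param base a `diet_spec`.
#' @param supplement named numeric vector: component -> g/day.
#' @param composition optional [food_composition()] (needed for food-name
#'   components).
#' @param molecular_weights named numeric vector, g/mol.
#' @param name name of the resulting diet.
#' @return a new `diet_spec`.
#' @export
#' @examples
#' mw <- c(mos = 504.44)
#' base <- build_diet_fluxes(tibble::tibble(food = character(),
#'                                          g_per_day = numeric()),
#'                           food_composition(), mw)
#' add_supplement(base, c(mos = 5), molecular_weights = mw)
add_supplement <- function(base, supplement, composition = NULL,
                           molecular_weights, name = NULL) {
  fx <- stats::setNames(base$mmol_per_day, base$metabolite)
  for (comp in names(supplement)) {
    g <- supplement[[comp]]
    if (g < 0) stop("negative supplement dose for ", comp, call. = FALSE)
    if (comp %in% names(molecular_weights)) {
      add <- stats::setNames(g * 1000 / molecular_weights[[comp]], comp)
    } else if (!is.null(composition) &&
               comp %in% composition$nutrients$food) {
      nut <- composition$nutrients[composition$nutrients$food == comp, ]
      miss <- setdiff(nut$metabolite, names(molecular_weights))
      if (length(miss))
        stop("no molecular weight for metabolite(s): ",
             paste(miss, collapse = ", "), call. = FALSE)
      add <- stats::setNames(
        g * (nut$mg_per_100g / 100) / molecular_weights[nut$metabolite],
        nut$metabolite)
    } else {
      stop("unknown supplement component '", comp,
           "': not a known metabolite or composed food", call. = FALSE)
    }
    for (m in names(add)) fx[m] <- (fx[m] %|na|% 0) + add[[m]]
  }
  fx <- fx[fx > 0]
  out <- tibble::tibble(metabolite = names(fx),
                        mmol_per_day = unname(fx)) |>
    dplyr::arrange(metabolite)
  new_diet_spec(out,
                name = name %||% paste0(attr(base, "diet_name"), "+supplement"),
                provenance = attr(base, "provenance"))
}

`%|na|%` <- function(a, b) if (length(a) == 0 || is.na(a)) b else a

#' Compare metabolite support across diets
#'
#' Reports, per metabolite, presence in each diet, whether the metabolite is
#' shared by all diets, and whether its flux exceeds `threshold` in every
#' diet (the criterion used to pick out quantitatively important shared
#' nutrients).
#'
#' @param diets named list of `diet_spec` objects (>= 2).
#' @param threshold flux threshold in mmol/day (default 1).
#' @return tibble with one row per metabolite: per-diet flux columns,
#'   `shared` and `exceeds_everywhere` logicals.
#' @export
compare_diets <- function(diets, threshold = 1) {
  stopifnot(length(diets) >= 2L)
  if (is.null(names(diets)) || any(!nzchar(names(diets))))
    names(diets) <- purrr::map_chr(seq_along(diets), function(i)
      attr(diets[[i]], "diet_name") %||% paste0("diet", i))
  long <- purrr::imap_dfr(diets, function(d, nm)
    tibble::tibble(diet = nm, metabolite = d$metabolite,
                   mmol_per_day = d$mmol_per_day))
  wide <- tidyr::pivot_wider(long, names_from = diet,
                             values_from = mmol_per_day,
                             values_fill = 0)
  fluxcols <- setdiff(names(wide), "metabolite")
  fluxmat <- as.matrix(wide[, fluxcols])
  wide$shared <- apply(fluxmat > 0, 1L, all)
  wide$exceeds_everywhere <- apply(fluxmat > threshold, 1L, all)
  dplyr::arrange(wide, metabolite)
}

#' Construct a food composition database
#'
#' @param nutrients tibble with columns `food`, `metabolite`,
#'   `mg_per_100g`, `source` (`"primary"` or `"manual"`).
#' @param macros tibble with columns `food`, `carbohydrate`, `fat`,
#'   `protein`, `alcohol` (g per 100 g edible portion).
#' @return a `food_composition` object (a named list of the two tibbles).
#' @export
food_composition <- function(nutrients = NULL, macros = NULL) {
  if (is.null(nutrients))
    nutrients <- tibble::tibble(food = character(), metabolite = character(),
                                mg_per_100g = numeric(), source = character())
  if (is.null(macros))
    macros <- tibble::tibble(food = character(), carbohydrate = numeric(),
                             fat = numeric(), protein = numeric(),
                             alcohol = numeric())
  stopifnot(all(c("food", "metabolite", "mg_per_100g", "source") %in%
                  names(nutrients)),
            all(c("food", "carbohydrate", "fat", "protein", "alcohol") %in%
                  names(macros)))
  if (any(nutrients$mg_per_100g < 0))
    stop("negative nutrient masses in composition table", call. = FALSE)
  structure(list(nutrients = nutrients, macros = macros),
            class = "food_composition")
}
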
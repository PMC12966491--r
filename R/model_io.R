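#' Read a metabolic model from disk
#'
#' Two formats are supported: the package's JSON model dialect (read/write)
#' and SBML Level 3 with the FBC package (flux bounds via parameter
#' references, biomass via the active objective). Bounds absent from a file
#' default to the open bound of +/- 1e6 mmol/day.
#'
#' The JSON dialect is a single object with fields `model_id`, `taxonomy`
#' (phylum/family/genus/species), `metabolites` (array of `{id, name,
#' compartment, molecular_weight}`), `reactions` (array of `{id,
#' stoichiometry: {met: coef}, lower_bound, upper_bound, kind}`) and
#' `biomass_reaction_id`.
#'
#' @param path file to read.
#' @param format `"json"` or `"sbml"`; guessed from the extension when
#'   missing.
#' @return a validated `taxon_model`.
#' @export
load_model <- function(path, format = c("auto", "json", "sbml")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE))
      "sbml" else "json"
  }
  m <- switch(format, json = read_model_json(path), sbml = read_model_sbml(path))
  assert_valid_model(m)
  m
}

#' Write a metabolic model to disk
#'
#' The JSON dialect round-trips every field exactly; the SBML writer emits
#' Level 3 + FBC with bounds as parameters and the biomass reaction as the
#' active objective, and stashes the reaction kinds and molecular weights
#' in an annotation so that an SBML round trip is also lossless.
#'
#' @param model a valid `taxon_model`.
#' @param path output file.
#' @param format `"json"` or `"sbml"`.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path, format = c("auto", "json", "sbml")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE))
      "sbml" else "json"
  }
  assert_valid_model(model)
  switch(format,
         json = write_model_json(model, path),
         sbml = write_model_sbml(model, path))
  invisible(path)
}

read_model_json <- function(path) {
  d <- tryCatch(jsonlite::read_json(path),
                error = function(e) stop("cannot parse JSON model '", path,
                                         "': ", conditionMessage(e),
                                         call. = FALSE))
  for (f in c("model_id", "metabolites", "reactions", "biomass_reaction_id")) {
    if (is.null(d[[f]]))
      stop("JSON model '", path, "' lacks required field '", f, "'",
           call. = FALSE)
  }
  mets <- purrr::map_dfr(d$metabolites, function(m) {
    if (is.null(m$id)) stop("metabolite without id in '", path, "'",
                            call. = FALSE)
    metabolite(m$id, m$name %||% m$id, m$compartment %||% "c",
               m$molecular_weight %||% NA_real_)
  })
  rxns <- purrr::map_dfr(d$reactions, function(r) {
    if (is.null(r$id) || is.null(r$stoichiometry))
      stop("reaction without id/stoichiometry in '", path, "'", call. = FALSE)
    s <- unlist(r$stoichiometry)
    reaction(r$id, s,
             lower_bound = r$lower_bound %||% -1e6,
             upper_bound = r$upper_bound %||% 1e6,
             kind = r$kind %||% "internal")
  })
  tax <- d$taxonomy %||% list()
  m <- taxon_model(d$model_id, mets, rxns, d$biomass_reaction_id,
                   taxonomy = list(phylum = tax$phylum %||% NA_character_,
                                   family = tax$family %||% NA_character_,
                                   genus = tax$genus %||% NA_character_,
                                   species = tax$species %||% NA_character_),
                   check = FALSE)
  if (!is.null(d$members)) m <- community_fields_from_json(m, d)
  m
}

write_model_json <- function(model, path) {
  rxns <- purrr::pmap(model$reactions, function(id, stoichiometry,
                                                lower_bound, upper_bound,
                                                kind) {
    list(id = id, stoichiometry = as.list(stoichiometry),
         lower_bound = lower_bound, upper_bound = upper_bound, kind = kind)
  })
  d <- list(model_id = model$model_id,
            taxonomy = model$taxonomy,
            metabolites = purrr::pmap(model$metabolites,
                                      function(id, name, compartment,
                                               molecular_weight) {
                                        list(id = id, name = name,
                                             compartment = compartment,
                                             molecular_weight = molecular_weight)
                                      }),
            reactions = rxns,
            biomass_reaction_id = model$biomass_reaction_id)
  if (inherits(model, "community_model")) d <- community_fields_to_json(model, d)
  jsonlite::write_json(d, path, auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null", pretty = TRUE)
  invisible(path)
}

## ---- SBML Level 3 + FBC ----------------------------------------------------

SBML_NS <- c(sbml = "http://www.sbml.org/sbml/level3/version1/core",
             fbc = "http://www.sbml.org/sbml/level3/version1/fbc/version2",
             gf = "https://gutflux.invalid/annotation")

read_model_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("cannot parse SBML '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "sbml")
  model_node <- xml2::xml_find_first(doc, ".//sbml:model", ns)
  if (inherits(model_node, "xml_missing"))
    stop("SBML file '", path, "' has no <model> element", call. = FALSE)
  model_id <- xml2::xml_attr(model_node, "id") %||% "model"

  params <- xml2::xml_find_all(doc, ".//sbml:listOfParameters/sbml:parameter", ns)
  pval <- stats::setNames(as.numeric(xml2::xml_attr(params, "value")),
                          xml2::xml_attr(params, "id"))

  sp <- xml2::xml_find_all(doc, ".//sbml:listOfSpecies/sbml:species", ns)
  mets <- metabolite(
    id = xml2::xml_attr(sp, "id"),
    name = dplyr::coalesce(xml2::xml_attr(sp, "name"), xml2::xml_attr(sp, "id")),
    compartment = xml2::xml_attr(sp, "compartment"),
    molecular_weight = suppressWarnings(
      as.numeric(xml2::xml_attr(sp, "gf:molecularWeight", ns = ns))))

  rx_nodes <- xml2::xml_find_all(doc, ".//sbml:listOfReactions/sbml:reaction", ns)
  obj_ref <- xml2::xml_find_first(
    doc, ".//fbc:listOfObjectives/fbc:objective/fbc:listOfFluxObjectives/fbc:fluxObjective",
    ns)
  biomass_id <- if (!inherits(obj_ref, "xml_missing"))
    xml2::xml_attr(obj_ref, "reaction") else NA_character_

  rxns <- purrr::map_dfr(rx_nodes, function(nd) {
    rid <- xml2::xml_attr(nd, "id")
    if (is.na(rid)) stop("SBML reaction without id in '", path, "'",
                         call. = FALSE)
    rs <- xml2::xml_find_all(nd, "./sbml:listOfReactants/sbml:speciesReference", ns)
    ps <- xml2::xml_find_all(nd, "./sbml:listOfProducts/sbml:speciesReference", ns)
    coef <- function(nodes, sgn) {
      if (length(nodes) == 0L) return(numeric(0))
      st <- as.numeric(xml2::xml_attr(nodes, "stoichiometry"))
      st[is.na(st)] <- 1
      stats::setNames(sgn * st, xml2::xml_attr(nodes, "species"))
    }
    s <- c(coef(rs, -1), coef(ps, 1))
    s <- tapply(s, names(s), sum)            # merge duplicated species refs
    s <- stats::setNames(as.numeric(s), names(s))
    lb_ref <- xml2::xml_attr(nd, "fbc:lowerFluxBound", ns = ns)
    ub_ref <- xml2::xml_attr(nd, "fbc:upperFluxBound", ns = ns)
    lb <- if (!is.na(lb_ref) && lb_ref %in% names(pval)) pval[[lb_ref]] else -1e6
    ub <- if (!is.na(ub_ref) && ub_ref %in% names(pval)) pval[[ub_ref]] else 1e6
    kind <- xml2::xml_attr(nd, "gf:kind", ns = ns)
    if (is.na(kind)) {
      kind <- if (identical(rid, biomass_id)) "biomass"
      else if (length(s) == 1L) "exchange" else "internal"
    }
    reaction(rid, s, lb, ub, kind)
  })

  tax <- list(phylum = xml2::xml_attr(model_node, "gf:phylum", ns = ns),
              family = xml2::xml_attr(model_node, "gf:family", ns = ns),
              genus = xml2::xml_attr(model_node, "gf:genus", ns = ns),
              species = xml2::xml_attr(model_node, "gf:species", ns = ns))
  bid <- if (!is.na(biomass_id)) biomass_id else
    rxns$id[match("biomass", rxns$kind)]
  taxon_model(model_id, mets, rxns, bid, taxonomy = tax, check = FALSE)
}

write_model_sbml <- function(model, path) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  num <- function(x) sprintf("%.17g", x)
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf(paste0('<sbml xmlns="%s" xmlns:fbc="%s" xmlns:gf="%s" level="3"',
                   ' version="1" fbc:required="false">'),
            SBML_NS[["sbml"]], SBML_NS[["fbc"]], SBML_NS[["gf"]]))
  tax <- model$taxonomy
  tax_attr <- paste0(
    purrr::imap_chr(tax[c("phylum", "family", "genus", "species")],
                    function(v, k) {
                      if (is.null(v) || is.na(v)) "" else
                        sprintf(' gf:%s="%s"', k, esc(v))
                    }), collapse = "")
  lines <- c(lines, sprintf('  <model id="%s" fbc:strict="false"%s>',
                            esc(model$model_id), tax_attr))
  comps <- unique(model$metabolites$compartment)
  lines <- c(lines, "    <listOfCompartments>",
             sprintf('      <compartment id="%s" constant="true"/>', esc(comps)),
             "    </listOfCompartments>", "    <listOfSpecies>")
  for (i in seq_len(nrow(model$metabolites))) {
    mt <- model$metabolites[i, ]
    mw <- if (is.na(mt$molecular_weight)) "" else
      sprintf(' gf:molecularWeight="%s"', num(mt$molecular_weight))
    lines <- c(lines, sprintf(
      paste0('      <species id="%s" name="%s" compartment="%s"',
             ' hasOnlySubstanceUnits="false" boundaryCondition="false"',
             ' constant="false"%s/>'),
      esc(mt$id), esc(mt$name), esc(mt$compartment), mw))
  }
  lines <- c(lines, "    </listOfSpecies>", "    <listOfParameters>")
  rxn <- model$reactions
  for (i in seq_len(nrow(rxn))) {
    lines <- c(lines,
               sprintf('      <parameter id="lb_%d" value="%s" constant="true"/>',
                       i, num(rxn$lower_bound[i])),
               sprintf('      <parameter id="ub_%d" value="%s" constant="true"/>',
                       i, num(rxn$upper_bound[i])))
  }
  lines <- c(lines, "    </listOfParameters>", "    <listOfReactions>")
  for (i in seq_len(nrow(rxn))) {
    s <- rxn$stoichiometry[[i]]
    open <- sprintf(
      paste0('      <reaction id="%s" reversible="%s" fast="false"',
             ' fbc:lowerFluxBound="lb_%d" fbc:upperFluxBound="ub_%d"',
             ' gf:kind="%s">'),
      esc(rxn$id[i]), tolower(rxn$lower_bound[i] < 0), i, i, rxn$kind[i])
    sref <- function(ids, coefs) sprintf(
      '          <speciesReference species="%s" stoichiometry="%s" constant="true"/>',
      esc(ids), num(coefs))
    body <- character(0)
    cons <- s[s < 0]; prod <- s[s > 0]
    if (length(cons))
      body <- c(body, "        <listOfReactants>",
                sref(names(cons), -unname(cons)), "        </listOfReactants>")
    if (length(prod))
      body <- c(body, "        <listOfProducts>",
                sref(names(prod), unname(prod)), "        </listOfProducts>")
    lines <- c(lines, open, body, "      </reaction>")
  }
  lines <- c(lines, "    </listOfReactions>",
             '    <fbc:listOfObjectives fbc:activeObjective="obj">',
             '      <fbc:objective fbc:id="obj" fbc:type="maximize">',
             "        <fbc:listOfFluxObjectives>",
             sprintf('          <fbc:fluxObjective fbc:reaction="%s" fbc:coefficient="1"/>',
                     esc(model$biomass_reaction_id)),
             "        </fbc:listOfFluxObjectives>",
             "      </fbc:objective>",
             "    </fbc:listOfObjectives>",
             "  </model>", "</sbml>")
  writeLines(lines, path, useBytes = FALSE)
  invisible(path)
}
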
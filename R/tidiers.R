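#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a taxon or community model into a reaction table
#'
#' @param x a `taxon_model` or `community_model`.
#' @param ... unused.
#' @return tibble with one row per reaction: `reaction`, `kind`,
#'   `lower_bound`, `upper_bound`, `n_metabolites`.
#' @exportS3Method generics::tidy
tidy.taxon_model <- function(x, ...) {
  tibble::tibble(reaction = x$reactions$id,
                 kind = x$reactions$kind,
                 lower_bound = x$reactions$lower_bound,
                 upper_bound = x$reactions$upper_bound,
                 n_metabolites = purrr::map_int(x$reactions$stoichiometry,
                                               length))
}

#' One-row model summary
#'
#' @param x a `taxon_model` or `community_model`.
#' @param ... unused.
#' @return one-row tibble: metabolite/reaction/exchange counts and, for
#'   communities, the member count.
#' @exportS3Method generics::glance
glance.taxon_model <- function(x, ...) {
  tibble::tibble(
    model_id = x$model_id,
    n_metabolites = nrow(x$metabolites),
    n_reactions = nrow(x$reactions),
    n_exchanges = sum(x$reactions$kind == "exchange"),
    n_members = if (!is.null(x$members)) nrow(x$members) else 1L)
}

#' Tidy an FVA result
#'
#' @param x an `fva_result`.
#' @param ... unused.
#' @return the underlying tibble.
#' @exportS3Method generics::tidy
tidy.fva_result <- function(x, ...) tibble::as_tibble(x)

#' One-row FVA summary
#'
#' The secretion capacity counts exchange reactions whose maximum flux is
#' positive -- for a community's fecal exchanges this is the number of
#' secretable metabolites.
#'
#' @param x an `fva_result`.
#' @param ... unused.
#' @exportS3Method generics::glance
glance.fva_result <- function(x, ...) {
  fecal <- grepl("__fe$", x$reaction)
  tibble::tibble(
    n_reactions = nrow(x),
    n_unbounded = sum(x$unbounded_min | x$unbounded_max),
    secretion_capacity = sum(fecal & x$maximum > 1e-9))
}
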
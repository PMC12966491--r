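#' Normalize genome coverage into relative abundances
#'
#' Converts a sample x model coverage table (reads mapped normalized by
#' genome size) into per-sample relative abundance fractions, drops entries
#' whose fraction does not strictly exceed `cutoff` (default 0.001%), and
#' renormalizes the survivors so each sample sums to exactly 1. The strict
#' inequality means a fraction exactly equal to the cutoff is dropped.
#'
#' @param coverage tibble in long form (`sample`, `model_id`, `coverage`)
#'   or wide form (`model_id` column plus one numeric column per sample,
#'   the shape coverage tools emit).
#' @param cutoff abundance fraction below or at which entries are dropped;
#'   `1e-5` corresponds to 0.001%.
#' @param renormalize renormalize retained fractions to sum 1 (default
#'   `TRUE`); with `FALSE` the raw post-cutoff fractions are returned.
#' @return an `abundance_profile`: long tibble (`sample`, `model_id`,
#'   `abundance`) with attribute `cutoff`.
#' @export
normalize_coverage <- function(coverage, cutoff = 1e-5, renormalize = TRUE) {
  long <- as_coverage_long(coverage)
  if (any(long$coverage < 0))
    stop("negative coverage values", call. = FALSE)
  tot <- long |>
    dplyr::group_by(sample) |>
    dplyr::summarise(total = sum(coverage), .groups = "drop")
  dead <- tot$sample[tot$total <= 0]
  if (length(dead))
    stop("sample(s) with all-zero coverage: ",
         paste(dead, collapse = ", "), call. = FALSE)
  out <- long |>
    dplyr::left_join(tot, by = "sample") |>
    dplyr::mutate(fraction = coverage / total) |>
    dplyr::filter(fraction > cutoff) |>
    dplyr::group_by(sample) |>
    dplyr::mutate(abundance = if (renormalize) fraction / sum(fraction)
                  else fraction) |>
    dplyr::ungroup() |>
    dplyr::select(sample, model_id, abundance) |>
    dplyr::arrange(sample, model_id)
  structure(out, cutoff = cutoff,
            class = c("abundance_profile", class(out)))
}

as_coverage_long <- function(coverage) {
  stopifnot(is.data.frame(coverage))
  if (all(c("sample", "model_id", "coverage") %in% names(coverage))) {
    return(tibble::as_tibble(coverage[, c("sample", "model_id", "coverage")]))
  }
  stopifnot("model_id" %in% names(coverage))
  tidyr::pivot_longer(tibble::as_tibble(coverage), -model_id,
                      names_to = "sample", values_to = "coverage")
}

#' Models present in a given fraction of samples
#'
#' Returns the model identifiers detected (positive post-cutoff abundance)
#' in at least `prevalence` of the samples. The comparison is `>=`, so with
#' 4 samples and `prevalence = 0.5` a model present in exactly 2 samples is
#' included.
#'
#' @param profile an `abundance_profile`.
#' @param prevalence required fraction of samples (default 0.5).
#' @return character vector of model ids.
#' @export
shared_models <- function(profile, prevalence = 0.5) {
  n_samp <- dplyr::n_distinct(profile$sample)
  stopifnot(n_samp >= 1L)
  profile |>
    dplyr::filter(abundance > 0) |>
    dplyr::distinct(sample, model_id) |>
    dplyr::count(model_id) |>
    dplyr::filter(n / n_samp >= prevalence) |>
    dplyr::pull(model_id)
}

#' Aggregate an abundance profile at a taxonomic rank
#'
#' Joins the taxonomy table onto the profile and sums abundances within the
#' requested rank, preserving each sample's total.
#'
#' @param profile an `abundance_profile`.
#' @param taxonomy tibble with columns `model_id`, `phylum`, `family`,
#'   `genus`, `species`.
#' @param rank one of `"phylum"`, `"family"`, `"genus"`, `"species"`.
#' @return tibble (`sample`, `taxon`, `abundance`).
#' @export
attach_taxonomy <- function(profile, taxonomy,
                            rank = c("genus", "species", "family",
                                     "phylum")) {
  rank <- match.arg(rank)
  unresolved <- setdiff(unique(profile$model_id), taxonomy$model_id)
  if (length(unresolved))
    stop("model id(s) missing from taxonomy table: ",
         paste(unresolved, collapse = ", "), call. = FALSE)
  profile |>
    dplyr::left_join(taxonomy[, c("model_id", rank)], by = "model_id") |>
    dplyr::rename(taxon = dplyr::all_of(rank)) |>
    dplyr::group_by(sample, taxon) |>
    dplyr::summarise(abundance = sum(abundance), .groups = "drop") |>
    dplyr::arrange(sample, taxon)
}

#' Read / write coverage and abundance tables as TSV
#'
#' `read_coverage()` accepts the wide, coverage-tool-style shape (rows =
#' model ids, one column per sample). `write_abundance()` /
#' `read_abundance()` round-trip the long profile shape.
#'
#' @param path file path.
#' @export
read_coverage <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' @rdname read_coverage
#' @param profile an `abundance_profile`.
#' @export
write_abundance <- function(profile, path) {
  readr::write_tsv(tibble::as_tibble(profile), path)
  invisible(path)
}

#' @rdname read_coverage
#' @param cutoff cutoff recorded on the profile being read.
#' @export
read_abundance <- function(path, cutoff = 1e-5) {
  d <- readr::read_tsv(path, show_col_types = FALSE,
                       col_types = readr::cols(
                         sample = readr::col_character(),
                         model_id = readr::col_character(),
                         abundance = readr::col_double()))
  structure(d, cutoff = cutoff, class = c("abundance_profile", class(d)))
}
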
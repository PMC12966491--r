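#' Plot flux variability ranges
#'
#' Horizontal range segments per reaction, mmol/day.
#'
#' @param object an `fva_result`.
#' @param ... unused.
#' @return a ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.fva_result <- function(object, ...) {
  d <- tibble::as_tibble(object)
  ggplot2::ggplot(d, ggplot2::aes(y = stats::reorder(reaction, maximum))) +
    ggplot2::geom_segment(ggplot2::aes(x = minimum, xend = maximum,
                                       yend = stats::reorder(reaction,
                                                             maximum)),
                          linewidth = 1.5, colour = "steelblue") +
    ggplot2::geom_point(ggplot2::aes(x = maximum), size = 1) +
    ggplot2::labs(x = "flux (mmol/day)", y = NULL,
                  title = "Flux variability ranges") +
    ggplot2::theme_minimal()
}

#' Plot per-taxon secretion contributions
#'
#' Stacked mean secretion-side contributions (FVA maxima truncated at
#' zero, averaged over samples) by taxon and metabolite -- the shape used
#' to compare top producer taxa.
#'
#' @param object a `contribution_table`.
#' @param ... unused.
#' @return a ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.contribution_table <- function(object, ...) {
  n_samples <- max(1L, dplyr::n_distinct(object$sample))
  d <- object |>
    dplyr::group_by(taxon, metabolite) |>
    dplyr::summarise(mean_secretion = sum(pmax(maximum, 0)) / n_samples,
                     .groups = "drop")
  ggplot2::ggplot(d, ggplot2::aes(x = stats::reorder(taxon, -mean_secretion),
                                  y = mean_secretion, fill = metabolite)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "mean secretion flux (mmol/day)",
                  fill = "metabolite",
                  title = "Per-taxon secretion contributions") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Plot net secretion fluxes
#'
#' @param net_fluxes tibble from [net_exchange_fluxes()].
#' @param top show the `top` metabolites by net secretion.
#' @return a ggplot object.
#' @export
plot_net_fluxes <- function(net_fluxes, top = 20) {
  d <- net_fluxes |>
    dplyr::arrange(dplyr::desc(net_secretion)) |>
    utils::head(top)
  ggplot2::ggplot(d, ggplot2::aes(x = net_secretion,
                                  y = stats::reorder(metabolite,
                                                     net_secretion))) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "net secretion (mmol/day)", y = NULL,
                  title = "Net metabolite secretion") +
    ggplot2::theme_minimal()
}
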
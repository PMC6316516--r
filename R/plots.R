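# ggplot2 surfaces for the two figure types of the analysis.

#' Boxplots of methylation level per population, allele and motif
#'
#' One box per population and allele, faceted motif x region, with
#' individual levels overplotted: the population-diversification view of
#' the cross.
#'
#' @param levels Tibble with `population`, `region_id`, `allele`, `motif`,
#'   `level`.
#' @return A ggplot object.
#' @export
plot_population_levels <- function(levels) {
  levels |>
    filter(!is.na(.data$level)) |>
    mutate(motif = motif_factor(.data$motif)) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$population, y = .data$level,
                                 colour = .data$allele)) +
    ggplot2::geom_boxplot(outlier.shape = NA,
                          position = ggplot2::position_dodge2(preserve = "single")) +
    ggplot2::geom_point(position = ggplot2::position_jitterdodge(jitter.width = 0.12),
                        size = 0.8, alpha = 0.7) +
    ggplot2::facet_grid(motif ~ region_id) +
    ggplot2::scale_colour_manual(values = c(Col = "#c23b22", Ler = "#2b6cb0")) +
    ggplot2::labs(x = NULL, y = "weighted methylation level",
                  colour = "allele") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Scatter of heterozygote allele levels with regression and 95% bounds
#'
#' @param object An [allele_correlation()] result.
#' @param ... Unused.
#' @return A ggplot object: per-motif scatter of Ler vs Col levels, solid
#'   best-fit OLS line and dashed pointwise 95% confidence bounds.
#' @method autoplot allele_correlation
#' @export
autoplot.allele_correlation <- function(object, ...) {
  dat <- object$data |> mutate(motif = motif_factor(.data$motif))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$Col, y = .data$Ler)) +
    ggplot2::geom_point(size = 1, alpha = 0.8) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fit)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$lower), linetype = "dashed") +
    ggplot2::geom_line(ggplot2::aes(y = .data$upper), linetype = "dashed") +
    ggplot2::facet_wrap(~motif, scales = "free") +
    ggplot2::labs(x = "Col allele methylation level",
                  y = "Ler allele methylation level",
                  title = paste0("F2 heterozygotes, ", object$region)) +
    ggplot2::theme_bw()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
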
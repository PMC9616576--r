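#' Plot the proteins-per-EV distribution of a profile summary
#'
#' @param object An `ev_profile_summary` from [summarize_profile()].
#' @param ... Unused.
#' @return A ggplot: bar chart of the number of EVs by distinct-protein
#'   count, singleton bar highlighted.
#' @export
autoplot.ev_profile_summary <- function(object, ...) {
  d <- object$proteins_per_ev %>%
    mutate(singleton = .data$n_proteins == 1L)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$n_proteins, y = .data$n_evs,
                                  fill = .data$singleton)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#d55e00",
                                          `FALSE` = "grey40")) +
    ggplot2::labs(
      x = "Distinct proteins per EV", y = "Number of EVs",
      title = sprintf("Sample %s: %.1f%% singleton EVs",
                      object$sample_id, 100 * object$singleton_fraction)
    ) +
    ggplot2::theme_minimal()
}

#' QQ plot of a genome scan
#'
#' @param object An `ev_gwas` tibble from [linear_gwas()].
#' @param ... Unused.
#' @return A ggplot: observed vs expected -log10(P) with the identity line
#'   and the genomic-control lambda in the title.
#' @export
autoplot.ev_gwas <- function(object, ...) {
  p <- sort(object$p[!is.na(object$p)])
  d <- tibble(
    expected = -log10(stats::ppoints(length(p))),
    observed = -log10(p)
  )
  ggplot2::ggplot(d, ggplot2::aes(.data$expected, .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::labs(
      x = expression(Expected ~ -log[10](P)),
      y = expression(Observed ~ -log[10](P)),
      title = sprintf("lambda[GC] = %.3f", lambda_gc(object))
    ) +
    ggplot2::theme_minimal()
}

#' Heatmap of association effects across exposures and traits
#'
#' Mirrors the standard presentation of EV-trait association screens: a
#' tile per exposure-trait pair coloured by the effect estimate, with FDR
#' significance marked.
#'
#' @param results Tibble from [associate_all()] (columns `exposure`,
#'   `trait`, `beta_ev` and optionally `q`).
#' @param effect Column to colour by (default `"beta_ev"`; use
#'   `"beta_int"` for the sex-interaction panel).
#' @return A ggplot.
#' @export
plot_association_effects <- function(results, effect = "beta_ev") {
  d <- results
  if ("q" %in% names(d)) {
    d <- mutate(d, stars = dplyr::case_when(
      .data$q < 0.05 ~ "***", .data$q < 0.1 ~ "**", .data$q < 0.2 ~ "*",
      TRUE ~ ""
    ))
  } else {
    d$stars <- ""
  }
  ggplot2::ggplot(d, ggplot2::aes(x = .data$trait, y = .data$exposure,
                                  fill = .data[[effect]])) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$stars), size = 3) +
    ggplot2::scale_fill_gradient2(low = "#b2182b", mid = "white",
                                  high = "#2166ac", midpoint = 0) +
    ggplot2::labs(x = NULL, y = NULL, fill = effect) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Bar chart of heritability enrichment scores
#'
#' One bar per SNP set with jackknife standard-error bars and a dashed line
#' at 1 (no enrichment).
#'
#' @param scores Tibble with columns `set_label`, `enrichment`, `se`.
#' @return A ggplot.
#' @export
plot_enrichment <- function(scores) {
  ggplot2::ggplot(scores, ggplot2::aes(x = .data$set_label,
                                       y = .data$enrichment)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$enrichment - .data$se,
                                        ymax = .data$enrichment + .data$se),
                           width = 0.3) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2, colour = "#d55e00") +
    ggplot2::labs(x = NULL, y = "Heritability enrichment") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
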
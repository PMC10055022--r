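#' @importFrom ggplot2 ggplot aes geom_point geom_tile geom_col geom_line
#'   labs scale_fill_gradient theme_minimal geom_errorbar
NULL

#' Plot PCoA sample coordinates
#'
#' Scatter of the first two principal coordinates, coloured by population,
#' with axis percentages in the labels.
#'
#' @param object A [pcoa()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pcoa_result
#' @export
autoplot.pcoa_result <- function(object, ...) {
  sc <- object$scores
  if (!"axis2" %in% names(sc)) sc$axis2 <- 0
  lab <- function(i) {
    pct <- object$pct_variance[i]
    if (is.na(pct)) sprintf("Axis %d", i)
    else sprintf("Axis %d (%.1f%%)", i, pct)
  }
  ggplot(sc, aes(x = .data$axis1, y = .data$axis2,
                 colour = .data$population)) +
    geom_point(size = 2) +
    labs(x = lab(1), y = lab(2), colour = "Population") +
    theme_minimal()
}

#' Plot AMOVA variance partition
#'
#' Bar chart of the percentage of molecular variance among and within
#' populations.
#'
#' @param object An [amova()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot amova
#' @export
autoplot.amova <- function(object, ...) {
  tab <- object$table %>% dplyr::filter(.data$source != "Total")
  ggplot(tab, aes(x = .data$source, y = .data$pct, fill = .data$source)) +
    geom_col(show.legend = FALSE) +
    labs(x = NULL, y = "% of molecular variance",
         title = sprintf("PhiPT = %.3f%s", object$phi_pt,
                         if (!is.na(object$p_value))
                           sprintf(", p = %.3g", object$p_value) else "")) +
    theme_minimal()
}

#' Heatmap of a genetic-similarity matrix
#'
#' @param object A [simple_matching_gs()] matrix.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot gs_matrix
#' @export
autoplot.gs_matrix <- function(object, ...) {
  long <- tidy(object)
  ggplot(long, aes(x = .data$sample_a, y = .data$sample_b,
                   fill = .data$gs)) +
    geom_tile() +
    scale_fill_gradient(low = "white", high = "darkred", limits = c(0, 1)) +
    labs(x = NULL, y = NULL, fill = "GS") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       size = 6),
                   axis.text.y = ggplot2::element_text(size = 6))
}

#' Heatmap of a cross-prediction matrix
#'
#' Tiles show expected progeny heterozygosity (upper triangle), GS (lower
#' triangle) and parental homozygosity (diagonal), on the population-block
#' parent ordering.
#'
#' @param object A [cross_prediction_matrix()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cross_prediction
#' @export
autoplot.cross_prediction <- function(object, ...) {
  m <- object$matrix
  ids <- rownames(m)
  long <- tidyr::expand_grid(i = seq_along(ids), j = seq_along(ids)) %>%
    dplyr::mutate(
      parent1 = factor(ids[.data$i], levels = ids),
      parent2 = factor(ids[.data$j], levels = rev(ids)),
      value = m[cbind(.data$i, .data$j)]
    )
  ggplot(long, aes(x = .data$parent1, y = .data$parent2,
                   fill = .data$value)) +
    geom_tile() +
    scale_fill_gradient(low = "white", high = "darkblue", limits = c(0, 1)) +
    labs(x = NULL, y = NULL,
         fill = "GS / exp. het",
         title = "GS below diagonal, expected progeny heterozygosity above") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       size = 6),
                   axis.text.y = ggplot2::element_text(size = 6))
}

#' Plot the Evanno delta-K profile
#'
#' @param delta_k_table Output of [evanno_delta_k()].
#' @return A ggplot object (delta-K against K; undefined K omitted).
#' @export
plot_delta_k <- function(delta_k_table) {
  dat <- delta_k_table %>% dplyr::filter(.data$defined)
  ggplot(dat, aes(x = .data$k, y = .data$delta_k)) +
    geom_line() +
    geom_point() +
    labs(x = "K", y = expression(Delta * K)) +
    theme_minimal()
}

#' Plot strategy-wise expected progeny heterozygosity
#'
#' Crossbar summary (median, quartiles, extremes) of expected progeny
#' heterozygosity per breeding strategy and group, from
#' [strategy_summary()].
#'
#' @param summary_tbl Output of [strategy_summary()].
#' @return A ggplot object.
#' @export
plot_strategy_summary <- function(summary_tbl) {
  dat <- summary_tbl %>%
    dplyr::mutate(strategy = factor(.data$strategy,
                                    levels = c("S", "FS", "F1")))
  ggplot(dat, aes(x = .data$group, colour = .data$strategy)) +
    ggplot2::geom_boxplot(
      aes(ymin = .data$min, lower = .data$q1, middle = .data$median,
          upper = .data$q3, ymax = .data$max),
      stat = "identity"
    ) +
    geom_point(aes(y = .data$mean), shape = 4, size = 2) +
    ggplot2::facet_grid(~strategy, scales = "free_x", space = "free_x") +
    labs(x = NULL, y = "expected progeny heterozygosity",
         colour = "Strategy") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
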
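#' Scree plot of variance explained
#'
#' @param x A `morphoscreen_svd`.
#' @param n_components Components to show.
#' @return A ggplot.
#' @export
plot_variance_explained <- function(x, n_components = min(20, length(x$d))) {
  df <- tibble::tibble(component = seq_len(n_components),
                       variance = x$variance_explained[seq_len(n_components)])
  ggplot2::ggplot(df, ggplot2::aes(.data$component, .data$variance)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::geom_line(ggplot2::aes(y = cumsum(.data$variance)),
                       colour = "firebrick") +
    ggplot2::scale_y_continuous(labels = function(v) paste0(100 * v, "%")) +
    ggplot2::labs(x = "principal component",
                  y = "variance explained (bars) / cumulative (line)") +
    ggplot2::theme_minimal()
}

#' Colony score scatter coloured by well phenotype frequency
#'
#' The per-colony projection on two components, coloured by the frequency
#' of one phenotype in each colony's well of origin.
#'
#' @param x A `morphoscreen_svd` built from a feature table.
#' @param profiles Well profiles.
#' @param phenotype Phenotype whose well frequency colours the points.
#' @param components Length-2 component indices.
#' @return A ggplot.
#' @export
plot_pc_scatter <- function(x, profiles, phenotype = "inverted",
                            components = c(1, 2)) {
  fcol <- paste0("f_", phenotype)
  freq <- profiles[[fcol]][match(x$ids$well_id, profiles$well_id)]
  df <- tibble::tibble(s1 = x$scores[, components[1]],
                       s2 = x$scores[, components[2]],
                       frequency = freq)
  ggplot2::ggplot(df, ggplot2::aes(.data$s1, .data$s2,
                                   colour = .data$frequency)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.6) +
    ggplot2::scale_colour_viridis_c(name = paste0("f(", phenotype, ")")) +
    ggplot2::labs(x = paste0("PC", components[1]),
                  y = paste0("PC", components[2])) +
    ggplot2::theme_minimal()
}

#' Factor-signature panel
#'
#' Least-squares mean proportions per factor level with standard errors,
#' faceted by factor category; significance codes from the Tukey-Kramer
#' contrasts against the first level are printed above the bars.
#'
#' @param x A `factor_signature`.
#' @return A ggplot.
#' @export
plot_signature <- function(x) {
  lsm <- x$ls_means
  ref <- x$contrasts |>
    dplyr::group_by(.data$factor) |>
    dplyr::filter(.data$levelA == dplyr::first(.data$levelA) |
                    .data$levelB == dplyr::first(.data$levelA)) |>
    dplyr::ungroup()
  codes <- lsm |>
    dplyr::left_join(
      dplyr::transmute(ref, factor = .data$factor,
                       level = ifelse(.data$levelA == .data$levelB[1],
                                      .data$levelB, .data$levelA),
                       code = .data$code),
      by = c("factor", "level"))
  ggplot2::ggplot(codes, ggplot2::aes(.data$level, .data$ls_mean)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ls_mean - .data$se,
                                        ymax = .data$ls_mean + .data$se),
                           width = 0.3) +
    ggplot2::geom_text(ggplot2::aes(label = .data$code,
                                    y = .data$ls_mean + .data$se),
                       vjust = -0.4, na.rm = TRUE) +
    ggplot2::facet_wrap(~factor, scales = "free_x") +
    ggplot2::labs(title = paste0("Signature: ", x$phenotype),
                  x = NULL, y = "LS-mean proportion") +
    ggplot2::theme_minimal()
}

#' Ranked-map composition heat map
#'
#' Percentage of top-ranked wells at each factor level, per phenotype.
#'
#' @param report Long composition table from [composition_report()].
#' @return A ggplot.
#' @export
plot_ranked_map <- function(report) {
  ggplot2::ggplot(report,
                  ggplot2::aes(.data$phenotype, .data$level,
                               fill = .data$percent)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = round(.data$percent)),
                       size = 3, colour = "white") +
    ggplot2::facet_grid(category ~ ., scales = "free_y", space = "free_y") +
    ggplot2::scale_fill_viridis_c(name = "% of top wells") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.morphoscreen_svd <- function(object, ...) {
  plot_variance_explained(object, ...)
}

#' @export
autoplot.factor_signature <- function(object, ...) plot_signature(object)

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
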
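#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy an SVD result
#'
#' One row per (measurement, component) loading for the selected number of
#' components.
#'
#' @param x A `morphoscreen_svd`.
#' @param n_components Components to keep.
#' @param ... Unused.
#' @return Tibble `measurement, component, loading`.
#' @export
tidy.morphoscreen_svd <- function(x, n_components = min(10, length(x$d)), ...) {
  tibble::tibble(
    measurement = rep(rownames(x$loadings), n_components),
    component = rep(seq_len(n_components), each = nrow(x$loadings)),
    loading = as.vector(x$loadings[, seq_len(n_components)]))
}

#' @rdname tidy.morphoscreen_svd
#' @export
glance.morphoscreen_svd <- function(x, ...) {
  tibble::tibble(
    n_colonies = nrow(x$scores),
    n_measurements = nrow(x$loadings),
    var_pc1 = x$variance_explained[1],
    var_top10 = sum(x$variance_explained[seq_len(min(10, length(x$d)))]))
}

#' Tidy a factor signature
#'
#' @param x A `factor_signature`.
#' @param what `"contrasts"` (Tukey-Kramer pairs) or `"ls_means"`.
#' @param ... Unused.
#' @return Tibble of contrasts or least-squares means with a `phenotype`
#'   column.
#' @export
tidy.factor_signature <- function(x, what = c("contrasts", "ls_means"), ...) {
  what <- match.arg(what)
  dplyr::mutate(x[[what]], phenotype = x$phenotype, .before = 1)
}

#' @rdname tidy.factor_signature
#' @export
glance.factor_signature <- function(x, ...) {
  tibble::tibble(
    phenotype = x$phenotype,
    formula = deparse(stats::formula(x$model$fit)),
    dispersion = x$model$dispersion,
    n_wells = nrow(x$model$data),
    separation_adjusted = x$model$separation_adjusted)
}

#' Tidy a classification summary
#'
#' @param x A `classification_summary`.
#' @param ... Unused.
#' @return Tibble `phenotype, n, fraction, percent`.
#' @export
tidy.classification_summary <- function(x, ...) {
  tibble::tibble(
    phenotype = x$phenotypes,
    n = x$class_counts,
    fraction = x$class_fractions,
    percent = class_fractions(x$class_counts, x$n_total))
}

#' Tidy a ranked map
#'
#' @param x A `ranked_map`.
#' @param ... Unused.
#' @return The long composition tibble.
#' @export
tidy.ranked_map <- function(x, ...) {
  dplyr::mutate(x$composition, phenotype = x$phenotype %||% NA_character_,
                .before = 1)
}
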
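#' @importFrom rlang %||% abort warn .data
#' @importFrom stats median sd quantile setNames rnbinom qnbinom rnorm runif
#'   cor coef predict as.dist hclust cophenetic prcomp glm quasibinomial
#'   binomial as.formula terms rmultinom p.adjust mad
#' @importFrom utils head tail
NULL

# numerically stable softmax
softmax <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

#' @keywords internal
assert_that <- function(ok, msg) {
  if (!ok) rlang::abort(msg)
  invisible(TRUE)
}

# Derive a stream of child seeds from a parent seed, kept within the
# 32-bit integer range so they are valid arguments to set.seed().
derive_seeds <- function(seed, n, stream = 0L) {
  set.seed((as.integer(seed) + 1000003L * as.integer(stream)) %% .Machine$integer.max)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Canonical phenotype labels
#'
#' The four colony phenotypes scored in the screen, in the order used
#' throughout the package: apico-basally polarized (round colony with a
#' central actin belt), non-polarized (round, spatially uniform actin),
#' spread (elongated colony with diffuse actin fibers), and inverted
#' (actin bundles concentrated at the colony edge).
#'
#' @return Character vector of length four.
#' @export
phenotypes <- function() c("polarized", "nonpolarized", "spread", "inverted")

sig_code <- function(p) {
  dplyr::case_when(
    p < 0.001 ~ "***",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ ""
  )
}
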
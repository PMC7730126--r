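#' Z-score scaling of the feature table
#'
#' Scales each measurement to zero mean and unit variance across colonies.
#' Constant (zero-variance) measurements cannot be scaled and are dropped
#' with a warning; their names are recorded on the result.
#'
#' @param features Feature tibble from [feature_table()] (id columns are
#'   carried through untouched) or a plain numeric matrix.
#' @return A `scaled_features` object: `matrix` (colonies x measurements),
#'   `ids` (tibble of id columns, if any), `dropped` (constant
#'   measurements).
#' @export
scale_features <- function(features) {
  if (is.matrix(features)) {
    ids <- NULL
    m <- features
  } else {
    feat_cols <- intersect(feature_columns(), names(features))
    if (length(feat_cols) == 0) {
      feat_cols <- names(features)[vapply(features, is.numeric, logical(1))]
      feat_cols <- setdiff(feat_cols, c("colony_id", "cx", "cy"))
    }
    ids <- features[intersect(c("well_id", "colony_id"), names(features))]
    m <- as.matrix(features[feat_cols])
  }
  assert_that(nrow(m) >= 2, "need at least 2 colonies to scale")
  sds <- apply(m, 2, sd)
  constant <- sds < 1e-12 | !is.finite(sds)
  if (all(constant)) rlang::abort("all measurements are constant; nothing to scale")
  if (any(constant)) {
    rlang::warn(paste0("dropping constant measurement(s): ",
                       paste(head(colnames(m)[constant], 8), collapse = ", "),
                       if (sum(constant) > 8) " ..."))
  }
  dropped <- colnames(m)[constant]
  m <- m[, !constant, drop = FALSE]
  sc <- scale(m)
  attr(sc, "scaled:center") <- NULL
  attr(sc, "scaled:scale") <- NULL
  structure(list(matrix = sc, ids = ids, dropped = dropped),
            class = "scaled_features")
}

#' Singular value decomposition of the scaled feature matrix
#'
#' Thin SVD `X = U D V'` of the colonies x measurements z-score matrix.
#' Colony scores are the left singular vectors (unit norm), loadings the
#' right singular vectors, and per-component variance explained is
#' `d_i^2 / sum(d^2)`. The sign of each component is fixed so that its
#' largest-magnitude loading is positive, making loadings and score signs
#' reproducible.
#'
#' @param scaled A `scaled_features` object or plain numeric matrix.
#' @return A `morphoscreen_svd`: `scores` (n x k), `loadings` (p x k,
#'   rownames = measurement names), `d` (singular values, decreasing),
#'   `variance_explained`, `ids`.
#' @export
svd_decompose <- function(scaled) {
  m <- if (inherits(scaled, "scaled_features")) scaled$matrix else scaled
  ids <- if (inherits(scaled, "scaled_features")) scaled$ids else NULL
  if (!all(is.finite(m))) rlang::abort("scaled matrix contains non-finite values")
  s <- svd(m)
  flip <- vapply(seq_len(ncol(s$v)), function(j) {
    v <- s$v[, j]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  flip[flip == 0] <- 1
  u <- sweep(s$u, 2, flip, "*")
  v <- sweep(s$v, 2, flip, "*")
  rownames(v) <- colnames(m)
  colnames(v) <- colnames(u) <- paste0("PC", seq_len(ncol(u)))
  structure(list(scores = u, loadings = v, d = s$d,
                 variance_explained = s$d^2 / sum(s$d^2),
                 ids = ids),
            class = "morphoscreen_svd")
}

#' @export
print.morphoscreen_svd <- function(x, ...) {
  cat("SVD of scaled morphometry:", nrow(x$scores), "colonies x",
      nrow(x$loadings), "measurements\n")
  ve <- round(100 * x$variance_explained[seq_len(min(10, length(x$d)))], 1)
  cat("variance explained (top ", length(ve), " PCs): ",
      paste0(ve, "%", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Select leading components
#'
#' Returns the indices of the first `min(max_k, k*)` components, where
#' `k*` is the smallest number of components whose cumulative variance
#' explained reaches `threshold` (at least one component is always
#' selected).
#'
#' @param x A `morphoscreen_svd`.
#' @param threshold Cumulative variance-explained target.
#' @param max_k Hard cap on the number of components.
#' @return List with `components` (integer vector) and
#'   `cumulative_variance` of the selection.
#' @export
select_components <- function(x, threshold = 0.73, max_k = 10) {
  cum <- cumsum(x$variance_explained)
  k_star <- which(cum >= threshold)[1]
  if (is.na(k_star)) k_star <- length(cum)
  k <- max(1L, min(max_k, k_star))
  list(components = seq_len(k), cumulative_variance = cum[k])
}

#' Correlation of component scores with phenotype frequencies
#'
#' For each selected component, the Pearson correlation between the
#' colony-level component scores and the frequency of a phenotype in each
#' colony's well of origin (the well frequency broadcast to its colonies).
#' With `aggregate = "well"` the scores are first averaged per well and
#' correlated against the well frequencies directly.
#'
#' @param x A `morphoscreen_svd` whose `ids` carry `well_id` per colony.
#' @param profiles Well profile tibble from [well_profiles()].
#' @param components Integer vector of component indices.
#' @param aggregate `"colony"` (default) or `"well"`.
#' @return Tibble `component, phenotype, pcc, n, undefined`; correlations
#'   against a zero-variance frequency are flagged undefined (`NA` pcc).
#' @export
pc_phenotype_correlation <- function(x, profiles,
                                     components = seq_len(min(10, length(x$d))),
                                     aggregate = c("colony", "well")) {
  aggregate <- match.arg(aggregate)
  assert_that(!is.null(x$ids) && "well_id" %in% names(x$ids),
              "svd result carries no well ids; build it from a feature table")
  wells <- x$ids$well_id
  fcols <- paste0("f_", phenotypes())
  prof <- profiles[c("well_id", fcols)]
  missing <- setdiff(unique(wells), prof$well_id)
  if (length(missing) > 0) {
    rlang::abort(paste0("no profile for well(s): ",
                        paste(head(missing, 5), collapse = ", ")))
  }
  if (aggregate == "colony") {
    freq <- prof[match(wells, prof$well_id), fcols]
    score_mat <- x$scores
  } else {
    agg <- rowsum(x$scores[, components, drop = FALSE], wells) /
      as.vector(table(wells)[sort(unique(wells))])
    agg <- agg[order(rownames(agg)), , drop = FALSE]
    freq <- prof[match(rownames(agg), prof$well_id), fcols]
    score_mat <- matrix(NA_real_, nrow(agg), max(components))
    score_mat[, components] <- agg
  }
  purrr::map_dfr(components, function(k) {
    purrr::map_dfr(seq_along(phenotypes()), function(j) {
      f <- freq[[fcols[j]]]
      s <- score_mat[, k]
      ok <- is.finite(f) & is.finite(s)
      undef <- sd(f[ok]) < 1e-12 || sd(s[ok]) < 1e-12 || sum(ok) < 3
      tibble::tibble(
        component = k, phenotype = phenotypes()[j],
        pcc = if (undef) NA_real_ else cor(s[ok], f[ok]),
        n = sum(ok), undefined = undef)
    })
  })
}

#' Measurement contributions to a component
#'
#' Decomposes a component's loadings into the three measurement families
#' (absolute-contribution distribution summaries) and reports the most
#' positive and most negative signed loadings.
#'
#' @param x A `morphoscreen_svd`.
#' @param component Component index.
#' @param manifest Feature manifest tibble (`name`, `family`).
#' @param n_top Contributors to report per sign.
#' @return List with `family` (tibble `family, total_abs, share, mean_abs,
#'   max_abs`) and `top` (tibble `name, family, loading, sign`).
#' @export
measurement_contributions <- function(x, component, manifest = feature_manifest(),
                                      n_top = 4) {
  v <- x$loadings[, component]
  fam <- manifest$family[match(names(v), manifest$name)]
  if (anyNA(fam)) {
    rlang::abort(paste0("measurements missing from manifest: ",
                        paste(head(names(v)[is.na(fam)], 5), collapse = ", ")))
  }
  family <- tibble::tibble(name = names(v), family = fam, loading = v) |>
    dplyr::group_by(.data$family) |>
    dplyr::summarise(total_abs = sum(abs(.data$loading)),
                     mean_abs = mean(abs(.data$loading)),
                     max_abs = max(abs(.data$loading)), .groups = "drop") |>
    dplyr::mutate(share = .data$total_abs / sum(.data$total_abs))
  ord <- order(v)
  top_neg <- head(ord, n_top)
  top_pos <- rev(tail(ord, n_top))
  top <- tibble::tibble(
    name = names(v)[c(top_pos, top_neg)],
    family = fam[c(top_pos, top_neg)],
    loading = v[c(top_pos, top_neg)],
    sign = rep(c("positive", "negative"), each = n_top))
  list(family = family, top = top)
}

#' Hierarchical co-occurrence clustering of the four phenotypes
#'
#' Clusters the four phenotype frequency vectors (indexed by well) by
#' correlation distance (1 - Pearson r) with average linkage, revealing
#' which phenotypes co-occur in the same wells and which are mutually
#' exclusive.
#'
#' @param profiles Well profile tibble ([well_profiles()]); wells with
#'   undefined profiles are dropped.
#' @return List with `hclust` (the merge tree; leaves are the four
#'   phenotype labels), `cophenetic` (distance matrix), and `distance`
#'   (the correlation-distance matrix used).
#' @export
phenotype_cooccurrence_clustering <- function(profiles) {
  fcols <- paste0("f_", phenotypes())
  m <- as.matrix(profiles[fcols])
  keep <- stats::complete.cases(m)
  m <- m[keep, , drop = FALSE]
  assert_that(nrow(m) >= 3, "need at least 3 wells with defined profiles")
  if (nrow(unique(m)) < 2) rlang::abort("need at least 2 distinct profiles")
  colnames(m) <- phenotypes()
  cc <- suppressWarnings(cor(m))
  cc[!is.finite(cc)] <- 0
  d <- as.dist(1 - cc)
  hc <- hclust(d, method = "average")
  list(hclust = hc, cophenetic = cophenetic(hc), distance = d)
}
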
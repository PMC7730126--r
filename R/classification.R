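#' Training protocol for the phenotype classifier
#'
#' Mirrors the screen's annotate-validate loop: at least
#' `min_train_per_class` labelled examples per phenotype enter the training
#' set, each iteration validates on at least `min_validation` held-out
#' examples, and iteration stops once at least `min_correct` validation
#' examples have been classified correctly (cumulatively across
#' iterations), up to `max_iterations`.
#'
#' @param min_train_per_class Training examples per class.
#' @param min_validation Held-out examples validated per iteration.
#' @param min_correct Cumulative correct validations required to stop.
#' @param max_iterations Iteration cap (reaching it raises a warning).
#' @return A `training_protocol` object.
#' @export
training_protocol <- function(min_train_per_class = 30, min_validation = 10,
                              min_correct = 15, max_iterations = 20) {
  vals <- c(min_train_per_class, min_validation, max_iterations)
  assert_that(all(vals > 0) && min_correct >= 0,
              "protocol sizes must be positive")
  structure(list(min_train_per_class = min_train_per_class,
                 min_validation = min_validation,
                 min_correct = min_correct,
                 max_iterations = max_iterations),
            class = "training_protocol")
}

#' Stratified training / validation split
#'
#' Draws a seeded stratified split from a labelled feature table:
#' `min_train_per_class` rows per phenotype for training, everything else
#' held out for validation. Errors if any class cannot satisfy the
#' protocol, naming the deficient class.
#'
#' @param features Feature tibble including a `phenotype` column.
#' @param protocol A [training_protocol()].
#' @param seed Integer seed.
#' @return List with `train` and `validation` tibbles.
#' @export
build_training_set <- function(features, protocol = training_protocol(),
                               seed = 1) {
  stopifnot("phenotype" %in% names(features))
  features <- dplyr::filter(features, !is.na(.data$phenotype))
  counts <- table(features$phenotype)
  need <- protocol$min_train_per_class + protocol$min_validation
  short <- names(counts)[counts < need]
  missing_classes <- setdiff(phenotypes(), names(counts))
  if (length(c(short, missing_classes)) > 0) {
    rlang::abort(paste0(
      "insufficient labelled examples for class(es): ",
      paste(unique(c(short, missing_classes)), collapse = ", "),
      " (need ", need, " per class)"))
  }
  set.seed(seed)
  idx <- features |>
    dplyr::mutate(.row = dplyr::row_number()) |>
    dplyr::group_by(.data$phenotype) |>
    dplyr::slice_sample(prop = 1) |>
    dplyr::mutate(.take = dplyr::row_number() <= protocol$min_train_per_class) |>
    dplyr::ungroup()
  list(train = features[idx$.row[idx$.take], ],
       validation = features[idx$.row[!idx$.take], ])
}

#' Iteratively validated random-forest training
#'
#' Fits a random forest on the training set, then repeatedly validates on
#' `min_validation` fresh held-out examples per iteration, folding each
#' validated batch into the training set for the next refit (emulating the
#' interactive annotate-and-refine loop). Stops once the cumulative number
#' of correctly classified validation examples reaches `min_correct`, or at
#' `max_iterations` with a warning.
#'
#' @param split Output of [build_training_set()].
#' @param protocol A [training_protocol()].
#' @param seed Integer seed (forest and validation draws).
#' @param num_trees Trees in the forest.
#' @return A `phenotype_classifier`: the fitted forest, the feature
#'   manifest used, and a per-iteration log
#'   (`iteration, n_validated, n_correct, cum_correct, accuracy`).
#' @export
train_iterative <- function(split, protocol = training_protocol(), seed = 1,
                            num_trees = 100) {
  feat_cols <- intersect(feature_columns(), names(split$train))
  assert_that(length(feat_cols) > 0, "no feature columns found in split")
  train <- split$train
  pool <- split$validation
  log <- list()
  cum_correct <- 0L
  fit <- NULL
  seeds <- derive_seeds(seed, protocol$max_iterations, stream = 7L)
  for (it in seq_len(protocol$max_iterations)) {
    set.seed(seeds[it])
    fit <- randomForest::randomForest(
      x = as.matrix(train[feat_cols]),
      y = factor(train$phenotype, levels = phenotypes()),
      ntree = num_trees)
    n_val <- min(protocol$min_validation, nrow(pool))
    if (n_val == 0) {
      rlang::warn("validation pool exhausted before stopping criterion met")
      break
    }
    take <- sample.int(nrow(pool), n_val)
    batch <- pool[take, ]
    pool <- pool[-take, ]
    pred <- predict(fit, as.matrix(batch[feat_cols]))
    n_corr <- sum(as.character(pred) == batch$phenotype)
    cum_correct <- cum_correct + n_corr
    log[[it]] <- tibble::tibble(iteration = it, n_validated = n_val,
                                n_correct = n_corr,
                                cum_correct = cum_correct,
                                accuracy = n_corr / n_val)
    train <- dplyr::bind_rows(train, batch)
    if (cum_correct >= protocol$min_correct) break
    if (it == protocol$max_iterations) {
      rlang::warn("stopping criterion not met within max_iterations; returning last model")
    }
  }
  structure(list(forest = fit, feature_columns = feat_cols,
                 log = dplyr::bind_rows(log), protocol = protocol),
            class = "phenotype_classifier")
}

#' Classify all colonies of a plate
#'
#' Applies a trained classifier to a feature table and summarises class
#' composition. Colonies with forest vote fraction below
#' `confidence_floor` are left unclassified (`NA`); the default floor of 0
#' classifies everything.
#'
#' @param classifier A `phenotype_classifier` from [train_iterative()].
#' @param features Feature tibble (columns must cover the classifier's
#'   manifest).
#' @param confidence_floor Minimum winning vote fraction.
#' @return A `classification_summary`: `predictions` (tibble `well_id,
#'   colony_id, predicted_phenotype, confidence`), `class_counts`,
#'   `class_fractions` (of all colonies, classified or not), and `n_total`.
#' @export
classify_plate <- function(classifier, features, confidence_floor = 0) {
  missing <- setdiff(classifier$feature_columns, names(features))
  if (length(missing) > 0) {
    rlang::abort(paste0("feature table does not match training manifest; missing: ",
                        paste(head(missing, 5), collapse = ", ")))
  }
  votes <- predict(classifier$forest,
                   as.matrix(features[classifier$feature_columns]),
                   type = "vote")
  win <- max.col(votes, ties.method = "first")
  conf <- votes[cbind(seq_len(nrow(votes)), win)]
  pred <- colnames(votes)[win]
  pred[conf < confidence_floor] <- NA_character_
  predictions <- tibble::tibble(
    well_id = features$well_id,
    colony_id = features$colony_id,
    predicted_phenotype = pred,
    confidence = conf)
  cc <- table(factor(pred, levels = phenotypes()))
  structure(list(predictions = predictions,
                 class_counts = as.integer(cc),
                 class_fractions = as.numeric(cc) / nrow(predictions),
                 phenotypes = phenotypes(),
                 n_total = nrow(predictions)),
            class = "classification_summary")
}

#' Phenotype class fractions from counts
#'
#' Per-class percentages against the total segmented colony count, rounded
#' to one decimal as reported by the screen (so the four classes need not
#' sum to exactly 100).
#'
#' @param counts Named integer vector of per-class colony counts.
#' @param total Total number of segmented colonies.
#' @return Named numeric vector of percentages (one decimal).
#' @export
class_fractions <- function(counts, total) {
  assert_that(total > 0, "total must be positive")
  round(100 * counts / total, 1)
}

#' Per-well phenotype frequency profiles
#'
#' Joins colony-level predictions onto the plate layout and computes, per
#' well, the frequency of each phenotype relative to the well's segmented
#' colony count. Wells present in the layout but without colonies are kept
#' with zero counts and flagged.
#'
#' @param predictions Prediction tibble (from a `classification_summary`)
#'   or any tibble with `well_id` and `predicted_phenotype`.
#' @param layout Design/layout tibble with a `well_id` column.
#' @return Tibble `well_id, n_colonies, n_<phenotype> x4, f_<phenotype> x4,
#'   empty_well`.
#' @export
well_profiles <- function(predictions, layout) {
  orphans <- setdiff(unique(predictions$well_id), layout$well_id)
  if (length(orphans) > 0) {
    rlang::abort(paste0("predictions reference wells absent from layout: ",
                        paste(head(orphans, 5), collapse = ", ")))
  }
  counts <- predictions |>
    dplyr::filter(!is.na(.data$predicted_phenotype)) |>
    dplyr::count(.data$well_id, .data$predicted_phenotype) |>
    tidyr::pivot_wider(names_from = "predicted_phenotype",
                       values_from = "n", values_fill = 0L,
                       names_prefix = "n_")
  for (ph in phenotypes()) {
    col <- paste0("n_", ph)
    if (!col %in% names(counts)) counts[[col]] <- 0L
  }
  totals <- dplyr::count(predictions, .data$well_id, name = "n_colonies")
  out <- tibble::tibble(well_id = layout$well_id) |>
    dplyr::left_join(totals, by = "well_id") |>
    dplyr::left_join(counts, by = "well_id") |>
    dplyr::mutate(dplyr::across(dplyr::starts_with("n_"),
                                ~ tidyr::replace_na(.x, 0L)))
  for (ph in phenotypes()) {
    out[[paste0("f_", ph)]] <- ifelse(out$n_colonies > 0,
                                      out[[paste0("n_", ph)]] / out$n_colonies,
                                      NA_real_)
  }
  dplyr::mutate(out, empty_well = .data$n_colonies == 0)
}
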
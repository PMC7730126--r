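#' Pipeline configuration
#'
#' A single nested configuration for the end-to-end run: design levels,
#' planted effect model, rendering parameters, segmentation parameters,
#' training protocol, and the analysis thresholds. Every stochastic stage
#' draws from a named seed derived from `seed`.
#'
#' @param seed Master seed.
#' @param levels A [factor_levels()].
#' @param model A [phenotype_effect_model()].
#' @param params A [plate_params()].
#' @param segmentation List of [segment_well()] arguments.
#' @param protocol A [training_protocol()].
#' @param svd_threshold,svd_max_k Component-selection settings.
#' @param top_fraction Ranked-map selection fraction.
#' @param label_fraction Fraction of wells whose matched ground truth is
#'   used as training labels (the synthetic stand-in for the interactive
#'   annotator).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1,
                            levels = factor_levels(),
                            model = phenotype_effect_model(),
                            params = plate_params(),
                            segmentation = list(sigma = 2, min_area = 100),
                            protocol = training_protocol(),
                            svd_threshold = 0.73, svd_max_k = 10,
                            top_fraction = 0.05,
                            label_fraction = 0.25) {
  structure(list(seed = seed, levels = levels, model = model, params = params,
                 segmentation = segmentation, protocol = protocol,
                 svd_threshold = svd_threshold, svd_max_k = svd_max_k,
                 top_fraction = top_fraction, label_fraction = label_fraction),
            class = "pipeline_config")
}

#' Run the full screen-analysis pipeline
#'
#' Executes design -> simulate -> segment -> measure -> classify ->
#' profile -> SVD / GLM signatures / ranked maps on a synthetic plate.
#' Wells are processed in a streaming fashion (generate, segment, measure,
#' then discard the image) so a full plate never needs to be held in
#' memory; set `out_dir` to persist per-stage artifacts as CSV/JSON (and
#' `write_images = TRUE` to keep the TIFFs).
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory for artifacts and manifest.
#' @param write_images Write per-well TIFFs under `out_dir/wells/`.
#' @param signatures Fit the per-phenotype GLM signatures (the slowest
#'   analysis stage).
#' @return A `pipeline_result` with `design`, `truth`, `counts`,
#'   `features`, `classifier`, `classification`, `profiles`, `svd`,
#'   `associations`, `clustering`, `signatures`, `maps`, and `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         write_images = FALSE, signatures = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  seeds <- derive_seeds(config$seed, 6, stream = 99L)

  conditions <- enumerate_conditions(config$levels)
  design <- assign_wells(conditions, replicates = config$levels$replicates,
                         seed = seeds[1])
  pr <- condition_phenotype_probs(config$model, design)
  pm <- as.matrix(pr[paste0("p_", phenotypes())])
  well_seeds <- derive_seeds(seeds[2], nrow(design))

  if (!is.null(out_dir) && !dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  if (write_images && !is.null(out_dir)) {
    dir.create(file.path(out_dir, "wells"), showWarnings = FALSE)
  }

  truth <- feats <- vector("list", nrow(design))
  n_seg <- integer(nrow(design))
  seg_args <- config$segmentation
  for (i in seq_len(nrow(design))) {
    w <- generate_well(design$well_id[i], pm[i, ], well_seeds[i], config$params)
    if (write_images && !is.null(out_dir)) {
      write_well_image(w$image, file.path(out_dir, "wells",
                                          paste0(design$well_id[i], ".tif")))
    }
    seg <- do.call(segment_well, c(list(image = w$image), seg_args))
    fw <- well_features(seg, w$image, design$well_id[i])
    if (nrow(fw) > 0) {
      matched <- match_truth(seg$colonies, w$truth)
      fw$true_phenotype <- matched$phenotype[match(fw$colony_id,
                                                   matched$colony_id)]
    }
    truth[[i]] <- w$truth
    feats[[i]] <- fw
    n_seg[i] <- nrow(seg$colonies)
  }
  truth <- dplyr::bind_rows(truth)
  features <- dplyr::bind_rows(feats)
  counts <- count_colonies(tibble::tibble(well_id = design$well_id,
                                          n_colonies = n_seg))

  # training labels: matched ground truth on a seeded subset of wells
  # (the synthetic stand-in for interactive annotation)
  set.seed(seeds[3])
  n_lab <- max(1, round(config$label_fraction * nrow(design)))
  label_wells <- sample(design$well_id, n_lab)
  labelled <- features |>
    dplyr::filter(.data$well_id %in% label_wells,
                  !is.na(.data$true_phenotype)) |>
    dplyr::mutate(phenotype = .data$true_phenotype)
  split <- build_training_set(labelled, config$protocol, seed = seeds[4])
  classifier <- train_iterative(split, config$protocol, seed = seeds[5])
  classification <- classify_plate(classifier, features)
  profiles <- well_profiles(classification$predictions, design)

  sc <- scale_features(features)
  sv <- svd_decompose(sc)
  sel <- select_components(sv, config$svd_threshold, config$svd_max_k)
  assoc <- pc_phenotype_correlation(sv, profiles, sel$components)
  clustering <- phenotype_cooccurrence_clustering(profiles)
  sigs <- if (signatures) {
    setNames(lapply(phenotypes(), function(ph)
      phenotype_signature(profiles, design, ph)), phenotypes())
  }
  maps <- composition_report(profiles, design, config$top_fraction)

  manifest <- list(
    seed = config$seed,
    n_conditions = nrow(conditions),
    n_wells = nrow(design),
    n_colonies_truth = nrow(truth),
    n_colonies_segmented = counts$total,
    n_colonies_measured = nrow(features),
    n_features = length(intersect(feature_columns(), names(features))),
    classifier_iterations = nrow(classifier$log),
    svd_components = length(sel$components),
    svd_cumulative_variance = sel$cumulative_variance,
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))

  result <- structure(
    list(design = design, truth = truth, counts = counts,
         features = features, classifier = classifier,
         classification = classification, profiles = profiles,
         svd = sv, selected_components = sel, associations = assoc,
         clustering = clustering, signatures = sigs, maps = maps,
         manifest = manifest),
    class = "pipeline_result")

  if (!is.null(out_dir)) {
    readr::write_csv(design, file.path(out_dir, "design.csv"))
    readr::write_csv(truth, file.path(out_dir, "truth.csv"))
    readr::write_csv(features, file.path(out_dir, "features.csv"))
    readr::write_csv(classification$predictions,
                     file.path(out_dir, "predictions.csv"))
    readr::write_csv(profiles, file.path(out_dir, "profiles.csv"))
    readr::write_csv(maps, file.path(out_dir, "ranked_maps.csv"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  m <- x$manifest
  cat("morphoscreen pipeline run\n")
  cat(sprintf("  %d conditions, %d wells, %d colonies segmented (%d true)\n",
              m$n_conditions, m$n_wells, m$n_colonies_segmented,
              m$n_colonies_truth))
  cat(sprintf("  %d features/colony; %d SVD components (%.1f%% variance)\n",
              m$n_features, m$svd_components,
              100 * m$svd_cumulative_variance))
  cat(sprintf("  elapsed: %.1f s\n", m$elapsed_s))
  invisible(x)
}
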
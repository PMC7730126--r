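#' Segment colonies in a whole-well image
#'
#' Classical threshold segmentation: Gaussian smoothing, a global Otsu
#' threshold (or a fixed override), hole filling, 8-connected component
#' labelling, and removal of components below `min_area`. Touching colonies
#' are not split; the synthetic generator guarantees non-overlap and
#' declumping is out of scope.
#'
#' A contrast guard protects against background-only wells: if the mean
#' separation between the putative foreground and background classes is
#' below `min_contrast_sd` background standard deviations, the Otsu split
#' is considered spurious and the well is reported empty. A constant image
#' likewise yields zero colonies (not an error).
#'
#' @param image Intensity matrix (finite, non-negative; 16-bit counts).
#' @param sigma Gaussian smoothing sigma in pixels (0 disables smoothing).
#' @param threshold Fixed intensity threshold in counts; `NULL` (default)
#'   uses Otsu's method on the smoothed image.
#' @param min_area Minimum component area in pixels.
#' @param fill_holes Fill holes inside components before labelling.
#' @param min_contrast_sd Contrast guard (see above); only applied when the
#'   threshold is automatic.
#' @return An object of class `segmentation`: `label_mask` (integer matrix,
#'   0 = background, labels consecutive from 1 in raster order), `colonies`
#'   (tibble `colony_id, cx, cy, area_px, xmin, xmax, ymin, ymax` with
#'   0-based pixel-centred centroids and half-open bounding boxes), and the
#'   resolved `threshold`.
#' @export
segment_well <- function(image, sigma = 2, threshold = NULL, min_area = 100,
                         fill_holes = TRUE, min_contrast_sd = 4) {
  if (!all(is.finite(image))) rlang::abort("image contains non-finite pixels")
  if (any(image < 0)) rlang::abort("image contains negative pixels")
  img <- image
  if (sigma > 0) {
    img <- as.matrix(EBImage::gblur(EBImage::Image(image / 65535), sigma)) * 65535
  }
  empty <- function(thr) {
    structure(list(label_mask = matrix(0L, nrow(image), ncol(image)),
                   colonies = empty_colony_table(), threshold = thr),
              class = "segmentation")
  }
  if (max(img) - min(img) < 1e-9) return(empty(NA_real_))
  if (is.null(threshold)) {
    # Otsu over the observed intensity range (the histogram would collapse
    # into a few bins of the full 16-bit range otherwise)
    rng <- range(img)
    norm <- (img - rng[1]) / diff(rng)
    thr <- rng[1] + EBImage::otsu(EBImage::Image(norm), range = c(0, 1)) * diff(rng)
    below <- img[img <= thr]; above <- img[img > thr]
    if (length(above) == 0 ||
        (mean(above) - mean(below)) < min_contrast_sd * max(sd(below), 1e-9)) {
      return(empty(thr))
    }
  } else {
    thr <- threshold
  }
  mask <- img > thr
  if (!any(mask)) return(empty(thr))
  m <- EBImage::Image(mask * 1)
  if (fill_holes) m <- EBImage::fillHull(m)
  labels <- EBImage::bwlabel(m)
  labels <- merge_diagonal_labels(as.matrix(EBImage::imageData(labels)))
  labels <- filter_relabel(labels, min_area)
  structure(list(label_mask = labels,
                 colonies = colony_table(labels),
                 threshold = thr),
            class = "segmentation")
}

empty_colony_table <- function() {
  tibble::tibble(colony_id = integer(0), cx = numeric(0), cy = numeric(0),
                 area_px = integer(0), xmin = integer(0), xmax = integer(0),
                 ymin = integer(0), ymax = integer(0))
}

# bwlabel is 4-connected; union labels that touch diagonally to obtain
# 8-connected components.
merge_diagonal_labels <- function(lab) {
  lab <- round(lab)
  mode(lab) <- "integer"
  nmax <- max(lab)
  if (nmax == 0) return(lab)
  parent <- seq_len(nmax)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  nr <- nrow(lab); nc <- ncol(lab)
  collect <- function(a, b) {
    keep <- a > 0L & b > 0L & a != b
    unique(cbind(a[keep], b[keep]))
  }
  pairs <- rbind(
    collect(lab[-nr, -nc], lab[-1, -1]),   # down-right diagonal
    collect(lab[-nr, -1], lab[-1, -nc])    # down-left diagonal
  )
  if (nrow(pairs) > 0) {
    for (i in seq_len(nrow(pairs))) {
      ra <- find(pairs[i, 1]); rb <- find(pairs[i, 2])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
    roots <- vapply(seq_len(nmax), find, integer(1))
    lab[lab > 0L] <- roots[lab[lab > 0L]]
  }
  lab
}

# drop small components and relabel consecutively in raster order
filter_relabel <- function(lab, min_area) {
  if (max(lab) == 0) return(lab)
  areas <- tabulate(lab, nbins = max(lab))
  keep <- which(areas >= min_area)
  if (length(keep) == 0) return(matrix(0L, nrow(lab), ncol(lab)))
  # order by first raster occurrence (column-major) for stable ids
  first <- match(keep, lab)
  keep <- keep[order(first)]
  map <- integer(max(lab))
  map[keep] <- seq_along(keep)
  out <- lab
  out[out > 0L] <- map[out[out > 0L]]
  out
}

colony_table <- function(lab) {
  n <- max(lab)
  if (n == 0) return(empty_colony_table())
  idx <- which(lab > 0L)
  id <- lab[idx]
  row <- (idx - 1L) %% nrow(lab) + 1L
  col <- (idx - 1L) %/% nrow(lab) + 1L
  tibble::tibble(id = id, row = row, col = col) |>
    dplyr::group_by(colony_id = .data$id) |>
    dplyr::summarise(
      cx = mean(.data$col) - 1, cy = mean(.data$row) - 1,
      area_px = dplyr::n(),
      xmin = min(.data$col) - 1L, xmax = max(.data$col),
      ymin = min(.data$row) - 1L, ymax = max(.data$row),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$colony_id)
}

#' Plate-level colony counts
#'
#' Summarises one segmentation per well into per-well counts plus the
#' plate totals reported by the screen (total colonies, median and spread
#' of counts per well).
#'
#' @param segmentations Named list of `segmentation` objects (names =
#'   well ids), or a tibble with columns `well_id`, `n_colonies`.
#' @return List with `per_well` (tibble `well_id, n_colonies`), `total`,
#'   `median`, and `spread` (sd of per-well counts).
#' @export
count_colonies <- function(segmentations) {
  per_well <- if (is.data.frame(segmentations)) {
    tibble::as_tibble(segmentations[c("well_id", "n_colonies")])
  } else {
    tibble::tibble(
      well_id = names(segmentations) %||% as.character(seq_along(segmentations)),
      n_colonies = unname(vapply(segmentations, function(s) nrow(s$colonies),
                                 integer(1)))
    )
  }
  list(per_well = per_well,
       total = sum(per_well$n_colonies),
       median = median(per_well$n_colonies),
       spread = sd(per_well$n_colonies))
}

#' Match segmented colonies to ground truth
#'
#' Nearest-neighbour centroid matching between a segmentation and the
#' generator's ground-truth table for the same well: each segmented colony
#' is matched to the nearest unmatched true colony if their centroids lie
#' within `max_dist_factor` times the true radius. Used to transfer true
#' phenotype labels onto segmented objects and to score recall/precision.
#'
#' @param colonies Segmented colony tibble (from a `segmentation`).
#' @param truth Ground-truth tibble for the same well.
#' @param max_dist_factor Matching radius as a multiple of the true colony
#'   radius.
#' @return `colonies` with added `phenotype` (NA when unmatched) and
#'   `matched_colony` (true colony id).
#' @export
match_truth <- function(colonies, truth, max_dist_factor = 1) {
  if (nrow(colonies) == 0 || nrow(truth) == 0) {
    return(dplyr::mutate(colonies, phenotype = NA_character_,
                         matched_colony = NA_integer_))
  }
  d <- outer(colonies$cx, truth$cx, "-")^2 + outer(colonies$cy, truth$cy, "-")^2
  d <- sqrt(d)
  lim <- matrix(truth$radius * max_dist_factor, nrow(colonies), nrow(truth),
                byrow = TRUE)
  d[d > lim] <- Inf
  match_idx <- rep(NA_integer_, nrow(colonies))
  taken <- rep(FALSE, nrow(truth))
  ord <- order(apply(d, 1, min))
  for (i in ord) {
    j <- which.min(ifelse(taken, Inf, d[i, ]))
    if (length(j) && is.finite(d[i, j])) {
      match_idx[i] <- j
      taken[j] <- TRUE
    }
  }
  colonies$phenotype <- truth$phenotype[match_idx]
  colonies$matched_colony <- truth$colony_id[match_idx]
  colonies
}
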
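#' The 102-measurement feature manifest
#'
#' Names and family tags of the per-colony morphometric profile: 20
#' area-shape measurements (moment geometry, boundary-polygon perimeter
#' derivatives, Hu invariant moments, boundary-radius statistics), 30
#' intensity measurements (order statistics, mass displacement, edge vs
#' interior statistics, and a 4-ring radial distribution with three
#' statistics per ring), and 52 texture measurements (13 gray-level
#' co-occurrence statistics at pixel distances 1 and 4, summarised as the
#' mean and range over the four 2D offsets). The count of exactly 102
#' measurements in these three families is a conformance contract of the
#' pipeline.
#'
#' @return Tibble with columns `name` and `family`
#'   (`areashape` / `intensity` / `texture`), 102 rows.
#' @export
feature_manifest <- function() {
  areashape <- c("area", "perimeter", "eccentricity", "compactness",
                 "form_factor", "solidity", "extent", "equivalent_diameter",
                 "major_axis_length", "minor_axis_length", "axis_ratio",
                 paste0("hu", 1:7), "radius_mean", "radius_sd")
  intensity <- c("int_mean", "int_median", "int_std", "int_min", "int_max",
                 "int_integrated", "int_mad", "int_q25", "int_q75", "int_cv",
                 "mass_displacement", "edge_mean", "edge_std", "edge_min",
                 "edge_max", "interior_mean", "interior_std",
                 "edge_interior_ratio",
                 paste0("frac_at_d_r", 1:4), paste0("mean_frac_r", 1:4),
                 paste0("radial_cv_r", 1:4))
  stats13 <- c("asm", "contrast", "correlation", "variance", "idm",
               "sum_average", "sum_variance", "sum_entropy", "entropy",
               "diff_variance", "diff_entropy", "imc1", "imc2")
  texture <- as.vector(outer(
    as.vector(outer(stats13, c("d1", "d4"), paste, sep = "_")),
    c("mean", "range"), paste, sep = "_"))
  texture <- paste0("tex_", texture)
  tibble::tibble(
    name = c(areashape, intensity, texture),
    family = rep(c("areashape", "intensity", "texture"),
                 times = c(length(areashape), length(intensity), length(texture)))
  )
}

# ---- geometry helpers -------------------------------------------------------

mask_coords <- function(mask) {
  idx <- which(mask)
  cbind(row = (idx - 1L) %% nrow(mask) + 1L,
        col = (idx - 1L) %/% nrow(mask) + 1L)
}

# pixels of the mask with at least one 4-neighbour outside the mask
boundary_mask <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(FALSE, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- mask
  inner <- pad[2:(nr + 1), 1:nc] & pad[2:(nr + 1), 3:(nc + 2)] &
    pad[1:nr, 2:(nc + 1)] & pad[3:(nr + 2), 2:(nc + 1)]
  mask & !inner
}

# Moore-neighbour boundary tracing; returns the closed polygon of boundary
# pixel centres (row, col), used for the perimeter estimate.
trace_boundary <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(FALSE, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- mask
  # clockwise Moore neighbourhood (rows grow downward), starting west
  off <- cbind(c(0, -1, -1, -1, 0, 1, 1, 1), c(-1, -1, 0, 1, 1, 1, 0, -1))
  start <- which(t(pad))[1]  # row-major scan
  if (is.na(start)) return(NULL)
  srow <- (start - 1L) %/% (nc + 2L) + 1L
  scol <- (start - 1L) %% (nc + 2L) + 1L
  start <- c(srow, scol)
  cur <- start
  prev_dir <- 1L  # backtrack = west of start (outside by scan order)
  path <- matrix(NA_integer_, 4L * sum(mask) + 8L, 2L)
  path[1, ] <- cur
  np <- 1L
  first_move <- NULL
  repeat {
    found <- FALSE
    for (k in 0:7) {
      d <- (prev_dir + k - 1L) %% 8L + 1L
      nxt <- cur + off[d, ]
      if (pad[nxt[1], nxt[2]]) {
        # re-anchor: next scan starts just after the backtrack direction
        # as seen from the new pixel
        back <- cur - nxt
        bidx <- which(off[, 1] == back[1] & off[, 2] == back[2])
        prev_dir <- (bidx %% 8L) + 1L
        cur <- nxt
        found <- TRUE
        break
      }
    }
    if (!found) break  # isolated pixel
    np <- np + 1L
    path[np, ] <- cur
    if (is.null(first_move)) {
      first_move <- cur
    } else if (all(cur == first_move) && all(path[np - 1L, ] == start)) {
      break  # closed the contour (Jacob's criterion)
    }
    if (np >= nrow(path)) break
  }
  path[seq_len(np), , drop = FALSE]
}

# Corrected chain length over the boundary polygon: Vossepoel-Smeulders
# step weights with a halved corner correction. The full correction is
# unbiased for digitized straight edges but pushes convex digital shapes
# (where pixel-count area exceeds the polygon area) below the isoperimetric
# bound; halving it keeps a digitized disk's compactness slightly above 1.
polygon_length <- function(path) {
  if (is.null(path) || nrow(path) < 2) return(0)
  d <- diff(path)
  diag_step <- abs(d[, 1]) == 1 & abs(d[, 2]) == 1
  n_even <- sum(!diag_step)
  n_odd <- sum(diag_step)
  dirs <- atan2(d[, 1], d[, 2])
  n_corner <- if (nrow(d) > 1) sum(dirs[-1] != dirs[-length(dirs)]) else 0
  0.980 * n_even + 1.406 * n_odd - 0.0455 * n_corner
}

shoelace_area <- function(xy) {
  n <- nrow(xy)
  if (n < 3) return(0)
  x <- xy[, 1]; y <- xy[, 2]
  abs(sum(x * y[c(2:n, 1)] - x[c(2:n, 1)] * y)) / 2
}

check_single_component <- function(mask) {
  if (sum(mask) < 4) rlang::abort("mask must contain at least 4 pixels")
  lab <- merge_diagonal_labels(
    as.matrix(EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask * 1)))))
  if (length(unique(lab[lab > 0])) != 1) {
    rlang::abort("mask must be a single connected component")
  }
  invisible(TRUE)
}

# ---- area-shape -------------------------------------------------------------

#' Area-shape features of a colony mask
#'
#' Moment-based geometry of a single connected binary region. Eccentricity
#' and the axis lengths come from the ellipse with matching second central
#' moments; the perimeter is the length of the closed polygon through the
#' boundary pixel centres (Moore tracing); compactness is
#' `perimeter^2 / (4 pi area)` and form factor its reciprocal; solidity
#' divides the pixel area by the area of the convex hull of the pixel
#' corners. Hu's seven invariant moments and the centroid-to-boundary
#' radius statistics complete the family.
#'
#' @param mask Logical matrix, one 8-connected component of >= 4 px.
#' @return Named numeric vector of the 20 area-shape measurements.
#' @export
areashape_features <- function(mask) {
  check_single_component(mask)
  xy <- mask_coords(mask)
  a <- nrow(xy)
  cy <- mean(xy[, "row"]); cx <- mean(xy[, "col"])
  dr <- xy[, "row"] - cy; dc <- xy[, "col"] - cx
  mu20 <- mean(dc^2); mu02 <- mean(dr^2); mu11 <- mean(dc * dr)
  tr <- mu20 + mu02
  det_rt <- sqrt(max((mu20 - mu02)^2 + 4 * mu11^2, 0))
  l1 <- (tr + det_rt) / 2; l2 <- (tr - det_rt) / 2
  l2 <- max(l2, 0)
  major <- 4 * sqrt(l1); minor <- 4 * sqrt(l2)
  ecc <- if (l1 > 0) sqrt(max(1 - l2 / l1, 0)) else 0

  path <- trace_boundary(mask)
  perim <- polygon_length(path)
  compact <- if (perim > 0) perim^2 / (4 * pi * a) else 0
  ff <- if (compact > 0) 1 / compact else 0

  # convex hull over pixel corners so the hull contains the pixel squares
  corners <- rbind(cbind(xy[, "col"] - 0.5, xy[, "row"] - 0.5),
                   cbind(xy[, "col"] + 0.5, xy[, "row"] - 0.5),
                   cbind(xy[, "col"] - 0.5, xy[, "row"] + 0.5),
                   cbind(xy[, "col"] + 0.5, xy[, "row"] + 0.5))
  h <- grDevices::chull(corners)
  hull_area <- shoelace_area(corners[h, , drop = FALSE])
  solidity <- if (hull_area > 0) min(a / hull_area, 1) else 1

  bb_area <- (diff(range(xy[, "row"])) + 1) * (diff(range(xy[, "col"])) + 1)
  extent <- a / bb_area
  eqd <- 2 * sqrt(a / pi)
  axis_ratio <- if (minor > 0) major / minor else 0

  bmask <- boundary_mask(mask)
  bxy <- mask_coords(bmask)
  brad <- sqrt((bxy[, "row"] - cy)^2 + (bxy[, "col"] - cx)^2)

  c(area = a, perimeter = perim, eccentricity = ecc, compactness = compact,
    form_factor = ff, solidity = solidity, extent = extent,
    equivalent_diameter = eqd, major_axis_length = major,
    minor_axis_length = minor, axis_ratio = axis_ratio,
    hu_moments(dr, dc),
    radius_mean = mean(brad), radius_sd = if (length(brad) > 1) sd(brad) else 0)
}

hu_moments <- function(dr, dc) {
  n <- length(dr)
  m <- function(p, q) sum(dc^p * dr^q)
  eta <- function(p, q) m(p, q) / n^(1 + (p + q) / 2)
  n20 <- eta(2, 0); n02 <- eta(0, 2); n11 <- eta(1, 1)
  n30 <- eta(3, 0); n03 <- eta(0, 3); n21 <- eta(2, 1); n12 <- eta(1, 2)
  h1 <- n20 + n02
  h2 <- (n20 - n02)^2 + 4 * n11^2
  h3 <- (n30 - 3 * n12)^2 + (3 * n21 - n03)^2
  h4 <- (n30 + n12)^2 + (n21 + n03)^2
  h5 <- (n30 - 3 * n12) * (n30 + n12) *
    ((n30 + n12)^2 - 3 * (n21 + n03)^2) +
    (3 * n21 - n03) * (n21 + n03) * (3 * (n30 + n12)^2 - (n21 + n03)^2)
  h6 <- (n20 - n02) * ((n30 + n12)^2 - (n21 + n03)^2) +
    4 * n11 * (n30 + n12) * (n21 + n03)
  h7 <- (3 * n21 - n03) * (n30 + n12) *
    ((n30 + n12)^2 - 3 * (n21 + n03)^2) -
    (n30 - 3 * n12) * (n21 + n03) * (3 * (n30 + n12)^2 - (n21 + n03)^2)
  c(hu1 = h1, hu2 = h2, hu3 = h3, hu4 = h4, hu5 = h5, hu6 = h6, hu7 = h7)
}

# ---- intensity --------------------------------------------------------------

#' Intensity features of a colony
#'
#' Order statistics of the pixel intensities inside the mask, the mass
#' displacement (distance between the binary and the intensity-weighted
#' centroid, in pixels), and edge-versus-interior statistics, where the
#' edge is the morphological boundary of the mask (pixels with a
#' 4-neighbour outside).
#'
#' @param mask Logical matrix, single component >= 4 px.
#' @param pixels Intensity matrix aligned with `mask`.
#' @return Named numeric vector of 18 intensity measurements.
#' @export
intensity_features <- function(mask, pixels) {
  check_single_component(mask)
  stopifnot(all(dim(mask) == dim(pixels)))
  v <- pixels[mask]
  xy <- mask_coords(mask)
  cy <- mean(xy[, "row"]); cx <- mean(xy[, "col"])
  w <- v / sum(v)
  if (!all(is.finite(w))) w <- rep(1 / length(v), length(v))  # zero-mass colony
  icy <- sum(xy[, "row"] * w); icx <- sum(xy[, "col"] * w)
  md <- sqrt((cy - icy)^2 + (cx - icx)^2)

  edge <- boundary_mask(mask)
  interior <- mask & !edge
  ev <- pixels[edge]
  iv <- if (any(interior)) pixels[interior] else ev
  imean <- mean(iv)
  c(int_mean = mean(v), int_median = median(v), int_std = sd(v),
    int_min = min(v), int_max = max(v), int_integrated = sum(v),
    int_mad = mad(v), int_q25 = unname(quantile(v, 0.25)),
    int_q75 = unname(quantile(v, 0.75)),
    int_cv = if (mean(v) > 0) sd(v) / mean(v) else 0,
    mass_displacement = md,
    edge_mean = mean(ev), edge_std = if (length(ev) > 1) sd(ev) else 0,
    edge_min = min(ev), edge_max = max(ev),
    interior_mean = imean,
    interior_std = if (length(iv) > 1) sd(iv) else 0,
    edge_interior_ratio = mean(ev) / max(imean, 1e-12))
}

# ---- radial distribution ----------------------------------------------------

# normalized centroid-to-boundary distance per pixel: the boundary radius
# is estimated per angular sector (32 sectors, circularly filled)
normalized_radius <- function(mask) {
  xy <- mask_coords(mask)
  cy <- mean(xy[, "row"]); cx <- mean(xy[, "col"])
  r <- sqrt((xy[, "row"] - cy)^2 + (xy[, "col"] - cx)^2)
  phi <- atan2(xy[, "row"] - cy, xy[, "col"] - cx)
  nsec <- 32L
  sec <- pmin(floor((phi + pi) / (2 * pi) * nsec) + 1L, nsec)
  bmax <- vapply(seq_len(nsec), function(s) {
    if (any(sec == s)) max(r[sec == s]) else NA_real_
  }, numeric(1))
  # fill empty sectors by nearest filled sector (circular)
  if (anyNA(bmax)) {
    filled <- which(!is.na(bmax))
    for (s in which(is.na(bmax))) {
      dd <- pmin(abs(filled - s), nsec - abs(filled - s))
      bmax[s] <- bmax[filled[which.min(dd)]]
    }
  }
  frac <- r / pmax(bmax[sec], 1e-9)
  list(frac = pmin(frac, 1), phi = phi, xy = xy)
}

#' Radial intensity distribution
#'
#' Bins the colony's pixels into `n_rings` equal-width annuli of the
#' normalized centroid-to-boundary distance and reports, per ring: the
#' fraction of total intensity (`FracAtD`), that fraction relative to the
#' ring's area fraction (`MeanFrac`), and the coefficient of variation of
#' mean intensity over 8 angular wedges within the ring (`RadialCV`).
#' Empty rings yield 0 with a warning.
#'
#' @inheritParams intensity_features
#' @param n_rings Number of annuli.
#' @param n_wedges Angular wedges per ring for RadialCV.
#' @return Named numeric vector, 3 x `n_rings` measurements.
#' @export
radial_distribution <- function(mask, pixels, n_rings = 4, n_wedges = 8) {
  check_single_component(mask)
  nr <- normalized_radius(mask)
  v <- pixels[mask]
  ring <- pmin(pmax(ceiling(nr$frac * n_rings), 1L), n_rings)
  wedge <- pmin(floor((nr$phi + pi) / (2 * pi) * n_wedges) + 1L, n_wedges)
  tot <- sum(v)
  out <- numeric(0)
  frac_at_d <- mean_frac <- radial_cv <- numeric(n_rings)
  for (k in seq_len(n_rings)) {
    in_ring <- ring == k
    if (!any(in_ring)) {
      rlang::warn(sprintf("radial ring %d is empty; reporting 0", k))
      next
    }
    frac_at_d[k] <- if (tot > 0) sum(v[in_ring]) / tot else 0
    area_frac <- sum(in_ring) / length(v)
    mean_frac[k] <- frac_at_d[k] / area_frac
    wm <- tapply(v[in_ring], wedge[in_ring], mean)
    mw <- mean(wm)
    radial_cv[k] <- if (length(wm) > 1 && mw > 0) sd(wm) / mw else 0
  }
  setNames(c(frac_at_d, mean_frac, radial_cv),
           c(paste0("frac_at_d_r", seq_len(n_rings)),
             paste0("mean_frac_r", seq_len(n_rings)),
             paste0("radial_cv_r", seq_len(n_rings))))
}

# ---- texture ----------------------------------------------------------------

# gray-level co-occurrence matrix restricted to the mask, for one offset
# (dr, dc); symmetric and normalized to sum 1. Returns NULL when no valid
# pixel pair exists.
glcm <- function(g, mask, dr, dc, n_levels) {
  nr <- nrow(g); nc <- ncol(g)
  r1 <- max(1, 1 - dr):min(nr, nr - dr)
  c1 <- max(1, 1 - dc):min(nc, nc - dc)
  if (length(r1) == 0 || length(c1) == 0) return(NULL)
  a_mask <- mask[r1, c1, drop = FALSE] & mask[r1 + dr, c1 + dc, drop = FALSE]
  if (!any(a_mask)) return(NULL)
  ga <- g[r1, c1, drop = FALSE][a_mask]
  gb <- g[r1 + dr, c1 + dc, drop = FALSE][a_mask]
  counts <- tabulate((ga - 1L) * n_levels + gb, nbins = n_levels^2)
  P <- matrix(counts, n_levels, n_levels, byrow = TRUE)
  P <- P + t(P)
  P / sum(P)
}

# the 13 classical co-occurrence statistics of a normalized symmetric GLCM
haralick_stats <- function(P) {
  n <- nrow(P)
  i <- matrix(seq_len(n), n, n)
  j <- t(i)
  px <- rowSums(P)
  mu <- sum(seq_len(n) * px)
  sdx <- sqrt(sum((seq_len(n) - mu)^2 * px))
  ent0 <- function(p) -sum(ifelse(p > 0, p * log(p), 0))

  asm <- sum(P^2)
  contrast <- sum((i - j)^2 * P)
  correlation <- if (sdx > 0) sum((i - mu) * (j - mu) * P) / sdx^2 else 0
  variance <- sum((i - mu)^2 * P)
  idm <- sum(P / (1 + (i - j)^2))
  sums <- as.vector(i + j)
  pxy_sum <- tapply(as.vector(P), sums, sum)
  kk <- as.numeric(names(pxy_sum))
  sum_average <- sum(kk * pxy_sum)
  sum_variance <- sum((kk - sum_average)^2 * pxy_sum)
  sum_entropy <- ent0(pxy_sum)
  entropy <- ent0(as.vector(P))
  diffs <- abs(as.vector(i - j))
  pxy_diff <- tapply(as.vector(P), diffs, sum)
  dk <- as.numeric(names(pxy_diff))
  dmean <- sum(dk * pxy_diff)
  diff_variance <- sum((dk - dmean)^2 * pxy_diff)
  diff_entropy <- ent0(pxy_diff)
  hx <- ent0(px)
  hxy1 <- -sum(ifelse(P > 0 & outer(px, px) > 0,
                      P * log(outer(px, px)), 0))
  hxy2 <- ent0(as.vector(outer(px, px)))
  imc1 <- if (hx > 0) (entropy - hxy1) / hx else 0
  imc2 <- sqrt(pmax(1 - exp(-2 * (hxy2 - entropy)), 0))
  c(asm = asm, contrast = contrast, correlation = correlation,
    variance = variance, idm = idm, sum_average = sum_average,
    sum_variance = sum_variance, sum_entropy = sum_entropy,
    entropy = entropy, diff_variance = diff_variance,
    diff_entropy = diff_entropy, imc1 = imc1, imc2 = imc2)
}

quantize_gray <- function(pixels, mask, n_levels = 8) {
  v <- pixels[mask]
  g <- matrix(1L, nrow(pixels), ncol(pixels))
  rng <- range(v)
  if (diff(rng) > 0) {
    q <- floor((pixels - rng[1]) / diff(rng) * n_levels) + 1L
    g <- pmin(pmax(q, 1L), n_levels)
  }
  g
}

#' Co-occurrence texture features
#'
#' Intensities inside the colony are min-max quantized to `n_levels` gray
#' levels; for each offset distance the gray-level co-occurrence matrix is
#' built over the four 2D directions (0, 45, 90, 135 degrees), restricted
#' to pixel pairs inside the mask, symmetrized and normalized. Thirteen
#' classical statistics are computed per direction and summarised by their
#' mean and range across directions. Colonies too small for an offset give
#' zeros with a warning.
#'
#' @inheritParams intensity_features
#' @param distances Offset distances in pixels.
#' @param n_levels Gray levels for quantization.
#' @return Named numeric vector, `13 x length(distances) x 2` measurements.
#' @export
texture_features <- function(mask, pixels, distances = c(1, 4), n_levels = 8) {
  check_single_component(mask)
  g <- quantize_gray(pixels, mask, n_levels)
  stat_names <- names(haralick_stats(diag(n_levels) / n_levels))
  means <- ranges <- list()
  for (d in distances) {
    offsets <- list(c(0L, d), c(d, d), c(d, 0L), c(d, -d))
    per_dir <- vapply(offsets, function(o) {
      P <- glcm(g, mask, o[1], o[2], n_levels)
      if (is.null(P)) return(rep(NA_real_, 13))
      haralick_stats(P)
    }, numeric(13))
    if (all(is.na(per_dir))) {
      rlang::warn(sprintf("colony too small for texture offset %d; reporting 0", d))
      per_dir[] <- 0
    }
    means[[as.character(d)]] <- rowMeans(per_dir, na.rm = TRUE)
    ranges[[as.character(d)]] <- apply(per_dir, 1, function(x) {
      x <- x[!is.na(x)]
      if (length(x) == 0) 0 else diff(range(x))
    })
  }
  out <- c(unlist(means), unlist(ranges))
  names(out) <- c(
    as.vector(outer(stat_names, paste0("d", distances), function(s, d)
      paste0("tex_", s, "_", d, "_mean"))),
    as.vector(outer(stat_names, paste0("d", distances), function(s, d)
      paste0("tex_", s, "_", d, "_range"))))
  manifest_order <- feature_manifest()$name[feature_manifest()$family == "texture"]
  if (setequal(names(out), manifest_order)) out[manifest_order] else out
}

# ---- per-colony and per-plate assembly -------------------------------------

#' All 102 features of one colony
#'
#' @inheritParams intensity_features
#' @return Named numeric vector ordered as [feature_manifest()].
#' @export
colony_features <- function(mask, pixels) {
  out <- c(areashape_features(mask),
           intensity_features(mask, pixels),
           radial_distribution(mask, pixels),
           texture_features(mask, pixels))
  out[feature_manifest()$name]
}

#' Feature table for one segmented well
#'
#' Crops each labelled colony (1 px pad) and computes the full feature
#' vector. Colonies whose measurement fails (degenerate masks) are dropped
#' with a warning.
#'
#' @param seg A `segmentation` object.
#' @param image The well's intensity matrix.
#' @param well_id Well identifier for the output rows.
#' @return Tibble `well_id, colony_id, cx, cy` + 102 feature columns.
#' @export
well_features <- function(seg, image, well_id) {
  cols <- seg$colonies
  if (nrow(cols) == 0) {
    return(tibble::tibble(well_id = character(0), colony_id = integer(0)))
  }
  rows <- purrr::map(seq_len(nrow(cols)), function(i) {
    r0 <- max(cols$ymin[i], 0L); r1 <- min(cols$ymax[i] + 1L, nrow(image))
    c0 <- max(cols$xmin[i], 0L); c1 <- min(cols$xmax[i] + 1L, ncol(image))
    sub_lab <- seg$label_mask[(r0 + 1L):r1, (c0 + 1L):c1, drop = FALSE]
    mask <- sub_lab == cols$colony_id[i]
    px <- image[(r0 + 1L):r1, (c0 + 1L):c1, drop = FALSE]
    fv <- tryCatch(colony_features(mask, px), error = function(e) NULL)
    if (is.null(fv)) {
      rlang::warn(sprintf("well %s colony %d dropped: measurement failed",
                          well_id, cols$colony_id[i]))
      return(NULL)
    }
    dplyr::bind_cols(
      tibble::tibble(well_id = well_id, colony_id = cols$colony_id[i],
                     cx = cols$cx[i], cy = cols$cy[i]),
      tibble::as_tibble(as.list(fv)))
  })
  dplyr::bind_rows(rows)
}

#' Feature table for a plate
#'
#' @param segmentations Named list of `segmentation` objects keyed by well.
#' @param images Named list of intensity matrices keyed by well.
#' @return Tibble with one row per colony across all wells.
#' @export
feature_table <- function(segmentations, images) {
  stopifnot(all(names(segmentations) %in% names(images)))
  purrr::map(names(segmentations), function(w) {
    well_features(segmentations[[w]], images[[w]], w)
  }) |>
    dplyr::bind_rows()
}

#' @export
feature_columns <- function() feature_manifest()$name
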
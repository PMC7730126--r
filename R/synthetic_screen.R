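#' Per-well colony count distribution
#'
#' Colony counts per well are modelled as negative binomial, parameterized
#' by the target median and spread rather than by mean and size. At the
#' defaults (median 159, spread 47) the distribution reproduces the
#' screen-wide count statistics the analysis assumes. `spread = 0`
#' degenerates to a constant count.
#'
#' @param median Target median colonies per well.
#' @param spread Target standard deviation of counts.
#' @return A `count_params` list with the resolved `size` and `mu`.
#' @export
count_params <- function(median = 159, spread = 47) {
  assert_that(median >= 0, "median must be non-negative")
  if (spread <= 0 || spread^2 <= median) {
    return(structure(list(median = median, spread = spread,
                          size = Inf, mu = median, constant = spread <= 0),
                     class = "count_params"))
  }
  size <- median^2 / (spread^2 - median)
  # smallest mu whose NB median hits the target (qnbinom is a step function)
  mu <- median
  while (qnbinom(0.5, size = size, mu = mu) < median && mu < median * 1.5) {
    mu <- mu + 0.5
  }
  structure(list(median = median, spread = spread, size = size, mu = mu,
                 constant = FALSE),
            class = "count_params")
}

#' Draw per-well colony counts
#'
#' @param n Number of wells to draw.
#' @param params A [count_params()] object.
#' @param seed Optional integer seed.
#' @return Integer vector of non-negative counts.
#' @examples
#' median(sample_colony_count(384, seed = 1))
#' @export
sample_colony_count <- function(n, params = count_params(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (isTRUE(params$constant)) return(rep(as.integer(round(params$mu)), n))
  if (!is.finite(params$size)) {
    # spread too small for NB overdispersion: fall back to Poisson
    return(stats::rpois(n, params$mu))
  }
  rnbinom(n, size = params$size, mu = params$mu)
}

#' Rendering parameters for synthetic wells
#'
#' Geometry and intensity defaults for the whole-well renderer. Images are
#' single-channel z-collapsed projections, 1024 x 1024 px at 5.2 um/px
#' (a 5.3 mm field covering a 384-well plate well), so the
#' default colony radii (log-normal around 13 px, spread phenotype scaled
#' 1.5x) correspond to 100-200 um colony diameters. Intensities are in
#' 16-bit counts over a constant background with additive Gaussian read
#' noise.
#'
#' @param image_size Image side in pixels.
#' @param pixel_size_um Physical pixel size, um/px.
#' @param background Constant background level (counts).
#' @param noise_sd Gaussian read-noise standard deviation (counts);
#'   0 renders noise-free wells.
#' @param radius_px Median colony radius in pixels (log-normal scale).
#' @param radius_sdlog Log-sd of the colony radius distribution.
#' @param spread_scale Radius multiplier for the spread phenotype.
#' @param texture_amplitude Relative amplitude of the speckle texture in
#'   non-polarized and spread colonies.
#' @param counts A [count_params()] object for per-well colony numbers.
#' @return A `plate_params` list.
#' @export
plate_params <- function(image_size = 1024, pixel_size_um = 5.2,
                         background = 400, noise_sd = 60,
                         radius_px = 13, radius_sdlog = 0.18,
                         spread_scale = 1.4, texture_amplitude = 0.35,
                         counts = count_params()) {
  structure(list(image_size = image_size, pixel_size_um = pixel_size_um,
                 background = background, noise_sd = noise_sd,
                 radius_px = radius_px, radius_sdlog = radius_sdlog,
                 spread_scale = spread_scale,
                 texture_amplitude = texture_amplitude, counts = counts),
            class = "plate_params")
}

# per-phenotype intensity architecture (16-bit counts)
phenotype_intensity <- function(phenotype) {
  switch(phenotype,
    polarized = list(interior = 2500, annulus = 9000,
                     annulus_in = 0.33, annulus_out = 0.57),
    nonpolarized = list(level = 5000),
    spread = list(level = 2200),
    inverted = list(interior = 1800, rim = 9000, rim_in = 0.85),
    rlang::abort(paste0("unknown phenotype: ", phenotype))
  )
}

#' Render one colony patch
#'
#' Draws the noise-free intensity footprint of a single colony of the given
#' phenotype: polarized colonies are disks with a bright interior actin
#' annulus (peak near 0.45 of the radius); inverted colonies are disks with
#' a bright peripheral rim and dark interior; non-polarized colonies are
#' uniform disks with fine speckle texture; spread colonies are elongated,
#' boundary-perturbed regions of lower mean intensity and larger footprint.
#'
#' @param phenotype One of [phenotypes()].
#' @param radius Nominal (equivalent) radius in pixels.
#' @param params A [plate_params()] (texture amplitude is read from it).
#' @param elongation Axis ratio for the spread phenotype.
#' @param angle Major-axis orientation (radians, spread only).
#' @param boundary_amp,boundary_waves Amplitude and lobe count of the
#'   sinusoidal boundary perturbation (spread only).
#' @param seed Optional seed for the texture speckle.
#' @return Numeric matrix of intensities, 0 outside the colony.
#' @export
render_colony <- function(phenotype, radius, params = plate_params(),
                          elongation = 2, angle = 0,
                          boundary_amp = 0.12, boundary_waves = 5,
                          seed = NULL) {
  assert_that(radius >= 2, "colony radius must be >= 2 px")
  if (!is.null(seed)) set.seed(seed)
  ip <- phenotype_intensity(phenotype)
  is_spread <- phenotype == "spread"
  half <- if (is_spread) {
    ceiling(radius * sqrt(elongation) * (1 + boundary_amp)) + 2L
  } else {
    ceiling(radius) + 2L
  }
  n <- 2L * half + 1L
  dx <- matrix(rep(-half:half, each = n), n, n)       # column offset
  dy <- matrix(rep(-half:half, times = n), n, n)      # row offset
  if (is_spread) {
    # rotate into the ellipse frame, perturb the boundary radius
    u <- cos(angle) * dx + sin(angle) * dy
    v <- -sin(angle) * dx + cos(angle) * dy
    r_eff <- sqrt((u / sqrt(elongation))^2 + (v * sqrt(elongation))^2)
    phi <- atan2(v, u)
    phase <- runif(1, 0, 2 * pi)
    rim <- radius * (1 + boundary_amp * sin(boundary_waves * phi + phase))
    inside <- r_eff <= rim
    patch <- matrix(0, n, n)
    tex <- 1 + params$texture_amplitude * runif(sum(inside), -1, 1)
    patch[inside] <- ip$level * tex
    return(patch)
  }
  r <- sqrt(dx^2 + dy^2) / radius
  inside <- r <= 1
  patch <- matrix(0, n, n)
  base <- switch(phenotype,
    polarized = ifelse(r >= ip$annulus_in & r <= ip$annulus_out,
                       ip$annulus, ip$interior),
    inverted = ifelse(r >= ip$rim_in, ip$rim, ip$interior),
    nonpolarized = matrix(ip$level, n, n)
  )
  patch[inside] <- base[inside]
  if (phenotype == "nonpolarized" && params$texture_amplitude > 0) {
    tex <- 1 + params$texture_amplitude * runif(sum(inside), -1, 1)
    patch[inside] <- patch[inside] * tex
  }
  patch
}

colony_bound_radius <- function(phenotype, radius, params,
                                elongation = 2, boundary_amp = 0.12) {
  if (phenotype == "spread") radius * sqrt(elongation) * (1 + boundary_amp) + 2
  else radius + 2
}

#' Generate one synthetic well
#'
#' Draws a colony count, phenotypes (i.i.d. from the supplied mixture),
#' log-normal radii and non-overlapping positions (rejection sampling), and
#' renders the summed noise-free scene plus background and Gaussian read
#' noise. If placement fails repeatedly the count is reduced with a
#' warning.
#'
#' @param well_id Well identifier carried into the ground-truth table.
#' @param probs Numeric 4-vector of phenotype probabilities in
#'   [phenotypes()] order (rows of [condition_phenotype_probs()] work:
#'   columns `p_polarized` .. `p_inverted`).
#' @param seed Integer seed for the well.
#' @param params A [plate_params()] object.
#' @param n_colonies Optional fixed colony count (overrides the count
#'   distribution).
#' @return List with `image` (intensity matrix, integer-valued) and
#'   `truth` (tibble `well_id, colony_id, phenotype, cx, cy, radius`);
#'   coordinates are 0-based pixel-centred (cx = column, cy = row).
#' @export
generate_well <- function(well_id, probs, seed, params = plate_params(),
                          n_colonies = NULL) {
  probs <- as.numeric(probs)
  assert_that(length(probs) == 4 && abs(sum(probs) - 1) < 1e-6,
              "probs must be a 4-vector summing to 1")
  set.seed(seed)
  sz <- params$image_size
  count <- n_colonies %||% sample_colony_count(1, params$counts)
  phen <- if (count > 0) sample(phenotypes(), count, replace = TRUE, prob = probs)
          else character(0)
  radius <- params$radius_px *
    exp(rnorm(count, 0, params$radius_sdlog)) *
    ifelse(phen == "spread", params$spread_scale, 1)
  angle <- runif(count, 0, pi)

  # sequential non-overlap placement
  bound <- vapply(seq_len(count), function(i)
    colony_bound_radius(phen[i], radius[i], params), numeric(1))
  cx <- cy <- numeric(0)
  placed <- integer(0)
  for (i in seq_len(count)) {
    ok <- FALSE
    for (try in seq_len(500)) {
      x <- runif(1, bound[i] + 1, sz - bound[i] - 2)
      y <- runif(1, bound[i] + 1, sz - bound[i] - 2)
      if (length(placed) == 0 ||
          all(sqrt((cx - x)^2 + (cy - y)^2) > bound[i] + bound[placed] + 4)) {
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      rlang::warn(sprintf("well %s: placed %d of %d colonies (crowded well)",
                          well_id, length(placed), count))
      break
    }
    cx <- c(cx, x); cy <- c(cy, y)
    placed <- c(placed, i)
  }
  phen <- phen[placed]; radius <- radius[placed]; angle <- angle[placed]
  bound <- bound[placed]

  img <- matrix(0, sz, sz)
  for (i in seq_along(placed)) {
    patch <- render_colony(phen[i], radius[i], params,
                           angle = angle[i])
    half <- (nrow(patch) - 1L) / 2L
    r0 <- round(cy[i]) - half + 1L; c0 <- round(cx[i]) - half + 1L
    rows <- r0:(r0 + nrow(patch) - 1L); cols <- c0:(c0 + ncol(patch) - 1L)
    img[rows, cols] <- img[rows, cols] + patch
  }
  img <- img + params$background
  if (params$noise_sd > 0) {
    img <- img + rnorm(length(img), 0, params$noise_sd)
  }
  img <- round(pmin(pmax(img, 0), 65535))
  truth <- tibble::tibble(
    well_id = well_id,
    colony_id = seq_along(placed),
    phenotype = phen,
    cx = round(cx), cy = round(cy),
    radius = radius
  )
  list(image = img, truth = truth)
}

#' Generate a full synthetic plate
#'
#' Applies [generate_well()] across a plate layout, deriving one child seed
#' per well from the plate seed. Images are either returned in memory (only
#' advisable for small plates) or written as 16-bit single-channel TIFFs
#' named `<well_id>.tif`.
#'
#' @param design Plate layout from [assign_wells()].
#' @param model A [phenotype_effect_model()].
#' @param seed Plate-level seed.
#' @param params A [plate_params()].
#' @param out_dir If non-`NULL`, write TIFFs here and do not keep images in
#'   memory; the ground truth is written as `truth.csv` alongside.
#' @return List with `truth` (all wells) and either `images` (named list)
#'   or `out_dir`.
#' @export
generate_plate <- function(design, model = phenotype_effect_model(), seed = 1,
                           params = plate_params(), out_dir = NULL) {
  pr <- condition_phenotype_probs(model, design)
  pm <- as.matrix(pr[paste0("p_", phenotypes())])
  seeds <- derive_seeds(seed, nrow(design))
  keep <- is.null(out_dir)
  if (!keep && !dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  images <- if (keep) vector("list", nrow(design))
  truths <- vector("list", nrow(design))
  for (i in seq_len(nrow(design))) {
    w <- generate_well(design$well_id[i], pm[i, ], seeds[i], params)
    truths[[i]] <- w$truth
    if (keep) {
      images[[i]] <- w$image
    } else {
      write_well_image(w$image, file.path(out_dir, paste0(design$well_id[i], ".tif")))
    }
  }
  truth <- dplyr::bind_rows(truths)
  if (keep) {
    names(images) <- design$well_id
    list(truth = truth, images = images)
  } else {
    readr::write_csv(truth, file.path(out_dir, "truth.csv"))
    list(truth = truth, out_dir = out_dir)
  }
}

#' Read / write well images as 16-bit TIFF
#'
#' @param image Intensity matrix in 16-bit counts (0..65535).
#' @param path TIFF file path.
#' @return `read_well_image` returns the intensity matrix in counts.
#' @export
write_well_image <- function(image, path) {
  tiff::writeTIFF(image / 65535, path, bits.per.sample = 16,
                  compression = "none")
  invisible(path)
}

#' @rdname write_well_image
#' @export
read_well_image <- function(path) {
  round(tiff::readTIFF(path) * 65535)
}
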
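test_that("the feature manifest defines exactly 102 measurements in 3 families", {
  mf <- feature_manifest()
  expect_equal(nrow(mf), 102)
  expect_equal(anyDuplicated(mf$name), 0)
  expect_equal(as.vector(table(mf$family)[c("areashape", "intensity", "texture")]),
               c(20L, 30L, 52L))
})

test_that("area-shape features match closed-form values on disks and ellipses", {
  f <- areashape_features(mk_disk(50))
  expect_lt(f[["eccentricity"]], 0.05)
  expect_gte(f[["compactness"]], 1.0)
  expect_lte(f[["compactness"]], 1.1)
  expect_lt(abs(f[["area"]] - pi * 50^2) / (pi * 50^2), 0.02)
  expect_lt(abs(f[["equivalent_diameter"]] - 2 * sqrt(f[["area"]] / pi)), 1e-9)

  fe <- areashape_features(mk_ellipse(50, 25))
  expect_lt(abs(fe[["eccentricity"]] - sqrt(1 - 0.25)), 0.03)
  expect_gt(fe[["axis_ratio"]], 1.8)
  expect_lt(fe[["axis_ratio"]], 2.2)
})

test_that("random blobs satisfy the definitional bounds", {
  for (s in 1:5) {
    m <- mk_blob(s)
    f <- areashape_features(m)
    expect_equal(f[["area"]], sum(m))               # brute-force pixel count
    expect_gte(f[["compactness"]], 1)
    expect_lte(f[["solidity"]], 1)
    expect_lte(f[["extent"]], 1)
    expect_equal(f[["form_factor"]], 1 / f[["compactness"]])
  }
})

test_that("degenerate masks are rejected", {
  expect_error(areashape_features(matrix(FALSE, 5, 5)), "at least 4")
  two <- matrix(FALSE, 10, 10)
  two[2:4, 2:4] <- TRUE
  two[7:9, 7:9] <- TRUE
  expect_error(areashape_features(two), "single connected")
})

test_that("intensity features obey order-statistic identities", {
  m <- mk_disk(20)
  const <- matrix(100, nrow(m), ncol(m))
  fi <- intensity_features(m, const)
  expect_equal(fi[["int_std"]], 0)
  expect_lt(fi[["mass_displacement"]], 1e-9)
  expect_equal(fi[["edge_mean"]], fi[["interior_mean"]])

  set.seed(2)
  noisy <- matrix(runif(nrow(m)^2, 10, 1000), nrow(m))
  fn <- intensity_features(m, noisy)
  expect_lte(fn[["int_min"]], fn[["int_median"]])
  expect_lte(fn[["int_median"]], fn[["int_max"]])
  expect_equal(fn[["int_integrated"]], fn[["int_mean"]] * sum(m))
})

test_that("edge-concentrated rendering shows edge > interior intensity", {
  inv <- render_colony("inverted", 20, plate_params(noise_sd = 0))
  fi <- intensity_features(inv > 0, inv)
  expect_gt(fi[["edge_mean"]], fi[["interior_mean"]])
  expect_gt(fi[["edge_interior_ratio"]], 1.5)
})

test_that("radial distribution separates uniform, polarized and hemispheric patterns", {
  m <- mk_disk(20)
  uni <- radial_distribution(m, matrix(100, nrow(m), ncol(m)))
  expect_true(all(uni[grep("radial_cv", names(uni))] == 0))
  expect_true(all(abs(uni[grep("mean_frac", names(uni))] - 1) <= 0.05))

  pol <- render_colony("polarized", 20, plate_params(noise_sd = 0))
  rp <- radial_distribution(pol > 0, pol)
  # the intensity peak sits in the ring containing relative radius 0.45
  expect_equal(unname(which.max(rp[paste0("frac_at_d_r", 1:4)])), 2L)

  # half-bright / half-dark disk: every ring strongly angularly heterogeneous
  half <- matrix(1000, nrow(m), ncol(m))
  half[, seq_len(ncol(m) / 2)] <- 9000
  rh <- radial_distribution(m, half)
  expect_true(all(rh[grep("radial_cv", names(rh))] > 0.5))
})

test_that("texture statistics match a direct co-occurrence construction", {
  m <- mk_disk(12)
  const <- matrix(100, nrow(m), ncol(m))
  tx <- texture_features(m, const)
  expect_equal(tx[["tex_asm_d1_mean"]], 1)
  expect_equal(tx[["tex_contrast_d1_mean"]], 0)
  expect_equal(tx[["tex_variance_d1_mean"]], 0)

  set.seed(7)
  noisy <- matrix(sample(0:255, nrow(m)^2, TRUE), nrow(m))
  tx <- texture_features(m, noisy)
  oracle <- oracle_glcm_stats(noisy, m, 1)
  expect_equal(tx[["tex_asm_d1_mean"]], oracle[["asm"]], tolerance = 1e-12)
  expect_equal(tx[["tex_contrast_d1_mean"]], oracle[["contrast"]], tolerance = 1e-12)
  expect_equal(tx[["tex_entropy_d1_mean"]], oracle[["entropy"]], tolerance = 1e-12)
  expect_equal(tx[["tex_idm_d1_mean"]], oracle[["idm"]], tolerance = 1e-12)
  oracle4 <- oracle_glcm_stats(noisy, m, 4)
  expect_equal(tx[["tex_contrast_d4_mean"]], oracle4[["contrast"]], tolerance = 1e-12)

  # checkerboard maximizes d=1 contrast among simple test patches
  n <- nrow(m)
  checker <- 1000 * (outer(1:n, 1:n, "+") %% 2)
  grad <- matrix(rep(seq(0, 1000, length.out = n), n), n)
  cb <- texture_features(m, checker)[["tex_contrast_d1_mean"]]
  expect_gt(cb, texture_features(m, grad)[["tex_contrast_d1_mean"]])
  expect_gt(cb, texture_features(m, noisy)[["tex_contrast_d1_mean"]])
})

test_that("tiny colonies warn and zero out infeasible texture offsets", {
  m <- matrix(FALSE, 6, 6)
  m[3:4, 3:4] <- TRUE
  px <- matrix(seq_len(36), 6)
  expect_warning(tx <- texture_features(m, px, distances = c(1, 5)), "too small")
  expect_true(all(tx[grep("_d5_", names(tx))] == 0))
})

test_that("all 102 features are translation invariant", {
  pol <- render_colony("polarized", 13, plate_params(noise_sd = 0))
  embed <- function(offset) {
    big <- matrix(0, 101, 101)
    big[offset + seq_len(nrow(pol)), offset + seq_len(ncol(pol))] <- pol
    colony_features(big > 0, big)
  }
  expect_equal(embed(5), embed(40), tolerance = 1e-10)
})

test_that("features covary correctly under intensity scaling", {
  set.seed(3)
  m <- mk_disk(15)
  px <- matrix(runif(nrow(m)^2, 500, 5000), nrow(m)) * m
  f1 <- colony_features(m, px)
  f2 <- colony_features(m, px * 3)
  scaled <- c("int_mean", "int_min", "int_max", "int_integrated", "int_std")
  invariant <- c("eccentricity", "compactness", "area", "int_cv",
                 "edge_interior_ratio", "mass_displacement",
                 paste0("radial_cv_r", 1:4), paste0("mean_frac_r", 1:4),
                 "tex_contrast_d1_mean", "tex_asm_d1_mean")
  expect_equal(unname(f2[scaled]), unname(3 * f1[scaled]), tolerance = 1e-9)
  expect_equal(f2[invariant], f1[invariant], tolerance = 1e-9)
})

test_that("a linear probe on three summary features separates the phenotypes", {
  p <- plate_params(image_size = 512, counts = count_params(30, 0))
  feats <- dplyr::bind_rows(lapply(1:6, function(s) {
    w <- generate_well(paste0("W", s), c(0.25, 0.25, 0.25, 0.25),
                       seed = 100 + s, params = p)
    seg <- segment_well(w$image)
    f <- well_features(seg, w$image, paste0("W", s))
    mt <- match_truth(seg$colonies, w$truth)
    f$phenotype <- mt$phenotype[match(f$colony_id, mt$colony_id)]
    f
  }))
  feats <- dplyr::filter(feats, !is.na(phenotype))
  probe <- MASS::lda(x = as.matrix(feats[c("edge_interior_ratio",
                                           "eccentricity", "area")]),
                     grouping = factor(feats$phenotype))
  pred <- predict(probe)$class
  expect_gte(mean(as.character(pred) == feats$phenotype), 0.90)
})

test_that("the feature table is complete and deterministic", {
  p <- plate_params(image_size = 384, counts = count_params(10, 0))
  w <- generate_well("A1", c(0.25, 0.25, 0.25, 0.25), seed = 21, params = p)
  seg <- segment_well(w$image)
  f1 <- feature_table(list(A1 = seg), list(A1 = w$image))
  expect_equal(nrow(f1), nrow(seg$colonies))
  expect_true(all(feature_columns() %in% names(f1)))
  expect_equal(sum(feature_columns() %in% names(f1)), 102)
  f2 <- feature_table(list(A1 = seg), list(A1 = w$image))
  expect_identical(f1, f2)
  expect_true(all(vapply(f1[feature_columns()],
                         function(x) all(is.finite(x)), logical(1))))
})
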
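test_that("phenotype probabilities are a temperature-scaled softmax", {
  flat <- phenotype_effect_model(
    baseline_logits = c(polarized = 0, nonpolarized = 0, spread = 0, inverted = 0),
    stiffness = list("2" = rep(c(polarized = 0, nonpolarized = 0,
                                 spread = 0, inverted = 0), 1)),
    egf = list("EGF+" = c(polarized = 0, nonpolarized = 0, spread = 0,
                          inverted = 0)),
    ecm_fibronectin = c(polarized = 0, nonpolarized = 0, spread = 0,
                        inverted = 0),
    mixing_temperature = c(high = 1))
  cond <- tibble::tibble(stiffness_kPa = 2, degradability = "high",
                         ecm = "blank", egf = "EGF+")
  pr <- condition_phenotype_probs(flat, cond)
  expect_equal(unlist(pr[paste0("p_", phenotypes())]),
               setNames(rep(0.25, 4), paste0("p_", phenotypes())))
})

test_that("probabilities sum to one over the whole default design", {
  pr <- condition_phenotype_probs(phenotype_effect_model(),
                                  enumerate_conditions())
  sums <- rowSums(as.matrix(pr[paste0("p_", phenotypes())]))
  expect_true(all(abs(sums - 1) < 1e-12))
})

test_that("stiff matrix without EGF is planted to be inverted-dominated", {
  cond <- enumerate_conditions() |>
    dplyr::filter(stiffness_kPa == 8, egf == "EGF-")
  pr <- condition_phenotype_probs(phenotype_effect_model(), cond)
  expect_true(all(pr$p_inverted > 0.95))
})

test_that("a missing factor level in the effect model is a configuration error", {
  m <- phenotype_effect_model()
  cond <- tibble::tibble(stiffness_kPa = 16, degradability = "high",
                         ecm = "blank", egf = "EGF+")
  expect_error(condition_phenotype_probs(m, cond), "stiffness")
})

test_that("colony count distribution is calibrated to the screen median", {
  x <- sample_colony_count(10000, seed = 1)
  expect_gte(median(x), 150)
  expect_lte(median(x), 168)
  expect_true(all(x >= 0))
  # degenerate spread gives a constant count
  expect_equal(sample_colony_count(5, count_params(40, 0), seed = 1),
               rep(40L, 5))
})

test_that("renderers produce the four planted actin architectures", {
  p0 <- plate_params(noise_sd = 0)

  pol <- render_colony("polarized", 20, p0)
  r <- sqrt(outer(seq_len(nrow(pol)) - (nrow(pol) + 1) / 2,
                  seq_len(ncol(pol)) - (ncol(pol) + 1) / 2,
                  function(a, b) a^2 + b^2)) / 20
  annulus <- r >= 0.33 & r <= 0.57
  outer_rim <- r > 0.57 & r <= 1
  expect_gte(mean(pol[annulus]), 2 * mean(pol[outer_rim]))

  inv <- render_colony("inverted", 20, p0)
  expect_gt(mean(inv[r >= 0.9 & r <= 1]), mean(inv[r <= 0.5]))

  # zero texture amplitude makes the non-polarized disk radially flat
  flat <- render_colony("nonpolarized", 20,
                        plate_params(noise_sd = 0, texture_amplitude = 0))
  rd <- radial_distribution(flat > 0, flat)
  expect_true(all(rd[grep("radial_cv", names(rd))] == 0))

  spr <- render_colony("spread", 20, p0, seed = 1)
  expect_gt(sum(spr > 0), sum(pol > 0))  # larger footprint at equal radius
  expect_lt(mean(spr[spr > 0]), mean(pol[pol > 0]))

  expect_error(render_colony("round", 20, p0), "unknown phenotype")
})

test_that("well generation is deterministic and truth-consistent", {
  p <- plate_params(image_size = 384, counts = count_params(15, 0))
  w1 <- generate_well("A1", c(0.25, 0.25, 0.25, 0.25), seed = 11, params = p)
  w2 <- generate_well("A1", c(0.25, 0.25, 0.25, 0.25), seed = 11, params = p)
  expect_identical(w1$image, w2$image)
  expect_identical(w1$truth, w2$truth)

  # colonies are inside bounds and pairwise non-overlapping
  tr <- w1$truth
  expect_true(all(tr$cx > 0 & tr$cx < 384 & tr$cy > 0 & tr$cy < 384))
  d <- as.matrix(dist(cbind(tr$cx, tr$cy)))
  diag(d) <- Inf
  lim <- outer(tr$radius, tr$radius, "+")
  expect_true(all(d > lim))

  # TIFF round trip preserves the 16-bit image exactly
  path <- withr::local_tempfile(fileext = ".tif")
  write_well_image(w1$image, path)
  expect_equal(read_well_image(path), w1$image)
})

test_that("ground-truth phenotype draws follow the planted mixture", {
  probs <- c(0.5, 0.3, 0.1, 0.1)
  p <- plate_params(image_size = 512, counts = count_params(60, 0))
  tr <- dplyr::bind_rows(lapply(1:6, function(s)
    generate_well(paste0("W", s), probs, seed = s, params = p)$truth))
  n <- nrow(tr)
  emp <- as.numeric(table(factor(tr$phenotype, levels = phenotypes()))) / n
  se <- sqrt(probs * (1 - probs) / n)
  expect_true(all(abs(emp - probs) <= 3 * se))
})

test_that("degradable conditions have strictly higher planted mixing entropy", {
  ent <- condition_entropy(phenotype_effect_model(), enumerate_conditions())
  byc <- ent |>
    dplyr::group_by(.data$stiffness_kPa, .data$ecm, .data$egf) |>
    dplyr::summarise(
      gap = .data$entropy[.data$degradability == "high"] -
        .data$entropy[.data$degradability == "low"], .groups = "drop")
  expect_true(all(byc$gap > 0))
})

test_that("the effect model round-trips through JSON", {
  m <- phenotype_effect_model()
  path <- withr::local_tempfile(fileext = ".json")
  write_effect_model(m, path)
  m2 <- read_effect_model(path)
  pr1 <- condition_phenotype_probs(m, enumerate_conditions())
  pr2 <- condition_phenotype_probs(m2, enumerate_conditions())
  expect_equal(pr1, pr2)
})
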
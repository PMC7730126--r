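null_model <- function() {
  phenotype_effect_model(
    baseline_logits = c(polarized = 0, nonpolarized = 0, spread = 0,
                        inverted = 0),
    stiffness = lapply(c("0.5" = 1, "2" = 1, "4" = 1, "8" = 1), function(x)
      c(polarized = 0, nonpolarized = 0, spread = 0, inverted = 0)),
    egf = lapply(c("EGF+" = 1, "EGF-" = 1), function(x)
      c(polarized = 0, nonpolarized = 0, spread = 0, inverted = 0)),
    ecm_fibronectin = c(polarized = 0, nonpolarized = 0, spread = 0,
                        inverted = 0),
    mixing_temperature = c(high = 1, low = 1))
}

test_that("the planted microenvironmental signature is recovered", {
  design <- assign_wells(enumerate_conditions(), replicates = 2, seed = 1)
  prof <- simulate_well_profiles(design, seed = 2,
                                 counts = count_params(40, 10))
  sig <- suppressWarnings(phenotype_signature(prof, design, "inverted"))
  ctr <- sig$contrasts
  sf <- dplyr::filter(ctr, factor == "SF")
  # EGF- minus EGF+ strongly positive on the log-odds scale
  expect_gt(sf$estimate * ifelse(sf$levelA == "EGF-", 1, -1), 5)
  expect_lt(sf$p_adj, 0.001)
  mp8 <- dplyr::filter(ctr, factor == "MP", levelA == "8" | levelB == "8")
  expect_equal(nrow(mp8), 3)
  expect_true(all(mp8$p_adj < 0.001))
  # all contrasts favour the 8 kPa level
  est_towards_8 <- ifelse(mp8$levelA == "8", mp8$estimate, -mp8$estimate)
  expect_true(all(est_towards_8 > 0))
  # degradability has no global effect
  expect_gt(sig$tests$p_value[sig$tests$factor == "DG"], 0.05)
})

test_that("fitted proportions stay inside (0,1) and average to the pooled rate", {
  design <- assign_wells(enumerate_conditions(small_levels()),
                         replicates = 3, seed = 2)
  prof <- simulate_well_profiles(design, null_model(), seed = 3,
                                 counts = count_params(30, 5))
  fit <- fit_phenotype_glm(prof, design, "polarized", family = "binomial")
  p <- predict(fit$fit, type = "response")
  expect_true(all(p > 0 & p < 1))
  # canonical-link identity: count-weighted fitted = observed pooled rate
  expect_equal(sum(p * fit$data$n) / sum(fit$data$n),
               sum(fit$data$k) / sum(fit$data$n), tolerance = 1e-8)
})

test_that("zero-colony wells are excluded with a warning", {
  design <- assign_wells(enumerate_conditions(small_levels()),
                         replicates = 2, seed = 4)
  prof <- simulate_well_profiles(design, null_model(), seed = 5,
                                 counts = count_params(20, 5))
  prof$n_colonies[1] <- 0L
  prof[1, paste0("n_", phenotypes())] <- 0L
  expect_warning(fit <- fit_phenotype_glm(prof, design, "spread"),
                 "zero-colony")
  expect_equal(fit$excluded_wells, prof$well_id[1])
  expect_equal(nrow(fit$data), nrow(design) - 1)
})

test_that("stepwise AIC keeps a strongly planted interaction and discriminates", {
  lv <- factor_levels(stiffness_kPa = c(2, 8), polymer_pct = c(1.5, 3),
                      ecm_base = "L", replicates = 6)
  design <- assign_wells(enumerate_conditions(lv), replicates = 6, seed = 1)

  # hand-built non-additive profiles: inverted needs both 8 kPa and EGF-
  sim_interaction <- function(design, seed, beta_int = 2.5) {
    set.seed(seed)
    n <- sample_colony_count(nrow(design), count_params(40, 5))
    eta <- -2 + beta_int * (design$stiffness_kPa == 8 & design$egf == "EGF-")
    k <- rbinom(nrow(design), n, plogis(eta))
    tibble::tibble(
      well_id = design$well_id, n_colonies = n,
      n_polarized = n - k, n_nonpolarized = 0L, n_spread = 0L,
      n_inverted = k,
      f_polarized = (n - k) / n, f_nonpolarized = 0, f_spread = 0,
      f_inverted = k / n, empty_well = n == 0)
  }

  kept_planted <- kept_null <- logical(12)
  for (s in seq_len(12)) {
    prof_i <- sim_interaction(design, seed = 100 + s)
    sel_i <- step_aic(suppressWarnings(
      fit_phenotype_glm(prof_i, design, "inverted", family = "binomial")))
    kept_planted[s] <- grepl("MP:SF", paste(deparse(stats::formula(sel_i$fit)),
                                            collapse = ""))
    prof_0 <- sim_interaction(design, seed = 200 + s, beta_int = 0)
    sel_0 <- step_aic(suppressWarnings(
      fit_phenotype_glm(prof_0, design, "inverted", family = "binomial")))
    kept_null[s] <- grepl("MP:SF", paste(deparse(stats::formula(sel_0$fit)),
                                         collapse = ""))
  }
  expect_gte(mean(kept_planted), 0.9)
  expect_lte(mean(kept_null), 0.4)

  # scope restricted to main effects leaves the model unchanged
  prof <- simulate_well_profiles(design, null_model(), seed = 1,
                                 counts = count_params(30, 5))
  fit <- fit_phenotype_glm(prof, design, "inverted")
  expect_identical(step_aic(fit, scope = "main"), fit)
})

test_that("LS-means reduce to raw level means on balanced linear fits", {
  design <- assign_wells(enumerate_conditions(small_levels()),
                         replicates = 3, seed = 6)
  prof <- simulate_well_profiles(design, seed = 7,
                                 counts = count_params(50, 0))
  fit <- fit_phenotype_glm(prof, design, "inverted", family = "linear")
  lsm <- ls_means(fit, "SF")
  raw <- dplyr::inner_join(prof, design, by = "well_id") |>
    dplyr::group_by(egf) |>
    dplyr::summarise(m = mean(n_inverted / n_colonies))
  expect_equal(lsm$ls_mean[match(raw$egf, lsm$level)], raw$m,
               tolerance = 1e-9)
  # invariance to factor level ordering
  design2 <- design[rev(seq_len(nrow(design))), ]
  fit2 <- fit_phenotype_glm(prof, design2, "inverted", family = "linear")
  lsm2 <- ls_means(fit2, "SF")
  expect_equal(lsm2$ls_mean[match(lsm$level, lsm2$level)], lsm$ls_mean,
               tolerance = 1e-9)
})

test_that("Tukey-Kramer adjustment is vacuous for two levels, conservative beyond", {
  design <- assign_wells(enumerate_conditions(), replicates = 2, seed = 8)
  prof <- simulate_well_profiles(design, seed = 9,
                                 counts = count_params(40, 10))
  fit <- suppressWarnings(fit_phenotype_glm(prof, design, "spread"))
  # two-level factor: adjusted p equals the single unadjusted comparison
  tk <- tukey_kramer(fit, "SF")
  em <- suppressMessages(emmeans::emmeans(fit$fit, "SF"))
  un <- suppressMessages(as.data.frame(
    emmeans::contrast(em, "pairwise", adjust = "none")))
  expect_equal(tk$p_adj, un$p.value, tolerance = 1e-9)
  # multi-level factor: adjusted >= unadjusted for every pair
  tk_mp <- tukey_kramer(fit, "MP")
  em_mp <- suppressMessages(emmeans::emmeans(fit$fit, "MP"))
  un_mp <- suppressMessages(as.data.frame(
    emmeans::contrast(em_mp, "pairwise", adjust = "none")))
  expect_true(all(tk_mp$p_adj >= un_mp$p.value - 1e-12))
  expect_equal(nrow(tk_mp), choose(4, 2))
  # significance codes follow the thresholds
  expect_equal(unique(tk_mp$code[tk_mp$p_adj >= 0.05]), "")
})
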
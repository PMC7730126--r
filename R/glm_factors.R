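#' Simulate per-well phenotype counts without rendering
#'
#' The count-level fast path of the synthetic screen: per well, a colony
#' count is drawn from the count distribution and phenotypes are drawn
#' multinomially from the condition's planted mixture. Produces the same
#' statistical structure as classifying a rendered plate, without images,
#' and is the workhorse for calibration simulations.
#'
#' @param design Plate layout from [assign_wells()].
#' @param model A [phenotype_effect_model()].
#' @param seed Integer seed.
#' @param counts A [count_params()] object.
#' @return Well-profile tibble as from [well_profiles()].
#' @export
simulate_well_profiles <- function(design, model = phenotype_effect_model(),
                                   seed = 1, counts = count_params()) {
  pr <- condition_phenotype_probs(model, design)
  pm <- as.matrix(pr[paste0("p_", phenotypes())])
  set.seed(seed)
  n <- sample_colony_count(nrow(design), counts)
  km <- vapply(seq_len(nrow(design)), function(i) {
    if (n[i] == 0) return(rep(0L, 4))
    as.integer(rmultinom(1, n[i], pm[i, ]))
  }, integer(4))
  out <- tibble::tibble(well_id = design$well_id, n_colonies = n)
  for (j in seq_along(phenotypes())) {
    out[[paste0("n_", phenotypes()[j])]] <- km[j, ]
    out[[paste0("f_", phenotypes()[j])]] <- ifelse(n > 0, km[j, ] / n, NA_real_)
  }
  out$empty_well <- n == 0
  out
}

# diverging coefficients / standard errors indicate cells with proportions
# of exactly 0 or 1 (complete or quasi-complete separation)
is_separated <- function(fit) {
  cf <- coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  ok <- is.finite(cf) & is.finite(se)
  !fit$converged || any(abs(cf[ok]) > 15) || any(se[ok] > 5)
}

# half-count (empirical-logit style) shrinkage: 0.5 pseudo-successes and
# 0.5 pseudo-failures per well
shrink_counts <- function(d) {
  d$k <- d$k + 0.5
  d$n <- d$n + 1
  d
}

glm_data <- function(profiles, design, phenotype) {
  assert_that(phenotype %in% phenotypes(), "unknown phenotype")
  d <- dplyr::inner_join(profiles, design, by = "well_id")
  excluded <- d$well_id[d$n_colonies == 0]
  if (length(excluded) > 0) {
    rlang::warn(paste0(length(excluded), " zero-colony well(s) excluded from GLM"))
  }
  d <- dplyr::filter(d, .data$n_colonies > 0)
  lev <- sort(unique(d$stiffness_kPa))
  d$MP <- factor(as.character(d$stiffness_kPa), levels = as.character(lev))
  d$DG <- factor(d$degradability)
  d$EC <- factor(d$ecm)
  d$SF <- factor(d$egf)
  d$k <- d[[paste0("n_", phenotype)]]
  d$n <- d$n_colonies
  list(data = d, excluded = excluded)
}

#' Binomial GLM for one phenotype's per-well proportions
#'
#' Models the per-well count of one phenotype against the well's colony
#' count as a binomial (logit link) GLM in the four microenvironmental
#' factor categories MP (stiffness), DG (degradability), EC (ECM subset)
#' and SF (EGF). The default quasi-binomial family estimates a dispersion
#' parameter to absorb overdispersion relative to pure within-well
#' multinomial sampling. Zero-colony wells are excluded (and recorded).
#'
#' A separation guard watches for diverging coefficients (cells where the
#' proportion is exactly 0 or 1); when detected, the model is refit with a
#' half-count shrinkage (0.5 pseudo-successes and -failures per well) and
#' flagged.
#'
#' @param profiles Well profiles ([well_profiles()] or
#'   [simulate_well_profiles()]).
#' @param design Plate layout.
#' @param phenotype One of [phenotypes()].
#' @param interactions `"none"` for main effects only, `"two-way"` to
#'   include all pairwise interactions in the initial fit.
#' @param family `"quasibinomial"` (default), `"binomial"`, or `"linear"`
#'   (an ordinary linear model on the frequencies, weighted by colony
#'   count, for comparability with proportion-scale analyses).
#' @return A `phenotype_glm`: the fit, the model data, dispersion, and
#'   bookkeeping flags.
#' @export
fit_phenotype_glm <- function(profiles, design, phenotype,
                              interactions = c("none", "two-way"),
                              family = c("quasibinomial", "binomial", "linear")) {
  interactions <- match.arg(interactions)
  family <- match.arg(family)
  gd <- glm_data(profiles, design, phenotype)
  d <- gd$data
  for (f in c("MP", "DG", "EC", "SF")) {
    assert_that(nlevels(droplevels(d[[f]])) >= 2 || nlevels(d[[f]]) >= 2,
                paste0("factor ", f, " needs >= 2 levels"))
  }
  rhs <- if (interactions == "two-way") "(MP + DG + EC + SF)^2" else "MP + DG + EC + SF"
  separation_adjusted <- FALSE
  if (family == "linear") {
    fml <- as.formula(paste("I(k / n) ~", rhs))
    fit <- stats::lm(fml, data = d, weights = d$n)
    disp <- summary(fit)$sigma^2
  } else {
    fml <- as.formula(paste("cbind(k, n - k) ~", rhs))
    fam <- if (family == "binomial") binomial() else quasibinomial()
    fit <- suppressWarnings(glm(fml, family = fam, data = d))
    if (is_separated(fit)) {
      rlang::warn(paste0("separation detected for ", phenotype,
                         "; refitting with half-count shrinkage"))
      d <- shrink_counts(d)
      fit <- suppressWarnings(glm(fml, family = fam, data = d))
      separation_adjusted <- TRUE
    }
    disp <- summary(fit)$dispersion
  }
  structure(list(fit = fit, data = d, phenotype = phenotype,
                 family = family, dispersion = disp,
                 excluded_wells = gd$excluded,
                 separation_adjusted = separation_adjusted),
            class = "phenotype_glm")
}

#' Stepwise AIC model selection over interaction terms
#'
#' Greedy bidirectional stepwise search minimizing AIC, with the four main
#' effects forced in and all two-way interactions as the candidate scope
#' (`scope = "two-way"`; `"main"` leaves the model unchanged). Because AIC
#' is undefined under quasi-likelihood, selection runs on the binomial
#' twin of the model; the selected formula is then refit with the original
#' family for inference.
#'
#' @param model A `phenotype_glm`.
#' @param scope `"two-way"` or `"main"`.
#' @return A `phenotype_glm` for the selected model, with the search trace
#'   in `$aic_trace`.
#' @export
step_aic <- function(model, scope = c("two-way", "main")) {
  scope <- match.arg(scope)
  if (scope == "main") return(model)
  d <- model$data
  base <- glm(cbind(k, n - k) ~ MP + DG + EC + SF, family = binomial(), data = d)
  lower <- ~ MP + DG + EC + SF
  upper <- ~ (MP + DG + EC + SF)^2
  stepped <- MASS::stepAIC(base, scope = list(lower = lower, upper = upper),
                           direction = "both", trace = 0)
  fml <- stats::formula(stepped)
  fam <- switch(model$family, binomial = binomial(), quasibinomial())
  separation_adjusted <- model$separation_adjusted
  refit <- if (model$family == "linear") {
    rhs <- deparse(fml[[3]])
    stats::lm(as.formula(paste("I(k/n) ~", rhs)), data = d, weights = d$n)
  } else {
    r <- suppressWarnings(glm(fml, family = fam, data = d))
    if (is_separated(r)) {
      rlang::warn(paste0("separation after term selection for ", model$phenotype,
                         "; refitting with half-count shrinkage"))
      d <- shrink_counts(d)
      separation_adjusted <- TRUE
      r <- suppressWarnings(glm(fml, family = fam, data = d))
    }
    r
  }
  out <- model
  out$data <- d
  out$separation_adjusted <- separation_adjusted
  out$fit <- refit
  out$aic_trace <- stepped$anova
  out$dispersion <- if (model$family == "linear") summary(refit)$sigma^2
                    else summary(refit)$dispersion
  out
}

#' Global factor tests
#'
#' Type-II tests per factor category: F tests under quasi-likelihood
#' (dispersion-adjusted), likelihood-ratio chi-square under the plain
#' binomial family.
#'
#' @param model A `phenotype_glm`.
#' @return Tibble `factor, statistic, df, p_value`.
#' @export
factor_tests <- function(model) {
  test <- if (model$family == "binomial") "LR" else "F"
  a <- car::Anova(model$fit, type = 2, test.statistic = test)
  tibble::tibble(
    factor = rownames(a),
    statistic = a[[1]],
    df = a[["Df"]],
    p_value = a[[grep("^Pr", names(a))[1]]])
}

#' Least-squares means per factor level
#'
#' Model-based marginal means: predictions at each level of `factor`,
#' averaged over the reference grid of the remaining factors on the link
#' scale, then back-transformed to the proportion scale with delta-method
#' standard errors.
#'
#' @param model A `phenotype_glm`.
#' @param factor One of `"MP"`, `"DG"`, `"EC"`, `"SF"`.
#' @return Tibble `factor, level, ls_mean, se, n_wells`.
#' @export
ls_means <- function(model, factor) {
  assert_that(factor %in% all.vars(stats::formula(model$fit)),
              paste0("factor ", factor, " is not in the model"))
  em <- suppressMessages(emmeans::emmeans(model$fit, specs = factor,
                                          type = "response"))
  s <- suppressMessages(as.data.frame(em))
  est_col <- intersect(c("prob", "response", "emmean"), names(s))[1]
  nw <- table(model$data[[factor]])
  tibble::tibble(
    factor = factor,
    level = as.character(s[[1]]),
    ls_mean = s[[est_col]],
    se = s[["SE"]],
    n_wells = as.integer(nw[as.character(s[[1]])]))
}

#' Tukey-Kramer pairwise contrasts
#'
#' All pairwise comparisons of the least-squares means of one factor, with
#' studentized-range (Tukey-Kramer) adjustment honouring unequal level
#' sizes; estimates are on the link (log-odds) scale. Significance codes:
#' `***` < 0.001, `**` < 0.01, `*` < 0.05.
#'
#' @inheritParams ls_means
#' @return Tibble `factor, levelA, levelB, estimate, se, p_adj, code`.
#' @export
tukey_kramer <- function(model, factor) {
  em <- suppressMessages(emmeans::emmeans(model$fit, specs = factor))
  pw <- suppressMessages(as.data.frame(
    emmeans::contrast(em, method = "pairwise", adjust = "tukey")))
  lv <- stringr::str_split_fixed(pw$contrast, " - ", 2)
  # emmeans prefixes numeric-looking levels with the factor name and may
  # wrap them in parentheses; report bare level labels
  strip <- function(x) {
    x <- stringr::str_remove_all(x, "[()]")
    stringr::str_remove(x, paste0("^", factor))
  }
  tibble::tibble(
    factor = factor,
    levelA = strip(lv[, 1]),
    levelB = strip(lv[, 2]),
    estimate = pw$estimate,
    se = pw$SE,
    p_adj = pw$p.value,
    code = sig_code(pw$p.value))
}

#' Full microenvironmental signature for one phenotype
#'
#' Convenience wrapper: fit the phenotype GLM, optionally run stepwise AIC
#' over two-way interactions, and collect least-squares means and
#' Tukey-Kramer contrasts for every factor category.
#'
#' @inheritParams fit_phenotype_glm
#' @param select Run [step_aic()] over two-way interactions.
#' @return A `factor_signature`: the model plus `ls_means` and `contrasts`
#'   tibbles covering MP, DG, EC and SF.
#' @export
phenotype_signature <- function(profiles, design, phenotype,
                                select = TRUE,
                                family = "quasibinomial") {
  m <- fit_phenotype_glm(profiles, design, phenotype, family = family)
  if (select) m <- step_aic(m)
  factors <- c("MP", "DG", "EC", "SF")
  lsm <- dplyr::bind_rows(lapply(factors, function(f) ls_means(m, f)))
  ctr <- dplyr::bind_rows(lapply(factors, function(f) tukey_kramer(m, f)))
  structure(list(model = m, phenotype = phenotype,
                 ls_means = lsm, contrasts = ctr,
                 tests = factor_tests(m)),
            class = "factor_signature")
}

#' @export
print.factor_signature <- function(x, ...) {
  cat("Microenvironmental signature:", x$phenotype, "\n")
  cat("model:", deparse(stats::formula(x$model$fit)), "\n")
  cat("dispersion:", round(x$model$dispersion, 2), "\n")
  print(x$tests)
  invisible(x)
}
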
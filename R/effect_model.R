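#' Planted phenotype effect model
#'
#' The generative model behind the synthetic screen: each condition maps to
#' a 4-vector of phenotype probabilities via a temperature-scaled softmax
#' over additive factor effects on the logit scale,
#' `p = softmax((baseline + sum of level effects) / temperature)`.
#' Colonies within a well are drawn i.i.d. from that vector.
#'
#' The default effects plant the qualitative structure the analysis stages
#' are expected to recover: absence of EGF or an 8 kPa matrix drives wells
#' to near-pure inverted colonies; the permissive regime (2-4 kPa with EGF)
#' yields polarized colonies, shifted towards non-polarized whenever the
#' ECM subset contains fibronectin; the softest matrix (0.5 kPa) enriches
#' spread colonies. Degradability carries no logit effect at all - instead
#' it sets the mixing temperature (default 1.05 for the MMP-degradable
#' crosslinker versus 1 for the non-degradable one), so degradable wells
#' show strictly higher within-well phenotype entropy while per-phenotype
#' mean frequencies move only marginally.
#'
#' @param baseline_logits Named 4-vector of baseline logits in
#'   [phenotypes()] order.
#' @param stiffness,egf,ecm_fibronectin Named lists / vectors of additive
#'   logit effects (see defaults for the expected shapes). `ecm_fibronectin`
#'   is applied to every ECM subset containing fibronectin (F).
#' @param mixing_temperature Named vector of softmax temperatures keyed by
#'   degradability level; values > 1 flatten the phenotype mixture.
#' @return An object of class `phenotype_effect_model`.
#' @examples
#' m <- phenotype_effect_model()
#' condition_phenotype_probs(m, enumerate_conditions())
#' @export
phenotype_effect_model <- function(
    baseline_logits = c(polarized = 1.5, nonpolarized = 0, spread = 0.5, inverted = 0),
    stiffness = list(
      "0.5" = c(polarized = -4, nonpolarized = 0, spread = 4, inverted = 0),
      "2"   = c(polarized = 3, nonpolarized = 3.3, spread = 0, inverted = 0),
      "4"   = c(polarized = 3, nonpolarized = 2.5, spread = 0, inverted = 0),
      "8"   = c(polarized = 0, nonpolarized = 0, spread = 0, inverted = 6)
    ),
    egf = list(
      "EGF+" = c(polarized = 0, nonpolarized = 0, spread = 0, inverted = 0),
      "EGF-" = c(polarized = 0, nonpolarized = 0, spread = 0, inverted = 9)
    ),
    ecm_fibronectin = c(polarized = -2.5, nonpolarized = 2.5, spread = 0, inverted = 0),
    mixing_temperature = c(high = 1.05, low = 1)) {
  ph <- phenotypes()
  chk <- function(v) {
    assert_that(all(ph %in% names(v)), "effect vectors must name all four phenotypes")
    v[ph]
  }
  structure(
    list(
      baseline_logits = chk(baseline_logits),
      stiffness = lapply(stiffness, chk),
      egf = lapply(egf, chk),
      ecm_fibronectin = chk(ecm_fibronectin),
      mixing_temperature = mixing_temperature
    ),
    class = "phenotype_effect_model"
  )
}

condition_logits <- function(model, stiffness_kPa, ecm, egf) {
  s_eff <- model$stiffness[[as.character(stiffness_kPa)]]
  if (is.null(s_eff)) rlang::abort(paste0("no effect entry for stiffness ", stiffness_kPa))
  e_eff <- model$egf[[egf]]
  if (is.null(e_eff)) rlang::abort(paste0("no effect entry for soluble-factor level ", egf))
  f_eff <- if (ecm_contains(ecm, "F")) model$ecm_fibronectin else 0
  model$baseline_logits + s_eff + e_eff + f_eff
}

#' Phenotype probabilities for screen conditions
#'
#' Evaluates the planted effect model on one or more conditions: the
#' temperature-scaled softmax of summed factor logits. Probabilities sum to
#' one for every condition.
#'
#' @param model A [phenotype_effect_model()].
#' @param conditions Tibble with columns `stiffness_kPa`, `degradability`,
#'   `ecm`, `egf` (e.g. from [enumerate_conditions()] or [assign_wells()]).
#' @return The input tibble with four added probability columns
#'   `p_polarized`, `p_nonpolarized`, `p_spread`, `p_inverted`.
#' @export
condition_phenotype_probs <- function(model, conditions) {
  stopifnot(inherits(model, "phenotype_effect_model"))
  temps <- model$mixing_temperature[conditions$degradability]
  if (anyNA(temps)) {
    rlang::abort("mixing_temperature must name every degradability level")
  }
  probs <- purrr::pmap(
    list(conditions$stiffness_kPa, conditions$ecm, conditions$egf, temps),
    function(mp, ec, sf, tt) softmax(condition_logits(model, mp, ec, sf) / tt)
  )
  pm <- do.call(rbind, probs)
  colnames(pm) <- paste0("p_", phenotypes())
  dplyr::bind_cols(conditions, tibble::as_tibble(pm))
}

#' Expected within-well phenotype entropy per condition
#'
#' Shannon entropy (nats) of the phenotype mixture of each condition; the
#' population counterpart of the empirical within-well mixing that higher
#' degradability is planted to increase.
#'
#' @inheritParams condition_phenotype_probs
#' @return Input tibble with an `entropy` column.
#' @export
condition_entropy <- function(model, conditions) {
  pr <- condition_phenotype_probs(model, conditions)
  pm <- as.matrix(pr[paste0("p_", phenotypes())])
  pr$entropy <- apply(pm, 1, function(p) -sum(ifelse(p > 0, p * log(p), 0)))
  pr
}

#' Serialize / restore an effect model
#'
#' The model round-trips through a plain JSON file so a simulated screen's
#' generative configuration can be archived with its outputs.
#'
#' @param model A `phenotype_effect_model`.
#' @param path JSON file path.
#' @export
write_effect_model <- function(model, path) {
  # named vectors become JSON objects (a bare vector would drop its names)
  x <- list(
    baseline_logits = as.list(model$baseline_logits),
    stiffness = lapply(model$stiffness, as.list),
    egf = lapply(model$egf, as.list),
    ecm_fibronectin = as.list(model$ecm_fibronectin),
    mixing_temperature = as.list(model$mixing_temperature))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_effect_model
#' @export
read_effect_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  phenotype_effect_model(
    baseline_logits = unlist(x$baseline_logits),
    stiffness = lapply(x$stiffness, unlist),
    egf = lapply(x$egf, unlist),
    ecm_fibronectin = unlist(x$ecm_fibronectin),
    mixing_temperature = unlist(x$mixing_temperature)
  )
}
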
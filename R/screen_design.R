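#' Factor levels of the combinatorial microenvironment screen
#'
#' Defines the four factor categories of the screen: mechanical properties
#' (MP; matrix stiffness, set by polymer content), degradability (DG; the
#' MMP sensitivity of the crosslinker peptide), ECM components (EC; every
#' subset of a base protein set, including the blank control), and soluble
#' factor (SF; EGF in the overlay medium). Defaults reproduce the screen's
#' 4 x 2 x 8 x 2 full factorial: stiffnesses 0.5/2/4/8 kPa (1/1.5/2/3 %
#' w/v polymer), high/low MMP degradability, all subsets of
#' {laminin (L), collagen IV (C), fibronectin (F)}, and EGF at 10 ng/ml
#' versus none, in triplicate.
#'
#' @param stiffness_kPa Numeric vector of stiffness levels in kPa.
#' @param polymer_pct Numeric vector of polymer contents (% w/v) paired
#'   one-to-one with `stiffness_kPa`; metadata, not a separate factor.
#' @param degradability Character vector of degradability levels; by
#'   convention `"high"` is the MMP-sensitive (degradable) crosslinker and
#'   `"low"` the less sensitive one.
#' @param ecm_base Character vector of single-letter ECM protein codes to
#'   expand into all subsets. The canonical letter order is L, C, F.
#' @param egf Character vector of soluble-factor levels.
#' @param replicates Number of replicate wells per condition.
#' @return An object of class `factor_levels`.
#' @examples
#' lv <- factor_levels()
#' length(ecm_subsets(lv$ecm_base)) # 8
#' @export
factor_levels <- function(stiffness_kPa = c(0.5, 2, 4, 8),
                          polymer_pct = c(1, 1.5, 2, 3),
                          degradability = c("high", "low"),
                          ecm_base = c("L", "C", "F"),
                          egf = c("EGF+", "EGF-"),
                          replicates = 3) {
  assert_that(length(stiffness_kPa) > 0 && !anyDuplicated(stiffness_kPa),
              "stiffness levels must be non-empty and duplicate-free")
  assert_that(length(polymer_pct) == length(stiffness_kPa),
              "polymer_pct must pair one-to-one with stiffness_kPa")
  assert_that(length(degradability) > 0 && !anyDuplicated(degradability),
              "degradability levels must be non-empty and duplicate-free")
  assert_that(!anyDuplicated(ecm_base),
              "ecm_base must be duplicate-free")
  assert_that(length(egf) > 0 && !anyDuplicated(egf),
              "soluble-factor levels must be non-empty and duplicate-free")
  assert_that(replicates >= 1, "replicates must be a positive integer")
  structure(
    list(stiffness_kPa = stiffness_kPa, polymer_pct = polymer_pct,
         degradability = degradability, ecm_base = ecm_base, egf = egf,
         replicates = as.integer(replicates)),
    class = "factor_levels"
  )
}

#' All ECM subsets of a base protein set
#'
#' Expands a k-protein base set into its 2^k subsets. Subsets are unordered;
#' each is labelled by its letters in the canonical base-set order (so
#' {C, L} is `"LC"`), and the empty set is labelled `"blank"`. Subsets are
#' returned ordered by size and then by label.
#'
#' @param base Character vector of single-letter protein codes.
#' @return Character vector of 2^length(base) subset labels.
#' @export
ecm_subsets <- function(base = c("L", "C", "F")) {
  k <- length(base)
  if (k == 0) return("blank")
  picks <- expand.grid(rep(list(c(FALSE, TRUE)), k))
  labels <- apply(picks, 1, function(w) paste0(base[as.logical(w)], collapse = ""))
  labels[labels == ""] <- "blank"
  sizes <- rowSums(picks)
  labels[order(sizes, match(labels, labels))]
}

ecm_contains <- function(ecm, protein) {
  ecm != "blank" & stringr::str_detect(ecm, stringr::fixed(protein))
}

#' Enumerate all conditions of a full-factorial screen design
#'
#' Takes the Cartesian product MP x DG x EC-subsets x SF in deterministic
#' order (stiffness slowest, soluble factor fastest). At default levels this
#' yields the screen's 128 unique culture conditions.
#'
#' @param levels A [factor_levels()] object.
#' @return A tibble with one row per condition: `condition_id`,
#'   `stiffness_kPa`, `polymer_pct`, `degradability`, `ecm`, `egf`.
#' @examples
#' nrow(enumerate_conditions(factor_levels())) # 128
#' @export
enumerate_conditions <- function(levels = factor_levels()) {
  stopifnot(inherits(levels, "factor_levels"))
  ec <- ecm_subsets(levels$ecm_base)
  grid <- tidyr::expand_grid(
    stiffness_kPa = levels$stiffness_kPa,
    degradability = levels$degradability,
    ecm = ec,
    egf = levels$egf
  )
  grid |>
    dplyr::mutate(
      polymer_pct = levels$polymer_pct[match(.data$stiffness_kPa, levels$stiffness_kPa)],
      condition_id = sprintf("MP%s-DG%s-EC%s-%s", .data$stiffness_kPa,
                             .data$degradability, .data$ecm, .data$egf)
    ) |>
    dplyr::select("condition_id", "stiffness_kPa", "polymer_pct",
                  "degradability", "ecm", "egf")
}

#' Gel precursor combinations
#'
#' The robotically premixed PEG precursor solutions: one per (stiffness,
#' degradability) pair, 8 at default levels. Projecting further onto the
#' ECM subsets gives the 64 unique gel + ECM combinations dispensed into
#' wells before the soluble factor is added.
#'
#' @inheritParams enumerate_conditions
#' @param with_ecm If `TRUE`, also cross with the ECM subsets (64 rows at
#'   defaults) instead of the bare precursor pairs (8 rows).
#' @return A tibble of precursor combinations in deterministic order.
#' @export
gel_precursor_combinations <- function(levels = factor_levels(), with_ecm = FALSE) {
  conds <- enumerate_conditions(levels)
  keys <- if (with_ecm) c("stiffness_kPa", "polymer_pct", "degradability", "ecm")
          else c("stiffness_kPa", "polymer_pct", "degradability")
  dplyr::distinct(conds, dplyr::pick(dplyr::all_of(keys)))
}

plate_well_ids <- function(n) {
  rows <- LETTERS[1:16]
  cols <- 1:24
  ids <- as.vector(t(outer(rows, cols, paste0)))
  if (n <= length(ids)) return(ids[seq_len(n)])
  plates <- ceiling(n / length(ids))
  ids <- as.vector(vapply(seq_len(plates),
                          function(p) paste0("P", p, "-", ids),
                          character(length(ids))))
  ids[seq_len(n)]
}

#' Assign conditions to wells in replicate
#'
#' Builds a plate layout with each condition replicated `replicates` times.
#' Wells are named with 384-well plate coordinates (A1..P24, row-major,
#' spilling onto additional plates if needed) and the condition-to-well
#' assignment is a seeded random permutation, so plate position carries no
#' information about the condition.
#'
#' @param conditions Condition tibble from [enumerate_conditions()].
#' @param replicates Replicate wells per condition.
#' @param seed Integer seed for the assignment permutation.
#' @return A tibble (`well_id`, `condition_id`, `replicate`) joined with the
#'   condition factor columns; one row per well.
#' @examples
#' nrow(assign_wells(enumerate_conditions(), replicates = 3)) # 384
#' @export
assign_wells <- function(conditions, replicates = 3, seed = 1) {
  assert_that(replicates >= 1, "replicates must be >= 1")
  assert_that(!anyDuplicated(conditions$condition_id),
              "condition_id values must be unique")
  slots <- tidyr::expand_grid(condition_id = conditions$condition_id,
                              replicate = seq_len(replicates))
  set.seed(seed)
  slots <- slots[sample.int(nrow(slots)), ]
  slots |>
    dplyr::mutate(well_id = plate_well_ids(nrow(slots)), .before = 1) |>
    dplyr::left_join(conditions, by = "condition_id")
}

#' Write / read a screen design table
#'
#' The design table is a plain CSV with columns `well_id`, `condition_id`,
#' `replicate`, `stiffness_kPa`, `polymer_pct`, `degradability`, `ecm`,
#' `egf`; `ecm` is the concatenated-letter subset label (`"blank"` for the
#' protein-free control). Reading a written table reproduces the layout
#' exactly.
#'
#' @param design Design tibble from [assign_wells()].
#' @param path File path.
#' @return `write_design` returns `path` invisibly; `read_design` returns
#'   the design tibble.
#' @export
write_design <- function(design, path) {
  readr::write_csv(design, path)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    well_id = readr::col_character(),
    condition_id = readr::col_character(),
    replicate = readr::col_integer(),
    stiffness_kPa = readr::col_double(),
    polymer_pct = readr::col_double(),
    degradability = readr::col_character(),
    ecm = readr::col_character(),
    egf = readr::col_character()
  ))
}
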
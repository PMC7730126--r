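#' Rank wells by a phenotype's frequency
#'
#' Wells sorted by descending frequency of the given phenotype. Ties are
#' broken by colony count (descending: a frequency supported by more
#' colonies ranks higher) and then by well id, giving a deterministic
#' total order. Wells with undefined profiles (no colonies) rank last.
#'
#' @param profiles Well profile tibble.
#' @param phenotype One of [phenotypes()].
#' @return `profiles` reordered, with a `rank` column.
#' @export
rank_wells <- function(profiles, phenotype) {
  assert_that(nrow(profiles) > 0, "profiles must be non-empty")
  assert_that(phenotype %in% phenotypes(), "unknown phenotype")
  f <- profiles[[paste0("f_", phenotype)]]
  ord <- order(-ifelse(is.na(f), -Inf, f), -profiles$n_colonies,
               profiles$well_id)
  out <- profiles[ord, ]
  out$rank <- seq_len(nrow(out))
  out
}

#' Microenvironmental composition of the top-ranked wells
#'
#' Selects the top `ceiling(top_fraction * N)` wells of a ranking and, for
#' each factor category (MP, DG, EC, SF), tabulates the percentage of
#' selected wells at each level. With `by = "condition"` the ranking is
#' done on replicate-averaged condition frequencies instead of individual
#' wells.
#'
#' @param ranked Ranked profiles from [rank_wells()] (or raw profiles,
#'   which are ranked internally when `phenotype` is given).
#' @param design Plate layout joining `well_id` to factor levels.
#' @param top_fraction Fraction of wells to select.
#' @param phenotype Needed when `ranked` is unranked or `by = "condition"`.
#' @param by Rank `"well"`s (default) or triplicate-averaged
#'   `"condition"`s.
#' @return A `ranked_map`: `phenotype`, `selected` (ids), and
#'   `composition` (tibble `category, level, n_wells, percent`; percentages
#'   sum to 100 within each category).
#' @export
top_fraction_map <- function(ranked, design, top_fraction = 0.05,
                             phenotype = NULL, by = c("well", "condition")) {
  by <- match.arg(by)
  factor_cols <- c(MP = "stiffness_kPa", DG = "degradability",
                   EC = "ecm", SF = "egf")
  if (by == "condition") {
    assert_that(!is.null(phenotype), "phenotype is required for by = 'condition'")
    cond <- dplyr::inner_join(ranked, design, by = "well_id") |>
      dplyr::group_by(.data$condition_id) |>
      dplyr::summarise(f = mean(.data[[paste0("f_", phenotype)]], na.rm = TRUE),
                       n_colonies = sum(.data$n_colonies), .groups = "drop") |>
      dplyr::arrange(dplyr::desc(.data$f), dplyr::desc(.data$n_colonies),
                     .data$condition_id)
    n_top <- ceiling(top_fraction * nrow(cond))
    sel_ids <- cond$condition_id[seq_len(n_top)]
    sel <- dplyr::distinct(design[design$condition_id %in% sel_ids,
                                  c("condition_id", unname(factor_cols))])
  } else {
    if (!"rank" %in% names(ranked)) {
      assert_that(!is.null(phenotype),
                  "phenotype is required to rank unranked profiles")
      ranked <- rank_wells(ranked, phenotype)
    }
    n_top <- ceiling(top_fraction * nrow(ranked))
    sel_wells <- ranked$well_id[seq_len(n_top)]
    orphan <- setdiff(sel_wells, design$well_id)
    if (length(orphan) > 0) {
      rlang::abort(paste0("selected well(s) missing from design: ",
                          paste(orphan, collapse = ", ")))
    }
    sel <- design[match(sel_wells, design$well_id), ]
  }
  composition <- purrr::imap_dfr(factor_cols, function(col, cat) {
    tb <- table(as.character(sel[[col]]))
    tibble::tibble(category = cat, level = names(tb),
                   n_wells = as.integer(tb),
                   percent = 100 * as.integer(tb) / sum(tb))
  })
  structure(list(phenotype = phenotype, selected = sel,
                 n_selected = nrow(sel), top_fraction = top_fraction,
                 composition = composition),
            class = "ranked_map")
}

#' Composition report over all four phenotypes
#'
#' Runs [rank_wells()] + [top_fraction_map()] for each phenotype and
#' binds the compositions into one tidy long table.
#'
#' @param profiles Well profile tibble.
#' @param design Plate layout.
#' @param top_fraction Fraction of wells per phenotype.
#' @return Tibble `phenotype, category, level, percent, n_wells`.
#' @export
composition_report <- function(profiles, design, top_fraction = 0.05) {
  purrr::map_dfr(phenotypes(), function(ph) {
    m <- top_fraction_map(rank_wells(profiles, ph), design,
                          top_fraction = top_fraction, phenotype = ph)
    dplyr::mutate(m$composition, phenotype = ph, .before = 1)
  }) |>
    dplyr::select("phenotype", "category", "level", "percent", "n_wells")
}
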
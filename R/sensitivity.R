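#' MMSE-decline outcome variant
#'
#' Alternative progression definition: a subject progresses when the MMSE
#' drops by `delta` or more points from baseline to follow-up (a drop of
#' exactly `delta` counts as progression). Subjects missing either MMSE
#' score cannot be classified and are excluded; their ids are recorded in
#' the `excluded` attribute.
#'
#' @param cohort Cohort data frame with `mmse_baseline` and `mmse_followup`.
#' @param delta Decline threshold in MMSE points (default 3).
#' @return The classifiable subset of the cohort with an `outcome` factor
#'   (`stable`/`progressed`).
#' @examples
#' df <- tibble::tibble(subject_id = c("a", "b"),
#'                      mmse_baseline = c(28, 28), mmse_followup = c(25, 26))
#' mmse_decline_outcome(df)$outcome
#' @export
mmse_decline_outcome <- function(cohort, delta = 3) {
  cohort <- tibble::as_tibble(cohort)
  ok <- !is.na(cohort$mmse_baseline) & !is.na(cohort$mmse_followup)
  out <- cohort[ok, ]
  out$outcome <- factor(
    ifelse(out$mmse_baseline - out$mmse_followup >= delta,
           "progressed", "stable"),
    levels = .outcome_levels
  )
  attr(out, "excluded") <- cohort$subject_id[!ok]
  out
}

#' Restrict a cohort to diagnosis subgroups
#'
#' @param cohort Cohort data frame with `diagnosis_group`.
#' @param keep Diagnosis groups to retain (default MCI + dementia, the
#'   pre-planned subgroup without subjective cognitive decline).
#' @return The filtered cohort; errors when nothing remains.
#' @export
subgroup_filter <- function(cohort, keep = c("MCI", "dementia")) {
  bad <- setdiff(keep, .diagnosis_levels)
  if (length(bad)) stop("Unknown diagnosis group(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  out <- dplyr::filter(tibble::as_tibble(cohort),
                       .data$diagnosis_group %in% keep)
  if (!nrow(out)) stop("No subjects left after subgroup filtering",
                       call. = FALSE)
  out
}

#' Define a sensitivity-analysis grid
#'
#' Enumerates the cells of the sensitivity grid: dichotomization threshold
#' magnitudes (a magnitude `t` is applied as `-t` to abnormal-low variables
#' and `+t` to abnormal-high ones, always jointly), lobe-count cut-offs,
#' outcome definitions, adjustment sets and cohort filters. The first value
#' of every axis defines the base cell of the primary analysis.
#'
#' @param z_thresholds Threshold magnitudes (default `c(0, 0.1, 0.5)`).
#' @param lobe_cutoffs Lobe-count cut-offs (default `c(2, 1, 3)`).
#' @param outcomes `"clinician"` and/or `"mmse_decline"`.
#' @param adjustments List of character vectors of adjustment covariates.
#' @param subgroups `"all"` and/or `"mci_dementia"`.
#' @return A tibble of class `np_grid_spec`, one row per cell.
#' @export
sensitivity_grid <- function(z_thresholds = c(0, 0.1, 0.5),
                             lobe_cutoffs = c(2L, 1L, 3L),
                             outcomes = c("clinician", "mmse_decline"),
                             adjustments = list(c("age", "sex")),
                             subgroups = c("all", "mci_dementia")) {
  stopifnot(all(z_thresholds >= 0), all(lobe_cutoffs %in% 1:3),
            all(outcomes %in% c("clinician", "mmse_decline")),
            all(subgroups %in% c("all", "mci_dementia")),
            is.list(adjustments), length(adjustments) >= 1)
  grid <- tidyr::expand_grid(
    z_threshold = z_thresholds,
    lobe_cutoff = as.integer(lobe_cutoffs),
    outcome_def = outcomes,
    adjustment = adjustments,
    subgroup = subgroups
  )
  structure(grid, class = c("np_grid_spec", class(grid)))
}

#' Run the sensitivity-analysis grid
#'
#' For every grid cell: filters the cohort, derives the requested outcome,
#' rebuilds the lobe-pattern features at the cell's threshold and cut-off,
#' refits the univariable and mutually adjusted multivariable pattern models,
#' and records odds ratios, confidence intervals, p-values and whether the
#' +A/+H point estimate keeps the direction (above/below 1) of the base
#' cell — the robustness criterion. Cell-level model failures are recorded
#' as structured failure messages, never raised.
#'
#' @param cohort A validated cohort (raw outcome still present).
#' @param grid A [sensitivity_grid()]; its first row is the base cell.
#' @param restandardize Recompute intracohort z-scores within a filtered
#'   subgroup (default `FALSE`: subgroup analyses reuse the full-cohort
#'   z-scores, so they are the same model on fewer patients).
#' @return A tibble of class `np_sensitivity`: the grid columns plus `n`,
#'   `n_excluded`, per-pattern univariable/multivariable odds ratios for the
#'   +A/+H predictor, `direction_match`, `failure` (NA when the cell
#'   succeeded) and a `result` list-column of full [model_table()] objects.
#' @examples
#' cohort <- generate_cohort(synthetic_spec(n = 100, seed = 8))
#' g <- sensitivity_grid(z_thresholds = 0, lobe_cutoffs = 2,
#'                       outcomes = "clinician", subgroups = "all")
#' run_sensitivity(cohort, g)$or_ah_uni
#' @export
run_sensitivity <- function(cohort, grid = sensitivity_grid(),
                            restandardize = FALSE) {
  cohort <- tibble::as_tibble(cohort)
  if (!nrow(grid)) stop("Empty grid", call. = FALSE)

  z_full <- compute_zscores(cohort, c(lobe_volume_roles(), lobe_suvr_roles()))

  run_cell <- function(z_threshold, lobe_cutoff, outcome_def, adjustment,
                       subgroup) {
    sub <- if (subgroup == "mci_dementia") {
      subgroup_filter(cohort, c("MCI", "dementia"))
    } else cohort
    sub <- if (outcome_def == "mmse_decline") {
      mmse_decline_outcome(sub)
    } else collapse_outcome(sub)
    excluded <- length(attr(sub, "excluded") %||% character(0)) +
      (nrow(cohort) - if (subgroup == "mci_dementia")
        nrow(subgroup_filter(cohort, c("MCI", "dementia"))) else nrow(cohort))

    z <- if (restandardize || identical(subgroup, "all")) {
      if (identical(subgroup, "all") && !restandardize) z_full
      else compute_zscores(sub, c(lobe_volume_roles(), lobe_suvr_roles()))
    } else z_full
    zc <- tibble::as_tibble(z)[match(sub$subject_id, z$subject_id), ]

    lobes <- classify_lobes(zc, z_threshold = -z_threshold)
    counts <- pattern_counts(lobes)
    feats <- dplyr::mutate(
      counts,
      ah = dichotomize_count(.data$n_ah, lobe_cutoff),
      a_only = dichotomize_count(.data$n_a_only, lobe_cutoff),
      h_only = dichotomize_count(.data$n_h_only, lobe_cutoff)
    )
    sub <- sub[setdiff(names(sub), setdiff(names(feats), "subject_id"))]
    data <- dplyr::left_join(sub, feats, by = "subject_id")
    tab <- model_table(data, terms = c("a_only", "h_only", "ah"),
                       adjust = adjustment)
    list(tab = tab, n = nrow(data), n_excluded = excluded)
  }

  rows <- purrr::pmap(grid, function(z_threshold, lobe_cutoff, outcome_def,
                                     adjustment, subgroup) {
    res <- tryCatch(
      run_cell(z_threshold, lobe_cutoff, outcome_def, adjustment, subgroup),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      tibble::tibble(
        z_threshold = z_threshold, lobe_cutoff = lobe_cutoff,
        outcome_def = outcome_def, adjustment = list(adjustment),
        subgroup = subgroup,
        n = NA_integer_, n_excluded = NA_integer_,
        or_ah_uni = NA_real_, or_ah_multi = NA_real_,
        failure = conditionMessage(res), result = list(NULL)
      )
    } else {
      tab <- res$tab
      ah <- tab[tab$term == "ah" & tab$level == "exposed", ]
      tibble::tibble(
        z_threshold = z_threshold, lobe_cutoff = lobe_cutoff,
        outcome_def = outcome_def, adjustment = list(adjustment),
        subgroup = subgroup,
        n = res$n, n_excluded = as.integer(res$n_excluded),
        or_ah_uni = ah$or_uni, or_ah_multi = ah$or_multi,
        failure = NA_character_, result = list(tab)
      )
    }
  })
  out <- dplyr::bind_rows(rows)
  base_dir <- out$or_ah_uni[1] > 1
  out$direction_match <- !is.na(out$or_ah_uni) & !is.na(base_dir) &
    (out$or_ah_uni > 1) == base_dir
  structure(out, class = c("np_sensitivity", class(out)))
}
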
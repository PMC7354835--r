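#' Classify lobe-wise atrophy/hypometabolism patterns
#'
#' For each of the eight unilateral lobes, flags pronounced atrophy (+A: lobe
#' volume z-score below threshold) and pronounced hypometabolism (+H: lobe
#' SUVR z-score below threshold), and labels the lobe with one of the four
#' joint patterns `+A/-H`, `-A/+H`, `+A/+H`, `-A/-H`.
#'
#' @param zscores An `np_zscores` panel from [compute_zscores()] containing
#'   all 8 lobe-volume and 8 lobe-SUVR z-columns.
#' @param z_threshold Dichotomization threshold (non-positive; default 0).
#' @return A tibble of class `np_lobes`, one row per subject x unilateral
#'   lobe: `subject_id`, `lobe`, `atrophy`, `hypometabolism` (logicals) and
#'   `pattern` (factor with the four joint labels).
#' @seealso [pattern_counts()], [anatomical_levels()]
#' @export
classify_lobes <- function(zscores, z_threshold = 0) {
  need <- paste0("z_", c(lobe_volume_roles(), lobe_suvr_roles()))
  missing_cols <- setdiff(need, names(zscores))
  if (length(missing_cols)) {
    stop("z-score panel lacks lobe column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  long <- tidyr::pivot_longer(
    tibble::as_tibble(zscores)[c("subject_id", need)],
    -"subject_id",
    names_to = c("modality", "lobe"),
    names_pattern = "z_(volume|suvr)_(.*)",
    values_to = "z"
  )
  wide <- tidyr::pivot_wider(long, names_from = "modality", values_from = "z")
  out <- dplyr::mutate(
    wide,
    atrophy = dichotomize(.data$volume, "abnormal_low", z_threshold),
    hypometabolism = dichotomize(.data$suvr, "abnormal_low", z_threshold),
    pattern = factor(
      dplyr::case_when(
        atrophy & !hypometabolism ~ "+A/-H",
        !atrophy & hypometabolism ~ "-A/+H",
        atrophy & hypometabolism ~ "+A/+H",
        TRUE ~ "-A/-H"
      ),
      levels = c("+A/-H", "-A/+H", "+A/+H", "-A/-H")
    )
  )
  out <- dplyr::select(out, "subject_id", "lobe", "atrophy",
                       "hypometabolism", "pattern")
  # preserve input subject order, then lobe order
  out$lobe <- factor(out$lobe, levels = lobe_names())
  out <- dplyr::arrange(out, match(.data$subject_id, zscores$subject_id), .data$lobe)
  structure(out, z_threshold = z_threshold,
            class = c("np_lobes", class(out)))
}

#' Count lobes per atrophy/hypometabolism pattern
#'
#' Summarizes a lobe-pattern profile into the three per-subject predictors
#' used by the pattern model: the number of unilateral lobes (0..8) carrying
#' `+A/-H`, `-A/+H` and `+A/+H` respectively (plus the residual `-A/-H`
#' count; the four always sum to 8).
#'
#' @param lobes An `np_lobes` tibble from [classify_lobes()].
#' @return A tibble: `subject_id`, `n_a_only`, `n_h_only`, `n_ah`,
#'   `n_neither`.
#' @export
pattern_counts <- function(lobes) {
  counts <- dplyr::summarise(
    dplyr::group_by(lobes, .data$subject_id),
    n_a_only = sum(.data$pattern == "+A/-H"),
    n_h_only = sum(.data$pattern == "-A/+H"),
    n_ah = sum(.data$pattern == "+A/+H"),
    n_neither = sum(.data$pattern == "-A/-H"),
    .groups = "drop"
  )
  counts[match(unique(lobes$subject_id), counts$subject_id), ]
}

#' Dichotomize a lobe count into an exposure flag
#'
#' Turns a per-subject pattern count (0..8) into the two-level predictor of
#' the printed tables: exposed when `count >= cutoff`. The default cut-off 2
#' gives the "0-1 affected lobes" vs "2 or more affected lobes" contrast;
#' cut-offs 1 and 3 are the sensitivity-analysis variants.
#'
#' @param count Integer vector of lobe counts in 0..8.
#' @param cutoff Cut-off in `{1, 2, 3}` (default 2).
#' @return Logical vector: `TRUE` = exposed.
#' @examples
#' dichotomize_count(c(0, 1, 2, 5))        # FALSE FALSE TRUE TRUE
#' dichotomize_count(1, cutoff = 1)        # TRUE
#' @export
dichotomize_count <- function(count, cutoff = 2L) {
  stopifnot(cutoff %in% 1:3)
  if (any(!is.na(count) & (count < 0 | count > 8))) {
    stop("Lobe counts must lie in 0..8", call. = FALSE)
  }
  count >= cutoff
}

#' Anatomical congruence levels per bilateral lobe
#'
#' Collapses the two hemispheres of each lobe into a 4-level anatomical
#' variable. With A = pronounced atrophy in the left and/or right hemisphere
#' and H = pronounced hypometabolism in the left and/or right hemisphere:
#' * `no_abnormality` — neither A nor H anywhere in the lobe (all four
#'   z-scores non-abnormal);
#' * `isolated_atrophy` — A without any H;
#' * `isolated_hypometabolism` — H without any A;
#' * `congruent_or_nonisolated` — both A and H, whether in the same
#'   hemisphere (congruence) or opposite hemispheres (non-isolated
#'   co-occurrence).
#'
#' @param lobes An `np_lobes` tibble from [classify_lobes()].
#' @return A tibble of class `np_anatomical`: `subject_id`, `lobe` (bilateral:
#'   frontal/temporal/parietal/occipital) and `level` (factor with
#'   `no_abnormality` as the first, reference level).
#' @export
anatomical_levels <- function(lobes) {
  lv <- c("no_abnormality", "congruent_or_nonisolated",
          "isolated_hypometabolism", "isolated_atrophy")
  base <- dplyr::mutate(
    tibble::as_tibble(lobes),
    region = sub("^(left|right)_", "", as.character(.data$lobe))
  )
  out <- dplyr::summarise(
    dplyr::group_by(base, .data$subject_id, .data$region),
    a = any(.data$atrophy), h = any(.data$hypometabolism),
    .groups = "drop"
  )
  out <- dplyr::mutate(
    out,
    level = factor(
      dplyr::case_when(
        !a & !h ~ "no_abnormality",
        a & h ~ "congruent_or_nonisolated",
        !a & h ~ "isolated_hypometabolism",
        TRUE ~ "isolated_atrophy"
      ),
      levels = lv
    )
  )
  out <- dplyr::transmute(
    out,
    subject_id = .data$subject_id,
    lobe = factor(.data$region, levels = bilateral_lobes()),
    level = .data$level
  )
  out <- dplyr::arrange(out, match(.data$subject_id, unique(lobes$subject_id)),
                        .data$lobe)
  structure(out, class = c("np_anatomical", class(out)))
}

#' Count abnormal global neurodegeneration markers
#'
#' Counts, per subject, how many markers in a configured set are abnormal
#' under the direction-aware dichotomization rule. Marker set `"M1"` is
#' ventricular volume + total SUVR + CSF tau (count 0..3, restricted to
#' subjects with tau measured); `"M2"` drops tau (count 0..2, whole cohort).
#' Subjects missing any marker in the set are excluded (complete-case) and
#' flagged.
#'
#' @param zscores An `np_zscores` panel containing the marker z-columns.
#' @param marker_set `"M1"`, `"M2"`, or a character vector of marker roles.
#' @param z_threshold Non-negative magnitude `t`; `abnormal_low` markers use
#'   `-t`, `abnormal_high` markers use `+t` (default 0).
#' @return A tibble of class `np_markers`: `subject_id`, `n_abnormal`,
#'   `complete_case`; `n_abnormal` is `NA` for incomplete cases. Attribute
#'   `markers` records the set used.
#' @examples
#' cohort <- generate_cohort(synthetic_spec(n = 60, seed = 2))
#' z <- compute_zscores(cohort)
#' table(abnormal_marker_count(z, "M2")$n_abnormal)
#' @export
abnormal_marker_count <- function(zscores, marker_set = c("M2", "M1"),
                                  z_threshold = 0) {
  if (is.character(marker_set) && length(marker_set) == 1L &&
      marker_set %in% c("M1", "M2")) {
    markers <- switch(marker_set,
                      M1 = c("ventricular_volume", "total_suvr", "csf_tau"),
                      M2 = c("ventricular_volume", "total_suvr"))
  } else {
    markers <- marker_set
  }
  stopifnot(z_threshold >= 0)
  dirs <- biomarker_directions()
  unknown <- setdiff(markers, names(dirs))
  if (length(unknown)) {
    stop("Unknown marker role(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cols <- paste0("z_", markers)
  missing_cols <- setdiff(cols, names(zscores))
  if (length(missing_cols)) {
    stop("z-score panel lacks marker column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  flags <- purrr::map2(markers, cols, function(m, cl) {
    thr <- if (dirs[[m]] == "abnormal_low") -z_threshold else z_threshold
    dichotomize(zscores[[cl]], dirs[[m]], thr)
  })
  flag_mat <- do.call(cbind, flags)
  complete <- !apply(is.na(flag_mat), 1L, any)
  if (!any(complete)) {
    stop("No subject has complete data for markers: ",
         paste(markers, collapse = ", "), call. = FALSE)
  }
  out <- tibble::tibble(
    subject_id = zscores$subject_id,
    n_abnormal = ifelse(complete, rowSums(flag_mat), NA_integer_),
    complete_case = complete
  )
  structure(out, markers = markers,
            class = c("np_markers", class(out)))
}
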
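#' Canonical cohort column schema
#'
#' Maps variable *roles* (the names the pipeline uses internally) to the
#' column names found in a cohort file. The default is the identity mapping on
#' the canonical snake_case role names; pass `role = "my column"` pairs to
#' adapt to a foreign file layout.
#'
#' @param ... Named character overrides, e.g. `age = "age_years"`.
#' @return Named character vector mapping every role to a column name.
#' @examples
#' sch <- cohort_schema(subject_id = "id", age = "age_at_baseline")
#' sch[["age"]]
#' @export
cohort_schema <- function(...) {
  roles <- c(.required_roles(), .optional_roles())
  schema <- stats::setNames(roles, roles)
  overrides <- c(...)
  if (length(overrides)) {
    unknown <- setdiff(names(overrides), roles)
    if (length(unknown)) {
      stop("Unknown schema role(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    schema[names(overrides)] <- overrides
  }
  schema
}

#' Read and validate a cohort table
#'
#' Reads a delimited per-subject cohort file (CSV or TSV, header required,
#' UTF-8) and validates it against the cohort data model: one row per subject,
#' demographics, diagnosis group, MMSE scores, the raw 4-level clinical
#' outcome, eight unilateral lobe volumes and SUVRs, total ventricular volume,
#' total grey+white-matter SUVR, and optional CSF tau / disease duration /
#' education. Missing optional columns become absent fields (all-`NA`
#' columns), never silent zeros.
#'
#' @param path Path to a `.csv` or `.tsv`/`.txt` file.
#' @param schema Role-to-column mapping from [cohort_schema()].
#' @return A validated cohort tibble in canonical column order, with a
#'   `provenance` attribute recording the source path.
#' @seealso [write_cohort()], [validate_cohort()]
#' @export
read_cohort <- function(path, schema = cohort_schema()) {
  delim <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE, show_col_types = FALSE)

  missing_req <- setdiff(.required_roles(), names(schema))
  if (length(missing_req)) {
    stop("Schema does not map required role(s): ",
         paste(missing_req, collapse = ", "), call. = FALSE)
  }
  absent <- setdiff(unname(schema[.required_roles()]), names(raw))
  if (length(absent)) {
    roles <- names(schema)[match(absent, schema)]
    stop("Cohort file is missing required column(s): ",
         paste(sprintf("%s (role %s)", absent, roles), collapse = ", "),
         call. = FALSE)
  }

  out <- tibble::tibble(.rows = nrow(raw))
  for (role in names(schema)) {
    col <- schema[[role]]
    if (col %in% names(raw)) {
      out[[role]] <- raw[[col]]
    } else if (role %in% .optional_roles()) {
      out[[role]] <- NA_character_
    }
  }

  for (role in intersect(.numeric_roles(), names(out))) {
    vals <- out[[role]]
    parsed <- suppressWarnings(as.numeric(vals))
    bad <- which(!is.na(vals) & vals != "" & is.na(parsed))
    if (length(bad)) {
      stop(sprintf("Non-numeric value '%s' in column for role '%s' (row %d)",
                   vals[bad[1]], role, bad[1]), call. = FALSE)
    }
    parsed[!is.na(vals) & vals == ""] <- NA_real_
    out[[role]] <- parsed
  }
  out$sex <- factor(out$sex, levels = .sex_levels)
  out$diagnosis_group <- factor(out$diagnosis_group, levels = .diagnosis_levels)
  out$outcome_raw <- factor(out$outcome_raw, levels = .outcome_raw_levels)

  cohort <- validate_cohort(out)
  attr(cohort, "provenance") <- path
  cohort
}

#' Validate a cohort tibble against the data model
#'
#' Checks the structural invariants of the cohort data model and either
#' errors (hard violations) or warns (soft, study-inclusion-style checks):
#' * `subject_id` unique and non-missing (error);
#' * sex / diagnosis / raw outcome labels among the known levels (error);
#' * the 8 lobe columns of a modality all present or all missing per subject
#'   (error);
#' * volumes and SUVRs strictly positive (error);
#' * MMSE in 0..30 (error) and baseline MMSE >= 18 (warning: inclusion
#'   criterion, not a data error);
#' * rows missing follow-up MMSE flagged (warning) since the MMSE-decline
#'   outcome variant must exclude them.
#'
#' @param cohort A cohort data frame.
#' @return The cohort as a tibble, invisibly validated (returned visibly).
#' @export
validate_cohort <- function(cohort) {
  cohort <- tibble::as_tibble(cohort)
  need <- setdiff(.required_roles(), names(cohort))
  if (length(need)) {
    stop("Cohort lacks required column(s): ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(cohort$subject_id) || anyDuplicated(cohort$subject_id)) {
    stop("subject_id must be present and unique", call. = FALSE)
  }
  for (col in c("sex", "diagnosis_group", "outcome_raw")) {
    v <- cohort[[col]]
    lv <- switch(col, sex = .sex_levels, diagnosis_group = .diagnosis_levels,
                 outcome_raw = .outcome_raw_levels)
    if (!is.factor(v)) {
      bad <- setdiff(stats::na.omit(unique(as.character(v))), lv)
      if (length(bad)) {
        stop(sprintf("Unknown %s label(s): %s", col, paste(bad, collapse = ", ")),
             call. = FALSE)
      }
      cohort[[col]] <- factor(as.character(v), levels = lv)
    } else if (anyNA(v) && !anyNA(as.character(v))) {
      stop(sprintf("Unknown %s label(s)", col), call. = FALSE)
    }
  }

  for (roles in list(lobe_volume_roles(), lobe_suvr_roles())) {
    present <- !is.na(as.matrix(cohort[roles]))
    partial <- rowSums(present) %in% seq_len(7L)
    if (any(partial)) {
      stop("Lobe columns must be all present or all missing per modality; ",
           "subject(s): ", paste(cohort$subject_id[partial], collapse = ", "),
           call. = FALSE)
    }
  }
  pos_roles <- c(lobe_volume_roles(), lobe_suvr_roles(),
                 "ventricular_volume", "total_suvr")
  for (role in pos_roles) {
    v <- cohort[[role]]
    if (any(!is.na(v) & v <= 0)) {
      stop("Non-positive value in '", role, "'; volumes and SUVRs must be > 0",
           call. = FALSE)
    }
  }
  for (role in c("mmse_baseline", "mmse_followup")) {
    if (!role %in% names(cohort)) next
    v <- cohort[[role]]
    if (any(!is.na(v) & (v < 0 | v > 30))) {
      stop(role, " outside 0..30", call. = FALSE)
    }
  }
  low <- !is.na(cohort$mmse_baseline) & cohort$mmse_baseline < 18
  if (any(low)) {
    warning(sum(low), " subject(s) with baseline MMSE < 18 (below the usual ",
            "inclusion criterion); retained", call. = FALSE)
  }
  if ("mmse_followup" %in% names(cohort) && anyNA(cohort$mmse_followup)) {
    warning(sum(is.na(cohort$mmse_followup)),
            " subject(s) without follow-up MMSE; the MMSE-decline outcome ",
            "variant will exclude them", call. = FALSE)
  }
  cohort
}

#' Write a cohort table to delimited text
#'
#' Inverse of [read_cohort()]: writes the canonical columns as CSV or TSV
#' (chosen from the file extension). Missing optional values are written as
#' empty cells so that a round trip is field-identical.
#'
#' @param cohort A cohort tibble.
#' @param path Output path (`.csv` or `.tsv`).
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  out <- dplyr::mutate(cohort, dplyr::across(dplyr::where(is.factor), as.character))
  if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) {
    readr::write_tsv(out, path, na = "")
  } else {
    readr::write_csv(out, path, na = "")
  }
  invisible(path)
}

#' Collapse the 4-level clinical disease course into a binary outcome
#'
#' The clinician rates the 12-month disease course as progression,
#' fluctuation, stable or improvement. Fluctuation and improvement are too
#' rare to analyse separately and are collapsed, together with stable, into a
#' single `stable` category; `progression` maps to `progressed`.
#'
#' @param cohort A cohort data frame with an `outcome_raw` column.
#' @return The cohort with an added `outcome` factor
#'   (levels `stable`, `progressed`; `stable` first so that `progressed` is
#'   the modelled event).
#' @examples
#' df <- tibble::tibble(outcome_raw = c("progression", "fluctuation",
#'                                      "improvement", "stable"))
#' collapse_outcome(df)$outcome
#' @export
collapse_outcome <- function(cohort) {
  raw <- as.character(cohort$outcome_raw)
  bad <- setdiff(stats::na.omit(unique(raw)), .outcome_raw_levels)
  if (length(bad)) {
    stop("Unknown outcome label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  cohort$outcome <- factor(
    dplyr::if_else(raw == "progression", "progressed", "stable"),
    levels = .outcome_levels
  )
  cohort
}

#' Write a model results table to delimited text
#'
#' Serializes a results table (one row per model term/level with group
#' counts, univariable and multivariable odds ratios, confidence intervals
#' and p-values — the layout of the printed tables) to CSV or TSV.
#'
#' @param results A non-empty data frame, e.g. from [model_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(results, path) {
  if (is.null(results) || !nrow(as.data.frame(results))) {
    stop("Results table is empty; nothing to write", call. = FALSE)
  }
  out <- dplyr::mutate(tibble::as_tibble(results),
                       dplyr::across(dplyr::where(is.factor), as.character),
                       dplyr::across(dplyr::where(is.list), ~ vapply(.x, paste, "", collapse = ";")))
  if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) {
    readr::write_tsv(out, path, na = "")
  } else {
    readr::write_csv(out, path, na = "")
  }
  invisible(path)
}

#' Read an analysis configuration file
#'
#' Loads a YAML (or JSON, which YAML subsumes) configuration holding a schema
#' mapping, dichotomization thresholds, lobe-count cut-off and seed, with
#' defaults filled in for anything omitted.
#'
#' @param path Path to a YAML/JSON config file.
#' @return A list with elements `schema` (see [cohort_schema()]),
#'   `z_threshold`, `lobe_cutoff`, `seed`.
#' @export
read_analysis_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  schema <- do.call(cohort_schema, as.list(cfg$schema %||% list()))
  list(
    schema = schema,
    z_threshold = cfg$z_threshold %||% 0,
    lobe_cutoff = cfg$lobe_cutoff %||% 2L,
    seed = cfg$seed %||% 1L
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x
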
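#' Intracohort z-scores of imaging and fluid biomarkers
#'
#' Standardizes each requested variable by the cohort's own mean and sample
#' standard deviation (denominator n-1), computed over the subjects
#' non-missing for that variable. No normative population is involved: a
#' z-score of 0 is the cohort average, and for CSF tau (measured in a subset)
#' the mean/SD come from the tau-complete subset — the only subjects that can
#' enter tau-based models.
#'
#' @param cohort A cohort data frame.
#' @param variables Character vector of variable roles to standardize;
#'   defaults to every biomarker with a direction convention (lobe volumes and
#'   SUVRs, ventricular volume, total SUVR, and CSF tau when present).
#' @return A tibble of class `np_zscores`: `subject_id` plus one `z_<role>`
#'   column per variable. Attributes: `direction` (named vector of
#'   `abnormal_low`/`abnormal_high` tags), `center` and `scale` (the mean/SD
#'   used), `n_used` (non-missing count per variable).
#' @examples
#' cohort <- generate_cohort(synthetic_spec(n = 20, seed = 1))
#' z <- compute_zscores(cohort)
#' round(mean(z$z_total_suvr), 12)  # intracohort mean is 0 by construction
#' @export
compute_zscores <- function(cohort, variables = NULL) {
  cohort <- tibble::as_tibble(cohort)
  dirs <- biomarker_directions()
  if (is.null(variables)) {
    variables <- intersect(names(dirs), names(cohort))
    variables <- variables[vapply(cohort[variables],
                                  function(v) any(!is.na(v)), logical(1))]
  }
  unknown <- setdiff(variables, names(dirs))
  if (length(unknown)) {
    stop("No direction convention for variable(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  missing_cols <- setdiff(variables, names(cohort))
  if (length(missing_cols)) {
    stop("Cohort lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }

  out <- tibble::tibble(subject_id = cohort$subject_id)
  center <- scale <- n_used <- stats::setNames(numeric(length(variables)), variables)
  for (v in variables) {
    x <- cohort[[v]]
    ok <- !is.na(x)
    if (sum(ok) < 2L) {
      stop("Variable '", v, "' has fewer than 2 non-missing values; ",
           "cannot standardize", call. = FALSE)
    }
    m <- mean(x[ok])
    s <- stats::sd(x[ok])
    if (!is.finite(s) || s == 0) {
      stop("Variable '", v, "' is degenerate (zero standard deviation)",
           call. = FALSE)
    }
    out[[paste0("z_", v)]] <- (x - m) / s
    center[v] <- m; scale[v] <- s; n_used[v] <- sum(ok)
  }
  structure(out,
            direction = dirs[variables],
            center = center, scale = scale, n_used = n_used,
            class = c("np_zscores", class(out)))
}

#' Dichotomize a z-score into an abnormality flag
#'
#' Applies the direction-aware abnormality rule: variables where disease
#' lowers the value (volumes, SUVRs) are abnormal when `z < threshold`;
#' variables where disease raises it (ventricular volume, CSF tau) are
#' abnormal when `z > threshold`. A z-score exactly at the threshold is *not*
#' abnormal (strict inequalities). The threshold must lie on the abnormal
#' side of zero or at zero: non-positive for `abnormal_low`, non-negative for
#' `abnormal_high`, so the sensitivity grid's +/-t pairing maps cleanly.
#'
#' @param z Numeric vector of z-scores.
#' @param direction `"abnormal_low"` or `"abnormal_high"`.
#' @param threshold Scalar threshold (default 0).
#' @return Logical vector: `TRUE` = abnormal. `NA` stays `NA`.
#' @examples
#' dichotomize(c(-0.2, 0, 0.2), "abnormal_low")       # TRUE FALSE FALSE
#' dichotomize(c(-0.2, 0.2), "abnormal_low", -0.5)    # FALSE FALSE
#' @export
dichotomize <- function(z, direction = c("abnormal_low", "abnormal_high"),
                        threshold = 0) {
  direction <- match.arg(direction)
  stopifnot(length(threshold) == 1L, is.finite(threshold))
  if (direction == "abnormal_low" && threshold > 0) {
    stop("threshold must be <= 0 for direction 'abnormal_low'", call. = FALSE)
  }
  if (direction == "abnormal_high" && threshold < 0) {
    stop("threshold must be >= 0 for direction 'abnormal_high'", call. = FALSE)
  }
  if (direction == "abnormal_low") z < threshold else z > threshold
}
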
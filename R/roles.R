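#' Lobe and variable-role conventions
#'
#' The pipeline works with eight unilateral brain lobes
#' (`{left,right} x {frontal,temporal,parietal,occipital}`), each carrying an
#' MRI volume (mm^3) and an \[18F\]FDG-PET SUVR, plus three global markers:
#' total ventricular volume (mm^3), total grey+white-matter SUVR and optional
#' CSF total tau (ng/L).
#'
#' `lobe_names()` returns the eight unilateral lobe labels;
#' `lobe_volume_roles()` / `lobe_suvr_roles()` the corresponding canonical
#' column names (`volume_left_frontal`, `suvr_right_occipital`, ...);
#' `biomarker_directions()` the direction convention attached to every
#' standardizable variable: `"abnormal_low"` for volumes and SUVRs (atrophy /
#' hypometabolism mean *low* values), `"abnormal_high"` for ventricular volume
#' and CSF tau (enlargement / elevation mean *high* values).
#'
#' @return Character vectors of role names, or for
#'   `biomarker_directions()` a named character vector mapping role to
#'   direction tag.
#' @examples
#' lobe_names()
#' biomarker_directions()[c("total_suvr", "csf_tau")]
#' @name roles
NULL

.sides <- c("left", "right")
.lobes <- c("frontal", "temporal", "parietal", "occipital")

#' @rdname roles
#' @export
lobe_names <- function() {
  as.vector(outer(.sides, .lobes, paste, sep = "_"))
}

#' @rdname roles
#' @export
lobe_volume_roles <- function() paste0("volume_", lobe_names())

#' @rdname roles
#' @export
lobe_suvr_roles <- function() paste0("suvr_", lobe_names())

#' @rdname roles
#' @export
bilateral_lobes <- function() .lobes

#' @rdname roles
#' @export
biomarker_directions <- function() {
  c(
    stats::setNames(rep("abnormal_low", 8L), lobe_volume_roles()),
    stats::setNames(rep("abnormal_low", 8L), lobe_suvr_roles()),
    total_suvr = "abnormal_low",
    ventricular_volume = "abnormal_high",
    csf_tau = "abnormal_high"
  )
}

# internal: columns the validator treats as required vs optional
.required_roles <- function() {
  c(
    "subject_id", "age", "sex", "diagnosis_group", "mmse_baseline",
    "outcome_raw", lobe_volume_roles(), lobe_suvr_roles(),
    "ventricular_volume", "total_suvr"
  )
}

.optional_roles <- function() {
  c(
    "etiology", "mmse_followup", "follow_up_days", "csf_tau",
    "disease_duration", "education"
  )
}

.numeric_roles <- function() {
  c(
    "age", "mmse_baseline", "mmse_followup", "follow_up_days",
    lobe_volume_roles(), lobe_suvr_roles(), "ventricular_volume",
    "total_suvr", "csf_tau", "disease_duration", "education"
  )
}

.sex_levels <- c("female", "male")
.diagnosis_levels <- c("SCD", "MCI", "dementia")
.outcome_raw_levels <- c("progression", "stable", "fluctuation", "improvement")
.outcome_levels <- c("stable", "progressed")
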
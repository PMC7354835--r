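# small deterministic cohort builders used across tests (no RNG)

# minimal valid cohort of n subjects with mild deterministic variation
tiny_cohort <- function(n = 3) {
  lobes <- lobe_names()
  co <- tibble::tibble(
    subject_id = sprintf("T%02d", seq_len(n)),
    age = 60 + seq_len(n),
    sex = factor(rep_len(c("female", "male"), n),
                 levels = c("female", "male")),
    diagnosis_group = factor(rep_len(c("SCD", "MCI", "dementia"), n),
                             levels = c("SCD", "MCI", "dementia")),
    etiology = NA_character_,
    mmse_baseline = rep(28, n),
    mmse_followup = rep(27, n),
    outcome_raw = factor(rep_len(c("progression", "stable"), n),
                         levels = c("progression", "stable", "fluctuation",
                                    "improvement")),
    follow_up_days = rep(400, n)
  )
  for (i in seq_along(lobes)) {
    co[[paste0("volume_", lobes[i])]] <- 100000 + 1000 * i + 10 * seq_len(n)
    co[[paste0("suvr_", lobes[i])]] <- 1 + 0.01 * i + 0.001 * seq_len(n)
  }
  co$ventricular_volume <- 50000 + 100 * seq_len(n)
  co$total_suvr <- 1 + 0.01 * seq_len(n)
  co$csf_tau <- 300 + seq_len(n)
  co$disease_duration <- rep(2, n)
  co$education <- rep(12, n)
  co
}

# z-score panel with explicit per-lobe values; defaults: everything normal (+1)
lobe_panel <- function(n = 1, vol = 1, suvr = 1) {
  z <- tibble::tibble(subject_id = sprintf("P%02d", seq_len(n)))
  for (l in lobe_names()) {
    z[[paste0("z_volume_", l)]] <- rep_len(vol, n)
    z[[paste0("z_suvr_", l)]] <- rep_len(suvr, n)
  }
  z
}

# set one lobe's z-scores on one subject
set_lobe <- function(panel, subject, lobe, vol = NULL, suvr = NULL) {
  i <- match(subject, panel$subject_id)
  if (!is.null(vol)) panel[[paste0("z_volume_", lobe)]][i] <- vol
  if (!is.null(suvr)) panel[[paste0("z_suvr_", lobe)]][i] <- suvr
  panel
}
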
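#' Printed-table contingency fixtures
#'
#' `contingency_fixtures()` lists the built-in 2x2 exposure-by-outcome count
#' tables read off the published results tables (cells in the order
#' `a` stable/unexposed, `b` progressed/unexposed, `c` stable/exposed,
#' `d` progressed/exposed), together with the feature kind each encodes.
#' `make_contingency_fixture()` turns such counts into a full subject-level
#' cohort whose derived binary feature and collapsed outcome cross-tabulate
#' exactly to the requested cells.
#'
#' For the imaging-pattern fixtures (`pattern_ah`, `pattern_a_only`,
#' `pattern_h_only`) the raw lobe volumes and SUVRs are constructed so that
#' running the real pipeline — intracohort z-scoring, lobe classification,
#' pattern counting and count dichotomization at the requested cut-off —
#' reproduces the intended exposure flags; this is verified internally after
#' construction. Exposed subjects carry the pattern in four lobes; flag
#' layouts alternate across subjects so every one of the 16 lobe columns
#' contains values on both sides of its cohort mean. `generic` fixtures
#' carry the exposure as a ready-made logical `exposed` column.
#'
#' @param x A fixture name from `names(contingency_fixtures())`, or a numeric
#'   vector `c(a, b, c, d)`.
#' @param feature Feature kind when `x` is raw counts (ignored for named
#'   fixtures): `"generic"`, `"pattern_ah"`, `"pattern_a_only"`,
#'   `"pattern_h_only"`.
#' @param lobe_cutoff Lobe-count cut-off the pattern feature must reproduce
#'   (default 2).
#' @return A validated cohort tibble with an `exposed` logical column and an
#'   `outcome` factor already collapsed. Attribute `requested` holds the
#'   target `np_xtab`.
#' @examples
#' fx <- make_contingency_fixture("table3_pattern_ah")
#' tidy(crosstab(fx, exposed))
#' @export
make_contingency_fixture <- function(x, feature = "generic", lobe_cutoff = 2L) {
  if (is.character(x) && length(x) == 1L) {
    reg <- contingency_fixtures()
    if (!x %in% names(reg)) {
      stop("Unknown fixture '", x, "'; see names(contingency_fixtures())",
           call. = FALSE)
    }
    counts <- reg[[x]]$counts
    feature <- reg[[x]]$feature
  } else {
    stopifnot(is.numeric(x), length(x) == 4L)
    counts <- x
  }
  if (any(counts < 0) || sum(counts) <= 0) {
    stop("Infeasible fixture request: counts must be non-negative with a ",
         "positive total", call. = FALSE)
  }
  a <- counts[1]; b <- counts[2]; c <- counts[3]; d <- counts[4]
  n <- sum(counts)
  exposed <- rep(c(FALSE, TRUE), times = c(a + b, c + d))
  progressed <- c(rep(c(FALSE, TRUE), times = c(a, b)),
                  rep(c(FALSE, TRUE), times = c(c, d)))

  # deterministic age spread decorrelated from the outcome/exposure blocks
  # (a fixed coprime stride) so age/sex-adjusted fits are well defined
  mult <- 7L
  while (n %% mult == 0L || mult %% 2L == 0L) mult <- mult + 1L
  age_perm <- (seq_len(n) * mult) %% n
  cohort <- tibble::tibble(
    subject_id = sprintf("F%04d", seq_len(n)),
    age = 55 + 30 * age_perm / max(age_perm, 1),
    sex = factor(rep_len(.sex_levels, n), levels = .sex_levels),
    diagnosis_group = factor(rep_len(c("MCI", "dementia"), n),
                             levels = .diagnosis_levels),
    etiology = NA_character_,
    mmse_baseline = rep(28, n),
    mmse_followup = 28 - ifelse(progressed, 4, 1),
    outcome_raw = factor(ifelse(progressed, "progression", "stable"),
                         levels = .outcome_raw_levels),
    follow_up_days = rep(420, n),
    exposed = exposed
  )

  if (feature == "generic") {
    flags <- NULL
  } else if (feature %in% c("pattern_ah", "pattern_a_only", "pattern_h_only")) {
    if (sum(exposed) < 1L || sum(!exposed) < 1L) {
      stop("Infeasible pattern fixture: both exposure groups must be ",
           "non-empty", call. = FALSE)
    }
    flags <- .pattern_fixture_flags(feature, exposed)
  } else {
    stop("Unknown feature kind '", feature, "'", call. = FALSE)
  }

  if (is.null(flags)) {
    # deterministic variation; generic fixtures do not drive the z pipeline
    for (l in lobe_names()) {
      cohort[[paste0("volume_", l)]] <- 100000 + 50 * seq_len(n)
      cohort[[paste0("suvr_", l)]] <- 1.0 + 0.002 * seq_len(n)
    }
  } else {
    region <- sub("^(left|right)_", "", lobe_names())
    for (j in seq_along(lobe_names())) {
      l <- lobe_names()[j]
      vm <- .vol_scale$mean[[region[j]]]
      cohort[[paste0("volume_", l)]] <- ifelse(flags$atrophy[, j],
                                               0.85 * vm, 1.15 * vm)
      cohort[[paste0("suvr_", l)]] <- ifelse(flags$hypometab[, j], 0.90, 1.30)
    }
  }
  cohort$ventricular_volume <- 50000 + 200 * seq_len(n)
  cohort$total_suvr <- 1.0 + 0.002 * seq_len(n)
  cohort$csf_tau <- 300 + 2 * seq_len(n)
  cohort$disease_duration <- rep(2.5, n)
  cohort$education <- rep(12, n)

  cohort <- validate_cohort(cohort)
  cohort <- collapse_outcome(cohort)

  if (!is.null(flags)) {
    derived <- .derive_pattern_exposure(cohort, feature, lobe_cutoff)
    if (!identical(unname(derived), unname(exposed))) {
      stop("Internal fixture construction failure: derived pattern exposure ",
           "does not reproduce the requested flags", call. = FALSE)
    }
  }
  xt <- crosstab(cohort, exposed)
  if (!all(c(xt$a, xt$b, xt$c, xt$d) == c(a, b, c, d))) {
    stop("Internal fixture construction failure: cross-tabulation mismatch",
         call. = FALSE)
  }
  attr(cohort, "provenance") <- sprintf("fixture(%s)", feature)
  attr(cohort, "requested") <- contingency(a, b, c, d)
  cohort
}

# per-subject, per-lobe target abnormality flags; layouts alternate across
# subjects so that every lobe column contains both flag values cohort-wide
.pattern_fixture_flags <- function(feature, exposed) {
  n <- length(exposed)
  atrophy <- matrix(FALSE, n, 8L)
  hypometab <- matrix(FALSE, n, 8L)
  signal <- 1:4          # lobes carrying the pattern for exposed subjects
  filler <- 5:8
  pat <- switch(feature,
                pattern_ah = c(TRUE, TRUE),
                pattern_a_only = c(TRUE, FALSE),
                pattern_h_only = c(FALSE, TRUE))
  idx_in_group <- ave(seq_len(n), exposed, FUN = seq_along)
  for (i in seq_len(n)) {
    odd <- idx_in_group[i] %% 2L == 1L
    if (exposed[i]) {
      atrophy[i, signal] <- pat[1]
      hypometab[i, signal] <- pat[2]
      if (!odd) {
        # congruent filler lobes never add to an isolated-pattern count and
        # keep every +A/+H count well above any cut-off in 1..3
        atrophy[i, filler] <- TRUE
        hypometab[i, filler] <- TRUE
      }
    } else if (feature == "pattern_ah") {
      # cycle unexposed subjects through three layouts, all with zero +A/+H
      # lobes; isolated atrophy and hypometabolism land on different
      # subjects so the three pattern predictors are never collinear
      switch(as.character(idx_in_group[i] %% 3L),
             "1" = {
               atrophy[i, c(1, 3, 5, 7)] <- TRUE   # isolated atrophy only
             },
             "2" = {
               hypometab[i, c(2, 4, 6, 8)] <- TRUE # isolated hypometab only
             },
             "0" = {})                             # all lobes normal
    } else if (odd) {
      # congruent flags in every lobe: 0 isolated-pattern lobes, and both
      # modalities vary in every column cohort-wide
      atrophy[i, ] <- TRUE
      hypometab[i, ] <- TRUE
    }
  }
  list(atrophy = atrophy, hypometab = hypometab)
}

.derive_pattern_exposure <- function(cohort, feature, lobe_cutoff) {
  z <- compute_zscores(cohort, c(lobe_volume_roles(), lobe_suvr_roles()))
  counts <- pattern_counts(classify_lobes(z))
  col <- switch(feature, pattern_ah = "n_ah", pattern_a_only = "n_a_only",
                pattern_h_only = "n_h_only")
  dichotomize_count(counts[[col]], cutoff = lobe_cutoff)
}

#' @rdname make_contingency_fixture
#' @export
contingency_fixtures <- function() {
  fx <- function(a, b, c, d, feature = "generic")
    list(counts = c(a, b, c, d), feature = feature)
  list(
    # abnormal-marker count levels vs level 0 (tau model / no-tau model)
    table2_m1_markers_1 = fx(16, 4, 14, 9),
    table2_m1_markers_2 = fx(16, 4, 16, 11),
    table2_m1_markers_3 = fx(16, 4, 3, 3),
    table2_m2_markers_1 = fx(42, 8, 35, 23),
    table2_m2_markers_2 = fx(42, 8, 22, 19),
    # pattern-count rows (>= 2 affected lobes vs 0-1) and the sex row
    table3_sex = fx(50, 27, 49, 23),
    table3_pattern_a = fx(58, 32, 41, 18, "pattern_a_only"),
    table3_pattern_h = fx(67, 32, 32, 18, "pattern_h_only"),
    table3_pattern_ah = fx(69, 17, 30, 33, "pattern_ah"),
    # anatomical congruence levels vs no abnormality, per bilateral lobe
    table4_frontal_congruent = fx(25, 4, 20, 25),
    table4_frontal_hypo = fx(25, 4, 23, 14),
    table4_frontal_atrophy = fx(25, 4, 31, 7),
    table4_temporal_congruent = fx(28, 6, 28, 30),
    table4_temporal_hypo = fx(28, 6, 21, 8),
    table4_temporal_atrophy = fx(28, 6, 22, 6),
    table4_parietal_congruent = fx(26, 7, 28, 27),
    table4_parietal_hypo = fx(26, 7, 20, 10),
    table4_parietal_atrophy = fx(26, 7, 25, 6),
    table4_occipital_congruent = fx(17, 9, 33, 21),
    table4_occipital_hypo = fx(17, 9, 20, 10),
    table4_occipital_atrophy = fx(17, 9, 29, 10)
  )
}
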
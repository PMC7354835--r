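test_that("grid bookkeeping enumerates exactly the requested cells", {
  g <- sensitivity_grid(z_thresholds = c(0, 0.1, 0.5), lobe_cutoffs = 2,
                        outcomes = "clinician", subgroups = "all")
  expect_equal(nrow(g), 3)
  g2 <- sensitivity_grid()
  expect_equal(nrow(g2), 3 * 3 * 2 * 1 * 2)
})

test_that("the base cell reproduces the primary analysis exactly", {
  fx <- make_contingency_fixture("table3_pattern_ah")
  g <- sensitivity_grid(z_thresholds = 0, lobe_cutoffs = 2,
                        outcomes = "clinician", subgroups = "all")
  res <- run_sensitivity(fx, g)
  expect_true(is.na(res$failure[1]))
  expect_equal(round(res$or_ah_uni[1], 2), 4.46)

  # bit-identical to running the pipeline by hand
  z <- compute_zscores(fx, c(lobe_volume_roles(), lobe_suvr_roles()))
  counts <- pattern_counts(classify_lobes(z))
  data <- dplyr::mutate(fx,
                        a_only = dichotomize_count(counts$n_a_only),
                        h_only = dichotomize_count(counts$n_h_only),
                        ah = dichotomize_count(counts$n_ah))
  direct <- model_table(data, terms = c("a_only", "h_only", "ah"))
  strip <- function(t) {
    t <- tibble::as_tibble(t)
    attributes(t)[setdiff(names(attributes(t)),
                          c("names", "row.names", "class"))] <- NULL
    t
  }
  expect_identical(strip(res$result[[1]]), strip(direct))
})

test_that("cells carry provenance and direction robustness flags", {
  co <- generate_cohort(synthetic_spec(n = 300, seed = 31,
                                       pattern_effect_log_or = log(6)))
  g <- sensitivity_grid(z_thresholds = c(0, 0.1, 0.5),
                        lobe_cutoffs = c(2, 1, 3),
                        outcomes = "clinician", subgroups = "all")
  res <- run_sensitivity(co, g)
  expect_equal(nrow(res), 9)
  ok <- is.na(res$failure)
  expect_true(all(res$n[ok] == 300))
  # strong generating effect: direction preserved wherever the cell fit
  expect_true(all(res$or_ah_uni[ok] > 1))
  expect_true(all(res$direction_match[ok]))
})

test_that("MMSE-decline outcome uses the 3-point boundary and logs exclusions", {
  df <- tibble::tibble(subject_id = c("a", "b", "c"),
                       mmse_baseline = c(28, 28, 28),
                       mmse_followup = c(25, 26, NA))
  out <- mmse_decline_outcome(df)
  expect_equal(as.character(out$outcome), c("progressed", "stable"))
  expect_equal(attr(out, "excluded"), "c")
})

test_that("a degenerate outcome becomes a structured cell failure", {
  fx <- make_contingency_fixture("table3_pattern_ah")
  fx$mmse_followup <- fx$mmse_baseline   # nobody declines
  g <- sensitivity_grid(z_thresholds = 0, lobe_cutoffs = 2,
                        outcomes = "mmse_decline", subgroups = "all")
  expect_no_error(res <- run_sensitivity(fx, g))
  expect_match(res$failure[1], "single class")
  expect_true(is.na(res$or_ah_uni[1]))
})

test_that("subgroup filtering removes SCD and keeps set arithmetic intact", {
  co <- collapse_outcome(generate_cohort(synthetic_spec(n = 149, seed = 32)))
  expect_equal(as.vector(table(co$diagnosis_group)), c(35, 33, 81))
  sub <- subgroup_filter(co)
  expect_equal(nrow(sub), 114)
  expect_false(any(sub$diagnosis_group == "SCD"))
  expect_identical(as.data.frame(subgroup_filter(co, c("SCD", "MCI", "dementia"))),
                   as.data.frame(co))

  truth <- attr(co, "truth")
  co$exposed_true <- truth$exposed_true
  sub <- subgroup_filter(co)
  full <- crosstab(co, exposed_true)
  scd <- crosstab(co[co$diagnosis_group == "SCD", ], exposed_true)
  subx <- crosstab(sub, exposed_true)
  expect_equal(c(subx$a, subx$b, subx$c, subx$d),
               c(full$a - scd$a, full$b - scd$b,
                 full$c - scd$c, full$d - scd$d))
  expect_error(subgroup_filter(co[co$diagnosis_group == "SCD", ],
                               c("MCI", "dementia")), "No subjects")
})

test_that("subgroup cells reuse full-cohort z-scores unless asked otherwise", {
  co <- generate_cohort(synthetic_spec(n = 200, seed = 33))
  g <- sensitivity_grid(z_thresholds = 0, lobe_cutoffs = 2,
                        outcomes = "clinician", subgroups = "mci_dementia")
  inherited <- run_sensitivity(co, g)
  restd <- run_sensitivity(co, g, restandardize = TRUE)
  expect_true(is.na(inherited$failure[1]) && is.na(restd$failure[1]))
  # restandardizing within the subgroup shifts the thresholded counts
  expect_false(isTRUE(all.equal(inherited$or_ah_uni, restd$or_ah_uni)))
})
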
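test_that("intracohort z-scores use the sample mean and SD", {
  df <- tibble::tibble(subject_id = c("a", "b", "c"),
                       total_suvr = c(1, 2, 3))
  z <- compute_zscores(df, "total_suvr")
  expect_equal(z$z_total_suvr, c(-1, 0, 1))   # sample SD of 1,2,3 is 1

  x <- c(2, 4, 4, 4, 5, 5, 7, 9)              # mean 5, sample SD sqrt(32/7)
  df <- tibble::tibble(subject_id = letters[1:8], total_suvr = x)
  z <- compute_zscores(df, "total_suvr")
  expect_equal(z$z_total_suvr[8], 4 / sqrt(32 / 7), tolerance = 1e-9)
  expect_equal(z$z_total_suvr[which(x == 5)], c(0, 0))

  # per-variable missingness: tau standardized over its measured subset only
  df$csf_tau <- c(NA, NA, NA, NA, 100, 200, 300, NA)
  z <- compute_zscores(df, c("total_suvr", "csf_tau"))
  expect_equal(z$z_csf_tau[5:7], c(-1, 0, 1))
  expect_true(all(is.na(z$z_csf_tau[c(1:4, 8)])))
  expect_equal(unname(attr(z, "n_used")["csf_tau"]), 3)
})

test_that("degenerate variables are rejected with their name", {
  df <- tibble::tibble(subject_id = c("a", "b"), total_suvr = c(1, 1))
  expect_error(compute_zscores(df, "total_suvr"), "total_suvr.*zero")
  df1 <- tibble::tibble(subject_id = "a", total_suvr = 1)
  expect_error(compute_zscores(df1, "total_suvr"), "fewer than 2")
})

test_that("re-standardizing a z-scored column is the identity", {
  co <- generate_cohort(synthetic_spec(n = 40, seed = 6))
  z <- compute_zscores(co, "total_suvr")
  df <- tibble::tibble(subject_id = z$subject_id, total_suvr = 2 + z$z_total_suvr)
  z2 <- compute_zscores(df, "total_suvr")
  expect_equal(z2$z_total_suvr, z$z_total_suvr, tolerance = 1e-9)
})

test_that("dichotomization uses strict, direction-aware inequalities", {
  expect_true(dichotomize(-0.2, "abnormal_low", 0))
  expect_false(dichotomize(0, "abnormal_low", 0))       # boundary: not abnormal
  expect_false(dichotomize(0, "abnormal_high", 0))
  expect_false(dichotomize(-0.2, "abnormal_low", -0.5)) # sensitivity threshold
  expect_true(dichotomize(-0.6, "abnormal_low", -0.5))
  expect_true(dichotomize(0.3, "abnormal_high", 0.1))
  expect_error(dichotomize(0, "abnormal_low", 0.5), "<= 0")
  expect_error(dichotomize(0, "abnormal_high", -0.5), ">= 0")
})

test_that("lobe classification counts the four joint patterns", {
  # every z negative: all 8 lobes +A/+H
  counts <- pattern_counts(classify_lobes(lobe_panel(1, vol = -1, suvr = -1)))
  expect_equal(unlist(counts[1, c("n_a_only", "n_h_only", "n_ah")],
                      use.names = FALSE), c(0, 0, 8))
  # every z positive: nothing
  counts <- pattern_counts(classify_lobes(lobe_panel(1, vol = 1, suvr = 1)))
  expect_equal(unlist(counts[1, c("n_a_only", "n_h_only", "n_ah")],
                      use.names = FALSE), c(0, 0, 0))
  # one isolated-atrophy and one isolated-hypometabolism lobe
  p <- lobe_panel(1)
  p <- set_lobe(p, "P01", "left_frontal", vol = -1, suvr = 1)
  p <- set_lobe(p, "P01", "right_temporal", vol = 1, suvr = -1)
  counts <- pattern_counts(classify_lobes(p))
  expect_equal(unlist(counts[1, c("n_a_only", "n_h_only", "n_ah")],
                      use.names = FALSE), c(1, 1, 0))
  expect_error(classify_lobes(p[-2]), "lobe column")
})

test_that("pattern counts always partition the 8 lobes", {
  set.seed(101)
  for (i in 1:25) {
    p <- lobe_panel(8)
    for (col in setdiff(names(p), "subject_id")) p[[col]] <- rnorm(8)
    counts <- pattern_counts(classify_lobes(p))
    expect_true(all(counts$n_a_only + counts$n_h_only + counts$n_ah +
                      counts$n_neither == 8))
  }
})

test_that("lowering the threshold never increases abnormality counts", {
  set.seed(102)
  p <- lobe_panel(200)
  for (col in setdiff(names(p), "subject_id")) p[[col]] <- rnorm(200)
  prev <- NULL
  for (thr in c(0, -0.1, -0.5)) {
    counts <- pattern_counts(classify_lobes(p, z_threshold = thr))
    total_abn <- counts$n_a_only + counts$n_h_only + 2 * counts$n_ah
    if (!is.null(prev)) expect_true(all(total_abn <= prev))
    prev <- total_abn
  }
})

test_that("count dichotomization matches the table level definitions", {
  expect_true(dichotomize_count(2, 2))
  expect_false(dichotomize_count(1, 2))
  expect_true(dichotomize_count(1, 1))
  expect_false(dichotomize_count(2, 3))
  expect_error(dichotomize_count(9, 2), "0..8")
  expect_error(dichotomize_count(2, 4))
})

test_that("anatomical levels match a brute-force truth table", {
  # all 16 combinations of (left A, left H, right A, right H) for one lobe
  combos <- expand.grid(la = c(FALSE, TRUE), lh = c(FALSE, TRUE),
                        ra = c(FALSE, TRUE), rh = c(FALSE, TRUE))
  p <- lobe_panel(nrow(combos))
  for (i in seq_len(nrow(combos))) {
    p <- set_lobe(p, p$subject_id[i], "left_frontal",
                  vol = ifelse(combos$la[i], -1, 1),
                  suvr = ifelse(combos$lh[i], -1, 1))
    p <- set_lobe(p, p$subject_id[i], "right_frontal",
                  vol = ifelse(combos$ra[i], -1, 1),
                  suvr = ifelse(combos$rh[i], -1, 1))
  }
  lev <- anatomical_levels(classify_lobes(p))
  frontal <- lev[lev$lobe == "frontal", ]
  frontal <- frontal[match(p$subject_id, frontal$subject_id), ]
  # independent truth table: any-hemisphere A/H flags
  A <- combos$la | combos$ra
  H <- combos$lh | combos$rh
  want <- ifelse(!A & !H, "no_abnormality",
          ifelse(A & H, "congruent_or_nonisolated",
          ifelse(A, "isolated_atrophy", "isolated_hypometabolism")))
  expect_equal(as.character(frontal$level), want)
  # untouched lobes are all normal
  expect_true(all(lev$level[lev$lobe != "frontal"] == "no_abnormality"))
})

test_that("abnormal marker counts respect direction and complete cases", {
  z <- tibble::tibble(
    subject_id = c("a", "b", "c"),
    z_ventricular_volume = c(0.5, 0, -1),
    z_total_suvr = c(-0.5, 0, 1),
    z_csf_tau = c(0.5, 0, NA)
  )
  m1 <- abnormal_marker_count(z, "M1")
  expect_equal(m1$n_abnormal, c(3, 0, NA))
  expect_equal(m1$complete_case, c(TRUE, TRUE, FALSE))
  m2 <- abnormal_marker_count(z, "M2")
  expect_equal(m2$n_abnormal, c(2, 0, 0))
  expect_true(all(m2$complete_case))

  co <- generate_cohort(synthetic_spec(n = 149, seed = 1))
  zz <- compute_zscores(co)
  expect_equal(sum(abnormal_marker_count(zz, "M1")$complete_case), 76)
  expect_equal(sum(abnormal_marker_count(zz, "M2")$complete_case), 149)

  z_none <- tibble::tibble(subject_id = "a", z_ventricular_volume = 1,
                           z_total_suvr = 1, z_csf_tau = NA_real_)
  expect_error(abnormal_marker_count(z_none, "M1"), "complete")
})
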
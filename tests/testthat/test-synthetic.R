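test_that("the generator is deterministic under a fixed seed", {
  a <- generate_cohort(synthetic_spec(n = 149, seed = 1))
  b <- generate_cohort(synthetic_spec(n = 149, seed = 1))
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_identical(attr(a, "truth"), attr(b, "truth"))
  c <- generate_cohort(synthetic_spec(n = 149, seed = 2))
  expect_false(identical(as.data.frame(a), as.data.frame(c)))
})

test_that("generator leaves the global RNG state untouched", {
  set.seed(42)
  before <- .Random.seed
  invisible(generate_cohort(synthetic_spec(n = 20, seed = 9)))
  expect_identical(.Random.seed, before)
})

test_that("crosstab of a generated cohort matches the generator's own counts", {
  co <- collapse_outcome(generate_cohort(synthetic_spec(n = 200, seed = 3)))
  truth <- attr(co, "truth")
  co$exposed_true <- truth$exposed_true
  xt <- crosstab(co, exposed_true)
  tc <- attr(co, "true_counts")
  expect_equal(c(xt$a, xt$b, xt$c, xt$d), c(tc$a, tc$b, tc$c, tc$d))
})

test_that("latent severity drives the imaging signals in the right directions", {
  co <- generate_cohort(synthetic_spec(n = 2000, seed = 4))
  truth <- attr(co, "truth")
  z <- compute_zscores(co)
  atrophy_total <- rowSums(as.matrix(
    tibble::as_tibble(z)[paste0("z_", lobe_volume_roles())]))
  hypo_total <- rowSums(as.matrix(
    tibble::as_tibble(z)[paste0("z_", lobe_suvr_roles())]))
  expect_lt(cor(atrophy_total, truth$severity), 0)
  expect_lt(cor(hypo_total, truth$severity), 0)
  expect_gt(cor(z$z_ventricular_volume, co$age), 0)
  expect_gt(cor(co$csf_tau, truth$severity, use = "complete.obs"), 0)
})

test_that("a single large cohort recovers the generating odds ratio", {
  spec <- synthetic_spec(n = 2000, pattern_effect_log_or = log(4), seed = 10)
  co <- collapse_outcome(generate_cohort(spec))
  z <- compute_zscores(co, c(lobe_volume_roles(), lobe_suvr_roles()))
  counts <- pattern_counts(classify_lobes(z))
  co$ah <- dichotomize_count(counts$n_ah)
  or <- tidy(fit_logistic(co, outcome ~ ah))$or[2]
  expect_gt(or, 3.0)
  expect_lt(or, 5.4)
})

test_that("with no effect the pattern-outcome association is null", {
  covered <- vapply(1:200, function(s) {
    spec <- synthetic_spec(n = 149, pattern_effect_log_or = 0,
                           latent_loading_atrophy = 0,
                           latent_loading_hypometab = 0, seed = 1000 + s)
    co <- collapse_outcome(generate_cohort(spec))
    truth <- attr(co, "truth")
    co$exposed_true <- truth$exposed_true
    fit <- tidy(fit_logistic(co, outcome ~ exposed_true))
    fit$conf.low[2] <= 1 && fit$conf.high[2] >= 1
  }, logical(1))
  expect_gte(mean(covered), 0.9)
})

test_that("every printed-table fixture reproduces its 2x2 exactly", {
  reg <- contingency_fixtures()
  for (nm in names(reg)) {
    fx <- make_contingency_fixture(nm)
    xt <- crosstab(fx, exposed)
    expect_equal(c(xt$a, xt$b, xt$c, xt$d), reg[[nm]]$counts, label = nm)
  }
})

test_that("pattern fixtures survive the full feature pipeline", {
  for (nm in c("table3_pattern_a", "table3_pattern_h", "table3_pattern_ah")) {
    fx <- make_contingency_fixture(nm)
    z <- compute_zscores(fx, c(lobe_volume_roles(), lobe_suvr_roles()))
    counts <- pattern_counts(classify_lobes(z))
    col <- switch(nm, table3_pattern_a = "n_a_only",
                  table3_pattern_h = "n_h_only", table3_pattern_ah = "n_ah")
    derived <- dichotomize_count(counts[[col]])
    expect_identical(unname(derived), fx$exposed, label = nm)
    # and at the sensitivity cut-offs too
    expect_identical(unname(dichotomize_count(counts[[col]], 1)), fx$exposed)
    expect_identical(unname(dichotomize_count(counts[[col]], 3)), fx$exposed)
  }
})

test_that("fixture construction rejects infeasible requests", {
  expect_error(make_contingency_fixture(c(-1, 2, 3, 4)), "non-negative")
  expect_error(make_contingency_fixture(c(0, 0, 0, 0)), "positive total")
  expect_error(make_contingency_fixture(c(2, 2, 0, 0), feature = "pattern_ah"),
               "non-empty")
  expect_error(make_contingency_fixture("no_such_table"), "Unknown fixture")
})

test_that("trivial 1/1/1/1 fixture has odds ratio 1", {
  fx <- make_contingency_fixture(c(1, 1, 1, 1))
  expect_equal(odds_ratio_woolf(crosstab(fx, exposed))$or, 1)
})
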
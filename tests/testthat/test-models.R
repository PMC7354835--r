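test_that("crosstab reproduces fixture counts and handles edge cases", {
  fx <- make_contingency_fixture("table3_pattern_ah")
  xt <- crosstab(fx, exposed)
  expect_equal(c(xt$a, xt$b, xt$c, xt$d), c(69, 17, 30, 33))
  td <- tidy(xt)
  expect_equal(td$pct_stable, c(100 * 69 / 99, 100 * 30 / 99))
  expect_equal(td$pct_progressed, c(100 * 17 / 50, 100 * 33 / 50))

  none <- tibble::tibble(exposed = c(FALSE, FALSE),
                         outcome = factor(c("stable", "progressed"),
                                          levels = c("stable", "progressed")))
  xt0 <- crosstab(none, exposed)
  expect_equal(c(xt0$c, xt0$d), c(0, 0))
  expect_error(crosstab(none[0, ], exposed), "Empty")
})

test_that("Woolf odds ratio has exact closed-form behaviour", {
  sym <- odds_ratio_woolf(contingency(10, 10, 10, 10))
  expect_equal(sym$or, 1)
  expect_equal(sym$p.value, 1)

  expect_error(odds_ratio_woolf(contingency(5, 0, 3, 2)), "Zero cell")
  hal <- odds_ratio_woolf(contingency(5, 0, 3, 2), haldane = TRUE)
  expect_match(hal$method, "haldane")
  expect_equal(hal$or, (2.5 * 5.5) / (0.5 * 3.5))
})

test_that("univariable logistic regression equals the 2x2 closed form", {
  for (nm in c("table3_pattern_ah", "table4_frontal_congruent")) {
    fx <- make_contingency_fixture(nm)
    woolf <- odds_ratio_woolf(crosstab(fx, exposed))
    fit <- tidy(fit_logistic(fx, outcome ~ exposed))[2, ]
    expect_equal(fit$or, woolf$or, tolerance = 1e-6, label = nm)
    expect_equal(fit$conf.low, woolf$conf.low, tolerance = 1e-4)
    expect_equal(fit$conf.high, woolf$conf.high, tolerance = 1e-4)
    expect_equal(fit$p.value, woolf$p.value, tolerance = 1e-4)
  }
  bal <- make_contingency_fixture(c(20, 20, 20, 20))
  expect_equal(tidy(fit_logistic(bal, outcome ~ exposed))$or[2], 1,
               tolerance = 1e-8)
})

test_that("fitted coefficients maximize the likelihood (grid oracle)", {
  set.seed(77)
  df <- tibble::tibble(
    x1 = rnorm(40), x2 = rep(c(0, 1), 20),
    outcome = runif(40) < stats::plogis(-0.5 + 0.8 * x1)
  )
  fit <- fit_logistic(df, outcome ~ x1 + x2)
  ll_at <- function(beta) {
    p <- stats::plogis(fit$X %*% beta)
    sum(log(ifelse(fit$y, p, 1 - p)))
  }
  ll_hat <- as.numeric(logLik(fit))
  beta_hat <- tidy(fit)$estimate
  for (j in seq_along(beta_hat)) {
    for (delta in seq(-0.5, 0.5, length.out = 201)) {
      b <- beta_hat
      b[j] <- b[j] + delta
      expect_lte(ll_at(b), ll_hat + 1e-10)
    }
  }
})

test_that("degenerate designs are reported, separation is only a warning", {
  df <- tibble::tibble(
    x = c(-2, -1.5, -1, 1, 1.5, 2),
    outcome = c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE)
  )
  expect_warning(fit <- fit_logistic(df, outcome ~ x), "separation")
  expect_true(fit$separation)
  expect_s3_class(tidy(fit), "tbl_df")

  df2 <- tibble::tibble(a = rep(c(0, 1), 10), outcome = rep(c(FALSE, TRUE), 10))
  df2$b <- df2$a
  expect_error(fit_logistic(df2, outcome ~ a + b), "collinear.*b")
  df2$c <- 1
  expect_error(fit_logistic(df2, outcome ~ c), "constant")
  expect_error(fit_logistic(dplyr::mutate(df2, outcome = FALSE), outcome ~ a),
               "single class")
})

test_that("model_table lays out counts and mutually adjusted odds ratios", {
  fx <- make_contingency_fixture("table3_pattern_ah")
  tab <- model_table(fx, terms = "exposed")
  expect_equal(tab$level, c("unexposed", "exposed"))
  expect_equal(tab$n_stable, c(69, 30))
  expect_equal(tab$n_progressed, c(17, 33))
  expect_true(is.na(tab$or_uni[1]))                   # reference level
  expect_equal(round(tab$or_uni[2], 2), 4.46)
  expect_equal(attr(tab, "n_multi"), 149)

  # with no adjustment, univariable and multivariable columns coincide
  tab0 <- model_table(fx, terms = "exposed", adjust = character(0))
  expect_equal(tab0$or_uni[2], tab0$or_multi[2], tolerance = 1e-10)

  # complete-case bookkeeping for the tau model
  co <- collapse_outcome(generate_cohort(synthetic_spec(n = 149, seed = 1)))
  z <- compute_zscores(co)
  m1 <- abnormal_marker_count(z, "M1")
  co$markers <- factor(m1$n_abnormal)
  tab1 <- model_table(co[m1$complete_case, ], terms = "markers")
  expect_equal(sum(tab1$n_stable) + sum(tab1$n_progressed), 76)
})

test_that("balanced accuracy is the mean of sensitivity and specificity", {
  expect_equal(balanced_accuracy(c(TRUE, FALSE), c(TRUE, FALSE)), 1)
  truth <- rep(c(TRUE, FALSE), c(5, 15))
  expect_equal(balanced_accuracy(rep(TRUE, 20), truth), 0.5)
  # sensitivity 0.6 (6/10), specificity 0.8 (8/10)
  truth <- rep(c(TRUE, FALSE), each = 10)
  pred <- c(rep(TRUE, 6), rep(FALSE, 4), rep(TRUE, 2), rep(FALSE, 8))
  expect_equal(balanced_accuracy(pred, truth), 0.7)
  expect_error(balanced_accuracy(pred, rep(TRUE, 20)), "single class")
})

test_that("repeated CV is deterministic and perfect on separable data", {
  df <- tibble::tibble(
    x = rep(c(-3, 3), each = 30) + rep(seq(-0.5, 0.5, length.out = 30), 2),
    outcome = rep(c(FALSE, TRUE), each = 30)
  )
  cv <- repeated_cv(df, outcome ~ x, k = 5, repeats = 10, seed = 3)
  expect_equal(cv$accuracy, 1)
  expect_true(all(cv$fold_accuracy == 1))
  expect_equal(cv$balanced_accuracy, 1)

  cv2 <- repeated_cv(df, outcome ~ x, k = 5, repeats = 10, seed = 3)
  expect_identical(tidy(cv), tidy(cv2))

  # different seeds give different partitions (visible on noisy data)
  noisy <- tibble::tibble(x = rep(seq(-1, 1, length.out = 30), 2),
                          outcome = rep(c(FALSE, TRUE), each = 30))
  cvA <- repeated_cv(noisy, outcome ~ x, k = 5, repeats = 5, seed = 3)
  cvB <- repeated_cv(noisy, outcome ~ x, k = 5, repeats = 5, seed = 4)
  expect_false(identical(cvA$fold_accuracy, cvB$fold_accuracy))

  expect_error(repeated_cv(df[c(1:6, 31:36), ], outcome ~ x, k = 10,
                           repeats = 2), "smaller k")
})

test_that("stratified folds preserve the outcome mix", {
  co <- collapse_outcome(generate_cohort(synthetic_spec(n = 100, seed = 12)))
  co$x <- seq_len(nrow(co))
  cv <- repeated_cv(co, outcome ~ x, k = 5, repeats = 3, seed = 1)
  expect_true(all(dim(cv$fold_accuracy) == c(3, 5)))
  expect_true(all(cv$fold_accuracy >= 0 & cv$fold_accuracy <= 1))
})

test_that("condition number follows the Belsley convention", {
  expect_equal(as.numeric(condition_number(diag(4))), 1)

  # exact correlation 0.8 built from an orthonormal basis
  n <- 50
  e1 <- rep(1 / sqrt(n), n)
  e2 <- rep(c(1, -1) / sqrt(n), n / 2)
  X <- cbind(e1, 0.8 * e1 + 0.6 * e2)
  expect_equal(as.numeric(condition_number(X)), sqrt(1.8 / 0.2),
               tolerance = 1e-10)

  dup <- cbind(1, c(1, 2, 3), c(1, 2, 3))
  expect_equal(as.numeric(condition_number(dup)), Inf)
  expect_error(condition_number(matrix(1, 3, 1)), "2 columns")

  co <- collapse_outcome(generate_cohort(synthetic_spec(n = 149, seed = 13)))
  fit <- fit_logistic(co, outcome ~ age + sex)
  kappa <- condition_number(fit)
  expect_true(is.finite(kappa) && kappa > 1)
})
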
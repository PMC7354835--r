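#' Baseline characteristics with stable-vs-progressed group tests
#'
#' Builds a baseline ("Table 1"-style) comparison of the two outcome groups,
#' dispatching the appropriate base-R test per variable:
#' * `"chisq"` — Pearson chi-squared *without* continuity correction
#'   (categorical variables with adequate cell counts);
#' * `"fisher"` — Fisher's exact test (sparse categorical);
#' * `"anova"` — one-way ANOVA (approximately normal numeric);
#' * `"kruskal"` — Kruskal–Wallis rank-sum test (skewed numeric).
#'
#' Chi-squared cells with expected counts below 5 trigger a warning
#' suggesting the Fisher test.
#'
#' @param cohort Data frame holding the variables and a binary `outcome`.
#' @param specs Named character vector mapping variable column names to test
#'   tags, e.g. `c(sex = "chisq", age = "anova")`.
#' @param outcome Name of the outcome column (default `"outcome"`).
#' @return A tibble of class `np_baseline`, one row per variable: `variable`,
#'   `test`, `statistic`, `p.value`, and per-group summaries (`summary_stable`,
#'   `summary_progressed`: mean (SD) for ANOVA, median (range) for
#'   Kruskal–Wallis, counts for categorical tests).
#' @examples
#' cohort <- collapse_outcome(generate_cohort(synthetic_spec(n = 80, seed = 4)))
#' baseline_table(cohort, c(sex = "chisq", age = "anova",
#'                          ventricular_volume = "kruskal"))
#' @export
baseline_table <- function(cohort, specs, outcome = "outcome") {
  cohort <- tibble::as_tibble(cohort)
  if (!outcome %in% names(cohort)) {
    stop("Cohort lacks outcome column '", outcome, "'", call. = FALSE)
  }
  oc <- .as_progressed(cohort[[outcome]])
  if (!any(oc) || !any(!oc)) stop("Both outcome groups must be non-empty",
                                  call. = FALSE)
  missing_cols <- setdiff(names(specs), names(cohort))
  if (length(missing_cols)) {
    stop("Cohort lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  bad <- setdiff(specs, c("chisq", "fisher", "anova", "kruskal"))
  if (length(bad)) stop("Unknown test tag(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)

  num_summary <- function(x, type) {
    if (type == "anova") sprintf("%.1f (%.1f)", mean(x, na.rm = TRUE),
                                 stats::sd(x, na.rm = TRUE))
    else sprintf("%.0f (%.0f-%.0f)", stats::median(x, na.rm = TRUE),
                 min(x, na.rm = TRUE), max(x, na.rm = TRUE))
  }
  rows <- purrr::imap(as.list(specs), function(test, var) {
    x <- cohort[[var]]
    ok <- !is.na(x) & !is.na(oc)
    x <- x[ok]; g <- oc[ok]
    if (test %in% c("chisq", "fisher")) {
      tab <- table(factor(x), g)
      if (test == "chisq") {
        exp_counts <- outer(rowSums(tab), colSums(tab)) / sum(tab)
        if (any(exp_counts < 5)) {
          warning("Expected count < 5 for '", var,
                  "'; consider the Fisher exact test", call. = FALSE)
        }
        ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
      } else {
        ht <- stats::fisher.test(tab)
      }
      smry <- function(grp) paste(
        sprintf("%s: %d (%.1f%%)", rownames(tab), tab[, grp],
                100 * tab[, grp] / sum(tab[, grp])), collapse = "; ")
      tibble::tibble(
        variable = var, test = test,
        statistic = if (test == "chisq") unname(ht$statistic) else NA_real_,
        p.value = ht$p.value,
        summary_stable = smry("FALSE"),
        summary_progressed = smry("TRUE"),
        n = length(x)
      )
    } else {
      ht <- if (test == "anova") {
        fit <- stats::aov(x ~ g)
        s <- summary(fit)[[1]]
        list(statistic = s[["F value"]][1], p.value = s[["Pr(>F)"]][1])
      } else {
        kt <- stats::kruskal.test(x, factor(g))
        list(statistic = unname(kt$statistic), p.value = kt$p.value)
      }
      tibble::tibble(
        variable = var, test = test,
        statistic = ht$statistic, p.value = ht$p.value,
        summary_stable = num_summary(x[!g], test),
        summary_progressed = num_summary(x[g], test),
        n = length(x)
      )
    }
  })
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("np_baseline", class(out)))
}

#' Pairwise Spearman correlations of baseline variables
#'
#' Rank correlations (average ranks for ties) with two-sided p-values from
#' the t approximation, computed on pairwise-complete observations — so
#' correlations involving CSF tau automatically use the tau-measured subset.
#' Pairs with p at or above `sig_level` are flagged not-significant, the
#' masking used in published correlograms.
#'
#' @param cohort Data frame.
#' @param vars Character vector of numeric column names (>= 2).
#' @param sig_level Flagging threshold (default 0.05).
#' @return A tibble of class `np_corr`, one row per unordered pair: `var1`,
#'   `var2`, `rho`, `p.value`, `n` (pairwise-complete count), `significant`.
#' @examples
#' cohort <- generate_cohort(synthetic_spec(n = 60, seed = 5))
#' spearman_matrix(cohort, c("age", "ventricular_volume", "total_suvr"))
#' @export
spearman_matrix <- function(cohort, vars, sig_level = 0.05) {
  cohort <- tibble::as_tibble(cohort)
  missing_cols <- setdiff(vars, names(cohort))
  if (length(missing_cols)) {
    stop("Cohort lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  stopifnot(length(vars) >= 2L)
  pairs <- utils::combn(vars, 2L, simplify = FALSE)
  rows <- purrr::map(pairs, function(pr) {
    x <- cohort[[pr[1]]]; y <- cohort[[pr[2]]]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 3L) {
      stop("Fewer than 3 paired observations for ", pr[1], " vs ", pr[2],
           call. = FALSE)
    }
    if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
      stop("Constant variable in pair ", pr[1], " vs ", pr[2],
           "; correlation undefined", call. = FALSE)
    }
    ct <- suppressWarnings(
      stats::cor.test(x[ok], y[ok], method = "spearman", exact = FALSE)
    )
    tibble::tibble(var1 = pr[1], var2 = pr[2],
                   rho = unname(ct$estimate), p.value = ct$p.value,
                   n = sum(ok))
  })
  out <- dplyr::mutate(dplyr::bind_rows(rows),
                       significant = .data$p.value < sig_level)
  structure(out, sig_level = sig_level, class = c("np_corr", class(out)))
}

#' Linear regression of MMSE change on a biomarker z-score
#'
#' Ordinary least squares of the MMSE change (follow-up minus baseline, so
#' cognitive decline is negative) on a standardized biomarker. Subjects
#' missing either MMSE score or the biomarker are excluded. The returned
#' object carries residuals and fitted values for the usual Q-Q/residual
#' diagnostics ([autoplot()]).
#'
#' @param cohort Data frame with `mmse_baseline`, `mmse_followup` and the
#'   z-score column (join the cohort to its [compute_zscores()] panel, or
#'   pass any numeric column).
#' @param z_var Name of the predictor column.
#' @return An object of class `np_reg` wrapping the [stats::lm()] fit, with
#'   `tidy()`/`glance()` methods reporting slope, intercept, r-squared and
#'   the slope p-value.
#' @export
mmse_change_regression <- function(cohort, z_var) {
  cohort <- tibble::as_tibble(cohort)
  need <- c("mmse_baseline", "mmse_followup", z_var)
  missing_cols <- setdiff(need, names(cohort))
  if (length(missing_cols)) {
    stop("Cohort lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  df <- tibble::tibble(
    change = cohort$mmse_followup - cohort$mmse_baseline,
    z = cohort[[z_var]]
  )
  df <- df[stats::complete.cases(df), ]
  if (nrow(df) < 3L) stop("Fewer than 3 complete observations", call. = FALSE)
  if (stats::sd(df$z) == 0) stop("Zero-variance predictor '", z_var, "'",
                                 call. = FALSE)
  fit <- stats::lm(change ~ z, data = df)
  structure(list(fit = fit, z_var = z_var, n = nrow(df)),
            class = "np_reg")
}

#' @export
print.np_reg <- function(x, ...) {
  g <- glance.np_reg(x)
  cat(sprintf("MMSE change ~ %s: slope %.3f, r2 = %.3f, p = %s (n = %d)\n",
              x$z_var, g$slope, g$r.squared, format_p(g$p.value), g$n))
  invisible(x)
}

#' @method tidy np_reg
#' @export
tidy.np_reg <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble::tibble(
    term = rownames(s),
    estimate = s[, "Estimate"],
    std.error = s[, "Std. Error"],
    statistic = s[, "t value"],
    p.value = s[, "Pr(>|t|)"]
  )
}

#' @method glance np_reg
#' @export
glance.np_reg <- function(x, ...) {
  s <- summary(x$fit)
  tibble::tibble(
    slope = unname(stats::coef(x$fit)[2]),
    intercept = unname(stats::coef(x$fit)[1]),
    r.squared = s$r.squared,
    p.value = s$coefficients[2, "Pr(>|t|)"],
    n = x$n
  )
}
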
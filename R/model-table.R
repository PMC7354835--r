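#' Univariable + multivariable results table for a set of predictors
#'
#' Reproduces the layout of the printed results tables: for every predictor,
#' per-level counts within each outcome group (with within-group
#' percentages), the univariable odds ratio from a model containing that
#' predictor alone, and the mutually adjusted multivariable odds ratio from a
#' single model holding all predictors plus the adjustment covariates
#' (age and sex by default). Reference levels (first factor level, or
#' `FALSE`/"unexposed" for logicals) carry no odds ratio.
#'
#' @param data Data frame holding `outcome` plus all predictor/adjustment
#'   columns (e.g. a cohort joined to its derived features).
#' @param terms Character vector of predictor column names.
#' @param adjust Character vector of adjustment covariates included in the
#'   multivariable model only (default `c("age", "sex")`); use `character(0)`
#'   for none, in which case a single-term call has identical univariable and
#'   multivariable columns.
#' @param outcome Name of the binary outcome column (default `"outcome"`).
#' @return A tibble of class `np_model_table`: one row per term level with
#'   `term`, `level`, `n_stable`, `pct_stable`, `n_progressed`,
#'   `pct_progressed`, `or_uni`, `conf.low_uni`, `conf.high_uni`, `p_uni`,
#'   and the `_multi` counterparts. Attributes `n_multi` (complete-case n of
#'   the multivariable fit) and `fit_multi` (the underlying [fit_logistic()]
#'   object).
#' @examples
#' cohort <- make_contingency_fixture("table3_pattern_ah")
#' tab <- model_table(cohort, terms = "exposed")
#' tab[tab$level == "exposed", c("or_uni", "conf.low_uni", "conf.high_uni")]
#' @export
model_table <- function(data, terms, adjust = c("age", "sex"),
                        outcome = "outcome") {
  data <- tibble::as_tibble(data)
  missing_cols <- setdiff(c(outcome, terms, adjust), names(data))
  if (length(missing_cols)) {
    stop("Data lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  for (tm in unique(c(terms, adjust))) {
    if (is.logical(data[[tm]])) {
      data[[tm]] <- factor(ifelse(data[[tm]], "exposed", "unexposed"),
                           levels = c("unexposed", "exposed"))
    } else if (is.character(data[[tm]])) {
      data[[tm]] <- factor(data[[tm]])
    }
  }

  all_rhs <- unique(c(terms, adjust))
  f_multi <- stats::reformulate(all_rhs, response = outcome)
  fit_multi <- fit_logistic(data, f_multi)
  multi <- tidy.np_fit(fit_multi)

  oc <- .as_progressed(data[[outcome]])
  rows <- purrr::map(terms, function(tm) {
    f_uni <- stats::reformulate(tm, response = outcome)
    fit_uni <- fit_logistic(data, f_uni)
    uni <- tidy.np_fit(fit_uni)
    v <- data[[tm]]
    if (is.factor(v)) {
      keep <- !is.na(v) & !is.na(oc)
      lev <- levels(v)
      n_st <- vapply(lev, function(l) sum(v[keep] == l & !oc[keep]), 0L)
      n_pr <- vapply(lev, function(l) sum(v[keep] == l & oc[keep]), 0L)
      coefnames <- paste0(tm, lev)
      out <- tibble::tibble(
        term = tm, level = lev,
        n_stable = as.integer(n_st),
        pct_stable = 100 * n_st / sum(n_st),
        n_progressed = as.integer(n_pr),
        pct_progressed = 100 * n_pr / sum(n_pr)
      )
    } else {
      coefnames <- tm
      out <- tibble::tibble(
        term = tm, level = "per unit",
        n_stable = NA_integer_, pct_stable = NA_real_,
        n_progressed = NA_integer_, pct_progressed = NA_real_
      )
    }
    add_est <- function(out, est, suffix) {
      idx <- match(coefnames, est$term)
      out[[paste0("or", suffix)]] <- est$or[idx]
      out[[paste0("conf.low", suffix)]] <- est$conf.low[idx]
      out[[paste0("conf.high", suffix)]] <- est$conf.high[idx]
      out[[paste0("p", suffix)]] <- est$p.value[idx]
      out
    }
    out <- add_est(out, uni, "_uni")
    add_est(out, multi, "_multi")
  })
  out <- dplyr::bind_rows(rows)
  structure(out,
            n_multi = fit_multi$n, fit_multi = fit_multi,
            class = c("np_model_table", class(out)))
}
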
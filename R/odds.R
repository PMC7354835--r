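#' Build a 2x2 exposure-by-outcome contingency table
#'
#' `crosstab()` cross-tabulates a binary exposure column against the binary
#' progression outcome; `contingency()` builds the same object directly from
#' the four counts, in the cell order used throughout: `a` (stable,
#' unexposed), `b` (progressed, unexposed), `c` (stable, exposed), `d`
#' (progressed, exposed).
#'
#' @param data A data frame with the exposure and outcome columns.
#' @param exposure Column (tidy-eval) that is logical, or a 2-level factor
#'   whose second level is "exposed".
#' @param outcome Column (tidy-eval) holding the binary outcome (factor with
#'   levels `stable`, `progressed`, or logical with `TRUE` = progressed).
#'   Defaults to `outcome`.
#' @param a,b,c,d Non-negative cell counts.
#' @return An object of class `np_xtab`: a list with the four counts and the
#'   variable labels. `tidy()` renders it as one row per exposure level with
#'   counts and within-outcome-column percentages, the layout of the printed
#'   tables.
#' @examples
#' contingency(69, 17, 30, 33)
#' @export
crosstab <- function(data, exposure, outcome = outcome) {
  data <- tibble::as_tibble(data)
  if (!nrow(data)) stop("Empty cohort", call. = FALSE)
  ex <- dplyr::pull(data, {{ exposure }})
  oc <- dplyr::pull(data, {{ outcome }})
  keep <- !is.na(ex) & !is.na(oc)
  ex <- ex[keep]; oc <- oc[keep]
  if (!length(ex)) stop("No subjects with both exposure and outcome defined",
                        call. = FALSE)
  ex <- .as_exposed(ex)
  oc <- .as_progressed(oc)
  contingency(
    a = sum(!ex & !oc), b = sum(!ex & oc),
    c = sum(ex & !oc), d = sum(ex & oc),
    exposure_label = rlang::as_label(rlang::enquo(exposure)),
    outcome_label = rlang::as_label(rlang::enquo(outcome))
  )
}

#' @rdname crosstab
#' @param exposure_label,outcome_label Optional display labels.
#' @export
contingency <- function(a, b, c, d, exposure_label = "exposure",
                        outcome_label = "outcome") {
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(counts < 0) || sum(counts) <= 0) {
    stop("Contingency counts must be non-negative with a positive total",
         call. = FALSE)
  }
  structure(
    list(a = a, b = b, c = c, d = d,
         exposure_label = exposure_label, outcome_label = outcome_label),
    class = "np_xtab"
  )
}

#' @export
print.np_xtab <- function(x, ...) {
  m <- matrix(c(x$a, x$c, x$b, x$d), 2, 2,
              dimnames = list(c("unexposed", "exposed"),
                              c("stable", "progressed")))
  cat("2x2 table:", x$exposure_label, "x", x$outcome_label, "\n")
  print(m)
  invisible(x)
}

#' @method tidy np_xtab
#' @export
tidy.np_xtab <- function(x, ...) {
  tot_stable <- x$a + x$c
  tot_prog <- x$b + x$d
  tibble::tibble(
    level = c("unexposed", "exposed"),
    n_stable = c(x$a, x$c),
    pct_stable = 100 * c(x$a, x$c) / tot_stable,
    n_progressed = c(x$b, x$d),
    pct_progressed = 100 * c(x$b, x$d) / tot_prog
  )
}

.as_exposed <- function(ex) {
  if (is.logical(ex)) return(ex)
  if (is.factor(ex)) {
    if (nlevels(ex) != 2L) stop("Exposure factor must have 2 levels", call. = FALSE)
    return(ex == levels(ex)[2L])
  }
  if (is.numeric(ex) && all(ex %in% 0:1)) return(ex == 1)
  stop("Exposure must be logical, 2-level factor or 0/1", call. = FALSE)
}

.as_progressed <- function(oc) {
  if (is.logical(oc)) return(oc)
  if (is.factor(oc) || is.character(oc)) {
    oc <- as.character(oc)
    ok <- oc %in% .outcome_levels
    if (!all(ok)) stop("Outcome labels must be 'stable'/'progressed'", call. = FALSE)
    return(oc == "progressed")
  }
  if (is.numeric(oc) && all(oc %in% 0:1)) return(oc == 1)
  stop("Outcome must be logical, stable/progressed factor or 0/1", call. = FALSE)
}

#' Woolf odds ratio with 95% confidence interval from a 2x2 table
#'
#' Closed-form odds ratio for a 2x2 exposure-by-outcome table:
#' `OR = (d*a) / (b*c)`, with the Woolf standard error of the log odds ratio
#' `SE = sqrt(1/a + 1/b + 1/c + 1/d)`, Wald confidence limits
#' `exp(log OR +/- z * SE)` and a two-sided normal p-value for
#' `log OR / SE`. With a zero cell the estimate is undefined and an error is
#' raised unless `haldane = TRUE`, which adds 0.5 to every cell
#' (Haldane–Anscombe) and flags the result.
#'
#' @param x An `np_xtab` from [crosstab()]/[contingency()], or a numeric
#'   vector `c(a, b, c, d)`.
#' @param conf_level Confidence level (default 0.95).
#' @param haldane Apply the +0.5 continuity correction to all cells when any
#'   cell is zero (default `FALSE`).
#' @return One-row tibble of class `np_or`: `or`, `conf.low`, `conf.high`,
#'   `p.value`, `method` (`"woolf_2x2"`, suffixed `"+haldane"` when
#'   corrected), and the cell counts.
#' @examples
#' odds_ratio_woolf(contingency(69, 17, 30, 33))  # OR 4.46 (2.16-9.22)
#' @export
odds_ratio_woolf <- function(x, conf_level = 0.95, haldane = FALSE) {
  if (inherits(x, "np_xtab")) {
    cells <- c(x$a, x$b, x$c, x$d)
  } else {
    stopifnot(is.numeric(x), length(x) == 4L)
    cells <- x
  }
  method <- "woolf_2x2"
  if (any(cells == 0)) {
    if (!haldane) {
      stop("Zero cell in 2x2 table: odds ratio undefined ",
           "(set haldane = TRUE for the +0.5 correction)", call. = FALSE)
    }
    cells <- cells + 0.5
    method <- "woolf_2x2+haldane"
  }
  a <- cells[1]; b <- cells[2]; c <- cells[3]; d <- cells[4]
  or <- (d * a) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  p <- 2 * stats::pnorm(-abs(log(or) / se))
  out <- tibble::tibble(
    or = or,
    conf.low = exp(log(or) - zq * se),
    conf.high = exp(log(or) + zq * se),
    p.value = p,
    method = method,
    a = cells[1], b = cells[2], c = cells[3], d = cells[4]
  )
  structure(out, class = c("np_or", class(out)))
}

#' Format a p-value the way the printed tables do
#'
#' Three decimals, with values below 0.001 rendered as `"<0.001"`.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector.
#' @examples
#' format_p(c(0.5238, 0.0004))
#' @export
format_p <- function(p) {
  ifelse(p < 0.001, "<0.001", sprintf("%.3f", p))
}
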
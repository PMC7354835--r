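#' Maximum-likelihood logistic regression with Wald inference
#'
#' Fits a binomial logistic model of progression by iteratively reweighted
#' least squares (convergence when the relative deviance change is below
#' `1e-12` — coefficients stable to well under `1e-8`, at
#' most 100 iterations), with an intercept and treatment coding against
#' first-level references (female; unexposed; `no_abnormality`; marker count
#' 0). Wald confidence intervals `exp(beta +/- z * SE)` and two-sided normal
#' p-values come from the inverse observed information. A rank-deficient
#' design is an error naming the aliased terms; quasi-separation (any
#' |coefficient| > 15 on the log-odds scale) attaches a warning but the
#' estimates are still returned.
#'
#' @param data A data frame containing the outcome and predictor columns.
#' @param formula Model formula, e.g. `outcome ~ exposed + age + sex`. The
#'   response may be a `stable`/`progressed` factor or a logical
#'   (`TRUE` = progressed).
#' @param conf_level Confidence level for the Wald intervals (default 0.95).
#' @return An object of class `np_fit` wrapping the underlying fit, with
#'   [tidy()] and [glance()] methods. `tidy()` reports per term: the
#'   log-odds coefficient, its standard error, the odds ratio `exp(beta)`
#'   with confidence limits, and the Wald p-value.
#' @examples
#' cohort <- make_contingency_fixture("table3_pattern_ah")
#' fit <- fit_logistic(cohort, outcome ~ exposed)
#' tidy(fit)  # exp(beta) matches the Woolf 2x2 odds ratio 4.46
#' @export
fit_logistic <- function(data, formula, conf_level = 0.95) {
  data <- as.data.frame(data)
  mf <- stats::model.frame(formula, data = data, na.action = stats::na.omit)
  y <- .as_progressed(stats::model.response(mf))
  X <- stats::model.matrix(formula, mf)
  n <- length(y)
  if (length(unique(y)) < 2L) {
    stop("Outcome has a single class in the complete-case set; ",
         "logistic model undefined", call. = FALSE)
  }
  if (n <= ncol(X)) {
    stop("More parameters than observations (n = ", n, ", p = ", ncol(X), ")",
         call. = FALSE)
  }
  const <- apply(X[, colnames(X) != "(Intercept)", drop = FALSE], 2,
                 function(v) length(unique(v)) < 2L)
  if (any(const)) {
    stop("Term(s) constant within the complete-case set: ",
         paste(names(const)[const], collapse = ", "), call. = FALSE)
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[seq.int(qrX$rank + 1L, ncol(X))]]
    stop("Rank-deficient design; collinear term(s): ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }

  fit <- suppressWarnings(stats::glm.fit(
    X, as.numeric(y), family = stats::binomial(),
    control = stats::glm.control(epsilon = 1e-12, maxit = 100)
  ))
  beta <- fit$coefficients
  separation <- any(abs(beta) > 15)
  if (separation) {
    warning("Possible separation: |coefficient| > 15 on the log-odds scale; ",
            "estimates are unreliable", call. = FALSE)
  }

  # observed information = X' W X at the MLE; glm.fit exposes the weighted QR
  p1 <- seq_len(fit$qr$rank)
  cov <- chol2inv(fit$qr$qr[p1, p1, drop = FALSE])
  nm <- names(beta)[fit$qr$pivot[p1]]
  dimnames(cov) <- list(nm, nm)
  cov <- cov[names(beta), names(beta), drop = FALSE]
  se <- unname(sqrt(diag(cov)))
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  terms_tbl <- tibble::tibble(
    term = names(beta),
    estimate = unname(beta),
    std.error = unname(se),
    statistic = unname(beta / se),
    p.value = 2 * stats::pnorm(-abs(unname(beta / se))),
    or = exp(unname(beta)),
    conf.low = exp(unname(beta) - zq * se),
    conf.high = exp(unname(beta) + zq * se)
  )
  structure(
    list(
      terms = terms_tbl, vcov = cov, n = n,
      deviance = fit$deviance, null.deviance = fit$null.deviance,
      aic = fit$aic, converged = fit$converged, iter = fit$iter,
      separation = separation, formula = formula,
      X = X, y = y, conf_level = conf_level
    ),
    class = "np_fit"
  )
}

#' @export
print.np_fit <- function(x, ...) {
  cat("Logistic progression model:", deparse(x$formula), "\n")
  cat("n =", x$n, "| deviance =", round(x$deviance, 2),
      "| converged:", x$converged, paste0("(", x$iter, " iter)"), "\n")
  print(x$terms, ...)
  invisible(x)
}

#' @method tidy np_fit
#' @export
tidy.np_fit <- function(x, ...) x$terms

#' @method glance np_fit
#' @export
glance.np_fit <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    deviance = x$deviance,
    null.deviance = x$null.deviance,
    AIC = x$aic,
    converged = x$converged,
    iter = x$iter,
    separation = x$separation
  )
}

#' @export
vcov.np_fit <- function(object, ...) object$vcov

#' Predicted progression probabilities from an np_fit
#'
#' @param object An `np_fit`.
#' @param newdata Optional data frame; defaults to the training design.
#' @param ... Unused.
#' @return Numeric vector of probabilities.
#' @export
predict.np_fit <- function(object, newdata = NULL, ...) {
  X <- if (is.null(newdata)) {
    object$X
  } else {
    stats::model.matrix(stats::delete.response(stats::terms(object$formula)),
                        as.data.frame(newdata))
  }
  as.vector(stats::plogis(X %*% object$terms$estimate))
}

#' Log-likelihood of an np_fit
#' @param object An `np_fit`.
#' @param ... Unused.
#' @export
logLik.np_fit <- function(object, ...) {
  p <- predict.np_fit(object)
  structure(sum(log(ifelse(object$y, p, 1 - p))),
            df = ncol(object$X), class = "logLik")
}
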
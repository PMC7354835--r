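#' Balanced accuracy of binary predictions
#'
#' Mean of sensitivity (recall of the progressed class) and specificity
#' (recall of the stable class); insensitive to class imbalance.
#'
#' @param predicted,truth Equal-length binary labels (logical with `TRUE` =
#'   progressed, or `stable`/`progressed` factors). Truth must contain both
#'   classes.
#' @return A single number in `[0, 1]`.
#' @examples
#' balanced_accuracy(c(TRUE, TRUE, FALSE, FALSE), c(TRUE, FALSE, TRUE, FALSE))
#' @export
balanced_accuracy <- function(predicted, truth) {
  predicted <- .as_progressed(predicted)
  truth <- .as_progressed(truth)
  stopifnot(length(predicted) == length(truth))
  if (length(unique(truth)) < 2L) {
    stop("Truth labels contain a single class; balanced accuracy undefined",
         call. = FALSE)
  }
  sens <- mean(predicted[truth])
  spec <- mean(!predicted[!truth])
  (sens + spec) / 2
}

#' Repeated stratified k-fold cross-validation of a logistic model
#'
#' Internal validation of a progression model: `repeats` independent random
#' partitions of the cohort into `k` folds stratified on the outcome (each
#' fold keeps the cohort's class mix), fitting the model on the training
#' folds and classifying the held-out subjects at a fixed probability
#' threshold (a predicted probability exactly at the threshold classifies as
#' progressed). Overall accuracy is the mean of the per-fold accuracies over
#' all repeats; balanced accuracy is computed on the pooled held-out
#' predictions within each repeat and averaged over repeats. Deterministic
#' under a fixed seed.
#'
#' @param data Data frame with the outcome and predictors.
#' @param formula Model formula as in [fit_logistic()].
#' @param k Number of folds (default 10).
#' @param repeats Number of random re-partitions (default 1000).
#' @param seed Integer seed; the global RNG state is restored afterwards.
#' @param threshold Classification probability threshold (default 0.5).
#' @param stratified Stratify folds on the outcome (default `TRUE`).
#' @return An object of class `np_cv` with [tidy()] (per-repeat accuracies)
#'   and [glance()] (overall summaries) methods.
#' @examples
#' cohort <- generate_cohort(synthetic_spec(n = 120, seed = 3))
#' cohort <- dplyr::mutate(collapse_outcome(cohort),
#'                         old = age > stats::median(age))
#' cv <- repeated_cv(cohort, outcome ~ old, k = 5, repeats = 20, seed = 1)
#' glance(cv)
#' @export
repeated_cv <- function(data, formula, k = 10, repeats = 1000, seed = NULL,
                        threshold = 0.5, stratified = TRUE) {
  data <- as.data.frame(data)
  mf <- stats::model.frame(formula, data = data, na.action = stats::na.omit)
  y <- .as_progressed(stats::model.response(mf))
  X <- stats::model.matrix(formula, mf)
  n <- length(y)
  if (length(unique(y)) < 2L) {
    stop("Both outcome classes must be present", call. = FALSE)
  }
  if (stratified && min(table(y)) < k) {
    stop("Smallest outcome class (", min(table(y)),
         ") is smaller than k = ", k, "; use a smaller k", call. = FALSE)
  }

  if (!is.null(seed)) {
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old_seed)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old_seed, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }

  fold_assign <- function() {
    folds <- integer(n)
    if (stratified) {
      for (cls in c(TRUE, FALSE)) {
        idx <- which(y == cls)
        folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
      }
    } else {
      folds <- sample(rep_len(seq_len(k), n))
    }
    folds
  }

  fold_acc <- matrix(NA_real_, nrow = repeats, ncol = k)
  bal_acc <- numeric(repeats)
  for (r in seq_len(repeats)) {
    folds <- fold_assign()
    pooled_pred <- logical(n)
    for (f in seq_len(k)) {
      test <- folds == f
      fit <- suppressWarnings(stats::glm.fit(
        X[!test, , drop = FALSE], as.numeric(y[!test]),
        family = stats::binomial(),
        control = stats::glm.control(epsilon = 1e-8, maxit = 100)
      ))
      p <- stats::plogis(X[test, , drop = FALSE] %*% fit$coefficients)
      pred <- p >= threshold
      pooled_pred[test] <- pred
      fold_acc[r, f] <- mean(pred == y[test])
    }
    bal_acc[r] <- balanced_accuracy(pooled_pred, y)
  }

  structure(
    list(
      k = k, repeats = repeats, seed = seed, threshold = threshold,
      stratified = stratified, n = n,
      fold_accuracy = fold_acc,
      repeat_balanced_accuracy = bal_acc,
      accuracy = mean(fold_acc),
      balanced_accuracy = mean(bal_acc),
      formula = formula
    ),
    class = "np_cv"
  )
}

#' @export
print.np_cv <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation, %d repeats (n = %d)\n",
              x$k, x$repeats, x$n))
  cat(sprintf("accuracy %.3f | balanced accuracy %.3f\n",
              x$accuracy, x$balanced_accuracy))
  invisible(x)
}

#' @method tidy np_cv
#' @export
tidy.np_cv <- function(x, ...) {
  tibble::tibble(
    repeat_id = seq_len(x$repeats),
    accuracy = rowMeans(x$fold_accuracy),
    balanced_accuracy = x$repeat_balanced_accuracy
  )
}

#' @method glance np_cv
#' @export
glance.np_cv <- function(x, ...) {
  tibble::tibble(
    k = x$k, repeats = x$repeats, n = x$n,
    accuracy = x$accuracy,
    balanced_accuracy = x$balanced_accuracy,
    threshold = x$threshold,
    stratified = x$stratified
  )
}
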
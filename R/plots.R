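#' Plot odds ratios of a results table
#'
#' Dot-and-interval display of the univariable and multivariable odds ratios
#' of a [model_table()] on a log scale, one row per non-reference term level.
#'
#' @param object An `np_model_table`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot np_model_table
#' @export
autoplot.np_model_table <- function(object, ...) {
  df <- dplyr::filter(tibble::as_tibble(object), !is.na(.data$or_uni))
  long <- dplyr::bind_rows(
    dplyr::transmute(df, label = paste(.data$term, .data$level, sep = ": "),
                     model = "univariable", or = .data$or_uni,
                     lo = .data$conf.low_uni, hi = .data$conf.high_uni),
    dplyr::transmute(df, label = paste(.data$term, .data$level, sep = ": "),
                     model = "multivariable", or = .data$or_multi,
                     lo = .data$conf.low_multi, hi = .data$conf.high_multi)
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$or, y = .data$label,
                                     colour = .data$model)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$lo, xmax = .data$hi),
                             position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "odds ratio (log scale)", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the cross-validation accuracy distribution
#'
#' Histograms of the per-repeat mean fold accuracy and per-repeat balanced
#' accuracy of a [repeated_cv()] result.
#'
#' @param object An `np_cv`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot np_cv
#' @export
autoplot.np_cv <- function(object, ...) {
  df <- tidyr::pivot_longer(tidy.np_cv(object), -"repeat_id",
                            names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 30, fill = "steelblue", colour = "white") +
    ggplot2::facet_wrap(~metric, scales = "free_x") +
    ggplot2::labs(x = "accuracy", y = "repeats") +
    ggplot2::theme_minimal()
}

#' Diagnostic plots for an MMSE-change regression
#'
#' Residuals-versus-fitted and normal Q-Q panels, the visual checks of the
#' linear-model assumptions.
#'
#' @param object An `np_reg` from [mmse_change_regression()].
#' @param ... Unused.
#' @return A ggplot object (two panels via facets).
#' @method autoplot np_reg
#' @export
autoplot.np_reg <- function(object, ...) {
  fit <- object$fit
  r <- stats::residuals(fit)
  df <- dplyr::bind_rows(
    tibble::tibble(panel = "residuals vs fitted",
                   x = stats::fitted(fit), y = r),
    tibble::tibble(panel = "normal Q-Q",
                   x = stats::qnorm(stats::ppoints(length(r)))[order(order(r))],
                   y = r)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::facet_wrap(~panel, scales = "free") +
    ggplot2::labs(x = NULL, y = "residual") +
    ggplot2::theme_minimal()
}

#' Plot a Spearman correlation matrix
#'
#' Tile display of pairwise Spearman correlations; pairs flagged
#' not-significant are blanked, the usual correlogram masking.
#'
#' @param object An `np_corr` from [spearman_matrix()].
#' @param mask_ns Blank non-significant pairs (default `TRUE`).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot np_corr
#' @export
autoplot.np_corr <- function(object, mask_ns = TRUE, ...) {
  df <- tibble::as_tibble(object)
  df <- dplyr::bind_rows(df, dplyr::rename(df, var1 = "var2", var2 = "var1"))
  if (mask_ns) df$rho[!df$significant] <- NA_real_
  ggplot2::ggplot(df, ggplot2::aes(x = .data$var1, y = .data$var2,
                                   fill = .data$rho)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1), na.value = "grey90") +
    ggplot2::labs(x = NULL, y = NULL, fill = "Spearman rho") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
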
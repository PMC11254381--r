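#' Plot the model-search criterion landscape
#'
#' One point per candidate subset, criterion value against subset size,
#' with the winning subset highlighted.
#'
#' @param object A `hemilat_search`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hemilat_search <- function(object, ...) {
  crit <- object$criterion
  tab <- dplyr::mutate(object$table,
                       winner = .data$subset ==
                         paste(object$winner, collapse = "+"))
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$k, y = .data[[crit]])) +
    ggplot2::geom_jitter(ggplot2::aes(colour = .data$winner), width = 0.12,
                         height = 0, alpha = 0.8) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "firebrick"),
                                 guide = "none") +
    ggplot2::labs(x = "Number of LV regressors",
                  y = toupper(crit),
                  title = sprintf("Exhaustive subset search (winner: %s)",
                                  paste(object$winner, collapse = " + ")))
}

#' Plot winning-model coefficients with standard errors
#'
#' @param object A `hemilat_ols`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hemilat_ols <- function(object, ...) {
  ct <- dplyr::filter(tidy(object), .data$term != "(Intercept)")
  ggplot2::ggplot(ct, ggplot2::aes(x = .data$term, y = .data$estimate)) +
    ggplot2::geom_col(fill = "steelblue", width = 0.6) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$estimate - .data$std.error,
                                        ymax = .data$estimate + .data$std.error),
                           width = 0.15) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(x = NULL, y = "Coefficient (beta)",
                  title = sprintf("%s ~ %s", object$response,
                                  paste(object$regressors, collapse = " + ")))
}

#' Plot condition-wise multivariate regression coefficients
#'
#' Per-condition coefficient bars for each structural regressor, with
#' standard errors — the per-outcome view of the condition-wise fit.
#'
#' @param object A `hemilat_mmr`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hemilat_mmr <- function(object, ...) {
  ct <- dplyr::filter(tidy(object), .data$term != "(Intercept)")
  ggplot2::ggplot(ct, ggplot2::aes(x = .data$outcome, y = .data$estimate,
                                   fill = .data$term)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$estimate - .data$std.error,
                                        ymax = .data$estimate + .data$std.error),
                           position = ggplot2::position_dodge(width = 0.8),
                           width = 0.2) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(x = "Condition outcome", y = "Coefficient (beta)",
                  fill = "Structure")
}

#' Histogram of the cohort's HLM(alpha) distribution
#'
#' @param laterality Laterality table with an `hlm` column (see
#'   [cohort_laterality()]).
#' @param bins Number of histogram bins.
#' @return A ggplot object.
#' @export
plot_hlm_distribution <- function(laterality, bins = 15) {
  ggplot2::ggplot(laterality, ggplot2::aes(x = .data$hlm)) +
    ggplot2::geom_histogram(bins = bins, fill = "steelblue",
                            colour = "white") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "HLM(alpha)", y = "Subjects",
                  title = "Hemispheric lateralization modulation")
}

#' Plot a group-level MI(alpha) sensor map as a left/right ladder
#'
#' Mirror pairs on the y axis, hemispheres side by side; fill encodes the
#' modulation index.
#'
#' @param group_mi Tibble of per-location MI values.
#' @return A ggplot object.
#' @export
plot_mi_map <- function(group_mi) {
  ggplot2::ggplot(group_mi,
                  ggplot2::aes(x = .data$hemisphere,
                               y = factor(.data$pair_id),
                               fill = .data$mi)) +
    ggplot2::geom_tile(colour = "grey30") +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white",
                                  high = "firebrick", midpoint = 0) +
    ggplot2::labs(x = NULL, y = "Mirror pair", fill = "MI(alpha)",
                  title = "Group-level alpha modulation index")
}
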
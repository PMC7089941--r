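#' Plot a Kaplan-Meier curve
#'
#' Step survival curves, one per group when the curve was fitted by group.
#'
#' @param object A `km_curve` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.km_curve <- function(object, ...) {
  df <- as_tibble(object)
  if (!"group" %in% names(df)) df$group <- "all"
  # prepend S(0) = 1 per group so curves start at 1
  origin <- distinct(df, .data$group) %>%
    mutate(time = 0, survival = 1)
  df <- bind_rows(origin, df[, c("group", "time", "survival")]) %>%
    arrange(.data$group, .data$time)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$survival,
                                   colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Months", y = "Survival probability", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot HRD calls
#'
#' Histogram of LST counts coloured by class, with the ploidy-specific
#' cut-offs marked.
#'
#' @param object An `hrd_calls` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.hrd_calls <- function(object, ...) {
  cutoffs <- unique(object$cutoff)
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$lst_count, fill = .data$lst_class)) +
    ggplot2::geom_histogram(binwidth = 1) +
    ggplot2::geom_vline(xintercept = cutoffs - 0.5, linetype = "dashed") +
    ggplot2::labs(x = "LST per genome", y = "Tumours", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a concordance table
#'
#' Tile plot of the cross-tabulation of two subgroup assignments, annotated
#' with counts and row percentages.
#'
#' @param object A `concordance` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.concordance <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$label_b, y = .data$label_a,
                                   fill = .data$row_pct)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%d (%.0f%%)", .data$n, .data$row_pct))) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = NULL, y = NULL, fill = "row %") +
    ggplot2::theme_minimal()
}

#' Plot pairwise log-rank adjusted p-values
#'
#' Lower-triangle tile plot of Benjamini-Hochberg adjusted pairwise log-rank
#' p-values.
#'
#' @param object A `pairwise_logrank` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.pairwise_logrank <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group1, y = .data$group2,
                                   fill = -log10(.data$p_adj))) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = signif(.data$p_adj, 2))) +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick") +
    ggplot2::labs(x = NULL, y = NULL, fill = "-log10 adj. p") +
    ggplot2::theme_minimal()
}
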
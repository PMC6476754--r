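#' Plot a per-genus binomial scan
#'
#' Lollipop display of each scanned genus: observed success fraction
#' (polymorphic species, or sharing pairs) against the uniform null rate
#' `p0` (dashed line), with genera showing a significant upper or lower
#' tail highlighted.
#'
#' @param object A `chplex_scan` tibble.
#' @param alpha Significance highlight threshold (default 0.05).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.chplex_scan <- function(object, alpha = 0.05, ...) {
  df <- tibble::as_tibble(object)
  if (nrow(df) == 0) {
    return(ggplot2::ggplot() +
             ggplot2::labs(title = "Empty scan (no genus met the size threshold)"))
  }
  df <- dplyr::mutate(
    df,
    observed = .data$k / .data$n,
    tail = dplyr::case_when(
      .data$p_plus < alpha ~ "above null",
      .data$p_minus < alpha ~ "below null",
      TRUE ~ "consistent with null"
    ),
    genus = stats::reorder(.data$genus, .data$n)
  )
  p0 <- df$p0[1]
  what <- if (identical(attr(object, "scan_type"), "pair_sharing")) {
    "sharing species pairs"
  } else {
    "polymorphic species"
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$genus, y = .data$observed)) +
    ggplot2::geom_hline(yintercept = p0, linetype = "dashed") +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$genus, yend = p0),
                          colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$tail, size = .data$n)) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = paste("Fraction of", what),
                  colour = "Binomial tail", size = "n") +
    ggplot2::theme_minimal()
}

#' Plot scenario-suite outcomes
#'
#' Violin-and-point display of the group-2 minus group-1 polymorphism-rate
#' difference (or another replicate-level outcome) across scenarios.
#'
#' @param object A `chplex_scenarios` tibble.
#' @param outcome Column to display (default `"rate_diff"`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.chplex_scenarios <- function(object, outcome = "rate_diff", ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$scenario,
                                   y = .data[[outcome]])) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::geom_violin(fill = "grey90", colour = "grey60") +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.3, size = 0.6) +
    ggplot2::stat_summary(fun = mean, geom = "point", colour = "red",
                          size = 2) +
    ggplot2::labs(x = NULL, y = outcome) +
    ggplot2::theme_minimal()
}
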
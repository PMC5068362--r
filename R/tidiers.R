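# broom-style accessors and ggplot2 display for partition results.

#' Tidy a variation partition
#'
#' One row per fraction with the raw (signed) adjusted-R-squared estimate,
#' the zero-clamped display value, and — when tests have been attached — the
#' permutation p-value and significance code.
#'
#' @param x A `commpart` from [partition_variation()].
#' @param ... Unused.
#' @return Tibble with columns `fraction`, `term`, `estimate`, `clamped`,
#'   `p_value`, `code`.
#' @export
tidy.commpart <- function(x, ...) {
  terms <- c(a = "environment | space",
             b = "spatially structured environment",
             c = "space | environment",
             d = "residual")
  p <- c(x$p_values["a"], NA_real_, x$p_values["c"], NA_real_)
  tibble::tibble(
    fraction = names(x$raw),
    term = unname(terms[names(x$raw)]),
    estimate = unname(x$raw),
    clamped = unname(x$clamped),
    p_value = unname(p),
    code = significance_code(unname(p))
  )
}

#' Model-level summary of a variation partition
#'
#' @param x A `commpart`.
#' @param ... Unused.
#' @return One-row tibble: total and block-wise adjusted R-squared, plus the
#'   unadjusted R-squared and dimensions of the full fit.
#' @export
glance.commpart <- function(x, ...) {
  tibble::tibble(
    adj_r_squared_full = x$totals[["abc"]],
    adj_r_squared_env = x$totals[["ab"]],
    adj_r_squared_space = x$totals[["bc"]],
    r_squared_full = x$fits$abc$r_squared,
    n = x$fits$abc$n,
    p_env = x$fits$ab$p,
    p_space = x$fits$bc$p
  )
}

#' Attach permutation test results to a partition
#'
#' @param x A `commpart`.
#' @param tests Output of [test_unique_taxonomic()] or [test_unique_trait()].
#' @return The partition with `p_values` filled in.
#' @export
add_partition_tests <- function(x, tests) {
  stopifnot(inherits(x, "commpart"))
  for (f in c("a", "c")) {
    hit <- tests$p_value[tests$fraction == f]
    if (length(hit)) x$p_values[[f]] <- hit
  }
  x
}

#' Bar-chart display of a variation partition
#'
#' Clamped fractions as a single stacked bar, annotated with significance
#' codes for the testable unique fractions.
#'
#' @param object A `commpart`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.commpart <- function(object, ...) {
  td <- tidy(object)
  td$fraction <- factor(td$fraction, levels = rev(c("a", "b", "c", "d")))
  lab <- ifelse(is.na(td$code) | td$code == "", "", td$code)
  ggplot2::ggplot(td, ggplot2::aes(x = "partition", y = .data$clamped,
                                   fill = .data$fraction)) +
    ggplot2::geom_col(colour = "grey30") +
    ggplot2::geom_text(ggplot2::aes(label = lab),
                       position = ggplot2::position_stack(vjust = 0.5)) +
    ggplot2::scale_fill_brewer(palette = "Blues", direction = -1,
                               name = "fraction") +
    ggplot2::labs(x = NULL, y = "adjusted R² (clamped)") +
    ggplot2::coord_flip() +
    ggplot2::theme_minimal()
}

#' Faceted fraction bars for a full report
#'
#' Mirrors the classic presentation: one stacked bar per season x scale,
#' faceted by response, clamped fractions on the adjusted-R-squared scale.
#'
#' @param results The `results` tibble of a `commdecomp_report` (or the
#'   report itself).
#' @return A ggplot object.
#' @export
plot_partition_report <- function(results) {
  if (inherits(results, "commdecomp_report")) results <- results$results
  long <- tidyr::pivot_longer(
    dplyr::select(results, dplyr::all_of(c("season", "scale", "response",
                                           "a_clamped", "b_clamped",
                                           "c_clamped", "d_clamped"))),
    cols = dplyr::ends_with("_clamped"),
    names_to = "fraction", values_to = "value")
  long$fraction <- factor(sub("_clamped", "", long$fraction),
                          levels = rev(c("a", "b", "c", "d")))
  ggplot2::ggplot(long,
                  ggplot2::aes(x = interaction(.data$season, .data$scale,
                                               sep = " / "),
                               y = .data$value, fill = .data$fraction)) +
    ggplot2::geom_col(colour = "grey30") +
    ggplot2::facet_wrap(~response) +
    ggplot2::scale_fill_brewer(palette = "Blues", direction = -1,
                               name = "fraction") +
    ggplot2::labs(x = "season / scale", y = "adjusted R² (clamped)") +
    ggplot2::coord_flip() +
    ggplot2::theme_minimal()
}
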
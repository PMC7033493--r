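#' Overview plots of an annotated site catalog
#'
#' Bar panels of the variant-type distribution (reference-strand labels)
#' and the genomic-feature distribution, the usual first look at an
#' editing-site catalog.
#'
#' @param annotated Annotated site tibble from [annotate_sites()].
#' @return A ggplot object.
#' @export
plot_editing_overview <- function(annotated) {
  d <- dplyr::bind_rows(
    annotated |> dplyr::count(value = .data$variant_type) |>
      dplyr::mutate(panel = "variant type"),
    annotated |> dplyr::count(value = .data$feature) |>
      dplyr::mutate(panel = "genomic feature")
  )
  ggplot(d, aes(x = stats::reorder(.data$value, -.data$n), y = .data$n)) +
    geom_col(fill = "steelblue") +
    facet_wrap(~panel, scales = "free_x") +
    labs(x = NULL, y = "editing sites") +
    theme_minimal()
}

#' Distribution of editing-expression correlation coefficients
#'
#' @param expression_cor Result of [correlate_editing_expression()].
#' @return A ggplot object.
#' @export
plot_pcc_distribution <- function(expression_cor) {
  ggplot(expression_cor, aes(x = .data$r)) +
    geom_histogram(bins = 30, fill = "grey40") +
    labs(x = "Pearson correlation (editing degree vs expression)",
         y = "sites") +
    theme_minimal()
}

#' Kaplan-Meier plot of a risk-group comparison
#'
#' @param object A `"survival_comparison"` from [km_logrank()].
#' @param ... Unused.
#' @return A ggplot object with the log-rank p in the subtitle.
#' @export
autoplot.survival_comparison <- function(object, ...) {
  km <- object$km |>
    dplyr::group_by(.data$group) |>
    dplyr::group_modify(~ dplyr::bind_rows(
      tibble(time = 0, survival = 1), .x[, c("time", "survival")])) |>
    dplyr::ungroup()
  ggplot(km, aes(x = .data$time, y = .data$survival,
                 colour = .data$group)) +
    geom_step() +
    labs(x = "days", y = "overall survival",
         subtitle = sprintf("log-rank p = %.3g", object$logrank_p)) +
    theme_minimal()
}
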
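#' Visualize post-processing rule outcomes
#'
#' Bar chart of how many mentions each rule removed or modified, from the
#' outcome log returned by [filter_mentions()], [correct_forms()] or
#' [postprocess_answerset()] (or attached by [extract_variants()]).
#'
#' @param log An outcome-log tibble.
#' @return A ggplot object.
#' @export
#' @examples
#' a <- extract_variants("T47D cells carry T790M but not L367L.")
#' plot_rule_outcomes(attr(a, "log"))
plot_rule_outcomes <- function(log) {
  d <- log |>
    dplyr::filter(!is.na(.data$rule_id)) |>
    dplyr::count(.data$rule_id, .data$action)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$rule_id, y = .data$n,
                                  fill = .data$action)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::labs(x = NULL, y = "mentions",
                  title = "Post-processing rule outcomes") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Visualize mention forms in an extraction result
#'
#' @param mentions A mentions tibble from [extract_mentions()].
#' @return A ggplot object.
#' @export
plot_mention_forms <- function(mentions) {
  d <- dplyr::count(mentions, .data$form, .data$informative)
  ggplot2::ggplot(d, ggplot2::aes(x = stats::reorder(.data$form, -.data$n),
                                  y = .data$n, fill = .data$informative)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "mentions",
                  title = "Extracted mention forms") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
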
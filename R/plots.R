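#' Plot the classification outcome of a variant table
#'
#' Stacked bar of classification tiers per variant class, faceted by gene.
#'
#' @param object An `acmg_tbl` from [classify_variants()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.acmg_tbl <- function(object, ...) {
  df <- tibble::as_tibble(object) |>
    dplyr::filter(!is.na(.data$classification)) |>
    dplyr::mutate(classification = factor(.data$classification,
                                          levels = c("P", "LP", "VUS", "LB", "B")))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$variant_class,
                                   fill = .data$classification)) +
    ggplot2::geom_bar() +
    ggplot2::facet_wrap(ggplot2::vars(.data$gene), scales = "free_x") +
    ggplot2::labs(x = "variant class", y = "distinct variants",
                  fill = "classification") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot a variant-spectrum summary
#'
#' Severity composition of each variant class from a [spectrum_table()].
#'
#' @param spectrum A tibble from [spectrum_table()].
#' @return A ggplot object.
#' @export
plot_spectrum <- function(spectrum) {
  df <- spectrum |>
    dplyr::filter(.data$variant_class != "total") |>
    tidyr::pivot_longer(cols = c("severe_n", "moderate_n", "mild_n", "unknown_n"),
                        names_to = "severity", values_to = "n") |>
    dplyr::mutate(severity = factor(sub("_n$", "", .data$severity),
                                    levels = SEVERITY_LEVELS))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$variant_class, y = .data$n,
                                   fill = .data$severity)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(ggplot2::vars(.data$gene), scales = "free") +
    ggplot2::labs(x = "variant class", y = "patients", fill = "severity") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot inhibitor incidence per group
#'
#' @param incidence A tibble from [inhibitor_incidence()].
#' @return A ggplot object.
#' @export
plot_inhibitor_incidence <- function(incidence) {
  df <- dplyr::filter(incidence, !.data$undefined)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$percent)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%d/%d", .data$positive, .data$tested)), vjust = -0.4) +
    ggplot2::labs(x = NULL, y = "inhibitor-positive (% of tested)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
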
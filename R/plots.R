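#' Plot a circuit trajectory
#'
#' Synaptic weights of both pathways over the course of a protocol, one
#' panel per stimulus. Under flupentixol the two curves separate: the
#' US-prediction pathway (CS->DA) keeps growing while the response pathway
#' (CS->CR) stays flat — the signature that later produces auto-blocking.
#'
#' @param object A `pe_trajectory` from [run_protocol()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.pe_trajectory <- function(object, ...) {
  df <- tibble::as_tibble(object) |>
    dplyr::mutate(event = dplyr::row_number(), .by = "stimulus") |>
    tidyr::pivot_longer(c("w_cs_cr", "w_cs_da"),
                        names_to = "pathway", values_to = "weight")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$event, y = .data$weight,
                                   color = .data$pathway)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(ggplot2::vars(.data$stimulus)) +
    ggplot2::scale_color_manual(
      values = c(w_cs_cr = "#D55E00", w_cs_da = "#0072B2"),
      labels = c(w_cs_cr = "CS→CR (response)",
                 w_cs_da = "CS→DA (US prediction)")) +
    ggplot2::labs(x = "event", y = "synaptic weight", color = NULL,
                  title = attr(object, "protocol_name")) +
    ggplot2::theme_minimal()
}

#' Box-and-whisker plot of preference-test records
#'
#' Relative preference for the conditioned source before (white) and after
#' (grey) training per group — the standard presentation of these
#' experiments. Only retained records are drawn.
#'
#' @param records Records tibble (see [generate_preferences()]).
#' @return A ggplot object.
#' @export
plot_preferences <- function(records) {
  df <- apply_retention_filter(records) |>
    dplyr::mutate(test = factor(.data$test, levels = c("pre", "post")))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$relative_preference,
                                   fill = .data$test)) +
    ggplot2::geom_boxplot(outlier.shape = 1) +
    ggplot2::scale_fill_manual(values = c(pre = "white", post = "grey70")) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "relative preference (conditioned source)",
                  fill = NULL) +
    ggplot2::theme_minimal()
}
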
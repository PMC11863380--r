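#' Per-residue prediction profile
#'
#' Plots the binding score along each sequence, with called residues
#' highlighted — the typical way to inspect a per-residue binding-site
#' prediction track.
#'
#' @param predictions A tibble from [predict_records()].
#' @param threshold Threshold line to draw (default 0.5).
#' @return A ggplot object, facetted by sequence id.
#' @export
plot_prediction_profile <- function(predictions, threshold = 0.5) {
  ggplot2::ggplot(predictions,
                  ggplot2::aes(x = .data$position, y = .data$score)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(
      data = dplyr::filter(predictions, .data$label == 1L),
      colour = "firebrick", size = 1.2
    ) +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::facet_wrap(ggplot2::vars(.data$id), scales = "free_x") +
    ggplot2::labs(x = "residue position", y = "binding score",
                  title = "Predicted calcium-binding profile") +
    ggplot2::theme_minimal()
}
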
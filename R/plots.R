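# ggplot2 views of the three result types: hydropathy profiles with called
# helices, screen summaries, and expression time courses.

#' Plot a protein's hydropathy profile with predicted helices
#'
#' @param sequence One protein sequence.
#' @param window,threshold,min_len,merge_gap Predictor settings, as in
#'   [predict_tm()].
#' @return A ggplot: centred window-mean Kyte-Doolittle hydropathy by
#'   residue, the threshold line, and predicted helix intervals shaded.
#' @export
plot_hydropathy <- function(sequence, window = 19L, threshold = 1.6,
                            min_len = 15L, merge_gap = 5L) {
  prof <- hydropathy_profile(sequence, window)
  topo <- predict_tm(c(protein = sequence), window, threshold, min_len, merge_gap)
  helices <- topo$helices[[1]]
  p <- ggplot2::ggplot(prof, ggplot2::aes(x = .data$position, y = .data$hydropathy))
  if (nrow(helices) > 0) {
    p <- p + ggplot2::geom_rect(
      data = helices,
      ggplot2::aes(xmin = .data$start, xmax = .data$end, ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, fill = "steelblue", alpha = 0.25
    )
  }
  p +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed", colour = "grey40") +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::labs(
      x = "Residue", y = "Mean hydropathy (Kyte-Doolittle)",
      title = sprintf("%d predicted transmembrane helix(es)", topo$n_tm[1])
    ) +
    ggplot2::theme_minimal()
}

#' @rdname run_screen
#' @param object A `ring_screen` object.
#' @export
autoplot.ring_screen <- function(object, ...) {
  ggplot2::ggplot(
    object$candidates,
    ggplot2::aes(x = factor(.data$n_tm), fill = .data$subtype)
  ) +
    ggplot2::geom_bar(position = "stack") +
    ggplot2::labs(
      x = "Transmembrane helices", y = "Candidate genes", fill = "RING subtype"
    ) +
    ggplot2::theme_minimal()
}

#' @rdname responsiveness
#' @param object An `er_responsiveness` object.
#' @export
autoplot.er_responsiveness <- function(object, ...) {
  alpha <- object$params$alpha
  d <- dplyr::mutate(object$comparisons,
    significant = .data$p_adj < alpha & .data$fold > 1
  )
  ggplot2::ggplot(d, ggplot2::aes(
    x = factor(.data$time_h), y = .data$fold, group = .data$gene
  )) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(colour = .data$significant)) +
    ggplot2::facet_grid(dplyr::vars(.data$gene), dplyr::vars(.data$condition)) +
    ggplot2::labs(
      x = "Hours of treatment", y = "Fold change vs control",
      colour = sprintf("adj. p < %.2g & fold > 1", alpha)
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
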
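#' Plot an ITC fit: observed and fitted injection heats
#'
#' Heat per injection against the cell molar ratio, with the fitted
#' single-site isotherm overlaid.
#'
#' @param object An `itc_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot itc_fit
#' @export
autoplot.itc_fit <- function(object, ...) {
  protocol <- object$experiment$protocol
  pred <- predict_isotherm(object$estimates$n, object$estimates$kd,
                           object$estimates$dh, protocol,
                           dilution_heat = object$estimates$dilution_heat)
  df <- tibble::tibble(molar_ratio = pred$molar_ratio,
                       observed = object$experiment$heats,
                       fitted = pred$heat)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$molar_ratio)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "steelblue") +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed)) +
    ggplot2::labs(x = "molar ratio (titrant / cell species)",
                  y = "heat per injection (µcal)",
                  title = sprintf("single-site fit: n = %.2f, K_D = %.1f µM",
                                  object$estimates$n, object$estimates$kd * 1e6)) +
    ggplot2::theme_minimal()
}

#' Plot a Debye molecular-weight profile
#'
#' Per-slice molecular weight across the elution, with the concentration
#' profile underlaid and peak-average weights annotated.
#'
#' @param object A `debye_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot debye_fit
#' @export
autoplot.debye_fit <- function(object, ...) {
  s <- object$slices
  scale <- max(s$mw, na.rm = TRUE) / max(s$conc)
  ggplot2::ggplot(s, ggplot2::aes(x = .data$time)) +
    ggplot2::geom_area(ggplot2::aes(y = .data$conc * scale),
                       fill = "grey85") +
    ggplot2::geom_point(ggplot2::aes(y = .data$mw), size = 0.6,
                        colour = "steelblue", na.rm = TRUE) +
    ggplot2::geom_hline(data = object$peaks,
                        ggplot2::aes(yintercept = .data$mw),
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::labs(x = "elution time (s)", y = "molecular weight (g/mol)",
                  title = "Debye-plot molecular weight across the peak") +
    ggplot2::theme_minimal()
}

#' Map annotated BIR-like modules along a sequence
#'
#' Draws module spans as horizontal segments with the Zn-coordinating
#' residues and anchors marked.
#'
#' @param annotations Tibble from [annotate_modules()] or [scan_fasta()]
#'   (single sequence).
#' @param seq_length Optional sequence length for the x-axis limit.
#' @return A ggplot object.
#' @export
plot_module_map <- function(annotations, seq_length = NULL) {
  ann <- dplyr::mutate(annotations, y = dplyr::row_number())
  lig <- ann |>
    dplyr::select("y", "kind", "c1", "c2", "h", "c3") |>
    tidyr::pivot_longer(c("c1", "c2", "h", "c3"),
                        names_to = "ligand", values_to = "pos")
  p <- ggplot2::ggplot(ann) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$span_start, xend = .data$span_end,
                                       y = .data$y, yend = .data$y,
                                       colour = .data$kind),
                          linewidth = 3, lineend = "round") +
    ggplot2::geom_point(data = lig,
                        ggplot2::aes(x = .data$pos, y = .data$y), shape = 124) +
    ggplot2::scale_y_continuous(breaks = NULL) +
    ggplot2::labs(x = "residue", y = NULL, colour = "module") +
    ggplot2::theme_minimal()
  if (!is.null(seq_length)) p <- p + ggplot2::xlim(1, seq_length)
  p
}
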
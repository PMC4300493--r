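#' Plot normalised codon translation rates
#'
#' Bar plot of per-codon translation rates (reciprocal dwell, normalised so
#' the slowest codon has rate 1), sorted by rate.
#'
#' @param object A `flow_fit` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.flow_fit <- function(object, ...) {
  df <- codon_rates(object) %>%
    dplyr::mutate(codon = stats::reorder(.data$codon, .data$rate))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$codon, y = .data$rate)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "translation rate (min = 1)") +
    ggplot2::theme_minimal(base_size = 9)
}

#' Plot the objective trace of a model fit
#'
#' @param fit A `flow_fit` object.
#' @return A ggplot object.
#' @export
plot_objective_trace <- function(fit) {
  df <- tibble::tibble(sweep = seq_along(fit$trace) - 1, objective = fit$trace)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sweep, y = .data$objective)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "coordinate-descent sweep", y = "objective") +
    ggplot2::theme_minimal()
}

#' Plot outlier strengths along a gene
#'
#' @param deltas Tibble from [outlier_deltas()].
#' @param gene A gene id.
#' @param T Slow-outlier threshold drawn as a reference line (default 1).
#' @return A ggplot object.
#' @export
plot_outliers <- function(deltas, gene, T = 1) {
  df <- deltas[deltas$gene_id == gene, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$delta)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.7) +
    ggplot2::geom_hline(yintercept = c(-1, 1), linetype = "dotted") +
    ggplot2::geom_hline(yintercept = T, colour = "red", linetype = "dashed") +
    ggplot2::labs(title = gene, x = "codon position",
                  y = expression(Delta)) +
    ggplot2::theme_minimal()
}

#' Plot a sliding-window signal profile
#'
#' Mean normalised window signal across genes, aligned to the start codon,
#' with the detected energy dip marked.
#'
#' @param object A `dms_windows` object.
#' @param mark_dip Mark [find_energy_dip()] with a vertical line (default
#'   TRUE).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dms_windows <- function(object, mark_dip = TRUE, ...) {
  p <- ggplot2::ggplot(object$profile,
                       ggplot2::aes(x = .data$position, y = .data$mean)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::labs(x = "nt from start codon", y = "normalised window signal") +
    ggplot2::theme_minimal()
  if (mark_dip) {
    dip <- find_energy_dip(object)
    if (!is.na(dip)) {
      p <- p + ggplot2::geom_vline(xintercept = dip, colour = "red",
                                   linetype = "dashed")
    }
  }
  p
}

#' Plot a learned Kozak motif as a PWM heat map
#'
#' @param object A `kozak_fit` object (or a 9 x 4 PWM matrix).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.kozak_fit <- function(object, ...) {
  pwm <- if (inherits(object, "kozak_fit")) object$pwm else object
  df <- tibble::as_tibble(pwm, rownames = "position") %>%
    tidyr::pivot_longer(-"position", names_to = "base", values_to = "prob") %>%
    dplyr::mutate(position = factor(.data$position,
                                    levels = as.character(KOZAK_POSITIONS)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$base,
                                   fill = .data$prob)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$prob)),
                       size = 2.5) +
    ggplot2::scale_fill_gradient(low = "white", high = "darkgreen",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = "position relative to AUG", y = NULL,
                  fill = "probability") +
    ggplot2::theme_minimal()
}
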
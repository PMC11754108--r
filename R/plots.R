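# ggplot2 visualizations of the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a stability-versus-evolutionary-fitness sigmoid fit
#'
#' Variants coloured by their residual to the fitted curve; large positive
#' residuals (above the curve) mark candidate functional mutations.
#'
#' @param object A [fit_sigmoid()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sigmoid_fit <- function(object, ...) {
  d <- object$data
  curve <- tibble::tibble(
    score = seq(min(d$score), max(d$score), length.out = 200)
  )
  curve$f_norm <- sigmoid_predict(curve$score, object$xmid, object$scal)
  ggplot2::ggplot(d, ggplot2::aes(.data$score, .data$f_norm)) +
    ggplot2::geom_point(
      ggplot2::aes(colour = .data$residual),
      size = 0.8, alpha = 0.7
    ) +
    ggplot2::geom_line(data = curve, linewidth = 0.8) +
    ggplot2::scale_colour_gradient2(low = "#2166ac", high = "#b2182b") +
    ggplot2::labs(
      x = "evolutionary fitness score",
      y = "normalized stability fitness",
      colour = "residual",
      title = object$domain_id
    ) +
    ggplot2::theme_minimal()
}

#' Plot held-out predictions of a cross-validated energy model
#'
#' @param object A [tenfold_cv()] report.
#' @param ... Unused.
#' @return A ggplot of observed versus held-out predicted fitness.
#' @export
autoplot.cv_report <- function(object, ...) {
  d <- object$assignment[!is.na(object$assignment$predicted), ]
  ggplot2::ggplot(d, ggplot2::aes(.data$predicted, .data$observed)) +
    ggplot2::geom_point(size = 0.5, alpha = 0.4) +
    ggplot2::geom_abline(linetype = 2, colour = "grey40") +
    ggplot2::labs(
      x = "held-out predicted fitness (h⁻¹)",
      y = "observed fitness (h⁻¹)",
      subtitle = sprintf("pooled held-out r = %.3f", object$pooled_r)
    ) +
    ggplot2::theme_minimal()
}

#' Heatmap of a family's inferred mutation energies
#'
#' @param object A fitted `family_energy_model`.
#' @param scaled Whether to plot scaled ddG (wild type 0, destabilizing
#'   positive) instead of raw energies.
#' @param ... Unused.
#' @return A ggplot tile map (columns by mutant residue).
#' @export
autoplot.family_energy_model <- function(object, scaled = TRUE, ...) {
  d <- rescale_energies(object)
  val <- if (scaled) "scaled_ddg" else "ddg"
  ggplot2::ggplot(d, ggplot2::aes(
    .data$column, .data$mut_aa,
    fill = .data[[val]]
  )) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", high = "#b2182b") +
    ggplot2::labs(
      x = "alignment column", y = "mutant amino acid",
      fill = if (scaled) "scaled ΔΔG" else "ΔΔG (RT)",
      title = object$family_id
    ) +
    ggplot2::theme_minimal()
}

#' Bar chart of stability classes per clinical label
#'
#' @param summary Output of [summarize_stability_classes()].
#' @return A stacked percentage bar chart.
#' @export
plot_stability_classes <- function(summary) {
  d <- summary[!is.na(summary$pct), ]
  d$stability_class <- factor(
    d$stability_class,
    levels = c("strong", "mild", "stable")
  )
  ggplot2::ggplot(d, ggplot2::aes(
    .data$label, .data$pct,
    fill = .data$stability_class
  )) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(
      strong = "#b2182b", mild = "#fddbc7", stable = "#d1e5f0"
    )) +
    ggplot2::labs(x = NULL, y = "% of variants", fill = "stability class") +
    ggplot2::theme_minimal()
}
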
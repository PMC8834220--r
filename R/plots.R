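#' Plot spectra
#'
#' Line plot of every spectrum over the wavenumber grid, colored by an
#' optional metadata column; the x axis is reversed to the descending
#' cm^-1 convention of FT-NIR instruments.
#'
#' @param spectra a spectra tibble.
#' @param color optional metadata column name used for the line color.
#' @return a ggplot object.
#' @export
plot_spectra <- function(spectra, color = NULL) {
  long <- tidyr::pivot_longer(spectra, cols = spectral_cols(spectra),
                              names_to = "wavenumber",
                              values_to = "absorbance")
  long$wavenumber <- as.numeric(long$wavenumber)
  aes <- if (is.null(color)) {
    ggplot2::aes(x = .data$wavenumber, y = .data$absorbance,
                 group = .data$sample_id)
  } else {
    ggplot2::aes(x = .data$wavenumber, y = .data$absorbance,
                 group = .data$sample_id,
                 color = factor(.data[[color]]))
  }
  ggplot2::ggplot(long, aes) +
    ggplot2::geom_line(alpha = 0.4, linewidth = 0.3) +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = expression(wavenumber ~ (cm^-1)), y = "absorbance",
                  color = color) +
    ggplot2::theme_minimal()
}

#' Coefficient curve of a PLS model
#'
#' Regression coefficients over the wavenumber grid, with the selected
#' wavenumbers highlighted when a selection result is supplied.
#'
#' @param object a `nir_pls` model.
#' @param selection optional `selection_result`.
#' @param ... ignored.
#' @method autoplot nir_pls
#' @export
autoplot.nir_pls <- function(object, selection = NULL, ...) {
  df <- tidy(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$wavenumber,
                                        y = .data$estimate)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = expression(wavenumber ~ (cm^-1)),
                  y = expression(beta)) +
    ggplot2::theme_minimal()
  if (!is.null(selection)) {
    sel <- df[selection$selected, , drop = FALSE]
    p <- p + ggplot2::geom_point(data = sel, color = "forestgreen",
                                 size = 0.9)
  }
  p
}

#' Training history of the network
#'
#' Loss (MSE) per epoch on the training and validation partitions, with
#' the best validation epoch marked.
#'
#' @param object a trained `nir_ann`.
#' @param ... ignored.
#' @method autoplot nir_ann
#' @export
autoplot.nir_ann <- function(object, ...) {
  if (is.null(object$history)) abort("network has not been trained")
  long <- tidyr::pivot_longer(object$history,
                              cols = c("loss", "val_loss"),
                              names_to = "partition", values_to = "mse")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$mse,
                                     color = .data$partition)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = 2) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(y = "MSE") +
    ggplot2::theme_minimal()
}

#' Predicted-vs-reference panels of a calibration run
#'
#' One panel per model and evaluation set is not stored in the report (the
#' predictions are recomputable from the fitted objects); this plot shows
#' the summary metrics instead: R-squared and RPD per model and set.
#'
#' @param object a `nir_run` report.
#' @param ... ignored.
#' @method autoplot nir_run
#' @export
autoplot.nir_run <- function(object, ...) {
  long <- tidyr::pivot_longer(object$metrics,
                              cols = c("r.squared", "rpd"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$model, y = .data$value,
                                     fill = .data$set)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(title = paste("Calibration:", object$response),
                  y = NULL) +
    ggplot2::theme_minimal()
}
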
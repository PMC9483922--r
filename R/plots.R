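# ggplot2 autoplot methods for the package's result types.

#' Plot a per-region potential histogram
#'
#' Line histogram of cell potentials per region, one colored trace per
#' species, normalized to probability per bin.
#'
#' @param object A [region_histogram()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot region_histogram
#' @export
autoplot.region_histogram <- function(object, ...) {
  df <- dplyr::mutate(dplyr::group_by(tibble::as_tibble(object),
                                      .data$region),
                      p = .data$count / sum(.data$count))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin_mid, y = .data$p,
                                   colour = .data$region)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "potential (mV)", y = "probability",
                  colour = "region") +
    ggplot2::theme_minimal()
}

#' Plot a WHAM titration curve
#'
#' Points at the evaluated pH grid with the fitted Henderson-Hasselbalch
#' curve overlaid and the fitted pKa marked.
#'
#' @param object A [titration_curve()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot titration_curve
#' @export
autoplot.titration_curve <- function(object, ...) {
  fit <- attr(object, "fit")
  grid <- tibble::tibble(pH = seq(min(object$pH), max(object$pH),
                                  length.out = 200))
  grid$fraction <- 1 / (1 + 10^(fit$hill * (grid$pH - fit$pKa)))
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$pH, y = .data$fraction)) +
    ggplot2::geom_line(data = grid, colour = "grey40") +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = fit$pKa, linetype = 3) +
    ggplot2::labs(x = "pH", y = "protonated fraction",
                  subtitle = sprintf("fitted pKa = %.2f", fit$pKa)) +
    ggplot2::theme_minimal()
}

#' Plot the bulk potential against the water fraction
#'
#' Scatter of `(f_w, phi_w)` points with the ordinary least squares line;
#' the line extrapolates to zero potential as the box becomes all water.
#'
#' @param object An `fw_fit` from [linear_fit_fw()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot fw_fit
#' @export
autoplot.fw_fit <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$f_w, y = .data$phi_w_mV)) +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "grey40") +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "water volume fraction f_w",
      y = "bulk solvent potential (mV)",
      subtitle = sprintf("phi_w = %.0f f_w %+.0f mV  (R^2 = %.2f, n = %d)",
                         object$slope, object$intercept, object$r_squared,
                         object$n)) +
    ggplot2::theme_minimal()
}
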
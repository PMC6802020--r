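#' Plot a grid raster
#'
#' @param object a [grid_raster].
#' @param ... unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.grid_raster <- function(object, ...) {
  df <- tibble::as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                        fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x", y = "y")
  if (object$categorical) {
    p + ggplot2::scale_fill_viridis_d() +
      ggplot2::aes(fill = factor(.data$value))
  } else {
    p + ggplot2::scale_fill_viridis_c()
  }
}

#' Boxplots of evaluation scores by dataset and strategy
#'
#' @param records evaluation records tibble.
#' @param metric `"auc"` or `"kappa"`.
#' @return A ggplot.
#' @export
plot_evaluations <- function(records, metric = c("auc", "kappa")) {
  metric <- match.arg(metric)
  ggplot2::ggplot(records,
                  ggplot2::aes(x = .data$dataset, y = .data[[metric]],
                               fill = .data$strategy)) +
    ggplot2::geom_boxplot() +
    ggplot2::facet_wrap(~algorithm) +
    ggplot2::labs(y = toupper(metric), x = NULL)
}

#' Response-curve panel for a fitted model
#'
#' @param model an `sdm_model`.
#' @param covariates which covariates to show (default all).
#' @param n_points evaluation points per curve.
#' @return A ggplot.
#' @export
plot_response_curves <- function(model, covariates = model$covariates,
                                 n_points = 50) {
  curves <- purrr::map_dfr(covariates, function(nm)
    response_curve(model, nm, n_points = n_points))
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$value,
                                       y = .data$prediction)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~covariate, scales = "free_x") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "covariate value", y = "mean predicted probability")
}

#' L-function diagnostic plot
#'
#' @param lcurve tibble from [ripley_l()].
#' @return A ggplot of `L(r) - r` with the CSR envelope.
#' @export
plot_ripley_l <- function(lcurve) {
  ggplot2::ggplot(lcurve, ggplot2::aes(x = .data$r)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$l_lower - .data$r,
                                      ymax = .data$l_upper - .data$r),
                         fill = "grey80") +
    ggplot2::geom_line(ggplot2::aes(y = .data$l_obs - .data$r)) +
    ggplot2::labs(x = "r", y = "L(r) - r")
}
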
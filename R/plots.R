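#' Plot methods
#'
#' ggplot2 visualisations for the main result types: radial distribution
#' profiles (g(r) with the cumulative number on a second panel-style
#' overlay), population-decay curves with the fitted exponential, and
#' event-location boxplots.
#'
#' @param object A result object.
#' @param ... Unused.
#' @return A ggplot object.
#' @name nanosite-plots
NULL

#' @rdname nanosite-plots
#' @method autoplot nanosite_rdf
#' @export
autoplot.nanosite_rdf <- function(object, ...) {
  df <- tidyr::pivot_longer(as_tibble(object), c("g", "n_cum"),
                            names_to = "quantity", values_to = "value")
  df$quantity <- factor(df$quantity, c("g", "n_cum"),
                        c("g(r)", "cumulative number N(r)"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$r, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~quantity, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "r (nm)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname nanosite-plots
#' @method autoplot nanosite_decay
#' @export
autoplot.nanosite_decay <- function(object, ...) {
  curve <- object$curve
  pred <- tibble(t_ns = seq(min(curve$t_ns), max(curve$t_ns), length.out = 200))
  pred$n <- object$n0 * exp(-object$lambda * pred$t_ns)
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$t_ns, y = .data$n)) +
    ggplot2::geom_step() +
    ggplot2::geom_line(data = pred, linetype = "dashed", colour = "red") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "existence time (ns)", y = "N(t)",
                  subtitle = sprintf("N0 = %.0f, lambda = %.1f ns^-1",
                                     object$n0, object$lambda)) +
    ggplot2::theme_minimal()
}

#' @rdname nanosite-plots
#' @method autoplot nanosite_events
#' @export
autoplot.nanosite_events <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$kind,
                                       y = .data$median_core_nm)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::labs(x = NULL, y = "median distance from core c.o.m. (nm)") +
    ggplot2::theme_minimal()
}

#' @rdname nanosite-plots
#' @param fit Optional [fit_internal_acf()] overlay.
#' @export
plot_acf <- function(object, fit = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$lag_ps, y = .data$acf)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "lag (ps)", y = expression(C(t))) +
    ggplot2::theme_minimal()
  if (!is.null(fit)) {
    pred <- tibble(lag_ps = object$lag_ps)
    pred$acf <- fit$s2 + fit$a1 * exp(-pred$lag_ps / fit$tau1_ps) +
      fit$a2 * exp(-pred$lag_ps / fit$tau2_ps)
    p <- p + ggplot2::geom_line(data = pred, colour = "red",
                                linetype = "dashed")
  }
  p
}
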
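long_measures <- function(df, cols) {
  tidyr::pivot_longer(df, dplyr::all_of(cols), names_to = "measure",
                      values_to = "value")
}

#' Plot methods
#'
#' `autoplot()` methods for the package's result objects: trajectories and
#' ensembles show `q_i(t)` and `q_i^f(t)` per opinion (ensembles with a
#' plus/minus one standard deviation ribbon), media sweeps show the
#' steady-state shares against the media strength with the located critical
#' points, and decompositions show the four components of the media opinion's
#' final share.
#'
#' @param object A result object from this package.
#' @param ... Unused.
#' @return A ggplot object.
#' @name opinionet-autoplot
NULL

#' @rdname opinionet-autoplot
#' @exportS3Method
autoplot.opinion_trajectory <- function(object, ...) {
  df <- long_measures(strip_result(object), c("q", "qf"))
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$value,
                                   colour = factor(.data$opinion))) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~measure, labeller = ggplot2::as_labeller(
      c(q = "population fraction q", qf = "weighted fraction q^f"))) +
    ggplot2::labs(x = "time (units of ~N regular updates)", y = NULL,
                  colour = "opinion")
}

#' @rdname opinionet-autoplot
#' @exportS3Method
autoplot.opinion_ensemble <- function(object, ...) {
  df <- strip_result(object)
  df <- tidyr::pivot_longer(df, c("q_mean", "qf_mean"), names_to = "measure",
                            values_to = "mean")
  df$sd <- ifelse(df$measure == "q_mean", df$q_sd, df$qf_sd)
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$mean,
                                   colour = factor(.data$opinion),
                                   fill = factor(.data$opinion))) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd),
                         alpha = 0.15, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~measure, labeller = ggplot2::as_labeller(
      c(q_mean = "population fraction q", qf_mean = "weighted fraction q^f"))) +
    ggplot2::labs(x = "time (units of ~N regular updates)", y = NULL,
                  colour = "opinion", fill = "opinion")
}

#' @rdname opinionet-autoplot
#' @exportS3Method
autoplot.meanfield_trajectory <- function(object, ...) {
  df <- long_measures(strip_result(object), c("q", "qf"))
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$value,
                                   colour = factor(.data$opinion))) +
    ggplot2::geom_line(linetype = "dashed") +
    ggplot2::facet_wrap(~measure) +
    ggplot2::labs(x = "time", y = NULL, colour = "opinion",
                  title = "Degree-class mean field")
}

#' @rdname opinionet-autoplot
#' @exportS3Method
autoplot.media_sweep <- function(object, ...) {
  df <- strip_result(object)
  cr <- attr(object, "crossings")
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$P, .data$q_inf,
                                        colour = factor(.data$opinion))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "media strength P", y = "steady-state share q(∞)",
                  colour = "opinion")
  if (!is.null(cr) && nrow(cr) && any(is.finite(cr$P_star))) {
    p <- p + ggplot2::geom_vline(xintercept = cr$P_star[is.finite(cr$P_star)],
                                 linetype = "dotted")
  }
  p
}

#' @rdname opinionet-autoplot
#' @exportS3Method
autoplot.media_decomposition <- function(object, ...) {
  df <- strip_result(object)
  df$part <- factor(df$part, levels = df$part)
  ggplot2::ggplot(df, ggplot2::aes(.data$part, .data$value)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "contribution to the media opinion's share")
}
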
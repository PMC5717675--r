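#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

strip_result <- function(x) {
  tibble::as_tibble(unclass(x)[seq_along(x)])
}

#' Tidy and summarize simulation and prediction objects
#'
#' `tidy()` returns the underlying tibble of any result object (long format,
#' one row per time/opinion or per part); `glance()` returns a one-row
#' summary.
#'
#' @param x A result object from this package.
#' @param ... Unused.
#' @return A tibble.
#' @name opinionet-tidiers
NULL

#' @rdname opinionet-tidiers
#' @exportS3Method
tidy.opinion_trajectory <- function(x, ...) strip_result(x)

#' @rdname opinionet-tidiers
#' @exportS3Method
tidy.opinion_ensemble <- function(x, ...) strip_result(x)

#' @rdname opinionet-tidiers
#' @exportS3Method
tidy.meanfield_trajectory <- function(x, ...) strip_result(x)

#' @rdname opinionet-tidiers
#' @exportS3Method
tidy.media_sweep <- function(x, ...) strip_result(x)

#' @rdname opinionet-tidiers
#' @exportS3Method
tidy.media_decomposition <- function(x, ...) strip_result(x)

#' @rdname opinionet-tidiers
#' @exportS3Method
tidy.opinion_prediction <- function(x, ...) {
  dplyr::mutate(strip_result(x), regime = attr(x, "regime"))
}

#' @rdname opinionet-tidiers
#' @exportS3Method
glance.opinion_trajectory <- function(x, ...) {
  last <- dplyr::filter(strip_result(x), .data$time == max(.data$time))
  lead <- last$opinion[which.max(last$q)]
  tibble::tibble(t_end = max(x$time), n_opinions = max(x$opinion),
                 leading_opinion = lead, leading_q = max(last$q))
}

#' @rdname opinionet-tidiers
#' @exportS3Method
glance.opinion_ensemble <- function(x, ...) {
  last <- dplyr::filter(strip_result(x), .data$time == max(.data$time))
  lead <- last$opinion[which.max(last$q_mean)]
  tibble::tibble(t_end = max(x$time), n_opinions = max(x$opinion),
                 n_realizations = attr(x, "n_realizations"),
                 leading_opinion = lead, leading_q_mean = max(last$q_mean))
}

#' @rdname opinionet-tidiers
#' @exportS3Method
glance.opinion_prediction <- function(x, ...) {
  tibble::tibble(regime = attr(x, "regime"), n_opinions = nrow(x),
                 n_surviving = sum(x$q_inf > 0),
                 leading_opinion = x$opinion[which.max(x$q_inf)])
}

#' @rdname opinionet-tidiers
#' @exportS3Method
glance.media_sweep <- function(x, ...) {
  cr <- attr(x, "crossings")
  tibble::tibble(media_opinion = attr(x, "media_opinion"),
                 n_grid = length(unique(x$P)),
                 P_star_min = if (nrow(cr)) suppressWarnings(min(cr$P_star, na.rm = TRUE)) else NA_real_)
}

#' @rdname opinionet-tidiers
#' @exportS3Method
glance.media_decomposition <- function(x, ...) {
  tibble::tibble(media_opinion = attr(x, "media_opinion"),
                 strength = attr(x, "strength"), q_inf_media = sum(x$value))
}
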
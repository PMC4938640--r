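# broom-style tidiers and autoplot methods for fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a decay fit
#'
#' @param x A `decay_fit` object.
#' @param ... Unused.
#' @return One-row tibble with `term`, `estimate` (lambda, min^-1) and the
#'   derived half-life.
#' @export
tidy.decay_fit <- function(x, ...) {
  tibble::tibble(term = "lambda", estimate = x$lambda,
                 t_half = x$t_half, t_half_sd = x$t_half_sd)
}

#' One-row summary of a decay fit
#'
#' @param x A `decay_fit` object.
#' @param ... Unused.
#' @return Tibble with `lambda`, `t_half`, `ssr`, `df`, `n_points`.
#' @export
glance.decay_fit <- function(x, ...) {
  tibble::tibble(lambda = x$lambda, t_half = x$t_half, ssr = x$ssr,
                 df = x$df, n_points = x$n_points)
}

#' Tidy a decay-curve comparison
#'
#' @param x A `curve_comparison` object.
#' @param ... Unused.
#' @return One-row tibble with the F statistic, degrees of freedom and
#'   p-value.
#' @export
tidy.curve_comparison <- function(x, ...) {
  tibble::tibble(curve_a = x$labels[1], curve_b = x$labels[2],
                 lambda_a = x$fitA$lambda, lambda_b = x$fitB$lambda,
                 F_stat = x$F_stat, df1 = x$df1, df2 = x$df2,
                 p_value = x$p_value)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a decay fit
#'
#' Percent-remaining points (by replicate when available) with the fitted
#' first-order decay curve overlaid.
#'
#' @param object A `decay_fit` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.decay_fit <- function(object, ...) {
  dat <- object$data
  if (!"replicate" %in% names(dat)) dat$replicate <- 1L
  grid <- tibble::tibble(
    time_min = seq(0, max(dat$time_min), length.out = 200))
  grid$pct <- object$amplitude * exp(-object$lambda * grid$time_min)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$time_min,
                                    y = .data$pct_remaining)) +
    ggplot2::geom_point(ggplot2::aes(shape = factor(.data$replicate)),
                        size = 2) +
    ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$pct),
                       color = "deeppink") +
    ggplot2::labs(x = "chase time (min)", y = "% remaining",
                  shape = "replicate",
                  subtitle = sprintf("t1/2 = %.2f min", object$t_half)) +
    ggplot2::theme_minimal()
}
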
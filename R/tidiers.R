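#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @export
tidy.power_law_fit <- function(x, ...) {
  tibble::tibble(term = c("alpha", "D", "D_s"),
                 estimate = c(x$alpha, x$D, x$D_s),
                 std.error = c(x$alpha_se, NA, NA))
}

#' @export
glance.power_law_fit <- function(x, ...) {
  tibble::tibble(alpha = x$alpha, D = x$D, D_s = x$D_s, rss = x$rss,
                 n_points = x$n_points,
                 window_min = x$window[1], window_max = x$window[2],
                 regime = as.character(classify_regime(x$alpha)))
}

#' @export
tidy.biexp_fit <- function(x, ...) {
  tibble::tibble(term = c("A", "tau_fast", "tau_slow"),
                 estimate = c(x$A, x$tau_fast, x$tau_slow))
}

#' @export
glance.biexp_fit <- function(x, ...) {
  tibble::tibble(A = x$A, tau_fast = x$tau_fast, tau_slow = x$tau_slow,
                 rss = x$rss, n = x$n, degenerate = x$degenerate)
}

#' @export
tidy.residence_result <- function(x, ...) {
  tibble::tibble(term = c("tau_residence", "tau_escape", "amplitude_fast"),
                 estimate = c(x$tau_residence, x$tau_escape, x$amplitude_fast))
}

#' @export
glance.residence_result <- function(x, ...) {
  tibble::tibble(tau_residence = x$tau_residence, tau_escape = x$tau_escape,
                 rss = x$rss, degenerate = x$degenerate)
}

#' @export
tidy.relaxation_time <- function(x, ...) {
  tibble::tibble(term = c("tau_R", "tau_trapz", "tau_tail", "tau_exp_fit"),
                 estimate = c(x$tau_R, x$tau_trapz, x$tau_tail, x$tau_exp_fit))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
autoplot.msd_result <- function(object, log = TRUE, ...) {
  df <- tibble::as_tibble(object)
  df <- df[df$time > 0 & is.finite(df$msd), ]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$msd)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::labs(x = "lag time (ps)", y = expression(MSD ~ (ring(A)^2)),
                  title = paste("MSD, layer:", attr(object, "layer"))) +
    ggplot2::theme_minimal()
  if (log) p <- p + ggplot2::scale_x_log10() + ggplot2::scale_y_log10()
  p
}

#' @export
autoplot.corr_series <- function(object, log_y = FALSE, ...) {
  df <- tibble::as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (ps)", y = attr(object, "label") %||% "C(t)") +
    ggplot2::theme_minimal()
  if (log_y) p <- p + ggplot2::scale_y_log10()
  p
}

#' @export
autoplot.van_hove_result <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$r, y = .data$density,
                                   colour = factor(.data$lag_time))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "r (Å)", y = expression(G[s](r, t)),
                  colour = "lag (ps)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.shape_series <- function(object, ...) {
  df <- tibble::as_tibble(object) |>
    tidyr::pivot_longer(c("Rg", "rmsd"), names_to = "metric")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "time (ps)", y = "Å") +
    ggplot2::theme_minimal()
}
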
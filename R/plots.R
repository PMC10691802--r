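#' Plot a staircase trajectory
#'
#' Opacity trace over trials with reversal trials marked and the converged
#' threshold as a horizontal line.
#'
#' @param x A `staircase_result`.
#' @return A ggplot object.
#' @export
plot_staircase <- function(x) {
  stopifnot(inherits(x, "staircase_result"))
  d <- tibble::tibble(trial = seq_along(x$opacity_trace),
                      opacity = x$opacity_trace)
  rev_d <- d[x$reversal_indices, ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$trial, y = .data$opacity)) +
    ggplot2::geom_line(color = "grey40") +
    ggplot2::geom_point(data = rev_d, color = "firebrick", size = 1.2) +
    ggplot2::geom_hline(yintercept = x$threshold, linetype = 2) +
    ggplot2::labs(x = "Trial", y = "Opacity",
                  title = sprintf("Weighted up-down staircase (threshold %.3f)",
                                  x$threshold)) +
    ggplot2::theme_minimal()
}

#' Posterior densities of group-level DDM regression coefficients
#'
#' @param object A `ddm_fit`.
#' @param parameters Parameters to show (default: the drift-rate
#'   coefficients).
#' @param ... Unused.
#' @return A ggplot object.
#' @importFrom ggplot2 autoplot
#' @export
autoplot.ddm_fit <- function(object,
                             parameters = c("v_drug", "v_validity",
                                            "v_drug:validity"), ...) {
  d <- posterior_draws(object, parameters)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$value,
                                  fill = .data$parameter)) +
    ggplot2::geom_density(alpha = 0.5, color = NA) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "Coefficient (evidence/s)", y = "Posterior density") +
    ggplot2::theme_minimal()
}

#' Plot condition-average ERP traces
#'
#' @param erp Long tibble from [erp_table()] (columns `time`, `value`, plus
#'   optional grouping column).
#' @param color Optional column name to color by.
#' @return A ggplot object.
#' @export
plot_erp <- function(erp, color = NULL) {
  aes <- if (is.null(color)) {
    ggplot2::aes(x = .data$time, y = .data$value)
  } else {
    ggplot2::aes(x = .data$time, y = .data$value,
                 color = .data[[color]])
  }
  erp |>
    dplyr::group_by(dplyr::across(dplyr::any_of(c("time", color)))) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop") |>
    ggplot2::ggplot(aes) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = 3) +
    ggplot2::labs(x = "Time (s)", y = "Amplitude") +
    ggplot2::theme_minimal()
}

#' Plot an alpha lateralization time course
#'
#' @param lat Tibble from [alpha_lateralization()].
#' @return A ggplot object showing trial-average contra, ipsi and their
#'   difference.
#' @export
plot_alpha_lateralization <- function(lat) {
  lat |>
    dplyr::group_by(.data$time) |>
    dplyr::summarise(contra = mean(.data$contra), ipsi = mean(.data$ipsi),
                     lateralization = mean(.data$lateralization)) |>
    tidyr::pivot_longer(-"time") |>
    ggplot2::ggplot(ggplot2::aes(x = .data$time, y = .data$value,
                                 color = .data$name)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::labs(x = "Time (s)", y = "Alpha power (dB)", color = NULL) +
    ggplot2::theme_minimal()
}
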
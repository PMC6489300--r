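#' Power curve across sample sizes
#'
#' Mean marginal power as a function of total sample size, one colour per
#' target effect size, with error bars at the 2.5th and 97.5th
#' across-replicate percentiles and a horizontal reference line at the
#' conventional 80% power goal.
#'
#' @param object A [`meth_power`][power_ewas] object.
#' @param power_goal Reference line position (default 0.8).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.meth_power <- function(object, power_goal = 0.8, ...) {
  df <- object$summary |>
    dplyr::mutate(effect = factor(.data$target_delta))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n_total,
                                   y = .data$marginal_power,
                                   colour = .data$effect)) +
    ggplot2::geom_hline(yintercept = power_goal, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$power_lo,
                                        ymax = .data$power_hi),
                           width = 4, alpha = 0.7) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Total sample size", y = "Marginal power",
                  colour = "Target Δβ") +
    ggplot2::theme_bw()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @rdname autoplot.meth_power
#' @param result A [`meth_power`][power_ewas] object.
#' @param path Optional file path (png/svg/pdf); when given the figure is
#'   saved there and the path returned invisibly.
#' @export
plot_power_curve <- function(result, path = NULL, power_goal = 0.8) {
  p <- autoplot(result, power_goal = power_goal)
  if (!is.null(path)) {
    dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
    ggplot2::ggsave(path, p, width = 7, height = 5)
    return(invisible(path))
  }
  p
}

#' Density of simulated effect sizes
#'
#' Kernel densities of the truncated-normal effect-size draws, one colour
#' per target effect size, matching the colours of the power curve. Shows
#' what a chosen target maximal difference implies for the full effect
#' distribution (most effects are much smaller than the target).
#'
#' @param result A [`meth_power`][power_ewas] object.
#' @param path Optional file path; when given the figure is saved.
#' @return A ggplot object, or `path` invisibly.
#' @export
plot_delta_density <- function(result, path = NULL) {
  df <- purrr::imap(result$deltas,
                    ~ tibble::tibble(effect = .y, delta = .x)) |>
    dplyr::bind_rows() |>
    dplyr::mutate(effect = factor(.data$effect,
                                  levels = names(result$deltas)))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$delta,
                                        colour = .data$effect)) +
    ggplot2::geom_density() +
    ggplot2::labs(x = "Simulated Δβ", y = "Density",
                  colour = "Target Δβ") +
    ggplot2::theme_bw()
  if (!is.null(path)) {
    dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
    ggplot2::ggsave(path, p, width = 7, height = 5)
    return(invisible(path))
  }
  p
}
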
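#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a power-analysis result into long format
#'
#' One row per grid cell and metric: `n_total`, `target_delta`, `metric`,
#' `mean`, and for the marginal power the 2.5th/97.5th percentile band
#' (`p2.5`, `p97.5`; `NA` for other metrics). This is the layout written to
#' `power_grid.tsv` by [write_power_report()].
#'
#' @param x A [`meth_power`][power_ewas] object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.meth_power <- function(x, ...) {
  long <- x$summary |>
    tidyr::pivot_longer(
      cols = c("classical_power", "marginal_power", "marginal_type1",
               "fdr", "fdc", "prob_detect_one"),
      names_to = "metric", values_to = "mean"
    ) |>
    dplyr::mutate(
      `p2.5` = dplyr::if_else(.data$metric == "marginal_power",
                              .data$power_lo, NA_real_),
      `p97.5` = dplyr::if_else(.data$metric == "marginal_power",
                               .data$power_hi, NA_real_)
    ) |>
    dplyr::select("n_total", "target_delta", "metric", "mean",
                  "p2.5", "p97.5")
  long
}

#' Glance at a power-analysis result
#'
#' One row per target effect size: the calibrated `tau`, the number of
#' shifted CpGs `k`, the truly-DM fraction, the maximum mean marginal power
#' reached on the sample-size grid, and the smallest grid sample size whose
#' mean marginal power reaches `power_goal` (`NA` when never reached).
#'
#' @param x A [`meth_power`][power_ewas] object.
#' @param power_goal Power threshold used for `n_at_goal` (default 0.8).
#' @param ... Unused.
#' @return A tibble with one row per effect size.
#' @export
glance.meth_power <- function(x, power_goal = 0.8, ...) {
  att <- x$summary |>
    dplyr::group_by(.data$target_delta) |>
    dplyr::summarise(
      max_power = max(.data$marginal_power, na.rm = TRUE),
      n_at_goal = {
        hit <- .data$n_total[!is.na(.data$marginal_power) &
                               .data$marginal_power >= power_goal]
        if (length(hit) == 0) NA_integer_ else as.integer(min(hit))
      },
      .groups = "drop"
    )
  x$effects |>
    dplyr::select(target_delta = "value", "tau", "k",
                  "truly_dm_fraction") |>
    dplyr::left_join(att, by = "target_delta")
}
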
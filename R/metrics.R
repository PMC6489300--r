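#' Confusion counts for one tested replicate
#'
#' Crosses detection calls with the simulated truth taxonomy. Each CpG falls
#' in exactly one of six categories:
#' detected/truly-DM = TP, detected/negligible = NP (neutral positive),
#' detected/null = FP, undetected/null = TN,
#' undetected/negligible = NN (neutral negative), undetected/truly-DM = FN.
#'
#' @param detected Logical vector of detection calls.
#' @param truth Factor from [classify_truth()] (levels `null`, `negligible`,
#'   `truly_dm`), same length.
#' @return One-row tibble with integer columns `TP`, `NP`, `FP`, `TN`, `NN`,
#'   `FN`; they always sum to `length(detected)`.
#' @export
#' @examples
#' confusion_counts(c(TRUE, TRUE, TRUE),
#'                  classify_truth(c(0.05, 0.005, 0)))
confusion_counts <- function(detected, truth) {
  stopifnot(length(detected) == length(truth))
  truth <- factor(truth, levels = c("null", "negligible", "truly_dm"))
  tibble::tibble(
    TP = sum(detected & truth == "truly_dm"),
    NP = sum(detected & truth == "negligible"),
    FP = sum(detected & truth == "null"),
    TN = sum(!detected & truth == "null"),
    NN = sum(!detected & truth == "negligible"),
    FN = sum(!detected & truth == "truly_dm")
  )
}

#' Power and error metrics from confusion counts
#'
#' The five reported ratios plus a flag for whether the replicate found any
#' true positive:
#' * `classical_power = (NP + TP) / (NP + NN + TP + FN)` — detected among all
#'   CpGs with any nonzero effect;
#' * `marginal_power = TP / (TP + FN)` — detected among truly DM CpGs only;
#' * `marginal_type1 = FP / (FP + TN)` — detected among null CpGs;
#' * `fdr = FP / (FP + NP + TP)` — wrongly detected among all detections;
#' * `fdc = FP / TP` — false discovery cost, wrongly detected per correctly
#'   detected CpG.
#'
#' Ratios with zero denominator are undefined and returned as `NA` (`fdc`
#' with `TP = 0` and `FP > 0` is `Inf`); [aggregate_metrics()] excludes
#' non-finite values from cell means rather than silently coercing them to
#' zero, which would bias power estimates.
#'
#' @param counts One-row tibble (or list) with `TP`, `NP`, `FP`, `TN`, `NN`,
#'   `FN`.
#' @return One-row tibble with the six counts, the five metrics and `any_tp`.
#' @export
#' @examples
#' power_metrics(confusion_counts(c(TRUE, FALSE), classify_truth(c(0.05, 0))))
power_metrics <- function(counts) {
  ratio <- function(num, den) ifelse(den == 0, NA_real_, num / den)
  with(counts, tibble::tibble(
    TP = TP, NP = NP, FP = FP, TN = TN, NN = NN, FN = FN,
    classical_power = ratio(NP + TP, NP + NN + TP + FN),
    marginal_power = ratio(TP, TP + FN),
    marginal_type1 = ratio(FP, FP + TN),
    fdr = ratio(FP, FP + NP + TP),
    fdc = dplyr::case_when(TP > 0 ~ FP / TP,
                           FP > 0 ~ Inf,
                           TRUE ~ NA_real_),
    any_tp = TP >= 1
  ))
}

#' Aggregate replicate metrics into a grid-cell summary
#'
#' Averages each metric across simulation replicates; for the marginal power
#' it also reports the 2.5th and 97.5th percentiles (linear interpolation
#' between order statistics) and the probability of detecting at least one
#' true positive (fraction of replicates with `any_tp`). Undefined (`NA`) and
#' infinite replicate values are excluded from the means; the number of
#' replicates with an undefined false discovery cost is reported as
#' `n_fdc_undefined`.
#'
#' @param reps Tibble of per-replicate rows from [power_metrics()], possibly
#'   with grouping columns (e.g. `n_total`, `target_delta`).
#' @param ... Grouping columns (tidy-select), e.g.
#'   `aggregate_metrics(reps, n_total, target_delta)`.
#' @return One summary row per group: metric means, `power_lo` / `power_hi`
#'   percentile band of the marginal power, `prob_detect_one`, `n_sims`.
#' @export
aggregate_metrics <- function(reps, ...) {
  mean_fin <- function(x) {
    x <- x[is.finite(x)]
    if (length(x) == 0) NA_real_ else mean(x)
  }
  reps |>
    dplyr::group_by(...) |>
    dplyr::summarise(
      # percentile band and the undefined-FDC count must be computed before
      # the same-named means: summarise exposes new columns to later
      # expressions
      power_lo = stats::quantile(.data$marginal_power[
        is.finite(.data$marginal_power)], 0.025, names = FALSE, type = 7),
      power_hi = stats::quantile(.data$marginal_power[
        is.finite(.data$marginal_power)], 0.975, names = FALSE, type = 7),
      n_fdc_undefined = sum(!is.finite(.data$fdc)),
      classical_power = mean_fin(.data$classical_power),
      marginal_power = mean_fin(.data$marginal_power),
      marginal_type1 = mean_fin(.data$marginal_type1),
      fdr = mean_fin(.data$fdr),
      fdc = mean_fin(.data$fdc),
      prob_detect_one = mean(.data$any_tp),
      n_sims = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::relocate("power_lo", "power_hi", .after = "marginal_power") |>
    dplyr::relocate("n_fdc_undefined", .after = "fdc")
}
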
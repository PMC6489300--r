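#' Serialize a power-analysis result to disk
#'
#' Writes into `dir`:
#' * `power_grid.tsv` — the tidy long-format summary from
#'   [tidy.meth_power()];
#' * `power_grid.json` — the per-cell summary, calibrated effects and every
#'   result-determining config field (seed included), for full
#'   reproducibility; byte-identical across repeated runs of the same
#'   configuration and seed regardless of thread count;
#' * `run.log` — config echo plus wall time per grid cell (execution
#'   details such as thread count and timings live here, not in the JSON);
#' * optionally `power_curve.png` and `delta_density.png`.
#'
#' @param result A [`meth_power`][power_ewas] object.
#' @param dir Output directory (created if needed).
#' @param plots Also write the two figures (default TRUE).
#' @param threads_used Recorded in `run.log` only.
#' @return `dir`, invisibly.
#' @export
write_power_report <- function(result, dir, plots = TRUE,
                               threads_used = NA_integer_) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  readr::write_tsv(tidy(result), file.path(dir, "power_grid.tsv"))

  payload <- list(
    config = result$config,
    effects = result$effects,
    summary = result$summary
  )
  jsonlite::write_json(payload, file.path(dir, "power_grid.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  log_lines <- c(
    paste0("methpower run log — ", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    paste0("threads: ", threads_used),
    "config:",
    paste0("  ", names(result$config), " = ",
           vapply(result$config, function(v) paste(v, collapse = ","),
                  character(1))),
    "cell wall times (s):",
    sprintf("  delta=%g n=%d: %.2f", result$timing$target_delta,
            result$timing$n_total, result$timing$seconds)
  )
  writeLines(log_lines, file.path(dir, "run.log"))

  if (plots) {
    plot_power_curve(result, file.path(dir, "power_curve.png"))
    plot_delta_density(result, file.path(dir, "delta_density.png"))
  }
  invisible(dir)
}
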
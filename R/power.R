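#' Monte-Carlo power analysis over a sample-size by effect-size grid
#'
#' The main entry point. For each target effect size, the effect-size spread
#' `tau` and the number of shifted CpGs `k` are calibrated once against the
#' panel ([resolve_effect()]). Then for every total sample size and
#' simulation replicate, a two-group study is simulated
#' ([simulate_study()]), tested ([dm_test()]), classified against the ground
#' truth and summarised into power and error metrics ([power_metrics()]),
#' which are finally averaged per grid cell with percentile bands
#' ([aggregate_metrics()]).
#'
#' Replicates are dispatched over `threads` forked workers; every replicate
#' re-seeds its own RNG stream from a seed derived deterministically from
#' `seed` and the replicate's grid position, so results are bit-identical
#' for any thread count.
#'
#' @param panel A [`meth_panel`][as_meth_panel] (see [load_panel()],
#'   [estimate_panel()], [synth_panel()]).
#' @param n_total Integer vector of total sample sizes (both groups
#'   combined), e.g. `seq(20, 260, by = 40)`.
#' @param target_delta Numeric vector of target maximal differences in mean
#'   beta-values, each in (0, 1). Exactly one of `target_delta` / `tau`.
#' @param tau Numeric vector of user-supplied effect-size standard
#'   deviations (skips calibration).
#' @param target_dm_cpgs Target number of truly differentially methylated
#'   CpGs among the `p_cpgs` tested.
#' @param p_cpgs Number of CpGs simulated and tested per replicate
#'   (default 100000, the usual post-filtering scale of a 450K EWAS; set to
#'   866836 for a full EPIC array).
#' @param group1_fraction Fraction of `n_total` allocated to group 1
#'   (default 0.5, a balanced design).
#' @param fdr_target FDR threshold for detection (default 0.05).
#' @param detection_limit Smallest biologically meaningful |effect|
#'   (default 0.01).
#' @param method Differential methylation test; see [dm_test()].
#' @param n_sims Simulation replicates per grid cell (default 50; the
#'   variance of the power estimate stabilizes near that count).
#' @param threads Forked workers for the replicate loop (default 1).
#' @param seed Master integer seed.
#' @param calib_reps,calib_draws Calibration effort passed to
#'   [resolve_effect()]; `calib_draws` defaults to `p_cpgs`.
#' @param n_density_draws Effect-size draws stored per target for
#'   [plot_delta_density()].
#'
#' @return An object of class `meth_power`: a list with
#'   * `summary` — one tibble row per (n_total, target_delta) cell with
#'     metric means, the 2.5/97.5 marginal-power percentile band and the
#'     probability of at least one true positive;
#'   * `replicates` — the per-replicate metric rows;
#'   * `effects` — the calibrated `tau`, `k` and truly-DM fraction per
#'     target;
#'   * `deltas` — stored effect-size draws for density plots;
#'   * `config` — every result-determining setting;
#'   * `timing` — wall time per grid cell (seconds).
#' @export
#' @examples
#' pan <- synth_panel(2000, seed = 1)
#' pw <- power_ewas(pan, n_total = c(20, 60), target_delta = 0.2,
#'                  target_dm_cpgs = 50, p_cpgs = 2000, n_sims = 3,
#'                  calib_reps = 5, seed = 1)
#' pw$summary
power_ewas <- function(panel, n_total,
                       target_delta = NULL, tau = NULL,
                       target_dm_cpgs,
                       p_cpgs = 100000,
                       group1_fraction = 0.5,
                       fdr_target = 0.05,
                       detection_limit = 0.01,
                       method = c("limma", "cpgassoc", "ttest", "wilcoxon"),
                       n_sims = 50,
                       threads = 1L,
                       seed = 1L,
                       calib_reps = 100L,
                       calib_draws = NULL,
                       n_density_draws = 10000L) {
  method <- match.arg(method)
  if (is.null(target_delta) == is.null(tau)) {
    stop("provide exactly one of `target_delta` or `tau`", call. = FALSE)
  }
  stopifnot(all(n_total >= 4), n_sims >= 1, p_cpgs >= target_dm_cpgs)
  if (!is.null(target_delta)) {
    stopifnot(all(target_delta > 0), all(target_delta < 1))
  }
  calib_draws <- calib_draws %||% p_cpgs
  effect_values <- target_delta %||% tau
  effect_mode <- if (is.null(tau)) "target_delta" else "tau"
  seed <- as.integer(seed)

  config <- list(
    source_label = attr(panel, "source_label") %||% "",
    panel_cpgs = nrow(panel),
    n_total = as.integer(n_total),
    effect_mode = effect_mode,
    effect_values = effect_values,
    target_dm_cpgs = as.integer(target_dm_cpgs),
    p_cpgs = as.integer(p_cpgs),
    group1_fraction = group1_fraction,
    fdr_target = fdr_target,
    detection_limit = detection_limit,
    method = method,
    n_sims = as.integer(n_sims),
    seed = seed,
    calib_reps = as.integer(calib_reps),
    calib_draws = as.integer(calib_draws)
  )

  effects <- vector("list", length(effect_values))
  deltas <- list()
  rep_rows <- list()
  timing <- list()

  for (d_i in seq_along(effect_values)) {
    eff_args <- list(panel = panel, target_dm_cpgs = target_dm_cpgs,
                     detection_limit = detection_limit,
                     p_cpgs = calib_draws, calib_reps = calib_reps,
                     seed = derive_seed(seed, d_i, 0L, 0L))
    eff_args[[effect_mode]] <- effect_values[d_i]
    eff <- do.call(resolve_effect, eff_args)
    effects[[d_i]] <- eff

    # stored draws for the effect-size density plot
    deltas[[as.character(effect_values[d_i])]] <- withr_seed(
      derive_seed(seed, d_i, 0L, 1L), {
        idx <- sample.int(nrow(panel), n_density_draws, replace = TRUE)
        sample_deltas(panel$mean[idx], panel$variance[idx], eff$tau)
      })

    for (n_i in seq_along(n_total)) {
      n <- n_total[n_i]
      t0 <- proc.time()[["elapsed"]]
      one_rep <- function(r) {
        sim <- simulate_study(panel, eff, n_total = n,
                              group1_fraction = group1_fraction,
                              p_cpgs = p_cpgs,
                              seed = derive_seed(seed, d_i, n_i, r))
        res <- dm_test(sim, method = method, fdr_target = fdr_target)
        m <- power_metrics(confusion_counts(res$detected, sim$truth))
        m$replicate <- r
        m
      }
      reps <- if (threads > 1L) {
        parallel::mclapply(seq_len(n_sims), one_rep, mc.cores = threads)
      } else {
        lapply(seq_len(n_sims), one_rep)
      }
      cell <- dplyr::bind_rows(reps)
      cell$n_total <- n
      cell$target_delta <- effect_values[d_i]
      rep_rows[[length(rep_rows) + 1L]] <- cell
      timing[[length(timing) + 1L]] <- tibble::tibble(
        n_total = n, target_delta = effect_values[d_i],
        seconds = proc.time()[["elapsed"]] - t0
      )
      message(sprintf(
        "[methpower] delta=%g n=%d: %d replicates, mean marginal power %.3f",
        effect_values[d_i], n, n_sims,
        mean(cell$marginal_power, na.rm = TRUE)))
    }
  }

  replicates <- dplyr::bind_rows(rep_rows) |>
    dplyr::relocate("n_total", "target_delta", "replicate")
  summary <- aggregate_metrics(replicates, .data$target_delta, .data$n_total)

  structure(
    list(summary = summary,
         replicates = replicates,
         effects = dplyr::bind_rows(effects) |>
           dplyr::mutate(value = effect_values, .before = 1),
         deltas = deltas,
         config = config,
         timing = dplyr::bind_rows(timing)),
    class = "meth_power"
  )
}

#' @export
print.meth_power <- function(x, ...) {
  cfg <- x$config
  cat("<meth_power> ", length(cfg$n_total), " sample size(s) x ",
      length(cfg$effect_values), " effect size(s), ", cfg$n_sims,
      " replicates, method '", cfg$method, "', P=", cfg$p_cpgs, "\n",
      sep = "")
  print(x$summary)
  invisible(x)
}

# deterministic per-replicate seed; kept below 2^31 - 1
derive_seed <- function(seed, delta_i, n_i, rep) {
  as.integer((as.double(seed %% 100000L) * 1009 +
                delta_i * 2466251 + n_i * 51407 + rep * 13) %%
               2147483629)
}
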
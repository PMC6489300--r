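#' Feasible effect-size bounds for a CpG
#'
#' A shift `delta` of a CpG's mean beta-value is only simulatable if the
#' shifted mean still admits a beta distribution with the CpG's (unchanged)
#' variance, i.e. `variance < (mean + delta) * (1 - mean - delta)`, and the
#' shifted mean stays inside (0, 1). Solving the quadratic gives the interval
#' `1/2 - mean +/- sqrt(1/4 - variance)`, intersected with
#' `(-mean, 1 - mean)`. The interval is open: boundary shifts make the
#' variance exactly maximal and are excluded. Because the panel constraint
#' `variance < mean * (1 - mean)` holds, the interval always contains 0.
#'
#' @param mean,variance Numeric vectors of per-CpG means in (0, 1) and
#'   variances in (0, 0.25); recycled to common length.
#'
#' @return A tibble with columns `lower` and `upper`.
#' @export
#' @examples
#' delta_bounds(0.3, 0.09)  # (-0.2, 0.6)
delta_bounds <- function(mean, variance) {
  n <- max(length(mean), length(variance))
  mean <- rep_len(mean, n)
  variance <- rep_len(variance, n)
  if (any(variance >= 0.25)) {
    stop("variance must be < 0.25 for any beta distribution", call. = FALSE)
  }
  if (any(!panel_feasible(mean, variance))) {
    stop("(mean, variance) must satisfy 0 < mean < 1 and ",
         "variance < mean * (1 - mean)", call. = FALSE)
  }
  s <- sqrt(0.25 - variance)
  tibble::tibble(
    lower = pmax(0.5 - mean - s, -mean),
    upper = pmin(0.5 - mean + s, 1 - mean)
  )
}

#' Draw truncated-normal effect sizes with per-CpG feasibility bounds
#'
#' Each effect is drawn from `Normal(0, tau^2)` truncated to that CpG's
#' feasible interval from [delta_bounds()], by inverse-CDF sampling.
#' Truncation is per-CpG: all CpGs share one `tau` but each has its own
#' bounds. Draws are clamped strictly inside the open interval so the shifted
#' mean always admits a valid beta distribution.
#'
#' @param mean,variance Per-CpG moments (recycled to common length `k`).
#' @param tau Standard deviation of the untruncated normal (> 0).
#' @param seed Optional integer seed; when given, draws are deterministic.
#'
#' @return Numeric vector of `k` effect sizes, each strictly inside its
#'   CpG's feasible interval.
#' @export
sample_deltas <- function(mean, variance, tau, seed = NULL) {
  stopifnot(tau > 0)
  b <- delta_bounds(mean, variance)
  draw <- function() {
    plo <- stats::pnorm(b$lower, 0, tau)
    phi <- stats::pnorm(b$upper, 0, tau)
    u <- stats::runif(nrow(b), plo, phi)
    d <- stats::qnorm(u, 0, tau)
    # keep strictly inside the open feasibility interval
    eps <- 1e-12 + 1e-9 * abs(b$upper - b$lower)
    pmin(pmax(d, b$lower + eps), b$upper - eps)
  }
  if (is.null(seed)) draw() else withr_seed(seed, draw())
}

#' Calibrate the effect-size spread to a target maximal difference
#'
#' Resolves a user-facing effect specification into the standard deviation
#' `tau` of the truncated-normal effect distribution and the number `k` of
#' CpGs that must receive nonzero effects. When a target maximal difference
#' in mean methylation (`target_delta`) is given, `tau` is adjusted until the
#' 99.99th percentile of the absolute simulated effects falls within
#' `target_delta +/- detection_limit / 2` (so the acceptance window equals
#' the detection limit, +/- 0.005 under the default limit of 0.01). The
#' search is a bracketed bisection on `tau`, evaluated with common random
#' numbers over `calib_reps` repetitions of `p_cpgs` draws from the panel
#' (CpGs sampled with replacement, per-CpG truncation). When `tau` is
#' supplied directly, calibration is skipped and `tau` passes through.
#'
#' Because effects near zero are biologically negligible, the number of CpGs
#' with nonzero effects is inflated to `k = ceiling(target_dm_cpgs / f)`,
#' where `f` is the Monte-Carlo estimate of
#' `P(|delta| >= detection_limit)` under the calibrated distribution, so
#' that the expected number of *truly* differentially methylated CpGs
#' matches `target_dm_cpgs`.
#'
#' @param panel A [`meth_panel`][as_meth_panel].
#' @param target_dm_cpgs Target number of truly differentially methylated
#'   CpGs (|effect| at or above the detection limit).
#' @param target_delta Target maximal difference in mean beta-values, in
#'   (0, 1). Exactly one of `target_delta` / `tau` must be given.
#' @param tau User-supplied effect-size standard deviation (skips
#'   calibration).
#' @param detection_limit Smallest biologically meaningful |effect|
#'   (default 0.01).
#' @param p_cpgs Number of per-repetition calibration draws; defaults to the
#'   number of CpGs later simulated.
#' @param calib_reps Repetitions of `p_cpgs` draws per evaluation
#'   (default 100).
#' @param seed Integer seed for the calibration draws.
#' @param max_steps Maximum bisection steps before reporting failure.
#'
#' @return A one-row tibble of class `meth_effect` with columns
#'   `target_delta`, `tau`, `truly_dm_fraction`, `k`, `achieved_q9999`,
#'   `detection_limit`, `target_dm_cpgs`.
#' @export
#' @examples
#' pan <- synth_panel(2000, seed = 1)
#' resolve_effect(pan, target_dm_cpgs = 100, target_delta = 0.1,
#'                p_cpgs = 5000, calib_reps = 5, seed = 1)
resolve_effect <- function(panel, target_dm_cpgs,
                           target_delta = NULL, tau = NULL,
                           detection_limit = 0.01,
                           p_cpgs = 100000, calib_reps = 100,
                           seed = 1L, max_steps = 50L) {
  if (is.null(target_delta) == is.null(tau)) {
    stop("provide exactly one of `target_delta` or `tau`", call. = FALSE)
  }
  stopifnot(detection_limit > 0, detection_limit < 1, target_dm_cpgs >= 1)

  # mean-over-reps 99.99th percentile of |delta| at a given tau, with
  # common random numbers so the objective is smooth and monotone in tau
  eval_q <- function(tau_val, keep_draws = FALSE) {
    withr_seed(seed, {
      qs <- numeric(calib_reps)
      frac <- numeric(calib_reps)
      last <- NULL
      for (r in seq_len(calib_reps)) {
        idx <- sample.int(nrow(panel), p_cpgs, replace = TRUE)
        d <- sample_deltas(panel$mean[idx], panel$variance[idx], tau_val)
        qs[r] <- stats::quantile(abs(d), 0.9999, names = FALSE, type = 7)
        frac[r] <- mean(abs(d) >= detection_limit)
        last <- d
      }
      list(q = mean(qs), frac = mean(frac),
           draws = if (keep_draws) last else NULL)
    })
  }

  if (is.null(tau)) {
    stopifnot(target_delta > 0, target_delta < 1)
    lo <- target_delta / 10
    hi <- 2 * target_delta
    q_hi <- eval_q(hi)$q
    # widen the bracket when per-CpG truncation binds hard
    while (q_hi < target_delta - detection_limit / 2 &&
           hi < 64 * target_delta) {
      hi <- 2 * hi
      q_hi <- eval_q(hi)$q
    }
    q_lo <- eval_q(lo)$q
    if (q_lo > target_delta + detection_limit / 2 ||
        q_hi < target_delta - detection_limit / 2) {
      stop(sprintf(paste0(
        "tau calibration failed: achievable 99.99th percentile of |delta| ",
        "spans [%.4f, %.4f] but the target window is [%.4f, %.4f]"),
        q_lo, q_hi, target_delta - detection_limit / 2,
        target_delta + detection_limit / 2), call. = FALSE)
    }
    tau_val <- (lo + hi) / 2
    q <- eval_q(tau_val)$q
    steps <- 0L
    # bisect towards q(tau) == target; stop once well inside the window
    while (steps < max_steps &&
           abs(q - target_delta) > detection_limit / 20) {
      if (q > target_delta) hi <- tau_val else lo <- tau_val
      tau_val <- (lo + hi) / 2
      q <- eval_q(tau_val)$q
      steps <- steps + 1L
    }
    if (abs(q - target_delta) > detection_limit / 2) {
      stop(sprintf(paste0(
        "tau calibration failed after %d steps: achieved 99.99th ",
        "percentile %.4f outside target %.4f +/- %.4f"),
        steps, q, target_delta, detection_limit / 2), call. = FALSE)
    }
  } else {
    stopifnot(tau > 0)
    tau_val <- tau
  }

  fin <- eval_q(tau_val)
  if (fin$frac <= 0) {
    stop("no calibration draw reached the detection limit; ",
         "the target number of truly DM CpGs is unreachable", call. = FALSE)
  }
  k <- compute_k(target_dm_cpgs, fin$frac)

  out <- tibble::tibble(
    target_delta = target_delta %||% NA_real_,
    tau = tau_val,
    truly_dm_fraction = fin$frac,
    k = k,
    achieved_q9999 = fin$q,
    detection_limit = detection_limit,
    target_dm_cpgs = as.integer(target_dm_cpgs)
  )
  class(out) <- c("meth_effect", class(out))
  out
}

#' Number of CpGs that must receive nonzero effects
#'
#' Inflates the target count of truly differentially methylated CpGs by the
#' probability that a drawn effect clears the detection limit:
#' `k = ceiling(target_dm_cpgs / truly_dm_fraction)`.
#'
#' @param target_dm_cpgs Target number of truly DM CpGs.
#' @param truly_dm_fraction Monte-Carlo estimate of
#'   `P(|delta| >= detection_limit)`, in (0, 1].
#' @return Integer `k >= target_dm_cpgs`.
#' @export
#' @examples
#' compute_k(2500, 0.8)  # 3125
compute_k <- function(target_dm_cpgs, truly_dm_fraction) {
  stopifnot(truly_dm_fraction > 0, truly_dm_fraction <= 1)
  as.integer(ceiling(target_dm_cpgs / truly_dm_fraction))
}

#' Classify simulated effects into the truth taxonomy
#'
#' A CpG with zero effect is `null`; a nonzero effect below the detection
#' limit in absolute value is `negligible` (differentially methylated but not
#' biologically meaningful); an absolute effect at or above the limit is
#' `truly_dm`.
#'
#' @param delta Numeric vector of per-CpG simulated effects.
#' @param detection_limit Smallest meaningful |effect| (default 0.01).
#' @return Factor with levels `null`, `negligible`, `truly_dm`.
#' @export
#' @examples
#' classify_truth(c(0, 0.005, -0.02))
classify_truth <- function(delta, detection_limit = 0.01) {
  cls <- ifelse(delta == 0, "null",
                ifelse(abs(delta) < detection_limit, "negligible",
                       "truly_dm"))
  factor(cls, levels = c("null", "negligible", "truly_dm"))
}
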
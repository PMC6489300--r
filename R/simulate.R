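#' Beta shape parameters from (mean, variance)
#'
#' Method-of-moments inversion of the beta distribution:
#' `a = mean^2 * ((1 - mean) / variance - 1 / mean)` and
#' `b = a * (1 / mean - 1)`. `Beta(a, b)` then has exactly the requested
#' mean and variance.
#'
#' @param mean,variance Numeric vectors with `0 < mean < 1` and
#'   `0 < variance < mean * (1 - mean)`; recycled to common length.
#' @return A tibble with columns `a` and `b`, both strictly positive.
#' @export
#' @examples
#' beta_shapes(0.5, 1 / 12)  # a = b = 1: the uniform distribution
beta_shapes <- function(mean, variance) {
  n <- max(length(mean), length(variance))
  mean <- rep_len(mean, n)
  variance <- rep_len(variance, n)
  if (any(!panel_feasible(mean, variance))) {
    stop("(mean, variance) infeasible for a beta distribution: need ",
         "0 < mean < 1 and 0 < variance < mean * (1 - mean)", call. = FALSE)
  }
  a <- mean^2 * ((1 - mean) / variance - 1 / mean)
  tibble::tibble(a = a, b = a * (1 / mean - 1))
}

#' Simulate a two-group methylation study
#'
#' Draws `p_cpgs` CpGs with replacement from the reference panel, imposes the
#' resolved effect distribution on a random subset of `k` CpGs (group 2's
#' means are shifted by the drawn effects; group 1 keeps the panel means;
#' variances are identical in both groups), converts each group's
#' (mean, variance) pairs to beta shape parameters, and generates the two
#' beta-value matrices. Values are clipped to `[clip, 1 - clip]` so the
#' downstream logit transform stays finite.
#'
#' @param panel A [`meth_panel`][as_meth_panel].
#' @param effect A [`meth_effect`][resolve_effect] row (supplies `tau`, `k`
#'   and the detection limit).
#' @param n_total Total sample size across both groups.
#' @param group1_fraction Fraction allocated to group 1 (default 0.5); group
#'   sizes round half away from zero and both must be at least 2.
#' @param p_cpgs Number of CpGs simulated and tested.
#' @param seed Integer seed; the study is bit-reproducible given
#'   (panel, effect, seed).
#' @param clip Guard band keeping draws strictly inside (0, 1)
#'   (default 1e-6).
#'
#' @return A list of class `meth_study`: `group1` and `group2` (numeric
#'   matrices, CpGs x samples), `delta` (length-`p_cpgs` imposed effects, 0
#'   for unshifted CpGs), `truth` (factor from [classify_truth()]), `mu`,
#'   `variance` (the sampled panel moments), and `seed`.
#' @export
#' @examples
#' pan <- synth_panel(500, seed = 1)
#' eff <- resolve_effect(pan, 20, target_delta = 0.1, p_cpgs = 2000,
#'                       calib_reps = 5, seed = 1)
#' sim <- simulate_study(pan, eff, n_total = 20, p_cpgs = 500, seed = 7)
#' dim(sim$group1)
simulate_study <- function(panel, effect, n_total, group1_fraction = 0.5,
                           p_cpgs = 100000, seed = 1L, clip = 1e-6) {
  n1 <- round_half_away(n_total * group1_fraction)
  n2 <- n_total - n1
  if (n1 < 2 || n2 < 2) {
    stop("both groups need at least 2 samples (got ", n1, " and ", n2, ")",
         call. = FALSE)
  }
  k <- effect$k
  if (k > p_cpgs) {
    stop("k (", k, ") exceeds the number of simulated CpGs (", p_cpgs, ")",
         call. = FALSE)
  }

  withr_seed(seed, {
    idx <- sample.int(nrow(panel), p_cpgs, replace = TRUE)
    mu <- panel$mean[idx]
    v <- panel$variance[idx]

    delta <- numeric(p_cpgs)
    shifted <- sample.int(p_cpgs, k)
    delta[shifted] <- sample_deltas(mu[shifted], v[shifted], effect$tau)

    sh1 <- beta_shapes(mu, v)
    sh2 <- beta_shapes(mu + delta, v)

    g1 <- matrix(stats::rbeta(p_cpgs * n1, sh1$a, sh1$b), nrow = p_cpgs)
    g2 <- matrix(stats::rbeta(p_cpgs * n2, sh2$a, sh2$b), nrow = p_cpgs)
    g1 <- pmin(pmax(g1, clip), 1 - clip)
    g2 <- pmin(pmax(g2, clip), 1 - clip)

    structure(
      list(group1 = g1, group2 = g2, delta = delta,
           truth = classify_truth(delta, effect$detection_limit),
           mu = mu, variance = v, seed = as.integer(seed)),
      class = "meth_study"
    )
  })
}

#' @export
print.meth_study <- function(x, ...) {
  cat("<meth_study> ", nrow(x$group1), " CpGs; groups ", ncol(x$group1),
      " + ", ncol(x$group2), " samples; ", sum(x$delta != 0),
      " shifted CpGs (", sum(x$truth == "truly_dm"), " truly DM)\n", sep = "")
  invisible(x)
}

#' Dump a simulated study to delimited text files
#'
#' Writes `group1.tsv` and `group2.tsv` (beta-value matrices with a `cpg`
#' index column) plus a `truth.tsv` sidecar (`cpg`, `delta`, `truth`) into
#' `dir`. Intended for debugging and external re-analysis.
#'
#' @param study A [`meth_study`][simulate_study].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (g in c("group1", "group2")) {
    m <- tibble::as_tibble(as.data.frame(study[[g]]), .name_repair = "minimal")
    names(m) <- paste0("s", seq_along(m))
    readr::write_tsv(dplyr::bind_cols(cpg = seq_len(nrow(m)), m),
                     file.path(dir, paste0(g, ".tsv")))
  }
  readr::write_tsv(
    tibble::tibble(cpg = seq_along(study$delta), delta = study$delta,
                   truth = as.character(study$truth)),
    file.path(dir, "truth.tsv")
  )
  invisible(dir)
}

# round half away from zero (base round() rounds half to even)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)
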
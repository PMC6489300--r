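#' Logit (M-value) transform of methylation beta-values
#'
#' `M = log2(beta / (1 - beta))`. M-values are approximately normal and are
#' what the t-type tests operate on; beta-values must already be strictly
#' inside (0, 1) (the simulator clips them).
#'
#' @param beta Numeric vector or matrix of beta-values in (0, 1).
#' @return Object of the same shape with M-values.
#' @export
#' @examples
#' m_transform(c(0.2, 0.5, 0.8))  # -2, 0, 2
m_transform <- function(beta) log2(beta / (1 - beta))

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: `q_(i) = min_{j >= i} min(1, m * p_(j) / j)`,
#' mapped back to input order. Delegates to [stats::p.adjust()].
#'
#' @param pvalues Numeric vector in \[0, 1\].
#' @return Adjusted values, elementwise at least `pvalues`.
#' @export
bh_adjust <- function(pvalues) stats::p.adjust(pvalues, method = "BH")

#' Per-CpG differential methylation testing
#'
#' Tests every CpG of a simulated study for a mean difference between the two
#' groups, adjusts p-values with Benjamini-Hochberg and calls a CpG detected
#' when its adjusted value is strictly below `fdr_target`. Methods:
#'
#' * `"limma"`: empirical-Bayes moderated t on M-values. Per-CpG pooled
#'   residual variances are shrunk towards a prior fitted across CpGs (see
#'   [squeeze_variances()]); p-values use `d0 + dg` degrees of freedom.
#' * `"cpgassoc"`: pooled-variance two-sample t on M-values (the two-group
#'   reduction of a per-CpG one-way ANOVA).
#' * `"ttest"`: Welch t on M-values (unpooled variances,
#'   Welch-Satterthwaite degrees of freedom).
#' * `"wilcoxon"`: rank-sum test on beta-values (exact null distribution for
#'   small combined samples without ties; normal approximation with
#'   continuity and tie corrections otherwise).
#'
#' @param study A [`meth_study`][simulate_study], or a list with `group1` /
#'   `group2` matrices (plus optional `delta`, `truth`).
#' @param method One of `"limma"`, `"cpgassoc"`, `"ttest"`, `"wilcoxon"`.
#' @param fdr_target FDR threshold for detection calls (default 0.05).
#'
#' @return A tibble with one row per CpG: `cpg`, `pvalue`, `qvalue`,
#'   `detected`, and (when present in `study`) `delta` and `truth`; the
#'   method and threshold are stored as attributes.
#' @export
#' @examples
#' pan <- synth_panel(300, seed = 1)
#' eff <- resolve_effect(pan, 10, target_delta = 0.2, p_cpgs = 1000,
#'                       calib_reps = 5, seed = 1)
#' sim <- simulate_study(pan, eff, n_total = 40, p_cpgs = 300, seed = 2)
#' dm_test(sim, method = "limma")
dm_test <- function(study, method = c("limma", "cpgassoc", "ttest",
                                      "wilcoxon"),
                    fdr_target = 0.05) {
  method <- match.arg(method)
  g1 <- study$group1
  g2 <- study$group2
  if (ncol(g1) < 2 || ncol(g2) < 2) {
    stop("each group needs at least 2 samples", call. = FALSE)
  }
  p <- switch(method,
    limma = row_moderated_t(m_transform(g1), m_transform(g2))$pvalue,
    cpgassoc = row_pooled_t(m_transform(g1), m_transform(g2))$pvalue,
    ttest = row_welch_t(m_transform(g1), m_transform(g2))$pvalue,
    wilcoxon = row_wilcoxon(g1, g2)
  )
  q <- bh_adjust(p)
  out <- tibble::tibble(
    cpg = seq_along(p), pvalue = p, qvalue = q,
    detected = q < fdr_target
  )
  if (!is.null(study$delta)) out$delta <- study$delta
  if (!is.null(study$truth)) out$truth <- study$truth
  attr(out, "method") <- method
  attr(out, "fdr_target") <- fdr_target
  out
}

# row means / unbiased row variances without matrixStats
row_moments <- function(x) {
  m <- rowMeans(x)
  v <- rowSums((x - m)^2) / (ncol(x) - 1)
  list(mean = m, var = v, n = ncol(x))
}

#' Row-wise pooled-variance two-sample t-test
#'
#' @param g1,g2 Numeric matrices (rows = CpGs) of M-values.
#' @return A list with `statistic`, `df`, `pvalue` (vectors). Rows where both
#'   groups are constant and equal get `p = 1`; constant but unequal rows get
#'   `p = 0`.
#' @keywords internal
row_pooled_t <- function(g1, g2) {
  a <- row_moments(g1); b <- row_moments(g2)
  df <- a$n + b$n - 2
  sp2 <- ((a$n - 1) * a$var + (b$n - 1) * b$var) / df
  se <- sqrt(sp2 * (1 / a$n + 1 / b$n))
  t <- (a$mean - b$mean) / se
  p <- 2 * stats::pt(-abs(t), df)
  zero <- se == 0
  p[zero] <- ifelse(a$mean[zero] == b$mean[zero], 1, 0)
  list(statistic = t, df = rep(df, length(t)), pvalue = p)
}

# row-wise Welch t with Satterthwaite df
row_welch_t <- function(g1, g2) {
  a <- row_moments(g1); b <- row_moments(g2)
  se2 <- a$var / a$n + b$var / b$n
  t <- (a$mean - b$mean) / sqrt(se2)
  df <- se2^2 / ((a$var / a$n)^2 / (a$n - 1) + (b$var / b$n)^2 / (b$n - 1))
  p <- 2 * stats::pt(-abs(t), df)
  zero <- se2 == 0
  p[zero] <- ifelse(a$mean[zero] == b$mean[zero], 1, 0)
  list(statistic = t, df = df, pvalue = p)
}

#' Empirical-Bayes shrinkage of per-CpG variances
#'
#' Fits a scaled inverse-chi-square prior `(d0, s0^2)` to the per-CpG
#' residual variances `s2` (each on `df` degrees of freedom) by the method of
#' moments on `log(s2)`: with `e = log(s2) - digamma(df/2) + log(df/2)`, the
#' model implies `Var(e) = trigamma(df/2) + trigamma(d0/2)` and
#' `E(e) = log(s0^2) + digamma(d0/2) - log(d0/2)`, so `d0` comes from a
#' trigamma inversion and `s0^2` from the mean. Zero variances are excluded
#' from the fit but still receive a positive shrunk value. Returns the
#' posterior variances `(d0 * s0^2 + df * s2) / (d0 + df)`.
#'
#' @param s2 Per-CpG sample variances.
#' @param df Residual degrees of freedom per CpG (scalar).
#' @param prior_df Optional override of the fitted `d0` (e.g. 0 disables
#'   shrinkage, `Inf` forces full pooling).
#' @return List with `var_post`, `d0`, `s02`.
#' @export
squeeze_variances <- function(s2, df, prior_df = NULL) {
  ok <- is.finite(s2) & s2 > 0
  z <- log(s2[ok])
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- stats::var(e)

  if (is.null(prior_df)) {
    resid <- evar - trigamma(df / 2)
    if (is.na(resid) || resid <= 0) {
      d0 <- Inf
    } else {
      d0 <- 2 * trigamma_inverse(resid)
    }
  } else {
    d0 <- prior_df
  }
  s02 <- if (is.infinite(d0)) {
    exp(emean)
  } else if (d0 <= 0) {
    exp(emean)  # irrelevant: zero prior weight
  } else {
    exp(emean + digamma(d0 / 2) - log(d0 / 2))
  }

  var_post <- if (is.infinite(d0)) {
    rep(s02, length(s2))
  } else {
    (d0 * s02 + df * s2) / (d0 + df)
  }
  list(var_post = var_post, d0 = d0, s02 = s02)
}

# Newton inversion of trigamma: find x > 0 with trigamma(x) = y
trigamma_inverse <- function(y) {
  if (y <= 0) return(Inf)
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:75) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, 2)
    x <- x + dif
    if (abs(dif / x) < 1e-10) break
  }
  x
}

#' Row-wise moderated t-test
#'
#' Pooled two-sample t on each row with the pooled variance replaced by its
#' empirical-Bayes posterior from [squeeze_variances()]; p-values use
#' `d0 + df` degrees of freedom. With `prior_df = 0` this reduces exactly to
#' the pooled t-test.
#'
#' @inheritParams row_pooled_t
#' @param prior_df Optional override of the fitted prior degrees of freedom.
#' @return List with `statistic`, `df`, `pvalue`, `d0`, `s02`.
#' @keywords internal
row_moderated_t <- function(g1, g2, prior_df = NULL) {
  a <- row_moments(g1); b <- row_moments(g2)
  dg <- a$n + b$n - 2
  sp2 <- ((a$n - 1) * a$var + (b$n - 1) * b$var) / dg
  sq <- squeeze_variances(sp2, dg, prior_df = prior_df)
  se <- sqrt(sq$var_post * (1 / a$n + 1 / b$n))
  t <- (a$mean - b$mean) / se
  df_tot <- sq$d0 + dg
  p <- if (is.infinite(df_tot)) {
    2 * stats::pnorm(-abs(t))
  } else {
    2 * stats::pt(-abs(t), df_tot)
  }
  zero <- se == 0
  p[zero] <- ifelse(a$mean[zero] == b$mean[zero], 1, 0)
  list(statistic = t, df = rep(df_tot, length(t)), pvalue = p,
       d0 = sq$d0, s02 = sq$s02)
}

#' Row-wise Wilcoxon rank-sum test
#'
#' Two-sided rank-sum test per row. When the combined sample size is at most
#' `exact_limit` and a row has no ties, the exact null distribution of the
#' rank-sum statistic is used; otherwise the normal approximation with
#' continuity correction and the midrank tie correction.
#'
#' @inheritParams row_pooled_t
#' @param exact_limit Largest combined sample size for the exact path
#'   (default 50, the usual convention).
#' @return Numeric vector of p-values.
#' @keywords internal
row_wilcoxon <- function(g1, g2, exact_limit = 50) {
  n1 <- ncol(g1); n2 <- ncol(g2); n <- n1 + n2
  x <- cbind(g1, g2)
  r <- t(apply(x, 1, rank))
  w <- rowSums(r[, seq_len(n1), drop = FALSE]) - n1 * (n1 + 1) / 2

  # midrank tie correction per row
  tiesum <- apply(x, 1, function(row) {
    tt <- table(row)
    sum(tt^3 - tt)
  })
  has_ties <- tiesum > 0

  use_exact <- (n <= exact_limit) & !has_ties
  p <- numeric(nrow(x))

  if (any(use_exact)) {
    wi <- w[use_exact]
    p_lo <- stats::pwilcox(wi, n1, n2)
    p_hi <- 1 - stats::pwilcox(wi - 1, n1, n2)
    p[use_exact] <- pmin(1, 2 * pmin(p_lo, p_hi))
  }
  if (any(!use_exact)) {
    wi <- w[!use_exact]
    mu <- n1 * n2 / 2
    sig2 <- n1 * n2 / 12 * ((n + 1) - tiesum[!use_exact] / (n * (n - 1)))
    z <- wi - mu
    cc <- sign(z) * 0.5
    z <- (z - cc) / sqrt(sig2)
    p[!use_exact] <- pmin(1, 2 * stats::pnorm(-abs(z)))
  }
  p
}
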
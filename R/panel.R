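#' Reference panels of per-CpG methylation moments
#'
#' A reference panel is a tibble with one row per CpG and columns `cpg_id`,
#' `mean` and `variance`, describing the per-CpG beta-value distribution of a
#' tissue type. Every retained row satisfies the beta-distribution feasibility
#' constraints `0 < mean < 1` and `0 < variance < mean * (1 - mean)`; rows
#' violating them cannot be simulated as beta variates and are dropped by the
#' constructors.
#'
#' @param x A data frame with columns `cpg_id`, `mean`, `variance`.
#' @param source_label Free-text provenance (tissue type, accession, ...).
#' @param quiet Suppress the message reporting dropped rows.
#'
#' @return A tibble of class `meth_panel` with columns `cpg_id` (character),
#'   `mean` and `variance` (double), and attribute `source_label`.
#' @export
#' @examples
#' as_meth_panel(data.frame(cpg_id = c("cg1", "cg2"),
#'                          mean = c(0.2, 0.8), variance = c(0.01, 0.02)))
as_meth_panel <- function(x, source_label = NULL, quiet = FALSE) {
  required <- c("cpg_id", "mean", "variance")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    stop("panel is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out <- tibble::as_tibble(x[required])
  out$cpg_id <- as.character(out$cpg_id)
  out$mean <- as.double(out$mean)
  out$variance <- as.double(out$variance)

  ok <- panel_feasible(out$mean, out$variance)
  n_drop <- sum(!ok)
  if (n_drop > 0 && !quiet) {
    message("Dropped ", n_drop, " CpG(s) violating beta-distribution ",
            "feasibility (0 < mean < 1 and 0 < variance < mean * (1 - mean)).")
  }
  out <- out[ok, ]
  if (nrow(out) == 0) {
    stop("no CpGs remain after the beta-feasibility filter ",
         "(0 < mean < 1, 0 < variance < mean * (1 - mean))", call. = FALSE)
  }
  attr(out, "source_label") <- source_label %||% attr(x, "source_label") %||% ""
  attr(out, "n_dropped") <- n_drop
  class(out) <- c("meth_panel", class(tibble::tibble()))
  out
}

# strict feasibility test for (mean, variance) pairs; NA-safe (NA -> FALSE)
panel_feasible <- function(mu, var) {
  ok <- is.finite(mu) & is.finite(var) &
    mu > 0 & mu < 1 & var > 0 & var < mu * (1 - mu)
  ok & !is.na(ok)
}

#' @export
print.meth_panel <- function(x, ...) {
  src <- attr(x, "source_label")
  cat("<meth_panel> ", format(nrow(x), big.mark = ","), " CpGs",
      if (nzchar(src %||% "")) paste0("  [", src, "]") else "", "\n", sep = "")
  NextMethod()
}

#' Estimate a reference panel from a beta-value matrix
#'
#' Computes per-CpG sample means and unbiased (n-1 denominator) sample
#' variances of methylation beta-values, one row per CpG, and filters out CpGs
#' whose moments are infeasible for a beta distribution (including
#' zero-variance rows). Missing values are allowed: moments are computed over
#' the observed entries of a row when at least two remain, otherwise the row
#' is dropped.
#'
#' @param beta A numeric matrix (CpGs in rows, samples in columns) with values
#'   in \[0, 1\], or a data frame whose first column holds CpG identifiers and
#'   remaining columns hold per-sample beta-values.
#' @param cpg_ids Optional character vector of CpG identifiers; defaults to
#'   rownames of `beta` or `cg1..cgJ`.
#' @param source_label Free-text provenance stored on the panel.
#' @inheritParams as_meth_panel
#'
#' @return A [`meth_panel`][as_meth_panel] tibble.
#' @export
#' @examples
#' beta <- matrix(stats::rbeta(200, 2, 5), nrow = 10)
#' estimate_panel(beta, source_label = "toy")
estimate_panel <- function(beta, cpg_ids = NULL, source_label = "",
                           quiet = FALSE) {
  if (is.data.frame(beta)) {
    if (is.character(beta[[1]]) || is.factor(beta[[1]])) {
      cpg_ids <- cpg_ids %||% as.character(beta[[1]])
      beta <- as.matrix(beta[-1])
    } else {
      beta <- as.matrix(beta)
    }
  }
  if (!is.matrix(beta) || !is.numeric(beta)) {
    stop("`beta` must be a numeric matrix or a data frame of beta-values",
         call. = FALSE)
  }
  if (ncol(beta) < 2) {
    stop("at least 2 samples (columns) are required to estimate variances",
         call. = FALSE)
  }
  rng <- range(beta, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 1) {
    stop("beta-values must lie in [0, 1]", call. = FALSE)
  }
  cpg_ids <- cpg_ids %||% rownames(beta) %||% paste0("cg", seq_len(nrow(beta)))

  n_obs <- rowSums(!is.na(beta))
  mu <- rowMeans(beta, na.rm = TRUE)
  v <- rowSums((beta - mu)^2, na.rm = TRUE) / pmax(n_obs - 1, 1)
  mu[n_obs < 2] <- NA_real_
  v[n_obs < 2] <- NA_real_

  as_meth_panel(
    tibble::tibble(cpg_id = cpg_ids, mean = mu, variance = v),
    source_label = source_label, quiet = quiet
  )
}

#' Read and write panel files
#'
#' Panels are stored as plain delimited text (TSV or CSV) with a header line
#' `cpg_id`, `mean`, `variance`, UTF-8 encoded with `.` as decimal mark --
#' the format a user would export from a GEO series matrix. `load_panel()`
#' auto-detects tab vs comma delimiters unless `delim` is given; rows failing
#' the beta-feasibility filter are dropped with a message.
#'
#' @param path File path.
#' @param delim Field delimiter; `NULL` (default) auto-detects `\t` vs `,`.
#' @inheritParams as_meth_panel
#'
#' @return `load_panel()` returns a [`meth_panel`][as_meth_panel];
#'   `save_panel()` returns `path` invisibly.
#' @export
load_panel <- function(path, delim = NULL, source_label = NULL,
                       quiet = FALSE) {
  if (!file.exists(path)) stop("panel file not found: ", path, call. = FALSE)
  if (is.null(delim)) {
    header <- readLines(path, n = 1L)
    delim <- if (grepl("\t", header)) "\t" else ","
  }
  tab <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  as_meth_panel(tab, source_label = source_label %||% basename(path),
                quiet = quiet)
}

#' @param panel A [`meth_panel`][as_meth_panel].
#' @rdname load_panel
#' @export
save_panel <- function(panel, path, delim = "\t") {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  readr::write_delim(panel[c("cpg_id", "mean", "variance")], path,
                     delim = delim)
  invisible(path)
}

#' Synthesize a tri-modal reference panel
#'
#' Generates a synthetic panel emulating the tri-modal mean structure of
#' Illumina array methylation: a mostly-unmethylated mode, an intermediate
#' mode, and a mostly-methylated mode. Component means are drawn from beta
#' hyper-distributions and per-CpG variances as a random fraction of the
#' maximal feasible variance `mean * (1 - mean)`, so every emitted CpG is
#' feasible by construction. Deterministic given `seed`.
#'
#' @param n_cpgs Number of CpGs to generate.
#' @param weights Length-3 mixture weights (low, intermediate, high
#'   methylation); must sum to 1.
#' @param mean_shapes 3x2 matrix of beta hyper-parameters for the component
#'   means; row order low, intermediate, high.
#' @param var_fraction Length-2 range: per-CpG variance is
#'   `runif(var_fraction) * mean * (1 - mean)`.
#' @param seed Integer seed.
#' @param source_label Provenance string stored on the panel.
#'
#' @return A [`meth_panel`][as_meth_panel] with exactly `n_cpgs` rows.
#' @export
#' @examples
#' synth_panel(1000, seed = 1)
synth_panel <- function(n_cpgs = 10000,
                        weights = c(0.35, 0.25, 0.40),
                        mean_shapes = rbind(low = c(5, 45),
                                            mid = c(10, 10),
                                            high = c(45, 5)),
                        var_fraction = c(0.002, 0.03),
                        seed = 1L,
                        source_label = "synthetic tri-modal") {
  if (length(weights) != 3 || abs(sum(weights) - 1) > 1e-8) {
    stop("`weights` must be three mixture weights summing to 1",
         call. = FALSE)
  }
  if (any(weights < 0)) stop("`weights` must be non-negative", call. = FALSE)
  stopifnot(nrow(mean_shapes) == 3, ncol(mean_shapes) == 2)

  withr_seed(seed, {
    comp <- sample.int(3L, n_cpgs, replace = TRUE, prob = weights)
    mu <- stats::rbeta(n_cpgs, mean_shapes[comp, 1], mean_shapes[comp, 2])
    # keep means away from 0/1 so variances stay strictly feasible
    mu <- pmin(pmax(mu, 1e-4), 1 - 1e-4)
    frac <- stats::runif(n_cpgs, var_fraction[1], var_fraction[2])
    v <- frac * mu * (1 - mu)
    as_meth_panel(
      tibble::tibble(cpg_id = sprintf("syn%06d", seq_len(n_cpgs)),
                     mean = mu, variance = v),
      source_label = source_label, quiet = TRUE
    )
  })
}

# evaluate `expr` under a temporary RNG state seeded with `seed`
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
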
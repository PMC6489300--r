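# Shared fixtures. Everything is generated in code under fixed seeds; no
# files on disk.

# small tri-modal panel reused across tests
test_panel <- function(n = 2000, seed = 11) synth_panel(n, seed = seed)

# a panel whose feasibility bounds never bind for modest effect targets:
# all CpGs centred at 0.5 with tiny variance
wide_bounds_panel <- function(n = 500, var = 1e-4) {
  as_meth_panel(tibble::tibble(
    cpg_id = paste0("w", seq_len(n)), mean = 0.5, variance = var
  ), source_label = "wide-bounds", quiet = TRUE)
}

# independent brute-force Benjamini-Hochberg step-up oracle:
# q_(i) = min over j >= i of min(1, m * p_(j) / j), literal double loop
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q_sorted <- vapply(seq_len(m), function(i) {
    min(vapply(i:m, function(j) min(1, m * ps[j] / j), numeric(1)))
  }, numeric(1))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# exact Wilcoxon rank-sum p-value by full enumeration of group assignments
wilcox_enum_oracle <- function(g1, g2) {
  n1 <- length(g1)
  x <- c(g1, g2)
  r <- rank(x)
  w_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(length(x), n1)
  w_all <- apply(combos, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  mu <- n1 * length(g2) / 2
  # two-sided: as extreme or more extreme in distance from the null mean
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
}
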
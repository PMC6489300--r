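---
title: "Power estimation for two-group EWAS: model, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Power estimation for two-group EWAS: model, calibration and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methpower)
```

## The simulation model

`methpower` estimates the power of a two-group EWAS by Monte-Carlo
simulation rather than a formula, because the quantity of interest —
marginal power under Benjamini-Hochberg FDR control across 10^4–10^6
heterogeneous beta-distributed tests, against an effect size that is itself
a random variable — has no tractable closed form.

The generative model is semi-parametric. Its empirical anchor is a
*reference panel*: per-CpG means and variances
$(\mu_j, \sigma^2_j)$, $j = 1,\dots,J$, estimated from a tissue-specific
beta-value matrix by row sample means and unbiased ($N-1$) sample
variances (`estimate_panel()`), or loaded from a delimited file
(`load_panel()`). Only pairs satisfying the beta-distribution feasibility
constraints $0 < \mu < 1$ and $0 < \sigma^2 < \mu(1-\mu)$ are retained;
boundary pairs (e.g. zero-variance rows) cannot be realized by any beta
distribution and are dropped with a reported count.

A simulated study of $P$ CpGs draws $P$ pairs from the panel *with
replacement*, which decouples $P$ from the panel size $J$ and lets users
scale from a filtered 450K analysis ($P = 10^5$, the default) up to a full
EPIC array. $K$ of the $P$ CpGs receive a shift $\Delta_{\beta,k}$ of the
group-2 mean; group 1 keeps the panel mean, and both groups share the
CpG-specific variance (homoscedasticity between comparator groups is an
explicit model assumption; violations in real data, where variance can
change with exposure, make these power estimates optimistic). Each group's
$(\text{mean}, \sigma^2)$ pairs are converted to beta shape parameters by
moment inversion,
$a = \mu^2\!\left(\frac{1-\mu}{\sigma^2} - \frac{1}{\mu}\right)$,
$b = a\left(\frac{1}{\mu} - 1\right)$, and the two beta-value matrices
($P \times N_1$, $P \times N_2$) are drawn independently across CpGs and
subjects.

## Bounded effect sizes and the calibration of τ

Because beta-value means live in $(0,1)$ and the variance is held fixed, a
shift $\Delta$ is only feasible on the open interval
$$\left(\tfrac{1}{2} - \mu - \sqrt{\tfrac{1}{4} - \sigma^2},\;
       \tfrac{1}{2} - \mu + \sqrt{\tfrac{1}{4} - \sigma^2}\right)
  \cap (-\mu,\, 1 - \mu),$$
on which the shifted mean still satisfies
$\sigma^2 < \mu'(1-\mu')$ (`delta_bounds()`). Effects are therefore drawn
from a normal distribution $N(0, \tau^2)$ truncated *per CpG* to this
interval (`sample_deltas()`, inverse-CDF sampling). The interval always
contains 0 for feasible panel rows, so no draw can fail; draws are clamped
strictly inside the open interval.

Users think in terms of a target maximal difference in methylation (e.g.
"effects up to 0.10"), not in terms of $\tau$. `resolve_effect()` maps one
to the other: $\tau$ is adjusted until the 99.99th percentile of
$|\Delta_\beta|$ falls within the target ± half the detection limit
(± 0.005 under the default limit of 0.01). The search is a bracketed
bisection with common random numbers — each candidate $\tau$ is evaluated
on the same RNG stream as a mean of per-repetition 99.99th percentiles
(linear interpolation between order statistics) over `calib_reps`
repetitions of `p_cpgs` panel draws — which makes the objective smooth and
strictly monotone in $\tau$, so the bisection converges deterministically.
The initial bracket is $[\text{target}/10,\; 2\cdot\text{target}]$; when
per-CpG truncation binds hard (tri-modal panels contain many CpGs near 0
or 1 whose short side of the interval clips large shifts), the upper end
is doubled, up to $64\cdot\text{target}$, before calibration is declared
failed. Failure is an explicit error reporting the achievable percentile
range, never a silent fallback. With wide bounds the calibrated value
approaches the closed form $\tau = \text{target}/\Phi^{-1}(0.99995)
\approx \text{target}/3.89$, which the tests verify.

A truncated normal centered at zero puts a sizable fraction of effects
below the detection limit; those CpGs are *differentially methylated but
negligibly so*. To make the expected count of truly differentially
methylated CpGs (|Δ| at or above the limit) match the user's target, the
number of shifted CpGs is inflated to
$K = \lceil \text{target} / \hat f \rceil$ where $\hat f$ is the
Monte-Carlo estimate of $P(|\Delta| \ge \text{limit})$ from the
calibration draws. Which $K$ of the $P$ CpGs are shifted is a uniform
random subset; the truncated normal is symmetric, so shifting group 2
rather than group 1 is immaterial.

## Testing and the six-way taxonomy

Beta-values are logit-transformed to M-values,
$M = \log_2 \beta/(1-\beta)$, before the t-type tests (the transform's
approximate normality is why); the Wilcoxon test ranks beta-values
directly, and ranks are invariant to the monotone logit anyway. Four
per-CpG tests are available:

* **moderated t** (`"limma"`, the default): pooled per-CpG variances are
  shrunk toward a scaled inverse-chi-square prior fitted across CpGs by
  method of moments on $\log s^2$ (trigamma inversion for the prior
  degrees of freedom $d_0$, the log-mean for the prior scale $s_0^2$);
  the statistic uses $\tilde s^2 = (d_0 s_0^2 + d_g s^2)/(d_0 + d_g)$ and
  $d_0 + d_g$ degrees of freedom. At $d_0 = 0$ it reduces exactly to the
  pooled t; the fit agrees with the standard empirical-Bayes
  implementation in the Bioconductor ecosystem, which the test suite uses
  as an independent oracle.
* **pooled t** (`"cpgassoc"`): the two-group reduction of a per-CpG
  one-way ANOVA.
* **Welch t** (`"ttest"`): unpooled variances, Satterthwaite degrees of
  freedom.
* **Wilcoxon rank-sum** (`"wilcoxon"`): exact null distribution for
  combined samples up to 50 without ties, otherwise the normal
  approximation with continuity and midrank-tie corrections.

Zero within-group variance is handled per test: the moderated and pooled
machinery still yields a positive (shrunk/pooled) variance, and the plain
t reports $p = 1$ when both groups are constant and equal, $p = 0$ when
constant and unequal. P-values are BH-adjusted and a CpG is *detected*
when its adjusted value is strictly below the FDR target (default 0.05).

Crossing detection with the simulated truth (null / negligible / truly DM)
gives six categories — TP, NP (neutral positive), FP, TN, NN (neutral
negative), FN — from which five ratios are computed: classical power
$(NP+TP)/(NP+NN+TP+FN)$, marginal power $TP/(TP+FN)$, marginal type I
error $FP/(FP+TN)$, empirical FDR $FP/(FP+NP+TP)$, and the false
discovery cost $FDC = FP/TP$. A $0/0$ ratio is reported as missing and
excluded from cell means (coercing it to 0 would bias power downward or
upward depending on the metric); an FDC with $TP = 0 < FP$ is infinite
and likewise excluded, with the count of such replicates reported
(`n_fdc_undefined`). The probability of at least one true positive — the
useful quantity for pilot studies — is the fraction of replicates with
$TP \ge 1$.

## Grid orchestration, seeding and reproducibility

`power_ewas()` calibrates $(\tau, K)$ once per target effect size, then
loops sample sizes and replicates. Every replicate re-seeds its own RNG
stream from a seed derived arithmetically from the master seed and the
replicate's (effect, sample-size, replicate) grid position, so the result
is bit-identical for any `threads` setting and any execution order;
replicates are dispatched with forked workers (`parallel::mclapply`).
Group sizes are $N_1 = \text{round}(n \cdot \text{fraction})$ with halves
rounded away from zero, and both groups must have at least 2 subjects.
Beta draws are clipped to $[10^{-6}, 1 - 10^{-6}]$ — exact 0/1 is possible
only by floating-point underflow, but the guard keeps the logit finite.

`write_power_report()` separates results from execution details:
`power_grid.json` carries the per-cell summary, the calibrated effects and
every result-determining configuration field (seed included) and is
byte-identical across thread counts; wall times and the thread count live
in `run.log`. The thread count cannot be part of a byte-stable result file
and is deliberately excluded from the JSON.

Defaults follow standard EWAS practice: $P = 10^5$ CpGs, balanced
allocation, FDR target 0.05, detection limit 0.01, moderated t, and 50
replicates per cell — around 50 the variance of the power estimate has
essentially stabilized, and more replicates buy little precision for
their cost. Calibration uses 100 repetitions of $P$ draws by default
(`calib_reps`), a knob that can be scaled down for exploratory runs.

## What the synthetic panel does and does not emulate

`synth_panel()` generates panels with the tri-modal mean structure
characteristic of array methylation: a mostly-unmethylated mode
(means ~ Beta(5, 45)), an intermediate mode (Beta(10, 10)) and a
mostly-methylated mode (Beta(45, 5)) with default weights 0.35 / 0.25 /
0.40 — arrays are dominated by the two extreme modes, with a minority of
intermediate CpGs. Variances are drawn as a uniform fraction (0.2–3%) of
the maximal feasible variance $\mu(1-\mu)$, giving per-CpG standard
deviations of roughly 0.01–0.09, the range typical of 450K data; validity
is guaranteed by construction. These choices are fixed design decisions,
not tuning dials.

The generator reproduces the *marginal* structure that drives power —
bounded bimodal-plus-intermediate means, heteroscedastic feasible
variances — but not several features of real data: spatial correlation
between neighboring CpGs (all draws are independent across CpGs),
group-specific variance changes, batch effects, or probe-type artifacts.
Tests passing on synthetic panels therefore validate the engine's
calibration, error control and internal consistency; absolute power
numbers for a real study should come from a panel estimated from data of
the target tissue. Under CpG correlation, BH still controls FDR but the
Monte-Carlo bands would widen.

## Numerical choices and problem sizes

Tolerances and tie-breaks that matter: the calibration window is half a
detection limit on either side of the target, with bisection continuing
to a twentieth of the limit for centering; quantiles everywhere use linear
interpolation between order statistics; truncated-normal sampling uses
the inverse CDF (numerically safe because the interval always straddles
0); the trigamma inversion in the variance-prior fit is Newton's method
with asymptotic guards at both ends; BH detection uses a strict
inequality.

The test suite and the acceptance script exercise the engine at reduced
problem sizes chosen to keep the full validation loop fast while leaving
Monte-Carlo error well inside every asserted tolerance: panels of
2×10^4 CpGs, studies of 10^4 CpGs, grids up to 260 subjects, 10–20
replicates per cell, and calibration with 10–20 repetitions of 10^4–10^5
draws. The qualitative behavior these verify — required sample size
decreasing in effect size, FDR control at the BH target, calibration
accuracy within half a detection limit — is scale-free; production runs
should use the defaults ($P = 10^5$, 50 replicates).

## Known limitations

Two-group comparisons only; no covariates, continuous phenotypes,
survival outcomes or more than two groups. No modeling of CpG-CpG
correlation or group-specific variances (power estimates are optimistic
when variance responds to the phenotype). Effect sizes are symmetric
truncated-normal; asymmetric or heavy-tailed effect distributions are out
of scope. Reference panels are taken as given — the package neither
downloads nor normalizes array data.
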
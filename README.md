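# methpower

Simulation-based power estimation for two-group epigenome-wide association
studies (EWAS) of array-based DNA methylation.

## The problem

An EWAS tests tens or hundreds of thousands of CpG sites for a difference in
mean methylation between two groups (cases vs controls, exposed vs
unexposed) under FDR control. Planning such a study requires answering: *how
many subjects are needed to detect a given number of differentially
methylated CpGs at a given effect size with, say, 80% power?* Closed-form
power formulas do not capture the realities of methylation data — bounded
beta-distributed measurements, wildly heterogeneous per-CpG variances,
effect sizes that are themselves a distribution, and FDR-adjusted detection
across 10⁵ correlated decisions — so `methpower` answers the question by
semi-parametric simulation.

## The model

Methylation beta-values at CpG *j* are modeled as Beta(*a<sub>j</sub>*,
*b<sub>j</sub>*) with shape parameters obtained by moment inversion from a
**reference panel** of per-CpG means and variances
(μ<sub>j</sub>, σ²<sub>j</sub>), estimated from a tissue-specific dataset or
synthesized (`synth_panel()` emulates the tri-modal mean structure of
Illumina arrays). A simulated study draws *P* CpGs from the panel with
replacement; *K* of them receive a group-2 mean shift

&nbsp;&nbsp;Δ<sub>β,k</sub> ~ N(0, τ²) truncated to
½ − μ<sub>k</sub> ± √(¼ − σ²<sub>k</sub>),

the interval on which the shifted mean still admits a beta distribution
with unchanged variance. τ is **calibrated** so that the 99.99th percentile
of |Δ<sub>β</sub>| matches the user's target maximal difference within half
the detection limit, and *K* = ⌈target DM CpGs / P(|Δ| ≥ detection
limit)⌉ so the expected count of *truly* differentially methylated CpGs
(|Δ| at or above the detection limit, default 0.01) matches the target.
Each replicate is tested per CpG on M-values (moderated t, pooled t, Welch
t) or beta-values (Wilcoxon), BH-adjusted, and thresholded at the target
FDR. Each CpG then falls into one of six categories (TP/NP/FP/TN/NN/FN by
detection × truth), from which the engine reports

- classical power (NP+TP)/(NP+NN+TP+FN),
- **marginal power** TP/(TP+FN) — the headline estimate,
- marginal type I error FP/(FP+TN),
- empirical FDR FP/(FP+NP+TP),
- false discovery cost FDC = FP/TP,
- probability of at least one true positive,

averaged over replicates with 2.5/97.5 percentile bands.

## Worked example

```r
library(methpower)

panel <- synth_panel(20000, seed = 1)        # tri-modal synthetic panel
pw <- power_ewas(
  panel,
  n_total        = seq(20, 100, by = 40),    # total subjects, both groups
  target_delta   = c(0.10, 0.20),            # target max difference in beta
  target_dm_cpgs = 250,                      # truly DM CpGs among P
  p_cpgs         = 10000,                    # CpGs simulated and tested
  n_sims         = 10, seed = 7,
  calib_reps = 10, calib_draws = 10000
)
pw$summary
glance(pw)
```

which prints (abridged):

```
  target_delta n_total classical_power marginal_power power_lo power_hi
1          0.1      20          0.0338         0.0482   0.0298   0.0815
2          0.1      60          0.271          0.376    0.331    0.413
3          0.1     100          0.36           0.508    0.473    0.567
4          0.2      20          0.217          0.255    0.193    0.298
5          0.2      60          0.522          0.622    0.581    0.655
6          0.2     100          0.633          0.739    0.711    0.771

  target_delta    tau     k truly_dm_fraction max_power n_at_goal
1          0.1 0.0269   355             0.705     0.508        NA
2          0.2 0.0549   296             0.847     0.739        NA
```

Reading: with 100 subjects split evenly, a study targeting differences up
to 0.2 in beta detects on average 74% of its truly differentially
methylated CpGs (`marginal_power`, band 0.71–0.77 across replicates); to
reach the conventional 80% (`n_at_goal`) a larger cohort is needed on this
grid. The calibrated effect distribution behind the 0.2 target has
τ = 0.055, and 296 CpGs receive nonzero shifts so that ~250 clear the 0.01
detection limit (fraction 0.847). `autoplot(pw)` draws the power curve with
percentile error bars and an 80% reference line; `plot_delta_density(pw)`
shows the simulated effect-size distributions; `tidy(pw)` returns the long
per-metric table; `write_power_report(pw, dir)` serializes TSV + JSON +
log + figures.

A command-line front end with the same knobs lives at
`inst/cli/methpower.R`:

```sh
Rscript inst/cli/methpower.R --synth-cpgs 20000 --n-min 20 --n-max 260 \
  --n-step 40 --target-dm 2500 --target-delta 0.1,0.15,0.2 \
  --p-cpgs 100000 --sims 50 --threads 4 --seed 1 --out results/
```

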
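# ebmgml

Three-stage super-efficiency EBM data envelopment analysis with global
Malmquist–Luenberger productivity decomposition, for benchmarking the
resource-utilization efficiency of production units (provinces, farms,
firms) that use several inputs to produce a desirable output together
with an undesirable one such as carbon emissions.

## The problem

Raw DEA efficiency scores confound three things: genuine management
performance, the external environment (urbanization, weather, policy
support, …), and statistical noise. A province that looks efficient may
simply farm in a favorable climate. The three-stage procedure separates
them:

1. **Stage 1 — EBM DEA.** Every unit-period observation is scored by an
   input-oriented epsilon-based-measure (EBM) model against a *global*
   frontier built from all observations of all periods. The EBM
   objective blends the radial contraction factor θ with weighted input
   slacks,

   γ\* = min θ − ε Σᵢ wᵢ⁻ sᵢ⁻ / xᵢₖ

   subject to Σⱼ λⱼ xᵢⱼ + sᵢ⁻ = θ xᵢₖ, Σⱼ λⱼ y₍ᵣⱼ₎ ≥ y₍ᵣₖ₎ (plus
   Σλ = 1 under VRS). ε = 0 recovers the radial CCR/BCC model; ε and
   w⁻ are set by the affinity-index procedure by default. Undesirable
   outputs enter the input side (or, optionally, as weak-disposability
   equality constraints). Super-efficiency scoring removes the
   evaluated observation from its own reference set, so frontier units
   can be ranked above 1. Comprehensive technical efficiency (CRS)
   factors as CTE = PTE × SE.

2. **Stage 2 — SFA on slacks.** Each input's stage-1 slack is regressed
   on environmental covariates with a half-normal stochastic frontier,
   S = zβ + v + u (u ≥ 0). The JLMS conditional mean E[u|ε] separates
   management inefficiency from noise, and inputs are harmonized to the
   least favorable observed environment and luck:
   X\* = X + (max f̂ − f̂) + (max v̂ − v̂).

3. **Stage 3 — re-scoring.** The EBM model is re-run on the adjusted
   inputs; remaining inefficiency is attributable to management.

Productivity change over time is measured by the global
Malmquist–Luenberger index GML = E_G(t+1)/E_G(t), decomposed as
GML = GEFC × GETC, GEFC = GPEC × GSEC, GETC = GPTC × GSTC. Because all
periods share one global frontier the index is transitive:
GML(t→t+2) = GML(t→t+1) · GML(t+1→t+2).

A synthetic panel generator (`generate_panel()`) emulates the study
design the method targets — 13 units × 20 years, 4 inputs, grain output,
carbon emissions, 5 covariates — with full ground truth (true frontier,
environment effects, management inefficiency), so the pipeline's
recovery properties are testable.

## Worked example

```r
library(ebmgml)

g      <- generate_panel(simulation_config(J = 13, T = 20, seed = 42))
report <- run_three_stage(g$panel)
report
#> Three-stage EBM-SFA-EBM report
#>   panel: 13 units x 20 periods
#>   EBM epsilon = 0.1752; super-efficiency: TRUE; bad outputs: as_input
#>   stage-2 dependent slack: radial_plus_slack
#>   weighted mean CTE: 0.548 (stage 1) -> 0.830 (stage 3)
#>   mean GML: 1.050 (before) / 1.014 (after adjustment)
#>   super-efficiency fallbacks: 1 (stage 1), 1 (stage 3)
```

The weighted mean CTE is the output-weighted average score across
units and years; its stage-1 → stage-3 movement shows how much of the
apparent dispersion was environmental. The per-unit rank table makes
the reshuffling explicit (units the environment flattered fall):

```r
head(report$summaries$rank_table[order(report$summaries$rank_table$rank1), ], 5)
#>  unit stage1 rank1 stage3 rank3 change
#>   U03  0.712     1  0.806    10   fall
#>   U10  0.617     2  0.844     4   fall
#>   U02  0.609     3  0.815     9   fall
#>   U05  0.605     4  0.866     3   rise
#>   U07  0.567     5  0.836     7   fall
```

The stage-2 regression table reads like a FRONTIER 4.1 output; a
positive significant coefficient means the covariate inflates that
input's slack (hinders efficiency):

```r
report$sfa[["input1"]]
#> Half-normal stochastic slack frontier (MLE)
#>             Estimate Std. Error t value
#> (Intercept)   2.8121     0.1108 25.3838
#> env1          1.3993     0.1008 13.8752
#> env2         -0.7957     0.0977 -8.1452
#> ...
#> sigma-squared = 10.78, gamma = 0.9886
#> log likelihood = -517.461 (OLS -554.664), LR = 74.406, n = 260
```

Because the panel is synthetic, recovery can be verified against the
generator's ground truth: on this draw the Kendall correlation between
scores and true management efficiency rises from 0.28 (stage 1) to 0.64
(stage 3).

Real data enter through `load_panel()` (wide or long CSV plus a
YAML/JSON schema); all tables are written by `write_stage_report()`.

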
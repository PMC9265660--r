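---
title: "Three-stage EBM efficiency measurement with environmental adjustment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Three-stage EBM efficiency measurement with environmental adjustment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ebmgml)
```

This vignette documents the models behind the package, the parameters a
user can turn, what the synthetic generator does and does not emulate,
and the numerical and design choices that were genuinely open.

## 1. The measurement model

### Stage 1: super-efficiency EBM on a global frontier

Each decision-making unit (DMU) observation $(j,t)$ uses inputs
$x \in \mathbb{R}^m_{>0}$ to produce desirable outputs $y \ge 0$ and an
undesirable output $b \ge 0$ (carbon). The input-oriented EBM program for
observation $k$ against reference set $R$ is

$$\gamma^* \;=\; \min_{\theta,\lambda,s^-}\;
\theta - \varepsilon \sum_i \frac{w_i^- s_i^-}{x_{ik}}
\quad\text{s.t.}\quad
\sum_{j\in R}\lambda_j x_{ij} + s_i^- = \theta x_{ik},\;\;
\sum_{j\in R}\lambda_j y_{rj} \ge y_{rk},\;\;
\lambda, s^- \ge 0,$$

with $\sum_j \lambda_j = 1$ added under variable returns to scale. The key
parameter $\varepsilon \in [0,1]$ interpolates between the radial CCR/BCC
model ($\varepsilon = 0$) and a slacks-dominated measure; the weights
$w^-$ (nonnegative, summing to one) express the relative importance of
the input slacks. With the default input orientation and no slack reward
on the output side the objective is already linear, so no
Charnes–Cooper transformation is needed.

**Undesirable outputs.** By default carbon is folded into the input side
(`bad_output_mode = "as_input"`): it is something to be contracted, it
receives its own slack and its own affinity weight. A
weak-disposability mode replaces this with equality constraints
$\sum_j \lambda_j b_j = b_k$ for sensitivity analysis. Every run report
records which mode was used.

**Global frontier.** All $J \times T$ observations form one reference
technology, so scores are comparable across years and the productivity
index below is transitive. Contemporaneous (same-year) frontiers are
also computed because the index decomposition needs them.

**Super-efficiency.** For the static ranking tables the evaluated
observation is removed from its own reference set, letting frontier
units score above 1. VRS super-efficiency programs can be infeasible;
the package falls back to the non-super score for that unit, flags it
(`status = "fallback-used"`), and counts the fallbacks in the report.
Under a global frontier of $J \times T$ observations this is rare (0–2
cells in a typical 13×20 panel).

**Choosing $\varepsilon$ and $w^-$.** When not supplied, both come from
the affinity-index procedure: for every pair of input columns the
affinity $S(a,b) = 1 - 2D(a,b)$, where $D$ measures the dispersion of
$\log(b_i/a_i)$ normalized by its range, equals 1 exactly for
proportional columns and falls toward 0 as profiles diverge. With
$\rho_{\max}$ the principal eigenvalue of the $m \times m$ affinity
matrix, $\varepsilon = (m - \rho_{\max})/(m-1)$ and $w^-$ is the
normalized principal eigenvector. Proportional inputs therefore give
$\varepsilon = 0$ (the radial model suffices — slacks carry no extra
information), and highly diverse inputs push $\varepsilon$ toward 1.
The procedure is scale-invariant, parameter-free and reproducible,
which is why it is the default; both values can be overridden in the
run configuration.

### Stage 2: stochastic frontier regression of the slacks

For each input $i$ the total stage-1 contraction gap
$S_i = (1-\theta)x_i + s_i^-$ (from the non-super-efficiency global CRS
run) is pooled over all $J \times T$ observations and regressed on the
$p$ environmental covariates:

$$S = z'\beta + v + u, \qquad v \sim N(0, \sigma_v^2), \quad
u \sim \left|N(0, \sigma_u^2)\right|.$$

Slack sitting *above* the environmental frontier is management
inefficiency ($u$); the symmetric part is luck ($v$). The likelihood is
maximized in the FRONTIER 4.1 parameterization
($\sigma^2 = \sigma_u^2 + \sigma_v^2$,
$\gamma = \sigma_u^2/\sigma^2$); per observation,
$\ln 2 - \ln\sigma + \ln\phi(\epsilon/\sigma) +
\ln\Phi(\epsilon\lambda/\sigma)$ with
$\lambda = \sqrt{\gamma/(1-\gamma)}$. The JLMS conditional mean

$$\hat u_i = \mu_{*i} + \sigma_* \frac{\phi(\mu_{*i}/\sigma_*)}
{\Phi(\mu_{*i}/\sigma_*)}, \qquad
\mu_* = \frac{\epsilon\,\sigma_u^2}{\sigma^2},\;\;
\sigma_*^2 = \frac{\sigma_u^2 \sigma_v^2}{\sigma^2},$$

splits each residual into inefficiency and noise, and the inputs are
harmonized to the worst observed footing:

$$X^*_i = X_i + \bigl[\max_j \hat f_j - \hat f_i\bigr]
              + \bigl[\max_j \hat v_j - \hat v_i\bigr],
\qquad \hat f = z'\hat\beta .$$

Both bracketed terms are nonnegative, so $X^* \ge X$ always, with
equality for the observation attaining both maxima. (The published
description of this adjustment formula is garbled in the source text;
the package implements the canonical max-based harmonization, which is
the standard reading.) The one-sided LR statistic against OLS is
referred to the mixed $\chi^2$ distribution (for one restriction,
$\tfrac12\chi^2_0 + \tfrac12\chi^2_1$; 5% critical value 2.706),
because $\gamma = 0$ lies on the parameter boundary.

### Stage 3 and the GML index

Stage 3 re-runs stage 1 on the adjusted inputs. Productivity change is
computed from non-super-efficiency ratio-form scores (global and
contemporaneous, CRS and VRS):

$$\mathrm{GML} = \frac{E_G(t+1)}{E_G(t)}, \quad
\mathrm{GEFC} = \frac{E_{t+1}(t+1)}{E_t(t)}, \quad
\mathrm{GETC} = \frac{\mathrm{GML}}{\mathrm{GEFC}},$$

with GPEC the contemporaneous VRS ratio, GSEC = GEFC/GPEC,
GPTC the ratio of global-to-contemporaneous VRS gaps, and
GSTC = GETC/GPTC. Super-efficiency is deliberately disabled inside the
index: capped scores keep every factor well defined and avoid VRS
infeasibilities inside ratios; super-efficiency remains a stage-1/3
ranking device only. Multi-period averages of indices are geometric
(they are multiplicative objects); the per-unit summary tables are also
offered as arithmetic means because published tables usually print
those.

## 2. Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `epsilon_x` | affinity-derived | radial-vs-slack mix, dimensionless in $[0,1]$ |
| `input_weights` | affinity-derived | slack weights over inputs (+ bads in `as_input` mode) |
| `super_efficiency` | `TRUE` (stage tables) | reference-set exclusion for ranking |
| `bad_output_mode` | `"as_input"` | carbon treatment in the technology |
| `slack_type` | `"radial_plus_slack"` | stage-2 dependent variable; `"pure_slack"` uses $s^-$ alone |
| `weight_pooling` | `"per_year"` | weighted means per year, then averaged; `"pooled"` pools all cells |
| `gamma_starts` | 0.1 / 0.5 / 0.9 | SFA multi-start grid (plus a COLS-skewness start) |

The stage-2 dependent variable deserves a note: the radial part
$(1-\theta)x_i$ spreads the overall contraction over all inputs, so each
input's gap partially reflects the others. This is the conventional
choice for the three-stage adjustment and is kept as the default; the
pure-slack option isolates the non-radial excess only. Because
super-efficiency makes $\theta > 1$ possible (negative gaps), slacks are
always extracted from the non-super-efficiency run.

## 3. What the synthetic generator emulates

`generate_panel()` reproduces the statistical structure the three-stage
method assumes, with full ground truth:

* a frontier input requirement $x^*_i = a_i\, y^{\rho} / g^{t}$ with
  scale elasticity $\rho = 0.97$ (mild decreasing returns — scale
  efficiencies stay near the 0.9+ typical of provincial panels) and
  Hicks-neutral drift $g = 1.02$ per year (a standard agricultural TFP
  growth rate, recoverable from the mean GML);
* environmental covariates with one shared factor that has a persistent
  unit component (provinces keep their climate and urbanization rank),
  giving pairwise covariate correlations of roughly 0.3–0.5 — the mild
  collinearity yearbook covariates show;
* per-input slack $f + u + v$: an environment effect $f = z'\beta$ with
  a common sign pattern across inputs (a disaster year inflates every
  input's slack, with input-specific strength), half-normal management
  inefficiency $u$ whose scale is persistently unit-specific
  (`mgmt_spread`), and Gaussian noise $v$;
* carbon emissions proportional to realized aggregate input use, and
  output-based weights.

**Environment–management confounding.** The parameter `env_mgmt_cor`
(default 0.45) correlates a unit's persistent environmental favorability
with its inefficiency scale, so poorly managed units tend to sit in
flattering environments. This is the situation the three-stage
adjustment exists to correct — with an orthogonal environment, stage-1
rankings are often already correct and the adjustment can only add
estimation noise. It also has an honest cost: correlation between $z$
and $u$ violates the SFA exogeneity assumption, attenuating
$\hat\beta$ and leaving part of the environmental advantage in the
stage-3 scores. The recovery experiments therefore measure a *partial*
correction, which is exactly what the method delivers in the field.

**Calibration.** Default scales (`sigma_u = 1.4`, `mgmt_spread = 0.9`,
`sigma_v = 0.2`, covariate pattern about $\pm 1$) were fixed once so
that (i) adjustment increments stay in the 5–25% range of input levels
(large additive harmonization constants would otherwise distort the
ratio-based scores of smaller units), (ii) stage-1 unit-mean score
dispersion lands around 0.15–0.35 — comparable to the ~0.36 spread seen
in provincial studies, and (iii) the flooring rule ($X \ge 0.05x^*$)
essentially never binds. Unit sizes are drawn with a deliberately tight
spread (`weight_profile = 0.12`): additive slacks on very heterogeneous
sizes would create size-driven efficiency differences that are neither
environment nor management.

**What it does not emulate:** actual provincial magnitudes and units
(tonnes, hectares), spatial correlation between neighboring units,
autocorrelated weather shocks, or measurement error in the covariates.
Passing recovery tests therefore show the pipeline does what it claims
under its own assumptions — not that those assumptions hold in any
particular yearbook panel.

**True efficiency** is defined management-only,
$\bar{e}_{jt} = \mathrm{mean}_i\, x^*_i/(x^*_i + u_i)$: the quantity
stage 3 targets, deliberately excluding the environment and noise
components stage 2 strips.

## 4. Numerical choices

* **LP solver.** The envelopment programs are solved by a dense
  two-phase primal simplex written for this package (DEA programs are
  small — a handful of rows, one column per reference observation — but
  number in the thousands per pipeline run and are highly degenerate,
  with zero right-hand sides on every input row). Dantzig pricing
  switches to Bland's rule after a burn-in to rule out cycling; the
  pivot/optimality tolerance is 1e-9 and score comparisons in tests use
  1e-7. The solver is cross-checked in the suite against an independent
  multiplier-form (dual) formulation solved by `pracma::linprog`,
  agreeing to better than 1e-10 on random panels.
* **Alternate optima.** DEA slacks are not always unique at the optimal
  score; the package reports the solver's optimal basis, and only
  scores and stage-2 slacks flow downstream. This non-uniqueness is a
  known property of DEA, not an implementation artifact.
* **SFA optimization.** BFGS on the unconstrained parameterization
  $(\beta, \log\sigma^2, \mathrm{logit}\,\gamma)$, COLS starting values
  (OLS $\beta$, third-moment $\sigma_u$ floored at a small positive
  value), multi-start over $\gamma$, relative tolerance 1e-12. If no
  interior candidate beats the $\gamma \to 0$ boundary (whose limit is
  exactly OLS), the boundary solution is returned, preserving the
  invariant that the reported likelihood never falls below the OLS
  likelihood.
* **Boundary behavior of $\gamma$.** Near $\gamma = 0$ the likelihood
  is flat along a ridge where a small $\gamma$ trades off against the
  intercept (the intercept absorbs $E[u] = \sigma_u\sqrt{2/\pi}$), so
  $\hat\gamma$ itself is weakly identified on no-inefficiency data
  while slopes and the LR test are pinned down; tests assert the
  latter. Fits with $\hat\gamma$ within 1e-4 of either boundary are
  flagged (`gamma_at_boundary`).
* **JLMS in the tails.** The inverse Mills ratio is evaluated in the
  log domain (`pnorm(..., log.p = TRUE)`), so extreme
  $\mu_*/\sigma_*$ never divides by a zero CDF; degenerate
  $\sigma_* \approx 0$ fits use the exact limiting decomposition.
* **Determinism.** Everything downstream of the data is deterministic:
  fixed multi-start order, no randomized pivoting, no sampling.
  Re-running `run_three_stage()` on the same panel bit-reproduces the
  report.

## 5. Design choices that were open

* **Slacks from the non-super run** (see §2).
* **Carbon in the aggregation:** treating the undesirable output as an
  input-side variable is the common practice when the source method is
  ratio-form; the weak-disposability equality mode is provided because
  neither choice dominates on principle.
* **GML on capped scores** (§1) — standard practice; super-efficiency
  inside index ratios would mix ranking artifacts into productivity
  factors and can be infeasible.
* **Pooled stage-2 regressions:** one regression per input over all
  $J \times T$ observations (matching the single reported coefficient
  set per input in published tables); the Eq.-style max operators range
  over the same pool. Per-year regressions would allow time-varying
  environmental effects but leave ~13 observations per fit.
* **Weighted "period average" cells** are computed per year and then
  averaged over years (output shares drift over two decades); a
  pooled-weights alternative is switchable.
* **Growth rates** are compound annual rates over $T-1$ intervals.
  Published pure-technical and scale-efficiency growth figures of this
  kind do not always reproduce exactly under this formula (recomputation
  gives 0.50%/1.25% against printed 0.51%/1.26%); the package reports
  the CAGR and does not reverse-engineer alternative formulas.
* **No shell entry point.** The package's users drive analyses from R;
  the exported functions plus `write_stage_report()` and the
  acceptance script are the scripting surface.

## 6. Problem sizes used in the test suite

The suite exercises hand-solvable 2–4 unit fixtures; oracle comparisons
on random panels up to 8 units × 3 inputs (about a hundred programs);
SFA recovery at $n$ = 200 and 2000 with a 400-replication size check of
the boundary LR test at $n$ = 100; and three full 13 × 20 pipeline
replicates for the ground-truth recovery checks. These sizes keep the
whole suite to a few minutes while leaving every property at the scale
the method is meant for.

## 7. Known limitations

* The JLMS estimate is a shrinkage of the true $u$; rank recovery of
  management efficiency is partial even with a perfectly specified
  model.
* Slacks of frontier units are censored at zero, which attenuates the
  stage-2 regression — the classic limitation of regressing DEA slacks.
* When environment and management are correlated (the very situation
  the method addresses), the SFA exogeneity assumption fails and the
  environmental effect is under-removed; stage 3 improves on stage 1
  but does not reach the oracle adjustment.
* Half-normal inefficiency only; truncated-normal, exponential and
  heteroskedastic $\sigma_u(z)$ variants are out of scope, as are
  output-oriented and non-oriented EBM, network/dynamic DEA, and
  bootstrap inference on scores or index changes.
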
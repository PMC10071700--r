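---
title: "Detecting and correcting publication bias in multilevel meta-analytic corpora"
author: "pubbias package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and correcting publication bias in multilevel meta-analytic corpora}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

When statistically significant findings are published more readily than
non-significant ones, the published record becomes a biased sample of the
evidence. Two observable signatures follow. First, the *small-study
effect*: studies with larger sampling error need larger estimates to clear
the significance threshold, so effect magnitude correlates with
uncertainty. Second, the *decline effect* (time-lag bias): striking early
results get published fastest, and the published mean drifts toward zero as
the more representative later literature accumulates. Both distort
meta-analytic means, and through them every quantity computed from a
"true-effect" proxy — statistical power, the exaggeration ratio (Type M
error), and the probability of a sign error (Type S error).

`pubbias` implements the full chain: multilevel model fitting, bias
detection and correction per meta-analysis, cross-meta-analysis
(second-order) synthesis, shrinkage quantification, and retrodesign
calculations, together with a synthetic-literature generator that provides
ground truth for calibration and recovery checks.

## The multilevel model

Each meta-analysis contributes effect sizes $ES_{ji}$ (observation $i$ in
study $j$) with known sampling variances $v_i$. The intercept-only model is

$$ES_{ji} = \beta_0 + s_j + o_{ji} + m_{ji},$$

with $s_j \sim N(0, \sigma^2_s)$ between-study effects,
$o_{ji} \sim N(0, \sigma^2_o)$ observation-level effects, and
$m_{ji} \sim N(0, v_i)$ the known sampling error. `fit_multilevel()`
estimates $(\sigma^2_s, \sigma^2_o)$ by restricted maximum likelihood and
$\beta$ by generalized least squares at the optimum. The marginal
covariance is block-diagonal by study, so the restricted likelihood is
evaluated with per-block rank-one updates rather than a dense solve; the
optimizer works on log-variances (L-BFGS-B with three deterministic starts
and a Nelder–Mead polish; convergence tolerance $10^{-8}$ on the restricted
log-likelihood; variances below $10^{-10}$ are treated as zero). Inference
is Wald-normal ($z$), the default of the standard multilevel meta-analytic
software; the confidence level is an argument everywhere.

Two numerical edge cases are handled explicitly. With one effect size per
study the two variance components are jointly unidentifiable; the fit then
reports the total heterogeneity in `sigma2_obs`, sets `sigma2_study = 0`,
and warns. Sampling variances of exactly zero are legal (that is how the
variance-components aggregation model is expressed); a $10^{-10}$ floor
keeps the marginal covariance nonsingular.

In repeated sampling the two variance components trade off: near the
$\sigma^2 \ge 0$ boundary the between-study component is estimated slightly
low and the observation-level component slightly high, while their sum is
essentially unbiased. This is a property of boundary-truncated REML itself
(the estimates agree with independent reference software to $10^{-6}$), and
the recovery tests therefore check the components with Monte-Carlo error
bands and the total heterogeneity alongside.

## Bias detection and correction

Detection augments the model with two moderators (the multilevel extension
of Egger's regression):

$$ES_{ji} = \beta_0 + \beta_1\,\mathrm{error}_i +
  \beta_2\,(year_i - year_{latest}) + s_j + o_{ji} + m_{ji}.$$

$\beta_1$ is the small-study indicator, $\beta_2$ the time-lag indicator.
Centring year at the latest publication year makes $\beta_0$ conditional on
"now". For SMD and lnRR the point estimate and its standard error are
artefactually correlated, so when group sizes are available the uncertainty
predictor is the effective-sample quantity
$\sqrt{1/\tilde n} = \sqrt{(n_e + n_c)/(n_e n_c)}$ instead of $se_i$
(`predictor_mode = "auto"`); Zr uses $se_i$, whose dependence on $n$ only
removes that artefact already. The *correction* model replaces the linear
uncertainty term with its square (the sampling-variance scale), which is
less biased as an estimate of the selection-free intercept when a true
effect exists; $\beta_0$ from that model, conditional on zero sampling
error at the latest year, is the bias-corrected overall effect.

High heterogeneity can flip the detected slopes to signs inconsistent with
selection, in which case keeping those terms harms the corrected intercept.
The sign decision tree compares detected against expected signs (for a
positive overall effect: $\beta_1 > 0$, $\beta_2 < 0$; mirrored for
negative) and selects: both expected — the full quadratic model; only the
small-study slope expected — a refit with the uncertainty term alone; only
the time-lag slope expected — a refit with the year term alone; neither —
the intercept-only model. Detection uses the linear-model slopes;
correction always uses quadratic-error refits, for coherence of the
correction family. An exactly zero overall effect leaves the expected signs
indeterminate; the tree then keeps the full-model intercept and warns. The
package also exposes an alternative mapping
(`correction_variant = "figure_caption"`) that swaps the two single-term
scenarios, because the method's sources describe both conventions; the main
mapping is the default.

Both corrected estimates are always stored: the full-model ("type 1")
intercept and the direction-controlled decision-tree ("type 2") intercept.
A practical warning from the simulations: with few studies the quadratic
correction can overshoot (the corrected intercept lands on the far side of
zero), which inflates its absolute value. This is inherent to
precision-effect-style corrections, not a defect of the decision tree, and
is one reason both estimates are kept.

## Second-order synthesis

Coefficients from different metrics are not comparable in raw units, so
before pooling, each meta-analysis is standardized: the response is divided
by its sample SD (denominator $k-1$, unweighted — no centring, which would
destroy the intercept), and the uncertainty and centred-year predictors are
z-scaled and then shifted so the intercept remains conditional on zero
error at the latest year (the shift replaces $z(x_i)$ by
$z(x_i) - z(x_0)$, which equals $(x_i - x_0)/\mathrm{SD}(x)$). The
z-scaling constants use plain unweighted means and SDs over the
meta-analysis' effect sizes. The quadratic correction model squares the
shifted uncertainty z-score. By scale equivariance of the fit, the
standardized overall effect times the response SD reproduces the raw
overall effect exactly (tested to $10^{-6}$).

The standardized slopes are pooled across meta-analyses by a random-effects
model — the same REML engine with a single level — weighting by inverse
squared standard errors, for the *full* case set and for the *reduced* set
restricted to slopes with expected direction. An effect-size-type moderator
(SMD / lnRR / Zr) yields per-metric pooled means and a marginal
$R^2 = \mathrm{var}(\hat y_{fixed}) / (\mathrm{var}(\hat y_{fixed}) + \tau^2)$.
Heterogeneity among cases is summarized by $\tau^2$ and
$I^2 = \tau^2 / (\tau^2 + \tilde v)$ with $\tilde v$ the Higgins-style
typical sampling variance
$(k-1)\sum w_i / ((\sum w_i)^2 - \sum w_i^2)$, $w_i = 1/v_i$ (a
harmonic-mean variant is available; the two differ by under 5% on typical
variance sets). Two cases cannot support a heterogeneity estimate, so a
two-case pool falls back to the fixed-effect average with a warning.

## Shrinkage: the folded-normal difference

The drop from uncorrected to corrected standardized effect is
$D = |\eta_u - \eta_c|$ with
$\mathrm{Var}(D) = SE_c^2 + SE_u^2 - 2 r\, SE_c SE_u$, $r = 1$ by
assumption (the two intercepts come from nearly identical models; $r$ is an
argument for sensitivity analysis, and $r = 1$ makes
$\mathrm{Var}(D) = (SE_c - SE_u)^2$). Because $D$ is an absolute value it
follows a folded normal distribution; its folded mean and variance

$$D_f = \sqrt{\tfrac{2}{\pi}\mathrm{Var}(D)}\,
  e^{-D^2/2\mathrm{Var}(D)} + D\left(1 - 2\Phi\!\left(\tfrac{-D}
  {\sqrt{\mathrm{Var}(D)}}\right)\right), \qquad
  \mathrm{Var}(D_f) = D^2 + \mathrm{Var}(D) - D_f^2$$

give an estimate and sampling variance suitable for pooling
(`pool_differences()`). The degenerate $\mathrm{Var}(D) = 0$ case uses the
analytic limit $D_f = D$. Folding preserves the second raw moment
($D_f^2 + \mathrm{Var}(D_f) = D^2 + \mathrm{Var}(D)$) and never shrinks the
mean ($D_f \ge D$, equality only in the degenerate case) — both asserted
numerically in the tests. Back-transformation multiplies standardized
differences by each meta-analysis' response SD; per-metric summaries use
the unweighted mean (a weighted variant is an argument), since no canonical
averaging rule exists for this step.

## Power, Type M and Type S errors

For an estimate $\hat\theta \sim N(\theta, se^2)$ tested two-sided at
$\alpha$, with $z_c = \Phi^{-1}(1 - \alpha/2)$ and
$\lambda = \theta / se$:

- power $= 1 - \Phi(z_c - \lambda) + \Phi(-z_c - \lambda)$;
- Type S $=$ P(wrong sign | significant)
  $= \Phi(-z_c - |\lambda|) / \mathrm{power}$;
- Type M $=$ E$[|\hat\theta|\,|$ significant$] / |\theta|$, computed in
  closed form from truncated-normal expectations.

All three depend on $(\lambda, \alpha)$ only. At $\theta = 0$ the
definitions force power $= \alpha$, Type S $= 1/2$, Type M undefined
(reported as `Inf` with a flag). `retrodesign_mc()` is the seeded
Monte-Carlo counterpart kept purely as an oracle for the closed forms.

The "true" effect for every effect size in a meta-analysis is that
meta-analysis' overall mean — uncorrected or bias-corrected (the
decision-tree estimate by default; `truth_mode = "type1"` switches to the
full-model one). This common-truth proxy ignores real context dependence of
true effects and is the method's acknowledged simplification. Sampling-level
aggregation uses a random-intercept-by-study variance-components model (the
REML engine with zero sampling variances) so multi-effect studies do not
dominate; meta-analysis-level aggregation uses a $k$-weighted regression.
Means and medians are both reported, and the post hoc variant drops
meta-analyses with non-significant overall effects before aggregating.
Type M values are stored uncapped; displays conventionally cap at 10.

## The synthetic-literature generator

The generator is a stand-in study system, not a model of any empirical
corpus: it exists so every stage can be tested against known truth at desk
scale. Per meta-analysis it draws study effects
$N(\mu, \sigma^2_{study})$, observation effects $N(0, \sigma^2_{obs})$,
group sizes and publication years uniformly from configured ranges, then
simulates metric-appropriate summary statistics (two-group means and SDs
for SMD and lnRR; a bivariate-normal sample correlation for Zr) and
converts them with the effect-size engine, so the estimate–variance
coupling matches real data. Selection retains significant records always
and non-significant ones with probability $e^{-strength}$ — the simplest
monotone mechanism that produces a small-study signature; with
`decline = TRUE` the strength falls linearly to zero at the latest year,
which induces a decline signature as well. One master seed yields
deterministic per-meta-analysis child seeds, so any single meta-analysis
can be regenerated in isolation.

Default conditions (30 studies per meta-analysis, 1–3 effects per study,
$\mu = 0.3$, $\sigma_{study} = 0.2$, $\sigma_{obs} = 0.1$, groups of
10–100, years 2000–2019) describe a realistic ecological/evolutionary
meta-analysis: moderate heterogeneity relative to sampling variance and
low-to-moderate primary-study power. What the generator deliberately does
*not* emulate: p-hacking, optional stopping, correlated sampling errors
within studies, citation dynamics, or the marginal distributions of any
particular empirical corpus. Passing recovery tests therefore demonstrates
internal correctness of the estimators under the assumed data-generating
process, not robustness to every real-world pathology.

## Problem sizes used in the checks

The recovery and calibration studies are sized for a desk-scale run: 200
replicate meta-analyses (30 studies, 1–3 effects each) for REML parameter
recovery; 40 replicate 8-meta-analysis corpora (15 studies each) for null
calibration of the pooled slopes; 90 meta-analyses of 40 studies for the
selection-recovery study; Monte-Carlo oracles use $10^7$ draws (design
calculus and folded moments). Second-order bias detection is genuinely
low-powered at a dozen cases — mirroring the field, where single
meta-analysis bias tests themselves have low power — hence the
selection-recovery checks pool over several dozen meta-analyses.

## Known limitations

- Correction quality degrades when the uncertainty predictor has little
  spread or the meta-analysis is small; the quadratic correction can
  overshoot zero. The decision tree mitigates but does not remove this.
- No selection-model (Copas / step-function) or trim-and-fill corrections;
  the regression-based family is the scope.
- Sampling errors are assumed independent given the hierarchy (no V
  matrices), and inference is Wald-normal without small-sample t
  adjustments.
- Effect-size conversions between metrics are intentionally not performed;
  each meta-analysis is analysed in its native metric.
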
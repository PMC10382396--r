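---
title: "Consensus scoring of multicentre evidence: model and implementation notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus scoring of multicentre evidence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcscore)
```

## The problem

Multicentre animal studies — the motivating case is haematology screens of
wild-type mice collected by a phenotyping consortium across eleven
laboratories — ask a deceptively simple question: do the centres *agree*
that a trait is sexually dimorphic, and in which direction?  Vote counting
("are all centres significant?") throws away effect magnitudes and is
brittle to a single under-powered centre; meta-analysis pools effects but
answers a different question (is the pooled effect nonzero, and is it
homogeneous?).  The consensus score sits between the two: it aggregates
each centre's corrected p-value and standardised effect size against
*expected* reference values, with an explicit penalty for disagreement in
direction.

## The score

For a trait measured by $\bar{M}$ of the study's $M$ centres, with
per-centre q-values $q_i$ and standardised effect sizes $\rho_i$
(male-positive, Cohen's $d$ scale):

$$
s \;=\;
\begin{cases}
\dfrac{\sum_i q_i \sqrt{|\rho_i|}}{\bar{M}^2\,\hat{q}\,\sqrt{\hat{\rho}}}
\times \max\!\left(\tfrac{M}{2}, \bar{M}\right),
& \bar{M} P > c \\[1ex]
1, & \text{otherwise}
\end{cases}
\qquad
P = \left|\tfrac{1}{\bar{M}}\textstyle\sum_i \operatorname{sign}(\rho_i)\right|
$$

Evidence is read off $-\log_{10} s$: positive values (that is, $s < 1$)
mean the centres jointly beat the reference evidence level and consensus
is declared, with direction given by the sign of the mean effect size.
The square root damps heterogeneous effect magnitudes ($\sqrt{x} > x$ for
$x<1$, $\sqrt{x} \le x$ for $x \ge 1$), so a mixture of very large and
small effects does not destabilise the score.

Three reference parameters encode prior expectation, with recommended
defaults for high-throughput screens:

| parameter | meaning | default |
|---|---|---|
| $c$ | minimum *net* number of direction-agreeing centres | 3 |
| $\hat{q}$ | expected q-value under a real effect | 0.05 |
| $\hat{\rho}$ | expected standardised effect size | 0.5 |

`calibrate_rho_hat()` offers the empirical alternative for $\hat{\rho}$: a
10% trimmed mean of observed absolute effect sizes.

Two branches deliberately return no score.  Fewer than $c+1$ reporting
centres (`INSUFFICIENT_CENTRES`) is below the minimum requirement for the
analysis; a net sign count $\bar{M}P \le c$ (`INSUFFICIENT_INFO`) means
the directions are too balanced for agreement to be assessable, and $s=1$
by definition.  We resolve two ambiguities in the method's description the
following way, and surface both in the documentation: the centre gate is
the strict reading "more than $c$ centres" (a 3-centre trait is not
scored under defaults), and the gate product uses $\bar{M}$ — the centres
that actually performed the test — rather than $M$.  Since
$\bar{M}P = |\sum_i \operatorname{sign}(\rho_i)|$ is an integer, the gate
is an exact integer comparison immune to floating-point noise.  A score of
1 can also arise from exact cancellation in the scored branch; the
`decision` field distinguishes the branches even though both are reported
as "not enough signal".  The logarithm is base 10, pinned by the internal
consistency of published score/neglog pairs (0.45 ↦ 0.35, 0.69 ↦ 0.16);
natural logs would give 0.80 and 0.37.  q-values are clamped to $[0,1]$ on
input, and $\rho_i = 0$ contributes zero to both numerator and penalty.

## Per-centre statistics

Upstream of the score, each centre × trait group is standardised to mean
0 and sample SD 1 (both sexes pooled, $n-1$ denominator), which removes
the additive and multiplicative equipment shifts that dominate
between-centre variation; every downstream effect size and p-value is
invariant to per-centre affine maps of the raw data, and the test suite
asserts this end to end.  The sex effect is then estimated from

$$\text{value} = \text{Sex} + \text{BodyWeight} + (1 \mid \text{Batch}) + \varepsilon$$

via `lmerTest` (Satterthwaite p-value for the sex term).  The reported
effect size is the model-adjusted standardised mean difference: the sex
coefficient divided by the residual standard deviation.  In the
no-covariate, single-batch case this is *exactly* two-sample Cohen's $d$
with the equal-variance t-test p-value, which the tests use as an oracle.
With fewer than three distinct batches, or a singular random-effect fit,
the model falls back to ordinary least squares with a logged message.
Records missing the body-weight covariate are dropped from the fit with a
logged count.  Its standard error uses the usual large-sample formula
$\sqrt{(n_a+n_b)/(n_a n_b) + d^2/(2(n_a+n_b))}$, feeding the
meta-analysis baseline.

A note on collinearity: with a ~5 g male–female body-weight gap and ~3 g
within-sex SD, sex and body weight correlate at $r \approx 0.6$, which
inflates the sex-term standard error by ~30% relative to the unadjusted
comparison.  This is the correct price of covariate adjustment, but it
means per-centre power at 50 animals per sex is noticeably below the
textbook unadjusted power at the same $d$.

q-values are Benjamini–Hochberg (`stats::p.adjust`), by default within
each centre's own family of traits — the correction is attached to "the
test performed in centre $i$" — with a `global` switch pooling all
centre × trait tests, since the family definition is genuinely a user
choice.

## Baselines

`all_agree()` is the binary rule: consensus only if every centre has
$q < \alpha$ and one common sign; it has no centre minimum.
`random_effects_meta()` is a self-contained DerSimonian–Laird
implementation (closed-form moment $\tau^2$, Cochran's $Q$ against
$\chi^2_{k-1}$, normal z-test for the pooled effect); DL was chosen over
REML because it is closed-form and dependency-free, and the baseline's
role here is comparison, not estimation — the test suite cross-checks it
against `metafor::rma(method = "DL")`.  Because a published "meta-analysis
p-value" column can mean either the pooled-effect test or the
heterogeneity test, `compare_baselines()` emits both and asserts neither.

## The synthetic generator

`simulate_measurements()` draws per-animal records from a configuration
with known ground truth: per-centre additive offsets and multiplicative
scales (equipment), batch (test-date) random effects shared within a
centre × batch cell, a body-weight slope, and a true standardised sex
effect `true_d` per trait (optionally per centre, which is how the
disagreement presets are built).  `true_d` is defined on the
covariate/batch-adjusted scale — the raw male−female gap is
`true_d × residual_sd` — so it is exactly the estimand of the per-centre
model; when slopes and batch variance are zero it coincides with the
marginal standardised difference.  The default consortium-style
configuration (`impc_mimic_config()`) has 11 centres × 22 traits × 50 per
sex, offsets drawn once from $N(0, 2^2)$, mild lognormal scale spread
(SD 0.15 on the log), 8 batches at SD 0.25, residual SD 1, body weights
30/25 ± 3 g and a 0.03 per-gram slope; the 22 true effects span roughly
−0.9 to +1.25, matching the magnitude range reported for haematology
traits.  `scenario_preset("S1")`–`"S6"` reproduce the canonical 4-centre
outcome patterns (all agree; 2-vs-2; borderline; strongly diverging;
2-positive-vs-2-negative; mixed), with borderline p-values induced by
effect size and sample size rather than injected, so presets exercise the
entire pipeline.

What the generator does *not* emulate: heavy-tailed or contaminated
residuals, temporal drift within batches, strain differences beyond a
label, missingness mechanisms, or unequal per-centre sample sizes.
Passing tests therefore demonstrate correctness of the statistical
machinery under the Gaussian mixed-model regime the per-centre test
assumes, not robustness of the method on messy real screens.

## Numerical and scale choices

Scores are kept at full precision internally and rounded (default 2
decimals) only in report tables.  The oracle tests compare the
implementation against an independent one-line transcription of the score
at $10^{-12}$ on a thousand random configurations.  Monte-Carlo checks
run at sizes chosen to keep the whole suite in a few minutes on one CPU
while leaving comfortable statistical margins: 200 replicates at 100
animals per sex for null-uniformity and parameter recovery (SE of the
mean $\hat{d}$ ≈ 0.01 against a 0.05 acceptance band), and 100 simulated
6-centre studies per arm for the operating characteristics (power ≥ 95%
at $d = 0.8$, false-consensus ≤ 10% at $d = 0$ — the latter protected
twice, by the sign gate and by large null q-values).

## Limitations

The score is a calibrated evidence ratio, not a test statistic with a
null distribution; its sampling properties are unexplored here, so
$-\log_{10} s$ thresholds other than 0 have no error-rate interpretation.
The per-centre model assumes Gaussian residuals and a common
within-centre variance across sexes.  The FDR family is a convention the
user must own.  And with default parameters nothing below five
direction-agreeing centres (net of disagreers) can ever be scored —
deliberately conservative for consortium-scale inference.
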
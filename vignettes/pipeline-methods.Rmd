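---
title: "Methods: differential expression, biomarker selection and pathway-clinical association mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential expression, biomarker selection and pathway-clinical association mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sepsisproteome)
```

This package implements the statistical core of a plasma-proteomics
case-control analysis with paired longitudinal sampling: a pediatric sepsis
cohort measured on a targeted (~120-protein, CNS-oriented) panel at
intensive-care days 1 and 3 (D1/D3), compared against age- and sex-matched
healthy controls (HC). This vignette documents the models, the tunable
parameters, the synthetic-data generator used for validation, and the
design decisions taken where the methodology was genuinely open.

## The synthetic cohort generator

Real patient-level data of this kind are rarely public, so the package
ships a generator (`sim_config()`, `simulate_cohort()`) that reproduces the
*statistical structure* the analysis assumes, together with the planted
ground truth needed for parameter-recovery testing.

The abundance model is log2-normal per protein: each protein $j$ has a
baseline mean $\mu_j \sim N(8, 2^2)$ (arbitrary log2 units — targeted
immunoassay platforms report normalized abundances whose absolute scale
carries no meaning here) and residual standard deviation
$\sigma = $ `sd_within` (default 0.5). A planted subset of `n_dep`
proteins (default 20) is shifted by a signed effect
$\pm$ `effect_log2fc` (default 1.5) in the sepsis D1 stratum. D3 values
are generated as the subject's D1 value plus the attenuation delta and
fresh noise,

$$x^{D3}_{ij} = x^{D1}_{ij} + (a - 1)\,\delta_j + \varepsilon,\qquad
a = \texttt{d3\_attenuation},$$

which yields both the attenuated D3-vs-HC mean shift ($a\,\delta_j$) and
the within-subject correlation that the paired D3$-$D1 contrast exploits.

**Planted severity correlations.** A per-protein target correlation
$\rho$ (`rho_outcome`, default 0.6) with the PELOD-2 organ-dysfunction
score cannot be achieved for several proteins simultaneously if their
residuals are independent: with $m$ independent proteins and a score built
from them, each protein's correlation is bounded by $1/\sqrt{m}$ scalings
that fail for $m \ge 1/\rho^2$ (for $\rho = 0.6$, $m \ge 3$). The
generator therefore gives the `n_outcome_proteins` outcome proteins a
shared latent severity factor $u_i \sim N(0,1)$ per subject with loading
$\gamma = \sqrt{\rho/(1-\rho)}$, and builds the score from the mean of the
standardized outcome-protein values plus noise with variance
$c^2/\rho^2 - c$, where $c = (\gamma^2 + 1/m)/(1 + \gamma^2)$ is the
covariance between one standardized protein and the mean. Each planted
protein then has population correlation exactly $\rho$ with the score.
The score is mapped to a PELOD-2-like scale ($10 + 4P$, floored at 0,
one decimal); the floor clips ~2% of values and attenuates the realized
correlation by at most a few hundredths. Outcome proteins are drawn from
the planted DEPs first — severity tracking the disease-driving proteins is
the structure the downstream pathway-clinical graph is designed to detect.

**Mortality** is drawn from a logistic model on the standardized D1 values
of `n_mortality_proteins` proteins, with the intercept solved numerically
(Gaussian integral + `uniroot`) so the marginal death probability matches
`mortality_rate` (default 0.15). Demographics and treatment flags (sex,
age, comorbidity and infection-source indicators, ventilation, circulatory
support, lengths of stay) are nuisance variables with no protein signal,
generated at rates typical of severe pediatric sepsis cohorts; they only
exercise the association-matrix and graph machinery.

What the generator does *not* emulate: assay chemistry or count-level
readout noise, inter-protein correlation beyond the single planted latent
factor, informative missingness (an optional completely-at-random mask is
available), or patient dropout — D3 samples exist for every sepsis
subject. Passing tests therefore demonstrate correctness of the
statistical machinery under the stated model, not robustness to every
feature of real clinical proteomics data.

## Differential expression

The DE stage (`de_test()`) is the classical empirical-Bayes moderated
t-test. For the unpaired D1-vs-HC contrast the per-protein effect is the
difference in group means with pooled two-sample variance
($d = n_A + n_B - 2$, unscaled variance $v = 1/n_A + 1/n_B$); the paired
D3-vs-D1 contrast is a one-sample analysis of within-subject differences
($d = n_{pairs} - 1$, $v = 1/n_{pairs}$). Whether the original analyses
paired the timepoints is not documented in this literature; both designs
are exposed and the paired form is the pipeline default because the
repeated-measures structure was collected. Reported fold changes follow
the signed convention $\mathrm{sign}(\beta)\,2^{|\beta|}$, so magnitudes
are always $\ge 1$ and sign carries direction.

The variance prior $s^2_g \sim s_0^2 \chi^{-2}$ with $d_0$ prior degrees
of freedom is estimated by matching the mean and variance of
$\log s^2_g$ to their theoretical digamma/trigamma moments; the trigamma
inversion uses Newton iteration at relative tolerance $10^{-8}$. When the
observed dispersion of log-variances is no larger than the sampling
component, the prior degrees of freedom are infinite and the common
variance is the geometric-mean-consistent value $\exp(\overline{e})$
(note this is the model-consistent estimate, not the arithmetic common
variance — the estimator attributes $\chi^2_d$ sampling noise to the
observed $s^2$ even when there is none). Proteins with exactly zero
residual variance are excluded from prior estimation but still tested
with the shrunken variance. The moderated statistic is

$$\tilde s^2 = \frac{d_0 s_0^2 + d\,s^2}{d_0 + d},\qquad
t = \frac{\hat\beta}{\tilde s \sqrt v},\qquad
\mathrm{df} = d_0 + d,$$

which reduces to the ordinary t-test at $d_0 = 0$ and to a fixed-variance
z-form as $d_0 \to \infty$. The test suite cross-checks the whole path
(prior, t, p) against limma on a simulated cohort.

DEP calling uses Benjamini-Hochberg adjusted $p \le 0.05$ and linear fold
change $\ge 2$, read symmetrically as $|\log_2 \mathrm{FC}| \ge 1$ with
boundaries inclusive — printed DEP lists in this literature contain both
large positive and large negative fold changes, so a one-sided reading
would be wrong. No minimum-expression filter is applied.

## Boruta feature selection

`boruta_select()` wraps depth-limited random forests (ranger, impurity
importance, single-threaded with fixed seeds for determinism). Each
iteration appends one shuffled shadow copy of **every** real feature,
trains a forest on the doubled matrix, and scores a hit for each
undecided feature whose importance strictly exceeds the maximum shadow
importance. A two-sided binomial test (success probability 0.5,
Bonferroni-corrected over the undecided features) confirms or rejects
after every iteration; features undecided after `max_iter` iterations are
reported tentative, never force-resolved.

Two design points deserve emphasis:

* **The full doubled design is retained every iteration.** A variant that
  removes rejected features (and their shadows) from subsequent
  iterations — as some implementations do — was measured here to be badly
  anticonservative: once the pool shrinks, the surviving feature with the
  largest spurious correlation beats the small fresh shadow pool in ~70%
  of iterations (versus ~7% against the full pool) and is eventually
  confirmed even on pure noise. Keeping all shadows holds the max-shadow
  threshold at the level of the whole feature pool and yields zero
  confirmations across seeded all-noise designs.
* **Forest sizes.** The published protocol ties 5,000 trees (maximum
  depth 5; read as tree depth — "5 leaves" is not a standard constraint)
  to the *classifiers*; the per-iteration Boruta forests here use 500
  trees, with the final re-ranking of confirmed features
  (`rerank_selected()`) at the full 5,000. Impurity importance is used
  rather than permutation importance for determinism and speed.

Class weights are untouched: the emulated cohorts are balanced by design.

## Outcome correlations

`correlate_panel()` computes protein-wise Pearson correlations against
continuous severity scores (per timepoint: D1 proteins vs D1 scores, D3
vs D3) and point-biserial correlations against mortality (identical to
Pearson under 0/1 coding — asserted to $10^{-12}$ in the tests).
P-values come from the exact t transform
$t = \rho\sqrt{n-2}/\sqrt{1-\rho^2}$. Missing values are removed pairwise
per protein; constant proteins are skipped with a warning.
Benjamini-Hochberg adjustment is applied within each (variable,
timepoint) panel — the family the corresponding volcano panel displays —
not across panels. Whether patients who die before D3 sampling should
leave the D3 mortality panel is not modeled: the generator produces a D3
sample for every subject, and with real data the panel uses whatever
samples exist at the timepoint. All tests are two-sided.

## Over-representation analysis

`enrich()` tests a DEP list against any GMT-style gene-set collection
with the one-sided hypergeometric upper tail (depletion is not tested),
the cross-product odds ratio (0 for empty overlap, $+\infty$ for a
degenerate zero cell with positive overlap), and Benjamini-Hochberg FDR
over the tested terms. The default universe is the measured panel, not a
whole-genome background: for a targeted panel, genome-background
enrichment conflates panel design with biology; the universe is an
explicit argument for callers who want the other convention. Terms are
tested only when their within-universe size is between 2 and $N-2$.

The direction z-score reported alongside each term is
$z = (U - D)/\sqrt{U + D}$, with $U$/$D$ the up/down counts among the
term's hit members (zero fold changes count in neither, with a warning).
The printed z-scores in this literature are not accompanied by a formula
and cannot be reverse-engineered without the underlying data, so this
definition is documented prominently and no numeric agreement is claimed.

## The pathway-clinical association graph

The graph stage is the bespoke part of the method. Each protein implicated
in a significantly enriched term gets a relative importance equal to the
Euclidean norm of its volcano-plot coordinates,

$$R = \sqrt{\left(\log_2 \mathrm{FC}\right)^2 +
            \left(-\log_{10} p_{adj}\right)^2},$$

and, for each clinical variable whose correlation with the protein is
significant at **raw** $p < 0.05$ (the gate is deliberately unadjusted,
matching the stated rule of the source method), contributes a signed
weight $w = \rho R$. Protein-level weights are aggregated into one edge
per (term, variable) pair; the aggregation is not specified in the source
and defaults to the **sum** (preserving evidence mass; the mean is
exposed). Adjusted p-values are floored at $10^{-300}$ before the
$-\log_{10}$ — printed adjusted p-values in such panels reach $10^{-28}$,
and a true zero would make $R$ infinite. $R$ uses the adjusted p from the
same contrast that defined the term's DEP membership (D1-vs-HC for the D1
analyses). The graph is strictly bipartite (pathway vs clinical nodes)
and serializes to GraphML with `node_type`, `weight` and `n_proteins`
attributes; the protein-level detail stays available in-memory as a graph
attribute.

## Cohort summary

`summarize_cohort()` reports median (IQR) for continuous variables —
quartiles by linear interpolation (type 7), the most common convention
and R's default, since no quartile rule is ever printed — and count
(percent) for categorical ones, with percentages rounded half-up to
integers (this reproduces every printed cohort percentage exactly).
Group comparisons use Mann-Whitney U (exact when the combined $n \le 20$
without ties, normal approximation with tie correction otherwise) and
Pearson chi-square without continuity correction. The pairwise
association heatmap (`association_matrix()`) tests every variable pair
with the type-appropriate test and assigns tiers from the raw and
BH-adjusted p-values over the whole family of pairs.

## Problem sizes and numerical choices

The validation suite runs at the emulated study scale (23 + 23 subjects,
120 proteins) for calibration and recovery checks — 20 seeds for the
global-null type-I envelope and the planted-DEP recovery, 5 seeds for the
Boruta power and null designs (n = 100, 5 planted + 55 noise features,
500-tree iterations) — and at inflated sizes (n = 200-1000) for
law-of-large-numbers checks of the generator itself. Exhaustive oracles
back the small-scale statistics: the hypergeometric tail is compared
against complete draw enumeration for all universes up to $N = 12$, the
BH adjustment against the brute-force step-up rejection rule on 1,000
random p-vectors, and the exact Mann-Whitney branch against full
arrangement enumeration.

Determinism is treated as a contract: every stochastic stage takes an
explicit seed, sub-seeds are derived with a fixed integer recurrence, and
two pipeline runs with the same configuration produce byte-identical
result tables (asserted in the tests). RNG state is restored after every
internal draw, so library calls never perturb a caller's random stream.

## Known limitations

* The moderated-t stage covers two-group and paired contrasts only — no
  covariate design matrices, array weights, or trend/robust variants.
* Impurity importance is biased toward high-cardinality features in
  general; with an all-continuous panel this is benign, but the choice is
  configurable in spirit (the forest backend supports permutation
  importance) and documented rather than hidden.
* The planted latent-factor structure means planted severity proteins are
  mutually correlated; estimators that assume independent proteins (e.g.
  the BH adjustment) operate under positive dependence, where BH remains
  valid.
* Printed headline counts from any specific study (numbers of DEPs or
  selected proteins) depend on the unpublished patient data and are not
  reproduction targets; the package validates calibration and recovery on
  data with known truth instead.
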
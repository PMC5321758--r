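---
title: "Cross-tumour KRAS signature discovery: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-tumour KRAS signature discovery: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`krassig` implements a discovery-and-validation workflow for transcriptional
signatures of oncogenic KRAS that generalize across tumour types. The
workflow has three stages — per-system differential expression with a
cross-system intersection rule, preranked enrichment across patient cohorts
with leading-edge recurrence filtering, and signature scoring with status
classification and survival stratification — plus standalone modules for
standardized-mean-difference meta-analysis, hypergeometric category
enrichment, and Chou–Talalay drug-combination analysis. This vignette
explains the models, their assumptions, the tunable parameters, and the
design choices made where the design was genuinely open.

## Moderated differential expression and the B statistic

Inputs are log2-scale, normalized genes × samples matrices with a two-group
phenotype (`KRAS_mut` vs `KRAS_wt`). Before testing, genes expressed below a
floor (default 5 log2 units; 4 for the knockdown-array configuration) in
strictly more than half of all samples are discarded — the convention being
that a gene low in *exactly* half the samples is retained.

For gene $g$, with group means $\bar{x}_A, \bar{x}_B$ and pooled residual
variance $s_g^2$ on $d$ degrees of freedom, the empirical-Bayes model places
a scaled inverse-chi-square prior on the true variances,
$s_g^2 \sim s_0^2\, d_0/\chi^2_{d_0}$. The hyperparameters $(d_0, s_0^2)$
are estimated by moment matching on $\log s_g^2$ (digamma/trigamma
identities; the trigamma function is inverted by Newton iteration). The
posterior variance
$\tilde{s}_g^2 = (d_0 s_0^2 + d\, s_g^2)/(d_0 + d)$ yields the moderated
statistic

$$ t_g = \frac{\bar{x}_A - \bar{x}_B}{\tilde{s}_g \sqrt{1/n_A + 1/n_B}}, $$

referred to a t distribution on $d_0 + d$ degrees of freedom. Two limits are
useful for verification and are exposed as overrides: $d_0 = 0$ recovers the
ordinary pooled-variance t, and $d_0 = \infty$ gives every gene the common
variance $s_0^2$ so that ranking by $|t|$ coincides with ranking by
$|\log_2 \mathrm{FC}|$.

The B statistic is the log posterior odds that a gene is differentially
expressed under a two-component mixture in which a proportion `p_prior`
(default 0.01, the method's conventional default; the choice is exposed
because no single value suits every platform) of genes carry a true effect
with prior variance $v_0$ (in units of the unscaled coefficient variance).
$v_0$ is estimated by quantile matching on the top 10% of genes by $|t|$.
With $r = (v + v_0)/v$,

$$ B = \log\frac{p}{1-p} - \tfrac{1}{2}\log r +
   \frac{1 + d_{tot}}{2}\,
   \log\frac{t^2 + d_{tot}}{t^2/r + d_{tot}}. $$

B is monotone in $t^2$ at fixed hyperparameters, so the `B > 0` cutoff used
throughout is a posterior-odds-greater-than-one rule. In the test suite the
moderated t and p-values are cross-checked against the independent `limma`
implementation (agreement to 1e-10 on shared hyperparameters), while B is
checked against a direct closed-form evaluation; the two routes are kept
separate so neither implementation validates itself.

**Selection rules.** A candidate gene must satisfy `B > 0` and
`log2FC > 1` (both strict) in at least two of the discovery systems; genes
absent from a system count as failing there. The knockdown signature uses
linear fold change below 0.5 (`log2FC < -1`) with `B > 0`.

## Preranked enrichment and leading-edge recurrence

Each validation cohort is ranked by the mutant-minus-wild-type log2 fold
change (descending, with a deterministic lexicographic tie-break). The
enrichment score is the signed maximum deviation of the weighted
Kolmogorov–Smirnov running sum: hits contribute $|m_i|^p / N_R$ (weight
exponent $p = 1$ by default, the reference method's default; $p = 0$ gives
the classical unweighted KS statistic) and misses $1/(N - N_H)$.

Significance uses a gene-resampling null — the only null available once the
data have been reduced to a ranked list — with same-size random sets:
$p = (1 + b)/(1 + B_s)$ where $b$ counts same-sign null scores at least as
extreme and $B_s$ the same-sign nulls; the +1 pseudo-count avoids zero
p-values. NES divides the observed score by the mean |null score| of the
same sign. Permutations use a fast path that evaluates the running-sum
extremes from hit ranks alone in $O(|S|\log|S|)$; the tests require it to
agree exactly with the literal $O(N)$ running sum and with a brute-force
$O(N\cdot|S|)$ oracle.

The leading edge is the subset of the gene set at or before the running-sum
maximum (at or after the minimum for negative scores). The core signature
keeps genes present in strictly more than `recurrence_min_fraction`
(default 0.5) of the per-cohort leading edges — a gene in 5 of 9 edges
passes, one in exactly 3 of 6 does not. By construction the core signature
is always a subset of the stage-1 candidate set; the pipeline halts with an
explicit status (not an error) whenever an intermediate set is empty, so
partial reports remain usable.

## Signature scores, classification, survival

Two per-sample scores are implemented because the source analyses used
both: the **geometric-mean** score $2^{\overline{\log_2 x}}$ over the
signature genes (the geometric mean of linear-scale values), and the
**z-summation** score, the sum of per-gene standardized expression. The
status classifier defaults to the summation score. Missing signature genes
are dropped with the exponent renormalized — real cohorts lose probes — but
only down to a configurable coverage floor (default 0.75 of the signature).

Status prediction is a single-feature logistic regression (IRLS via
`stats::glm`); complete separation is detected and reported as a flagged
fit rather than an error. Discrimination is summarized by the ROC/AUC in
the rank (Mann–Whitney) formulation with half-credit for ties, which the
tests verify against literal concordant-pair counting.

Survival analysis delegates Kaplan–Meier estimation, the Mantel–Cox
log-rank test and Cox proportional-hazards fitting (Efron tie correction;
it reduces to Breslow without ties) to the `survival` package behind the
module's validated interfaces. Patients are dichotomized at a configurable
within-stratum score quantile — the cutpoint used for published
Kaplan–Meier panels of this kind is rarely stated, so the default is a
median split and the quantile is recorded in the report; ties at the
threshold go to the low group. Stage is treated as an ordinal numeric
covariate and sex as binary.

## Meta-analysis, category enrichment, synergy

Per-study effects are Hedges' $g$: $d$ in pooled-SD units shrunk by
$J = 1 - 3/(4(n_1+n_2-2)-1)$, with the standard variance formula.
Pooling is inverse-variance fixed-effect or DerSimonian–Laird
random-effects ($\tau^2 = \max(0, (Q - df)/C)$); random effects is the
default since cross-platform cohorts are heterogeneous. The tests verify
both against `metafor` and check 95% CI coverage by simulation.

Category enrichment is the inclusive hypergeometric upper tail
$P(X \ge k)$ with Benjamini–Hochberg adjustment; categories are supplied as
GMT sets and taken as given (no ontology-graph propagation).

Drug-combination analysis follows the median-effect equation
$f_a/f_u = (D/D_m)^m$: ordinary least squares of
$\log_{10}(f_a/(1-f_a))$ on $\log_{10} D$ gives slope $m$ and median-effect
dose $D_m = 10^{-\mathrm{intercept}/m}$. Fractions of exactly 0 or 1 are
excluded from fitting (their logit is undefined) rather than clamped. The
combination index at observed combined effect $f_a$ is
$CI = d_1/D_{x,1} + d_2/D_{x,2}$ with $D_x = D_m (f_a/(1-f_a))^{1/m}$:
CI < 1 synergism, CI = 1 additive, CI > 1 antagonism. Doses are taken as
given (non-constant-ratio design, matching fixed concentration pairs used
in practice), and the categorical call treats $|CI - 1| \le 0.05$ as
additive — a reporting convenience around the strict thresholds.
The module also provides the noncentral-t two-sample power calculation
(both rejection tails retained), the exponential-growth population doubling
time $PD = T\log 2 / (\log N_t - \log N_0)$ — the conventional formula;
typeset variants that omit the division of elapsed time by the number of
doublings are dimensionally inconsistent — and the ellipsoid tumour volume
$\pi/6 \cdot \ell w^2$.

## What the synthetic data emulate — and what they do not

The generator produces the structure every stage assumes: multiple
expression matrices sharing one gene universe, a planted set of
genotype-associated genes, Gaussian log2-scale noise (matching
RMA-normalized inputs), censored exponential survival whose hazard is
log-linear in a centered score, and noise-free or logit-noise median-effect
curves. Defaults are fixed once: 2000 genes, 20 planted at +1.5 log2 units,
noise sd 0.5, 10 samples per group, 3 systems and 4 cohorts. Cohort effects
are attenuated by 0.7 to model cross-dataset heterogeneity, so the
recurrence filter is exercised non-trivially; per-gene baselines are
N(7, 1) log2 units — a typical post-RMA mid-range — so the floor-5 filter
removes a small tail of genes without touching the planted set. Survival
uses an exponential baseline for closed-form sanity checks.

The generator deliberately omits probe-level artifacts, batch effects,
heavy-tailed noise, correlated gene blocks and copy-number structure.
Passing the end-to-end tests therefore demonstrates that the machinery is
correct and calibrated under its stated model, not that real cohorts of
this size would yield equally clean recovery.

## Numerical choices and problem sizes

Tolerances: oracle-equivalence tests at 1e-10–1e-12; Cox and logistic
convergence at 1e-8; the additive-CI identity at 1e-9. Degenerate inputs
are handled explicitly: zero residual variance is floored at machine
epsilon with a warning, zero-variance genes are excluded from z-summation,
ranked-list ties break lexicographically, AUC ties earn half credit, and
the pipeline reports statuses instead of raising on empty gene sets. The
test suite's simulation sizes (2000-gene null calibration; 500 permutation
replicates at 300 permutations each; 20 replicates of n = 500 for Cox
recovery; 500-replicate coverage runs) were chosen to give stable
acceptance margins while keeping the whole suite in the tens of seconds on
one CPU.

## Known limitations

Two-group contrasts only (no general design matrices, array weights or
duplicate correlation); no FDR across multiple gene sets in the preranked
module (the workflow tests one candidate set per cohort); no
phenotype-permutation GSEA; no time-varying covariates or competing risks;
mouse-to-human mapping defaults to case-folded symbol equality with a
user-supplied two-column override table, since cross-species probe mapping
is dataset-specific. The package's function surface (with
`run_discovery()` as the driver and `write_discovery_report()` for
serialization) is the intended interface; no shell entry point is shipped.
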
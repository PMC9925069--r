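---
title: "Cis-instrument two-sample MR: models, defaults and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cis-instrument two-sample MR: models, defaults and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cismr)
```

## The problem cismr addresses

Drug-target Mendelian randomisation asks what sustained pharmacological
modulation of a protein would do to disease risk, using genetic variants in
or near the gene encoding the target as unconfounded proxies. The motivating
application is IL-6 receptor (IL6R) blockade: variants within a window of
*IL6R* that lower C-reactive protein (CRP, the canonical downstream readout
of IL-6 signalling) mimic IL-6 receptor antagonists such as tocilizumab, and
their associations with sepsis, severe COVID-19 and other infections — taken
from large case–control GWAS in separate cohorts — let us estimate the
causal effect of "one unit of natural-log CRP decrease" on the log-odds of
each outcome. cismr implements the full summary-statistics pipeline for this
design: harmonisation, cis instrument construction, the estimator suite, a
robustness battery, directional clustering of instrument signatures, and
cross-cohort meta-analysis, together with a calibrated simulator so every
stage is testable without access to biobank data.

## Model and estimators

For variant $j$, let $\hat\gamma_j$ (SE $s_{\gamma j}$) be its association
with the exposure and $\hat\Gamma_j$ (SE $s_{\Gamma j}$) with the outcome on
the log-odds scale, both expressed for the same effect allele after
harmonisation. Each variant gives a Wald ratio
$\hat\beta_j = \hat\Gamma_j / \hat\gamma_j$ with first-order standard error
$s_{\Gamma j}/|\hat\gamma_j|$; first-order means the exposure-side
uncertainty is ignored, which is accurate for strong instruments (the
bundled fixture's weakest variant has $F = (\hat\gamma/s_\gamma)^2 = 31.1$,
and the simulator's defaults put every $F$ above 70).

The inverse-variance weighted (IVW) estimate pools the ratios with weights
$w_j = \hat\gamma_j^2 / s_{\Gamma j}^2$:

$$\hat\beta_{IVW} = \frac{\sum_j w_j \hat\beta_j}{\sum_j w_j},
\qquad
\mathrm{SE}_{fixed} = \Big(\sum_j w_j\Big)^{-1/2},$$

algebraically identical to a zero-intercept weighted least-squares
regression of $\hat\Gamma$ on $\hat\gamma$ (the test suite asserts this
equivalence against an independent `lm()` solve on random inputs).
Heterogeneity is summarised by Cochran's
$Q = \sum_j w_j(\hat\beta_j - \hat\beta_{IVW})^2$ on $n-1$ df. The default
effects model is fixed (common effect); the multiplicative random-effects
variant, which scales the SE by $\max\{1, \sqrt{Q/(n-1)}\}$ without moving
the point estimate, is available by flag.

The sensitivity estimators relax the exclusion-restriction assumption in
different directions:

* **MR-Egger** regresses $\hat\Gamma_j$ on $\hat\gamma_j$ with a free
  intercept (weights $1/s_{\Gamma j}^2$, instruments re-signed so every
  $\hat\gamma_j > 0$). The intercept estimates the average directional
  pleiotropic effect; the slope is a pleiotropy-adjusted causal estimate.
  Coefficient SEs are inflated by $\max(1, \hat\sigma)$ and tested on
  $t_{n-2}$.
* The **weighted median** takes the ratio value at the 50th percentile of
  the weight-ordered ratio distribution (linear interpolation between
  cumulative-weight midpoints), consistent while valid instruments carry
  more than half the weight; its SE comes from a parametric bootstrap with a
  mandatory seed.
* **Unweighted pooling** discards the exposure weights entirely and
  inverse-variance-pools the $\hat\Gamma_j$ alone (per-allele scale) — the
  check that results do not hinge on the CRP weighting source.
* The **radial scan** decomposes $Q$ into per-variant contributions
  $q_j = w_j(\hat\beta_j - \hat\beta_{IVW})^2$, tests each against
  $\chi^2_1$, and flags outliers at a Bonferroni-adjusted $\alpha = 0.05$ by
  default, with a single re-estimation pass after removal. Because the same
  first-order weights are used throughout, $\sum_j q_j = Q$ exactly.
* **Leave-one-out** and **per-variant Wald ratios** complete the battery.

All odds ratios are reported, by default, on the blockade orientation:
`orient_to_blockade()` negates the exposure effects (swapping alleles and
mirroring frequencies) so a positive log-odds estimate means risk rises as
the exposure falls, matching how IL6R-blockade effects are conventionally
presented per unit of lnCRP *decrease*.

## Harmonisation rules

Outcome records are aligned to the exposure's effect allele by direct match,
allele swap (sign flip), or strand complement of either. Palindromic
variants (A/T, C/G) carry no strand information in their allele labels, so
orientation is inferred from allele frequency — accepted only when both
panels' frequencies are decisive, i.e. $|EAF - 0.5| >$ `freq_window` (default
0.08) in both — and dropped otherwise; a `drop` policy excludes them
outright. Palindromic variants lacking a frequency are always dropped. Every
exclusion carries a reason code, and matched + unmatched + excluded always
equals the exposure panel size. Proxy lookup (`find_proxy()`) returns the
highest-$r^2$ candidate at $r^2 \ge 0.8$ by default, ties broken by genomic
position. These thresholds are common two-sample-MR conventions, configurable
because the convention, not a derivation, fixes them.

Instrument construction keeps variants inside the closed interval
`[start - window_bp, end + window_bp]` around the gene (window 300 kb by
default, 10 kb for the restricted sensitivity run) and applies greedy LD
pruning: repeatedly keep the variant with the smallest exposure p-value and
drop everything with $r^2 \ge$ 0.1 against it. Ordering is canonical
(p-value, then position, then ID), so the output is independent of row
order. The LD matrix is a required input — the package never computes LD
from genotypes nor fetches annotation.

## Noise-augmented directional clustering

To probe heterogeneity, instruments are clustered on their standardised
multi-trait signatures: the matrix $z_{jt} = \hat\Gamma_{jt}/s_{\Gamma jt}$
(rows oriented to the exposure-increasing allele, traits missing any
instrument dropped). Rows are scaled to unit length — only the *direction*
of a variant's effect profile matters — and fitted with a mixture of $K=10$
von Mises–Fisher components (mean direction $\mu_k$, concentration
$\kappa_k$) plus one uniform-on-the-sphere noise component, by EM with 50
seeded restarts. The concentration M-step uses the Banerjee closed form
refined by Newton steps so the likelihood is non-decreasing at every
iteration (asserted in tests). Variants whose top cluster probability falls
below 0.8 are labelled noise.

Maximum likelihood with a deliberately generous $K$ has two well-known
pathologies, which the fit resolves in a consolidation pass after EM:
coincident components that split one tight bundle are merged (mean-direction
cosine > 0.9; antipodal directions are never merged, so opposite-effect
bundles stay distinct), and components that are under-occupied (< 4 expected
members) or barely more concentrated than chance alignments among isotropic
rows ($\kappa < 3T$ for $T$ traits — the concentration a component reaches
by latching onto the best-aligned handful of random directions) are
dissolved into the noise class. The published tool this emulates is not
described at the likelihood level in the available text, so the package
validates the *form* of the method by planted-partition recovery (adjusted
Rand index, noise recall) rather than by reproducing any specific reported
membership list. Per-cluster MR then reruns the IVW within each recovered
cluster.

## The synthetic-data generator

`simulate_two_sample()` emulates the geometry of the motivating study as its
default: 26 cis instruments, an exposure GWAS of $n = 522{,}681$ (the
CHARGE + UK Biobank hsCRP meta-analysis size), and a binary outcome GWAS of
11,643 cases / 474,841 controls (UK Biobank sepsis). Minor-allele
frequencies are uniform on (0.05, 0.45); true per-allele exposure effects
have uniform magnitudes on (0.02, 0.12) lnCRP with random signs — strong
instruments throughout, as cis pQTL/eQTL instruments typically are. Standard
errors use the score approximations $s_\gamma = (2n\,p(1-p))^{-1/2}$ for a
unit-variance exposure and
$s_\Gamma = (2n_{eff}\,p(1-p)\,\phi(1-\phi))^{-1/2}$ with case fraction
$\phi$; observed effects are normal draws around the truth. Fifteen percent
of variants are palindromic (with decisive frequencies) and fifteen percent
of outcome records are strand-flipped, plus half allele-swapped, so
harmonisation is always exercised end to end. Allele frequencies are
reported noise-free in both panels.

Pleiotropy models: `balanced` (mean-zero), `directional` (mean $\mu$,
defined per exposure-increasing allele — sign-coupled to $\gamma_j$, since a
mean shift on arbitrary allele labels would cancel under Egger
re-orientation), and `correlated` ($\alpha_j = \delta\gamma_j +$ noise on a
fraction of variants, default 0.3, violating InSIDE while keeping invalid
weight below half). The truth ledger satisfies
$\Gamma_j = \beta\gamma_j + \alpha_j$ exactly, and a single master seed
makes every panel byte-reproducible.

What the simulator does *not* emulate: LD between instruments feeding the
estimators (panels are generated independent; LD enters only through
`simulate_ld()` for pruning tests), winner's curse in instrument discovery,
sample overlap between exposure and outcome GWAS, and allele-frequency
estimation error. Calibration results under the simulator therefore speak to
the estimators' correctness under the stated model, not to robustness
against those real-data features.

## Calibration and verification strategy

The test suite (and `scripts/acceptance.R`) verifies, at problem sizes
chosen to keep a full run within a few minutes on one core:

* IVW type-I error at $\alpha = 0.05$ within the binomial band
  [0.035, 0.065] over 1,000 null replicates of the default scenario, and —
  at a true log-OR of $-0.223$ (OR 0.80) per exposure unit — mean estimate
  within 3 Monte-Carlo SEs of truth with 95% CI coverage in [0.93, 0.97].
* MR-Egger's intercept recovering the directional-pleiotropy mean $\mu$
  within 3 Monte-Carlo SEs over 300 replicates while IVW is measurably
  biased.
* Radial detection of a planted instrument displaced by 10 ratio-SEs in
  100% of 200 replicates. A caveat worth stating precisely: the *exact-set*
  rate (the planted variant flagged and nothing else) plateaus near
  0.92–0.95 rather than above it, because the outlier drags the pooled
  estimate every contribution is measured against — a structural property
  of the single-pass scan with all-SNP weights, present at any displacement
  large enough to guarantee detection. Both rates are reported.
* Clustering recovery (ARI $\ge 0.9$, $\ge 90\%$ noise recall) on a planted
  two-cluster matrix of 52 variants by 20 traits, and EM monotonicity on
  every fit.
* The worked meta-analysis examples: pooling the published UK Biobank
  sepsis OR 0.80 (0.66–0.96) with FinnGen streptococcal sepsis 0.79
  (0.48–1.31) gives 0.80 (0.67–0.95), and with FinnGen respiratory sepsis
  0.63 (0.29–1.35) gives 0.79 (0.66–0.95) — recomputed from the printed
  per-cohort intervals via $\ln OR$ and
  $SE = (\ln CI_{high} - \ln CI_{low}) / (2 \times 1.959964)$.

On the weighted median's breakdown property: under correlated pleiotropy
confined to a minority of weight, the median is consistent but carries a
finite-sample shift of roughly $0.57\sigma_r$ (it sits at the
$0.5/(1-f)$ quantile of the clean ratio distribution, $\sigma_r$ the
per-variant ratio SE, $f$ the invalid fraction). At biobank-scale noise this
shift, while several times smaller than the IVW bias, is not statistically
zero — so the suite asserts the comparative statement (median bias
significantly and substantially smaller than IVW bias in the direction of
$\delta$), which is the property that matters in practice.

## Numerical conventions and degenerate inputs

The normal 97.5% quantile is fixed at 1.959964 for every CI and CI-to-SE
conversion. P-values are two-sided normal except MR-Egger's $t_{n-2}$. A
single-instrument set routes IVW to the exact Wald ratio (multiplicative
falls back to fixed with a message); Egger and the weighted median require
three instruments. A zero exposure effect is an error for ratio-based
estimators, never silently dropped. `or_ci_to_log()` rejects zero-width
intervals. Forest-table ORs are rendered to two decimals with R's
round-half-even and trailing zeros trimmed ("0.3–0.78"), matching how such
tables are usually typeset. Pipeline reruns under a fixed configuration are
byte-identical; every stochastic step (median bootstrap, mixture restarts,
simulation) requires an explicit seed.

## Known limitations

Correlated instruments are pooled as if independent (generalised IVW using
the LD matrix is out of scope); the LD matrix serves pruning and proxy
search only. Meta-analysis is fixed-effects only, appropriate for the
common-effect question asked here. The clustering component's consolidation
thresholds (merge cosine 0.9, minimum occupancy 4, concentration floor
$3T$) are heuristics chosen for planted-partition behaviour and exposed as
arguments; they are not estimates of anything. The bundled 26-variant cis
fixture is synthetic — constructed on GRCh37 *IL6R* coordinates with the
documented window geometry (7 variants within 10 kb) and instrument-strength
floor — and stands in for a real instrument list structurally, not
numerically.
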
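---
title: "Artificial-imputation association testing: model, metric and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Artificial-imputation association testing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snipscan)
```

## The problem

A GWAS detects an untyped causal variant only through genotyped SNPs in
linkage disequilibrium (LD) with it. In populations poorly tagged by the
genotyping array — African populations on European-designed arrays being the
canonical case — no single genotyped SNP may be in strong LD with the causal
variant, yet several SNPs in *weak* LD with it may, considered together,
carry nearly equivalent information. Imputation and haplotype regression
exploit this but are computationally heavy and demand careful post-analysis
quality control.

The artificial-imputation (AI) test is a lightweight alternative. For each
genotyped **anchor** SNP it selects one nearby **partner** SNP and tests the
anchor *conditional* on the partner. If the local LD pattern is such that
anchor and partner carry complementary information about a causal variant,
the conditional test recovers signal that the single-SNP test misses.

## The test

For a binary trait, let $x_1$ and $x_2$ be the minor-allele dosages at the
anchor and partner SNPs. Two logistic models are compared:

$$\operatorname{logit} p = \beta_0 + \beta_1 x_1 + \beta_2 x_2
  \quad\text{vs.}\quad
  \operatorname{logit} p = \beta_0' + \beta_2' x_2,$$

both extended with any covariate terms (e.g. principal components). Twice
the gap in maximized log-likelihoods is the AI statistic, referred to
$\chi^2_1$. For a quantitative trait the corresponding linear models are
compared by $F = (\mathrm{RSS}_0 - \mathrm{RSS}_1) /
(\mathrm{RSS}_1 / (n - 3 - c))$ on $(1, n - 3 - c)$ degrees of freedom with
$c$ covariates; this denominator df is the standard nested-OLS choice.

Genotype effects are always coded additively on the log-odds scale.
Dominant/recessive *analysis* codings are deliberately not offered: they
lose power even when the causal model matches, a known property of tests on
SNPs in imperfect LD with the causal variant. Only the partner-selection
metric (below) has model variants.

Logistic maximization is by iteratively reweighted least squares
(`glm.fit`, tolerance `1e-10`, up to 50 iterations). A fit whose fitted
probabilities are numerically pinned at 0/1 is flagged as separated and the
anchor is reported `not_converged` rather than tested. Missing data are
handled complete-case per anchor: an individual missing the phenotype,
either genotype, or any covariate is dropped from that anchor's test only.
An anchor whose dosages are collinear with its partner's after the drop is
unidentifiable and reported `degenerate`.

## Partner selection

Candidates come from a window around the anchor: by default the 10 nearest
same-chromosome SNPs (`floor(w/2)` left, `ceiling(w/2)` right, extending to
the opposite side near chromosome ends), alternatively all SNPs within a
base-pair distance. Each candidate's squared Pearson correlation $r^2$ with
the anchor — computed on unphased dosages over **all** individuals,
cases and controls alike — is mapped through a precomputed score curve, and
the highest-scoring candidate wins; ties break to the earliest window
position. Because selection never looks at the phenotype, it is
statistically independent of the subsequent AI test, so the search adds no
type-I inflation — a property the test suite checks by permuting phenotypes
and asserting identical partner choices.

A partner too strongly correlated with the anchor adds nothing beyond the
anchor itself; one too weakly correlated adds nothing to condition on. The
useful range in between is found by simulation.

## Metric construction

Each replicate draws a random point from the space of three-SNP
(anchor, causal, partner) haplotype frequency configurations, simulates a
case/control study, and asks whether the AI test beat single-SNP testing:

1. The 8 haplotype frequencies are drawn by sequential uniform stick
   breaking: pick an undefined haplotype uniformly at random, draw its
   frequency uniformly on $[0, 1 - S]$ where $S$ is the total already
   assigned, and give the last haplotype the remainder. (The $1-S$ upper
   bound is the only choice under which the final remainder is a valid
   frequency.)
2. 1,000 cases and 1,000 controls are simulated under random mating with
   penetrances 0.01/0.015/0.0225 for 0/1/2 causal alleles (multiplicative
   risk). Sampling uses the exact conditional genotype distributions given
   affection status, collapsed to the 3×3 anchor×partner contingency table —
   mathematically identical to per-individual simulation but far faster, and
   implemented in compiled code.
3. The replicate records the all-sample anchor–partner $r^2$, the AI
   statistic, and the single-SNP logistic LRT statistic at the anchor.

Replicates whose AI-minus-single-SNP difference lands in the top 1% are
marked; $r^2$ is binned at width 0.05 (half-open bins, $r^2 = 1$ in the last
bin) and the per-bin proportion marked estimates how promising that
correlation range is. A degree-5 polynomial is fitted to the bin
midpoints/proportions, excluding the three lowest and highest populated
bins, and constrained to vanish at $r^2 = 0$ and $r^2 = 1$ by fitting
$p(x) = x(1-x)\,q(x)$ with $q$ cubic — this makes the anchoring exact rather
than approximate. The excluded tail ranges are covered by straight lines
from the anchor points to the polynomial's value at the junction bin
midpoint: joining the polynomial (rather than the raw bin proportion) keeps
the score map continuous, which matters because a discontinuity at the
joint lets sampling noise pin the curve's maximum to the joint itself.
Negative values are clamped to zero and the curve is scaled so its maximum
over a $10^{-3}$ grid is 100.

The bundled multiplicative curve (one million replicates, seed 1) peaks at
$r^2 \approx 0.32$, i.e. an optimal interval of roughly $[0.27, 0.37]$ —
partners moderately, not strongly, correlated with their anchor are the
useful ones. Lowering the top-percentage threshold shifts the peak toward
lower correlations; 1% is kept as the default trade-off between the size
and the attainability of the conditional signal.

Dominant and recessive metric variants are built the same way with
penetrances (0.01, 0.0225, 0.0225) and (0.01, 0.01, 0.0225). These preserve
the multiplicative set's baseline and maximum; they are this package's
choice, since only the multiplicative penetrances are pinned down
externally, and conclusions driven by the dominant/recessive peaks should
carry correspondingly wider error bars. All three curves ship as JSON under
`inst/extdata/` and can be rebuilt with `run_metric_construction()` or the
`build-metric` CLI subcommand.

## Scan behaviour

`run_scan()` iterates every SNP passing QC (default: no MAF filter, no
missingness filter — thresholds are user-set) as an anchor. SNPs failing QC
are excluded both as anchors *and* as partner candidates, so one bad SNP
cannot silently drive its neighbours' tests. Anchors with no usable partner
(e.g. all candidates monomorphic) are reported with a `no_partner` status
and NA AI statistics; the companion single-SNP result is still emitted when
defined. The scan is deterministic given its inputs.

## What the synthetic generators emulate — and what they do not

`multi_snp_scenario()`/`generate_panel()` build diploid individuals from a
small pool of `m`-SNP haplotypes under random mating, with disease risk
multiplying by the genotype relative risks (default 1.5/2.25, prevalence
0.01, 1,000 cases + 1,000 controls — the effect sizes and sample sizes used
throughout the evaluation). Exact conditional sampling gives fixed
case/control counts. The bundled `weak_tagging` scenario mirrors the LD
anatomy of the malaria worked example (causal allele at frequency
$\approx 0.075$ tagged at $r^2 \approx 0.26$ by the anchor, $\approx 0.004$
by the partner, anchor–partner $r^2 \approx 0.33$, combination
$r^2 \approx 0.44$); `strong_tagging` has the anchor tagging the causal SNP
at $r^2 \approx 0.9$; `null_panel` is six SNPs on four haplotypes with no
disease effect.

These generators deliberately omit recombination, genotyping error,
missingness patterns, population structure and genome-scale LD texture. A
passing suite therefore demonstrates the statistical behaviour of the test
under its own model — calibration, power ordering, selection independence —
not robustness to artefacts of real array data (the cautionary tale being
that a single poor-quality genotyped SNP can manufacture an impressive
regional signal; QC remains the user's responsibility).

## Problem sizes and numerical choices

The test suite runs the metric construction at $10^5$ replicates (the
acceptance script uses the full $10^6$; at $10^5$ the peak location carries
a Monte-Carlo standard deviation of roughly 0.02–0.03), null calibration
over $10^4$ anchors of 500 cases + 500 controls, and power comparisons at
300–400 replicates per scenario — sizes chosen so the whole suite runs in
a couple of minutes while keeping Monte-Carlo error well inside the
asserted bands. Other numerical choices: LRT statistics are clamped at
zero (the models are nested; tiny negative values are IRLS round-off);
quantitative `F` is set to 0 when the anchor's RSS reduction is below
$10^{-10}$ of the total sum of squares (exact collinearity); undefined
$r^2$ (monomorphic SNP, fewer than two complete pairs) scores 0 and an
anchor whose candidates are all undefined gets no partner; minor-allele
orientation uses all individuals with ties at frequency 0.5 keeping file
allele order.

## Known limitations

* Only PLINK 1 binary (SNP-major) input; no VCF/BGEN, no dosage data, no
  sex-chromosome handling.
* One partner per anchor; no multi-partner or haplotype-based selection.
* The dominant/recessive metric penetrances are an internal assumption (see
  above).
* P-values rely on asymptotic $\chi^2_1$/F distributions; no small-sample
  corrections are applied.
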
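---
title: "Allele balance bias: model, scoring and association re-evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Allele balance bias: model, scoring and association re-evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(abbscore)
library(dplyr)
```

## The problem

Short-read variant callers handle random sequencing error well, but
*systematic* errors — misalignment in low-complexity and repetitive
regions, capture-kit artefacts, unannotated CNVs and retroduplications —
recur at the same genomic positions in sample after sample and slip
through standard filters. Their footprint is a recurrent shift of the
allele balance (AB, the fraction of reads supporting the alternative
allele) away from what the genotype predicts: a heterozygote should sit
near 0.5, a homozygote near 0 or 1, while error-prone positions pile up
evidence around 0.2–0.35. `abbscore` scores every position of an exome or
genome for this allele balance bias (ABB) from a cohort of pileups, turns
the score into a genotype *callability* filter for VCF callsets, and
re-evaluates rare-variant association candidates whose case/control
burden is better explained by bias than by biology.

## Expected allele balance per genotype

Three distributions describe clean data at informative observations
(≥ 20 reads with base quality ≥ 20):

* **heterozygous**: the alternative read count is
  $\mathrm{Binomial}(D, p)$ with $p \approx 0.5$, estimated by the pooled
  MLE $\hat p = \sum \text{alt} / \sum D$ (default 0.5 when no training
  pairs are supplied);
* **homozygous reference**: AB follows a zero-inflated beta
  $\mathrm{BEINF}(\alpha, \gamma, \mu, \phi)$ with
  $P(y{=}0) = \alpha(1-\gamma)$, $P(y{=}1) = \alpha\gamma$ and density
  $(1-\alpha) f(y; \mu, \phi)$ on $(0,1)$, where the beta is
  parameterized by mean $\mu$ and precision $\phi$
  (shape1 $= \mu\phi$, shape2 $= (1-\mu)\phi$);
* **homozygous alternative**: the one-inflated mirror image.

Boundary parameters have closed-form MLEs ($\hat\alpha$ = fraction of
observations exactly at 0 or 1, $\hat\gamma$ = fraction of those at 1);
$(\mu, \phi)$ maximize the interior beta likelihood numerically with a
small ridge penalty on $\log\phi$ (weight $10^{-3}$) that keeps the
precision finite on nearly degenerate interior samples while moving
healthy estimates by less than one part in a thousand (asserted in the
test suite). Training pairs (observation, genotype label) are supplied by
the caller — a variant callset or the simulator — and the three fits are
cohort-global, not per position.

Each observation then receives one p-value per genotype: an exact
two-sided binomial p for the heterozygous hypothesis (minimum-likelihood
ordering — deviation in either direction is evidence of error), and
one-sided inflated-beta tails for the homozygous hypotheses (upper tail
for hom-ref, lower for hom-alt: the only directions evidence against
homozygosity can point). These
conventions are the package's own choices; both are isolated behind `genotype_pvalues()` and
documented. The largest p-value names the most likely genotype (ties
break hom_ref > het > hom_alt, deterministically), and the deviation
`devAB` is `ab` for hom-ref, `|ab − 0.5|` for het, `1 − ab` for hom-alt.

Because the binomial test is exact and the homozygous distributions carry
point masses, the per-genotype p-values are *super-uniform* rather than
uniform under their own distribution: $P(p \le t) \le t$. The test suite
asserts this bound on an empirical-CDF grid instead of a
continuous-uniformity test, which any discrete exact test would fail by
construction.

## Per-position bias measures

Per position, across informative samples (and only positions seen in at
least 80 of them):

* `rdab1` — mean devAB;
* `rdab2` — fraction of samples with a significant deviation (best-genotype
  p below `sig_threshold`, default 0.05 — the same conventional level the
  missed-call definition uses);
* `rdab3` — mean of $-\log_{10} p$, with p floored at $10^{-12}$ so that
  exact-zero tail probabilities at extreme counts cannot produce infinite
  means.

The best-genotype p-value feeds both `rdab2` and `rdab3`, consistent with
how `rdab2` is framed. On clean cohorts `rdab2` concentrates slightly
below `sig_threshold` (the exact tests are conservative); the suite
checks a 200 × 500 cohort lands within ±0.02 of the threshold.

## From measures to a callability score

Positions with at least `min_het` heterozygous-called samples (default
60, scaled down proportionally for small cohorts; the end-to-end tests
use 20 with 100-sample cohorts) are split into non-deviated (0) and
recurrently deviated (1) sets by a two-component univariate Gaussian
mixture on the mean heterozygous devAB, fitted by EM with k-means
initialization under a fixed seed, unequal variances with a small floor,
and log-likelihood tolerance $10^{-8}$; the larger-mean component is the
deviated class. A logistic regression (`stats::glm`, binomial family)
predicts these labels:

$$\mathrm{logit}(y) = \beta_0 + \beta_1\,\mathrm{rdab1} +
\beta_2\,\mathrm{rdab2} + \beta_3\,\mathrm{rdab3} +
\beta_4\,\mathrm{rdab2}\cdot\mathrm{rdab3}$$

Positions are split 2/3 : 1/6 : 1/6 into training, validation and test
sets, stratified by label. The response cutoff maximizes F1 on the
validation split (a brute-force scan over every distinct response value;
the suite cross-checks this against an independent scan). The cutoff is a
property of each cohort and is recomputed per training run, never reused
as a constant.

The ABB score itself is a *precision*: pooled validation + test responses
are sorted into 20 equal-count bins, the empirical precision (fraction of
label-1 positions) is computed per bin, monotonicity is enforced by
isotonic pooling (`stats::isoreg`), and new responses are linearly
interpolated through the resulting knots. Equal-count binning plus
isotonic pooling is the package's estimator choice for the
response-to-precision curve; it guarantees a usable monotone score by
construction. Scores bin into four confidence levels: high
(ABB ≤ 0.15), medium (0.15, 0.75], low (0.75, 0.9], very low (> 0.9);
the boundary 0.9 is assigned to *low*, following the textual definition
of the bins rather than the half-open table notation, and the VCF filter
removes strictly above 0.9.

## Association re-evaluation

A homozygous-reference call is a potentially **missed** alternative
genotype when its AB sits improbably high under the zero-inflated beta
(upper-tail p < 0.05). Given per-variant called/missed counts for
candidate genes in cases and controls, `associate_abb()` runs:

1. per variant, a two-sided Fisher exact test on the called/missed 2×2
   table, with Benjamini–Hochberg FDR across variants (flagged biased at
   FDR < 0.1, mirroring the gene-level level);
2. per gene, (i) the aggregated called–missed ratio test (Fisher when the
   smallest expected cell is below 5, Pearson chi-square otherwise — our
   choice, the aggregation statistic is not specified), (ii) a Pearson
   chi-square association re-run counting called + missed as carriers
   (dominant coding), (iii) the same re-run on called genotypes at
   non-biased variants only, each with BH FDR across genes.

A gene is `likely_false` when FDR₁ < 0.1, or when it is no longer
significant (FDR > 0.1) after re-genotyping or cleaning. Note the rule
also rejects candidates that were never significant in the re-evaluation
— the input is assumed to be a list of genes an upstream rare-variant
association scan already called significant. The upstream scan itself
(SKAT-O, burden and relatives) is out of scope; the chi-square re-runs
are the re-evaluation instrument.

A sensitivity worth knowing: the called–missed ratio test compares
called:missed *ratios*, so a gene with a strongly asymmetric called count
and non-negligible background missed noise can reach significance even
without any differential bias. Background missed calls arise at rate
$\approx (1-\alpha)/2$ to $(1-\alpha)$ per clean hom-ref sample (the
definition is itself a p < 0.05 tail test), so the test behaves best when
hom-ref evidence is clean — which is why candidate-variant re-evaluation
should use a hom-ref model fitted to post-QC calls.

## The synthetic cohort generator

`simulate_cohort()` emulates the study conditions end to end: per-site
alternative allele frequency uniform on 0.05–0.5 with Hardy–Weinberg
genotypes; depths negative-binomial (mean 60, dispersion 5 —
WES-like coverage heterogeneity; the exact depth law affects realism,
not correctness); heterozygous alt counts binomial at p = 0.5; homozygous
AB drawn from the inflated-beta error models (defaults
$\alpha = 0.9, \gamma = 0, \mu = 0.01, \phi = 100$ and its one-inflated
mirror — small alternative-read contamination, arbitrary but plausible);
and a configurable fraction of sites (default 5%) turned into
systematic-error sites where a penetrance fraction of samples (default
0.3, optionally restricted to a batch subset mimicking a capture-kit
effect) has evidence replaced by binomial draws at AB 0.25 — the centre
of the suspicious 0.2–0.35 band. Output is deterministic in the seed and
round-trips through the mpileup text writer and parser byte-identically.

Two generator choices deserve explanation:

* **Training labels are naive *calls*, not simulation truth.** The
  genotype AB model is meant to be fitted on a variant caller's output,
  where AB ≈ 0.25 evidence at a biased site is called heterozygous and
  therefore contaminates the het binomial (slightly), not the clean
  homozygous fits. Fitting on simulation truth instead drags the hom-ref
  beta mean an order of magnitude upward and blunts the whole method.
  The simulator therefore emits a `called_genotype` from a hard-threshold
  genotyper (AB ≤ 0.15 / ≥ 0.85), and that channel feeds
  `fit_ab_model()`.
* **The case/control generator draws clean hom-ref AB directly from the
  BEINF** (discretized to read counts) rather than re-sampling it through
  a second binomial layer: the BEINF models *observed* allele balance,
  and the extra layer inflates the missed-call false-positive rate from
  the model-consistent $\sim(1-\alpha)/2$ to several percent. Its default
  hom-ref model uses $\alpha = 0.999$ (false missed rate ≈ 0.1% per
  sample), representing the post-QC candidate-variant regime; with
  noisier hom-ref evidence the ratio-test sensitivity described above
  starts to reject genuinely associated genes.

What the simulator does **not** emulate: read-level error motifs
(homopolymers, 8-oxo-G), strand asymmetry, mapping-quality structure,
indels, linkage between sites, and per-kit coverage profiles. Passing
tests therefore demonstrate that the statistical machinery recovers
injected bias under the stated model, not that every real systematic
error mode is detectable.

## Problem sizes and numerical choices

The test and acceptance workloads use a 100-sample × 2,000-site cohort
(5% bias sites) for end-to-end scoring and twenty replicate 200 + 200
case/control cohorts of four 3-variant genes for the association
scenarios — sizes at which every distributional property under test has
comfortably converged while the whole suite stays fast. Other constants:
Phred+33 base-quality decoding only; 1-based coordinates throughout;
pileup alt allele = most frequent non-reference base with alphabetical
tie-break, strands pooled; binomial p-value ties absorbed with a relative
tolerance of $10^{-7}$ (the `binom.test` convention); GMM variance floor
$10^{-10}$; score tables serialized at six decimals.

## Known limitations

* The callability model is cohort-specific: scores from one pipeline
  (aligner, caller, capture kit) do not automatically transfer.
* Labeling requires enough heterozygous-called samples per position;
  rare-variant-only positions are scored by extrapolation of the
  logistic model, never labeled.
* SNVs only; indel AB behaves differently and is out of scope.
* The verdict rule treats "no longer significant" as evidence of a false
  positive, which conflates weak power with bias; genes near the FDR
  boundary deserve manual review.
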
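---
title: "Growth-curve inflection analytics and DGE profiling: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Growth-curve inflection analytics and DGE profiling: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(inflectr)
```

inflectr implements the computational backbone of a common study design in
livestock genomics: model a population's sigmoid growth curve, locate the
inflection point (the age of maximum daily gain), and profile muscle gene
expression at three developmental stages defined by that point — before it
(BIP), under/at it (UIP), and after it (AIP). This vignette explains each
model, the defensible choices made where the methodology was genuinely
open, and what the synthetic-data generators do and do not emulate.

## Sigmoid growth models

Three classical three-parameter growth functions are supported, each with
an asymptotic mature weight $A$ (kg), a shape constant $B$, and an
intrinsic rate $k$ (per day):

| model | $W(t)$ | $t^\*$ | $W^\*$ | $G_{\max}$ |
|---|---|---|---|---|
| logistic | $A/(1+Be^{-kt})$ | $\ln B/k$ | $A/2$ | $kW^\*/2$ |
| Gompertz | $A e^{-Be^{-kt}}$ | $\ln B/k$ | $A/e$ | $kW^\*$ |
| Von Bertalanffy | $A(1-Be^{-kt})^3$ | $\ln 3B/k$ | $8A/27$ | $3kW^\*/2$ |

$t^\*$ is the inflection age, $W^\*$ the inflection weight and $G_{\max}$
the maximum daily gain ($W'(t^\*)$). For the Von Bertalanffy model the
inflection age is $\ln(3B)/k$: differentiating
$W'(t)=3ABke^{-kt}(1-Be^{-kt})^2$ and solving $W''(t^\*)=0$ gives
$Be^{-kt^\*}=1/3$, which is also the unique value consistent with
$W^\*=8A/27$ and $G_{\max}=3kW^\*/2$. (A frequently reprinted variant,
$\ln 2B/k$, is inconsistent with those two companions and is not used.)

Goodness of fit is the coefficient of determination
$R^2 = 1 - \mathrm{RSE}/\mathrm{RST}$, with RSE the residual sum of
squares and RST the total sum of squares about the mean weight.
`compare_models()` ranks the three fits by descending $R^2$, breaking ties
within $10^{-6}$ alphabetically.

### Fitting

`fit_growth_model()` uses multi-start nonlinear least squares
(Levenberg–Marquardt via minpack.lm). Starting values seed the asymptote
at 1.05–2.5 times the maximum observed weight and obtain $(B_0, k_0)$
from the log-linearisation of each model at that asymptote (e.g.
$\log(A_0/W - 1) = \log B - kt$ for the logistic); the best converged
start by residual sum of squares wins. Parameters are bounded positive.
For the Von Bertalanffy curve a negative base $1-Be^{-kt}$ at small $t$
is cubed as a signed quantity rather than clamped, keeping the
least-squares objective smooth where $B > 1$.

### Numeric inflection cross-check

`inflection_point_numeric()` is deliberately independent of the closed
forms: it maximises a central-difference derivative over a coarse grid,
then refines at the requested resolution (default 0.001 d). Near its peak
the sampled derivative is flat at floating-point precision, so the
implementation returns the midpoint of the near-maximal plateau rather
than the raw argmax; this keeps the closed-form/numeric agreement inside
one grid step across the full supported parameter range
($A \in [50, 300]$, $k \in [0.005, 0.1]$). A non-unimodal sampled
derivative (impossible for valid parameters) is an error.

### Identifiability of the asymptote

The synthetic growth default emulates mean weight-by-age records of a
slow-growing indigenous pig breed followed from birth to 250 days at 20
time points: a Von Bertalanffy truth back-solved from an inflection at
193.40 d, 62.61 kg and 455.43 g/d ($A = 211.309$ kg, $B = 0.8515$,
$k = 0.004849$/d), plus additive Gaussian noise of 1 kg. A record window
ending at 250 days covers only about 40% of the asymptote, so $A$ (and
$W^\* = 8A/27$) is weakly identified: the linearised least-squares theory
gives $\mathrm{sd}(\hat A) \approx 18$ kg at $\sigma = 1$ kg, i.e. an
expected median relative error near 5.8%, and the observed median over
100 seeded replicates matches. The inflection age and the maximum daily
gain, which depend on the data-rich part of the curve, recover to well
under 5%. This is a property of the study design, not of the optimizer —
the fitted optimum beats the truth's residual sum of squares on every
replicate and agrees with an exhaustive grid-search oracle.

## Synthetic tag-count libraries

`simulate_counts()` emulates a 3-stage × 3-replicate DGE tag-profiling
design. Baseline transcript abundances follow a bounded Pareto
(exponent 0.8 on [1, 5000]) capped so that no transcript exceeds ~10% of
the library — the concentration seen in deep skeletal-muscle libraries,
where the single most abundant transcript holds just under a tenth of all
tags. A configurable fraction of genes (default 10%) receives a planted
step change of known magnitude (default $|\log_2\mathrm{FC}| = 2$)
between one pair of adjacent stages, recorded sign-and-all in a truth
table together with the gene's expected baseline count.

Counts are drawn by a gamma–multinomial construction: per-gene gamma
intensities with mean equal to the stage's expected share and variance
$\phi \mu^2$ (the negative-binomial mixing law, $\phi$ = `dispersion`,
default 0.1 — a typical biological coefficient of variation of ~30%),
then a multinomial allocation of the library's tags over genes. Marginally
each low-share gene behaves like a negative binomial; conditioning on the
total pins every library exactly at its target depth (default $10^6$),
as a sequencer's yield target would. At `dispersion = 0` the gamma layer
collapses and sampling is plain multinomial (Poisson-like).

What the generator does **not** emulate: read sequences, alignment and
mapping ambiguity, antisense tags, annotation errors, or correlated
gene–gene programs. Passing tests therefore demonstrate the statistical
operating characteristics of the calling rules under their stated
sampling assumptions, not robustness to alignment artefacts.

## Quantification and descriptive statistics

- **RPKM**: $10^9 c / (NL)$ with $N$ the library total and $L$ the exonic
  length; for single-end tag data RPKM and FPKM coincide, so one unit is
  used. When annotations cover all counted genes,
  $\sum_g \mathrm{RPKM}_g L_g = 10^9$ per library exactly — a conservation
  identity used as a test invariant.
- **Expressed transcripts** use a presence-based rule: non-zero count in
  at least one library of a stage (or anywhere, for the overall set). No
  abundance floor is applied; the rule is threshold-free by design.
- **Saturation curves** subsample tags without replacement (multivariate
  hypergeometric, implemented by sequential conditional hypergeometric
  draws) and report the mean number of distinct genes detected per depth;
  the closed-form expectation
  $\sum_g [1 - \binom{N-c_g}{d}/\binom{N}{d}]$ anchors the Monte-Carlo
  estimate in tests.
- **Replicate correlation** is Pearson's $r$ on $\log_{10}(\mathrm{RPKM}+1)$
  over genes expressed in at least one library of the pair; the +1 offset
  handles zeros, which the raw unit leaves undefined on a log scale.

## Differential expression

The stage contrasts use a pooled-replicate conditional exact test in the
classic digital-expression (Audic–Claverie) style: replicates are summed
within each group, and conditional on a gene's total $x_a + x_b$ the
group-b count is Binomial$(x_a+x_b,\, n_b/(n_a+n_b))$ under the null,
with $n_a, n_b$ the pooled library sizes. The two-sided p-value sums all
outcomes no more likely than the one observed. The implementation scans
only a ±12-SD central window and adds the strictly-less-likely far-tail
masses in closed form, which is exact and fast for totals in the
millions; it matches full enumeration for every total up to 50 and
`binom.test` on spot checks.

A DEG is a gene with $p \le 0.05$ **and** $|\log_2\mathrm{FC}| \ge 1$
(pooled mean RPKM ratio with a 0.001 pseudocount). No multiple-testing
correction enters the call — the rule is the conjunctive raw-p threshold
— but a Benjamini–Hochberg column is reported for information. Two
consequences worth knowing:

- under pure Poisson sampling the conditional test is conservative
  (type-I rate below nominal);
- under biological overdispersion the pooled test alone is anticonservative
  (it ignores replicate variance), and it is the fold-change filter that
  keeps the conjunctive false-positive rate low (≤ 2% at dispersion 0.1 in
  the null simulations). Replicate-aware negative-binomial testing is
  deliberately out of scope; the surrounding ecosystem (edgeR, DESeq2)
  covers that regime.

DEG-profile clustering is average-linkage agglomerative clustering of
libraries with distance $1 - r$ on $\log_{10}(\mathrm{RPKM}+1)$ — the
standard replicate-reproducibility display.

## Gene-set enrichment

`ease_score()` implements the EASE statistic: the one-tailed
hypergeometric (Fisher) over-representation p-value after decrementing
the query-overlap cell by one. Overlaps of 0 or 1 therefore score exactly
1, and every EASE score is at least the classical Fisher p — a deliberate
conservatism against single-gene hits. Scores across a family of sets are
Benjamini–Hochberg adjusted; significance is flagged on the raw EASE p at
0.05 with the adjusted value reported alongside (when a published
protocol is ambiguous about which of the two it filtered on, filtering on
the raw value and reporting both is the transparent choice). The
background defaults to all genes in the expression matrix, since
web-service-specific backgrounds cannot be reproduced offline.

## QTL-interval overlap

A gene qualifies as a QTL gene when the QTL region is shorter than 2 Mb
and the overlap covers at least half the gene's length **or** at least
half the region's length ("at least half" inclusive). The length filter
is applied to the region before overlap evaluation, so a ≥ 2 Mb region
can never yield a QTL gene. Coordinates are 0-based half-open
throughout. Overlap search uses interval trees (IRanges); a quadratic
all-pairs oracle verifies it exactly in tests.

The per-chromosome enrichment statistic is a 1-df chi-square without
continuity correction on the 2×2 table (stage-specific genes in/out of
QTL regions vs all genes in/out), plus a pooled genome-wide row; when an
expected cell drops below 1 the exact hypergeometric p is substituted and
flagged. The 2×2-against-background construction is one defensible
reading of a per-chromosome enrichment table whose expected model the
source protocol leaves unstated; it is a documented choice, not an
inference of intent. Chromosome summaries count a gene once however many
regions it hits, and merge overlapping regions before summing QTL length.

## qPCR quantification

`ddct_fold()` computes $2^{-\Delta\Delta C_t}$ with multi-reference
normalization: replicate $C_t$ values are averaged per gene, the
reference $C_t$ is the arithmetic mean of the reference genes' means
(equivalent to geometric-mean normalization of quantities, $C_t$ being a
log2 scale), $\Delta C_t = C_{t,\mathrm{target}} - C_{t,\mathrm{ref}}$,
and $\Delta\Delta C_t$ subtracts the calibrator condition, whose fold is
1 by construction. `mtdna_copy()` computes relative mtDNA copies per
diploid cell as $2^{\Delta C_t}$ with
$\Delta C_t = C_{t,\mathrm{nuclear}} - C_{t,\mathrm{mito}}$: the
orientation is fixed by the biology (mitochondrial templates outnumber a
single-copy nuclear gene, amplify earlier, and must yield copy numbers
above 1). Replicates are averaged before the $\Delta$ computations for
the point estimate; the SD transforms each replicate pair independently.
Both estimators are invariant to a global $C_t$ shift, and no
amplification-efficiency correction is applied (100% efficiency is
assumed throughout).

## Problem sizes and numerical settings

The test suite and the acceptance script run entirely on synthetic data
at desk scale, chosen as the smallest sizes at which each statistical
property is sharply testable: 20-point growth records with 100-replicate
recovery experiments; 2000-gene, $10^6$-tag libraries (3×3) for DEG
operating characteristics; exhaustive exact-test enumeration to totals of
50 under equal and 2:1 library sizes; EASE verification on a deterministic
grid of margins up to 200; 800-gene/120-region interval instances against
the quadratic oracle; 50-seed null calibrations for enrichment and QTL
chi-square rates. Fixed numerical settings: ranking tie tolerance
$10^{-6}$ on $R^2$; fold-change pseudocount 0.001 RPKM; log-offset +1;
numeric-inflection grid step 0.001 d; two-sided exact-test mass
comparison with a $1+10^{-7}$ relative guard against float ties.

## Known limitations

- The asymptote of a growth curve truncated well before maturity is
  weakly identified (see above); report $t^\*$ and $G_{\max}$ with more
  confidence than $A$ and $W^\*$ on such windows.
- The pooled exact test ignores replicate-level biological variance by
  design; its raw p-values should not be interpreted as FDR-controlled.
- Enrichment treats gene sets as flat lists: no ontology-graph
  propagation, no ortholog mapping.
- The chi-square table construction for QTL enrichment is one documented
  reading among several defensible ones.
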
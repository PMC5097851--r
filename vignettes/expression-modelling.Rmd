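---
title: "Modelling gene expression from TSS-proximal ChIP-seq signal"
author: "epimapred"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling gene expression from TSS-proximal ChIP-seq signal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epimapred)
```

## The model and its assumptions

The package treats genes as observations of regulatory activity. For each
gene $m$ and ChIP-seq feature $n$ it aggregates read-equivalents within a
fixed window around the transcription start site,

$$x_{m,n} = \sum_{r \in R_n,\; |d(r,m)| \le d^*} w(r)\,\phi(r, m),$$

with $\phi = 1$ for histone modifications (a constrained sum of tags) and
$\phi = \exp(-|d(r,m)|/d_0)$ for transcription factors, whose binding
profiles decay with distance from the TSS. Expression is then modelled
linearly, $Y = X\beta + \varepsilon$, on the transformed score matrix.

The assumptions this encodes, and which the synthetic generator mirrors,
are: (i) regulatory signal relevant to transcription is concentrated near
the TSS — marks acting in non-promoter regions (gene bodies, 3'-UTRs,
distal enhancers) are out of scope; (ii) the read-level signal enters
additively, so a gene's score is a weighted tag count; (iii) after a
monotone variance-stabilising transform, expression is approximately linear
in the scores with i.i.d. Gaussian gene-specific errors.

## Parameters that matter

* `d_star` (bp, default 2000): window half-width. Both window ends are
  inclusive ($|d| \le d^*$), and strand affects only the distance *sign*
  (downstream positive), never which reads are counted — signal on either
  side of the TSS contributes.
* `d0` (bp, default 5000): decay constant of the transcription-factor
  kernel. The absolute distance is used in the exponent; a signed distance
  would make upstream affinities exceed 1, and binding affinity has no
  reason to decay asymmetrically.
* Transform: `log` maps $x \mapsto \ln(x + 1)$ by default — the unit
  pseudocount preserves zeros exactly; `arsinh` needs no pseudocount.
  The transform applies to the feature columns of $X$ only. Whether and how
  to transform $Y$ is the user's choice (RNA-seq abundances are typically
  `log2(x + 1)`-transformed upstream); the package deliberately does not
  couple the two.
* Quantile normalisation maps every feature column onto the mean
  order-statistic reference. Ties receive the mean of their tied reference
  values, which keeps the procedure exactly idempotent on already-normalised
  input. Normalisation is across features of one sample; normalising across
  samples instead is possible by assembling the transposed matrix, but is
  not the default.
* `lambda`: the ridge penalty multiplies $\|\beta\|^2$ with the bias
  coefficient *included* by default (`penalize_bias = TRUE` corresponds to
  the plain $\lambda I_N$ penalty); excluding the intercept from shrinkage
  is the more common statistical convention and available as a flag.
* The automatic `lambda` search uses a 50-point log-spaced grid on
  $[10^{-4}, 10^4]$ and 10-fold cross-validation with the one-standard-error
  rule: the largest grid value whose mean CV error is within one SE (of the
  fold errors at the minimising value) of the minimum. Fold membership is a
  seeded permutation of genes into near-equal blocks; the seed is recorded
  in the fit.

## The MapReduce engine and determinism

Scoring and the two large regression products are phrased as programs over
a small in-process map-shuffle-reduce engine (`mr_program`,
`execute_program`). Three design choices make results reproducible to the
bit across worker counts:

1. **Canonical value order.** Before a reducer runs, its value list is
   sorted by a total order (numeric for numeric scalars, a type-tagged
   radix string order otherwise), so floating-point summation order — and
   hence the sum — does not depend on arrival order.
2. **Stable partitioning.** Work is split across workers by a fixed
   polynomial hash of the encoded key, never by a randomised hash.
3. **Canonical output order.** The final multiset is sorted by encoded key
   and value.

The matrix multiply decomposes $C = AB$ by output cell,
$c_{i,k} = A_{i,\star} \cdot B_{\star,k}$, with the shared dimension cut
into fixed-size blocks; mappers emit per-block partial dot products and the
reducer sums them. Because the block boundaries depend only on the matrix
shape, not on the worker count, the partial sums — and therefore the
result — are identical for any `workers` setting. The final $N \times N$
system is solved single-node with `solve()` (a stable linear solve rather
than an explicit inverse; the mathematical contract is identical and the
conditioning better), since no distribution scheme amortises its overhead
over so small a matrix. A reciprocal-condition-number check rejects
singular designs with a pointer to ridge regularisation.

The ridge fit's two routes — the closed form
$(X^\top X + \lambda D)^{-1} X^\top Y$ and the augmented system that stacks
$\sqrt{\lambda} D$ rows under $X$ and zeros under $Y$ — are both
implemented; their numerical agreement is asserted in the test suite over
hundreds of random triples, and $\lambda = 0$ reduces bitwise to OLS.

## The TSS index

Window queries use per-chromosome TSS arrays sorted ascending with binary
search (`findInterval`), giving the same $O(\log M)$ query contract as a
balanced search tree without the pointer overhead. A read within $d^*$ of
several TSSs contributes independently to every such gene — the per-gene
sums do not interact, so no tie-breaking is needed or wanted.

## Wiggle semantics

A WIG record with value $v$ is read as $v$ read-equivalents located at the
record's start coordinate; a `span` attribute does not multiply the weight.
This "sum-of-tags" reading keeps histone scores exact integers whenever the
WIG values are integral, which in turn lets the test suite demand *exact*
(not approximate) agreement with the brute-force oracle in histone mode.
Users preferring per-base semantics can pre-expand spans before import.
Only the `variableStep` and `fixedStep` dialects are parsed; bedGraph and
bigWig are out of scope for this version.

## What the synthetic generator does and does not emulate

Two generator levels exist, matching two uses.

* `make_fixture_suite` writes a complete WIG/BED/TSV directory: TSSs
  uniform per chromosome (inset by $d^*$ so pileups never leave the
  chromosome), Bernoulli(0.5) strands, per-gene Poisson read counts at
  offsets uniform in $[-d^*, d^*]$, a uniform Poisson background, and
  expression generated as a linear function of the *realized*
  log1p-transformed window sums plus Gaussian noise. Uniform (rather than
  peak-shaped) offsets make the expected histone score exactly the Poisson
  mean, giving a closed-form oracle; generating $Y$ from the realized
  window sums (the generator's own bookkeeping of every read it placed,
  including background and spillover between neighbouring windows) makes
  the scored design exactly linear, so coefficient recovery is limited only
  by the configured noise.
* `simulate_cell_lines` generates score matrices directly in the
  transformed design space — Gaussian feature columns plus bias — for the
  regression-level properties: shared or per-line-divergent coefficients,
  and an optional latent gene-level residual factor shared by chosen lines
  to induce correlated residuals.

Neither level attempts realistic fragment-length or GC models, peak-shaped
binding profiles, chromatin-state-dependent backgrounds, or the biology of
specific histone marks. Passing tests therefore demonstrate that the
*pipeline* is correct and self-consistent under its stated model — not that
the linear model is adequate for any particular real data set.

## Problem sizes and numerical choices

The test and acceptance workloads are sized so each stage is exercised at a
scale where its asymptotics matter while a full run stays in the minutes
range on one core: 200 random matrix pairs up to 20×20 against a naive
triple-loop oracle; a 1000-gene annotation against roughly $10^5$ WIG
records (written to and re-read from disk) for the scoring oracle, exact in
histone mode and within $10^{-9}$ relative in TF mode; 200 random ridge
triples for the augmentation identity at $10^{-8}$; coefficient recovery at
$M = 5000$, six features plus bias, with noise calibrated so the population
$R^2$ is 0.6 — the operating regime genome-wide histone models typically
reach; three 800-gene cell-lines for cross-evaluation; and 100 seeded
replicates of the four-line clustering construction.

Other numerical conventions: quartiles in `beta_summary` use linear
interpolation (`quantile` type 7); the adjusted $R^2$ is the Wherry form
$1 - (1 - R^2)(M-1)/(M-p-1)$ with $R^2 = 1 - \mathrm{SSE}/\mathrm{SST}$
(not a squared correlation) and the bias term not counted among the $p$
predictors; clustering defaults to $1 -$ Pearson correlation with average
linkage, both exposed as arguments since residual-profile clustering has no
single canonical metric; cross-line predictions always reuse the training
line's fitted $\lambda$ — the test line never informs the model; and the
common gene universe for multi-line analyses is the sorted intersection of
gene identifiers, computed once.

## Known limitations

* The engine is an in-process model of the map-shuffle-reduce contract:
  no fault tolerance, spill-to-disk, or inter-machine transport. It is the
  semantics — determinism and partition-invariance — that are load-bearing,
  not wall-clock speedup.
* $L^1$/lasso penalties are out of scope: the $L^1$ norm admits no
  closed-form normal-equation route, so it does not fit the two-product
  decomposition the package is built around.
* Only promoter-proximal scoring is supported; enhancer assignment and
  marks acting in non-promoter regions need a different aggregation scheme.
* `select_lambda` realises the "largest within one SE" rule by grid search;
  a continuous optimiser could land between grid points but would not be
  deterministic across platforms in the same simple way.
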
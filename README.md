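# epimapred

Predictive modelling of gene expression from TSS-proximal ChIP-seq signal,
with the heavy matrix work expressed as deterministic map-shuffle-reduce
programs.

The package is aimed at computational biologists who model genome-wide mRNA
abundance as a function of the local epigenetic landscape — histone
modifications or transcription-factor binding measured by ChIP-seq — and who
want the scoring and fitting stages phrased as mapper/reducer pairs so the
same pipeline can be partitioned across workers with bit-identical results.

## The model

For gene *m* and epigenetic feature *n*, the gene-level score aggregates the
reads *r* of that feature's ChIP-seq track around the transcription start
site:

$$x_{m,n} = \sum_{\substack{r \in R_n \\ |d(r,m)| \le d^\*}} \phi(r, m),
\qquad
\phi(r,m) = \begin{cases}
1 & \text{histone modifications}\\
\exp\left(-|d(r,m)|/d_0\right) & \text{transcription factors}
\end{cases}$$

where *d(r,m)* is the signed read-to-TSS distance in bp (downstream
positive), *d\** = 2000 bp is the window half-width and *d₀* = 5000 bp the
decay constant. Scores are log- (or arsinh-) transformed and optionally
quantile-normalised into the design matrix **X** (genes × features, plus a
unity bias column), and expression is modelled as

$$Y = \mathbf{X}\beta + \varepsilon,$$

fitted by ordinary least squares or ridge regression,

$$\hat\beta = (\mathbf{X}^\top\mathbf{X} + \lambda I_N)^{-1}\mathbf{X}^\top Y,$$

with λ chosen as the largest value whose mean 10-fold cross-validated error
is within one standard error of the minimum. The two large products
**X**ᵀ**X** and **X**ᵀY are computed by a MapReduce matrix multiply
(`mr_multiply`); only the small N × N solve runs single-node. Downstream,
`cross_cell_line_eval` trains and tests models over every directed pair of
cell-lines (adjusted R² per pair), `cluster_cell_lines` groups cell-lines by
their residual profiles ε = Y − Ŷ, and `beta_summary` tabulates coefficient
distributions across fits.

## Worked example

A fully synthetic study: simulate two cell-lines' worth of WIG/BED/TSV
files, score them back through the pipeline, fit a regularised model and
cross-evaluate.

```r
library(epimapred)

cfg <- simulation_config(n_genes = 400, n_features = 3, noise_sigma = 0.4,
                         reads_per_gene = 60, seed = 11,
                         beta_true = c(1, -0.8, 0.6, 2))
suite <- make_fixture_suite(cfg, "demo", n_cell_lines = 2)
datasets <- load_fixture_suite(suite, cfg)

fit <- fit_expression_model(datasets[[1]]$scores, datasets[[1]]$expression,
                            lambda = "auto", seed = 1)
fit
#> Expression model fit: 4 coefficients, lambda = 3.728
#>   adj. R2 = 0.9024 over 400 genes
round(fit$beta, 3)
#>  feat1  feat2  feat3   bias
#>  1.024 -0.762  0.647  1.522

cross_cell_line_eval(datasets, lambda = "auto", seed = 1)
#> Cross-cell-line evaluation over 2 cell-lines ( 4 directed train/test combinations)
#>        test
#> train   line1 line2
#>   line1 0.902 0.904
#>   line2 0.901 0.907
```

The fitted coefficients recover the generative values (1, −0.8, 0.6, 2) up
to sampling noise and ridge shrinkage; the adjusted R² of ~0.90 reflects
the configured noise level. Off-diagonal entries of the cross-evaluation
matrix sit within a few thousandths of the diagonal because both simulated
lines share one set of generative coefficients — training on either line
predicts the other essentially as well as itself.

The same pipeline is scriptable from a shell via the thin front end in
`inst/cli/epimapred.R` (`simulate`, `score`, `fit`, `crosseval`, `cluster`
subcommands).

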
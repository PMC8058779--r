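# modp — the modular optimal discovery procedure for gene expression studies

`modp` performs significance analysis of gene expression studies —
static group comparisons, independent-sampling time-course or
dose–response designs, and longitudinal designs — using the modular
optimal discovery procedure (mODP). It is aimed at statisticians and
computational biologists who want more power than gene-by-gene F-tests
by exploiting co-expression, with FDR-based error control.

## The method in brief

For gene *i* with measurements *y<sub>ijt</sub>* and covariate
*x<sub>jt</sub>*, the mean response is a natural cubic spline,

> μ<sub>i</sub>(x) = α<sub>i</sub>**1** + s(x) β<sub>i</sub>,

with s(x) a *d*-dimensional basis (knots at evenly spaced covariate
quantiles; *d* chosen by leave-one-out cross-validation on the top
eigen-genes). Null and alternative models are nested least-squares
fits; the fitted null mean is subtracted so the null becomes
"mean zero". The optimal discovery procedure scores gene *i* by the
summed alternative likelihoods over summed null likelihoods across
*all* genes; the modular approximation clusters genes into *K* modules
by a symmetric Kullback–Leibler distance and evaluates

> S(y′<sub>i</sub>) = Σ<sub>k</sub> g(y′<sub>i</sub>; c<sub>k1</sub>, υ<sub>k1</sub>) |R<sub>k</sub>| / Σ<sub>k</sub> f(y′<sub>i</sub>; 0, υ<sub>k0</sub>) |R<sub>k</sub>|,

reducing the cost from 2m² to 2Km likelihood evaluations. Because the
statistic has no theoretical null distribution, p-values come from a
residual-bootstrap empirical null pooled across genes, followed by
π₀ estimation, q-values and local FDR. RNA-seq counts are supported
through logCPM transformation and voom-style inverse-variance
precision weights, which reduce to ordinary least squares via a
√w data transform. F-test and moderated F-test comparators (with
optional bootstrap nulls) and a gene-set score (the estimated
proportion of true positives per set) are included, along with a
synthetic-study generator with known truth for FDR/power evaluation.

## Worked example

Simulate an independent-sampling study with known truth (1000 genes,
20 measurements on a covariate grid, 80% true nulls, 10 shared
alternative profiles), run the full pipeline, and compare calls with
the truth:

```r
library(modp)

sim <- simulateStudy("independent", m = 1000, N = 20, pi0 = 0.8,
                     U = 10, snr = 2, seed = 42)
res <- odp(sim$study,
           config = odpConfig("independent", K = 100, B = 100, seed = 42))
res
#> OdpResults over 1000 genes
#>   pi0 estimate:   1
#>   spline dim:     3
#>   bootstrap pool: 100000 null statistics
#>   q <= 0.05: 207  q <= 0.10: 221

evaluateCalls(res, sim$truth)
#>   cutoff discoveries        fdp power
#> 1  1e-04           0 0.00000000 0.000
#> 2  1e-03         190 0.00000000 0.950
#> 3  1e-02         198 0.01010101 0.980
#> 4  5e-02         207 0.04830918 0.985
#> 5  1e-01         221 0.10407240 0.990
```

Reading the output: the pipeline selected spline dimension 3 by
eigen-gene cross-validation (the generator draws its curves from a
3-dimensional basis) and estimated the proportion of true nulls at 1
(the pooled empirical p-values are mildly conservative in the tail, so
the estimate sits at its upper bound; the truth is 0.8). At a q-value
cutoff of 0.05 it made 207 discoveries with a realized false discovery
proportion of 0.048, recovering 98.5% of the 200 truly alternative
genes; at q <= 0.1 the realized FDP of this single replicate is 0.104,
consistent with the nominal 0.1 up to one-replicate noise (the
acceptance script below averages this quantity over 100 replicates). `resultsTable(res)`
holds the per-gene statistic, p-value, q-value and local FDR;
`modules(res)` exposes the gene–module assignments for downstream
enrichment work.

Real data enter through `readExpression()` / `readSampleMeta()`
(TSV/CSV matrix + metadata), `buildStudy()` to formulate the design,
and `odp(..., weights = "estimate")` for raw RNA-seq counts.

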
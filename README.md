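# cfdiff

Counterfactual confounder adjustment for case-control single-cell
differential expression.

## What problem does this solve?

In observational case-control single-cell RNA-seq, unmeasured covariates
(age, ancestry, batch, comorbidity) can drive both disease status and
gene expression. Pseudo-bulk differential expression — aggregate each
individual's cells, test genes across individuals — then mixes genuine
disease effects with confounding, costing power and calibration.

`cfdiff` applies the potential-outcomes view to pseudo-bulk analysis.
Every cell is matched to its nearest neighbours among cells of
opposite-condition individuals in a spectral embedding; a log-link
Poisson regression on the matched profiles imputes the cell's
counterfactual expression \(\hat Y^{(1-w)}\). The per-individual mean is
then decomposed multiplicatively,

λ<sub>gi</sub> = μ<sub>gi</sub> · δ<sub>gi</sub>,

where the confounder μ<sub>gi</sub> is estimated jointly from observed
*and* counterfactual profiles (so it is label-invariant by construction)
under a Poisson–Gamma variational scheme, and the residual disease
effect δ<sub>gi</sub> is re-estimated with μ fixed. Genes are ranked by
Wilcoxon rank-sum tests on δ across individuals; effect sizes are
summarised by the inverse-variance-weighted average disease effect
(ADE), its standard error and a Wald Z from the log-scale posterior
summaries E[ln δ] = ψ(1+ΣY) − log(1+μ̂ Σ E[ρ]) and V[ln δ] = (ΣY)⁻¹.

The package is aimed at analysts of individual-level case-control
single-cell studies, and includes the full generative benchmark
(confounded labels, structured gene means, Gamma-depth Poisson counts)
plus a marker-constrained von Mises–Fisher mixture for cell-type
annotation, so every claim about the method's behaviour is reproducible
from code.

## Worked example

```r
library(cfdiff)

sim <- simulate_dataset(sim_config(n_genes = 300, n_causal = 20,
                                   n_individuals = 16,
                                   cells_per_individual = 20, seed = 1))
fit <- cfdiff(sim$counts, sim$meta, rank = 10, knn = 10)
fit
#> cfdiff fit: 300 genes, 1 stratum/strata (all)
#> genes at q < 0.01: 0; q < 0.05: 0

summary(fit)
#> Top genes by Wilcoxon rank-sum p-value:
#>       gene celltype n_case n_ctrl wilcoxon_p q_value    ADE     SE      Z
#>  gene00053      all      9      7    0.00103  0.0918 0.2404 0.0446  5.386
#>  gene00091      all      9      7    0.00103  0.0918 0.2564 0.0436  5.885
#>  gene00126      all      9      7    0.00103  0.0918 0.0316 0.0618  0.511
#>  ...
```

Each row is one gene in one cell-type stratum: `wilcoxon_p`/`q_value`
rank the confounder-adjusted residuals between the 9 case and 7 control
individuals, `ADE` is the precision-weighted mean of E[ln δ] across
individuals (a log-scale effect size; gene00053 is up-regulated in
cases), and `Z = ADE/SE` its Wald statistic. At this deliberately small
example scale nothing clears q < 0.05 — sixteen individuals carry little
rank-sum power — which is itself the method behaving honestly; the
benchmark configurations below show the power gain over naive
pseudo-bulk. With a `cell_type` column in the metadata the pipeline runs
per cell type and `celltype` distinguishes the strata.

A thin command-line interface wraps the same functions:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "cfdiff.R", package = "cfdiff"))')
Rscript $CLI simulate --out simdir --seed 5 --genes 500 --individuals 20
Rscript $CLI adjust --mtx simdir/matrix.mtx --genes simdir/genes.tsv \
  --barcodes simdir/barcodes.tsv --cells simdir/cells.tsv \
  --labels simdir/labels.tsv --out deg.tsv --rank 10 --knn 20
```

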
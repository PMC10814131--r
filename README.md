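# refstab — reference-gene stability analysis for RT-qPCR

Relative quantification by RT-qPCR stands or falls with the housekeeping
gene (HKG) used as normalizer: a reference that itself responds to the
experimental treatment silently distorts every fold change computed
against it. `refstab` is an R package for choosing defensible reference
genes from cycle-threshold (Ct) data. It implements the four stability
algorithms in standard use, aggregates them into a consensus ranking, and
carries the surrounding workflow: technical normalization against control
wells, condition-combinatorial analysis, 2^−ΔΔCt fold-change
quantification, multivariate overviews, and a synthetic-data generator
with known ground truth.

The package ships a complete worked dataset (`asc_ct()`): Ct values of
five candidate HKGs (*ACTB*, *B2M*, *GAPDH*, *HPRT1*, *RPLP0*) measured
in adipose-derived mesenchymal stromal cells (ASCs) from three donors
under five culture conditions — serum (`F`), serum + IL-1β (`F+IL1`),
starvation (`S`), starvation + IL-1β (`S+IL1`), and starvation after
IL-1β priming (`F+IL1/S`). These conditions mirror the protocols used to
prime MSCs or to harvest their secretome for osteoarthritis-oriented
applications, where both inflammation and serum withdrawal turn out to
destabilise popular reference genes.

## The methods

For genes *i* on a sample subset, with Ct a log2-scale quantity
(1 cycle ≈ 2-fold):

- **Comparative ΔCt** — stability of gene *i* = mean over partners *j* of
  `sd(Ct_i − Ct_j)` (sample SD). Genes that co-vary tightly with the rest
  of the panel score low.
- **BestKeeper** — the mean absolute deviation of a gene's Ct from its
  arithmetic mean; the per-sample mean across candidates (BestKeeper
  index) and each gene's Pearson *r* with it are reported alongside.
- **NormFinder** — a variance-decomposition model: after removing gene
  and sample main effects, each gene's residual variance is estimated
  with a finite-panel bias correction; stability = √(max(σ̂², 0)). A
  grouped variant adds shrunken between-group differences.
- **geNorm** — M = mean SD of a gene's pairwise log-ratios; the worst
  gene is removed stepwise until a best pair remains.
- **Consensus** — geometric mean of the four ranks,
  (r_ΔCt · r_BK · r_NF · r_geNorm)^¼, with the geNorm final pair sharing
  rank 1.

## Worked example

```r
library(refstab)
asc <- asc_ct()                       # 15 samples x 5 genes
res <- run_plan(asc)                  # 12 analyses: 5 single, 6 coupled, ALL
res[["ALL"]]$consensus
#> <consensus_ranking> 5 genes, 15 samples (best first)
#>    gene rank_delta_ct rank_bestkeeper rank_normfinder rank_genorm geomean
#> 1 HPRT1             1               3               1           4    1.86
#> 2   B2M             4               1               4           1    2.00
#> 3 RPLP0             3               2               3           1    2.06
#> 4 GAPDH             2               4               2           3    2.63
#> 5  ACTB             5               5               5           5    5.00
```

Across all conditions *HPRT1* is the most stable candidate (geomean 1.86)
and *ACTB* the least (5.00, last by every method). Per condition the
winner changes — `F` → *HPRT1*, `F+IL1` → *GAPDH*, `S` → *B2M*,
`S+IL1` → *RPLP0*, `F+IL1/S` → *HPRT1* — which is the practical message:
the best reference gene must be re-validated for each culture condition.

The numbered drivers under `analysis/` walk the full study:
descriptives (`01`), stability rankings (`02`), PCA/clustering (`03`,
PC1 = 87.2% of variance; the top split separates starved from serum-fed
samples), and synthetic-data validation (`04`, including how an unstable
reference flips a fold-change call from `down` to `unchanged`). Each
writes its tables under `results/`.

## Package layout

- `R/` — data model and I/O, technical normalization, the four stability
  algorithms, consensus, analysis plans, fold-change quantification,
  multivariate overviews, synthetic generator
- `inst/extdata/asc_hkg_ct.csv` — the ASC Ct dataset
- `analysis/` — numbered narrative drivers
- `vignettes/reference-gene-stability.Rmd` — models, assumptions, design
  choices and limitations
- `tests/testthat/` — unit, property and acceptance tests with
  independent brute-force oracles
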
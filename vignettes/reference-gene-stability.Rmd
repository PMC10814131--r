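---
title: "Choosing stable reference genes: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Choosing stable reference genes: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(refstab)
```

## The problem

Relative RT-qPCR quantification divides a target gene's signal by a
reference ("housekeeping") gene's signal measured in the same sample.
The arithmetic is done on cycle-threshold (Ct) values, a log2-scale
quantity: one cycle corresponds to a two-fold difference in template.
If the reference gene itself responds to the treatment, its response is
transferred — inverted — onto every target. The packaged dataset
(`asc_ct()`) makes the stakes concrete: in adipose-derived mesenchymal
stromal cells, serum withdrawal moves *ACTB* by more than two cycles, so
normalizing a starvation-vs-serum comparison to *ACTB* silently adds a
~4-fold bias.

This vignette documents the models implemented, the parameters that
matter, the numerical conventions, and the choices made where the
methodology is genuinely underdetermined. The numbered scripts under
`analysis/` run the corresponding analyses; nothing claimed here is not
recomputed by the tests or `scripts/acceptance.R`.

## Data model and technical normalization

A `ct_table` holds one finite Ct per (sample, gene) cell, values
restricted to (0, 45) cycles, plus per-sample metadata (donor; one of
five culture conditions — serum `F`, serum + IL-1β `F+IL1`, starvation
`S`, starvation + IL-1β `S+IL1`, starvation after priming `F+IL1/S` —
each implying serum/IL-1β/priming flags). Technical duplicates are
collapsed on input, by arithmetic mean by default; the instruments'
duplicate wells estimate the same quantity, and the mean is the
convention unless a lab states otherwise. A median rule is available by
flag; replicates more than 1 cycle apart are collapsed with a warning,
since such spread usually signals a failed well. Missing cells are
representable but rejected by every stability method: with a 15 × 5
complete matrix the honest behaviour is to fail loudly rather than
impute. Amplification is called at Ct < 35, strictly.

`normalize_technical()` removes run-level technical variation using the
two control wells carried by each sample: the positive PCR control
(PPC, amplification efficiency) and the reverse-transcription control
(RTC, cDNA synthesis). The correction subtracts each control's
per-sample deviation from its cross-sample mean, sequentially, PPC
first:

$$Ct' = Ct - (ppc_s - \overline{ppc}) - (rtc_s - \overline{rtc})$$

Mean-centred deviations were chosen over alternatives (e.g. rescaling
to a fixed control value) because they preserve the overall Ct scale,
reduce to the identity when the controls are flat, are invariant to a
constant added to all control readings, and are idempotent. The exact
arithmetic used by instrument software is rarely published; the scheme
applied is therefore recorded in the `NormalizationReport`. The report's
SDs use the population (n) denominator, matching the descriptive-SD
convention below.

## The four stability algorithms

All four treat lower values as more stable and are computed per sample
subset. Their invariances are asserted by the test suite: adding a
per-sample constant to all genes leaves comparative ΔCt, geNorm and
NormFinder unchanged (pairwise differences and double-centring cancel
it) but *changes* BestKeeper, which looks at each gene's own dispersion;
adding per-gene constants changes nothing anywhere; sample and gene
order never matter.

**Comparative ΔCt.** Gene *i*'s value is the mean over partners *j* of
the sample SD (n − 1) of the per-sample difference series
$Ct_i - Ct_j$. The n − 1 denominator is required to reproduce the
reference values computed for the packaged dataset (e.g. *HPRT1* 0.14
in condition `F`).

**BestKeeper.** Reported as the mean absolute deviation (MAD) of a
gene's Ct from its arithmetic mean — this is the dispersion statistic
the original tool prints as "SD", and it reproduces the packaged
dataset's reference cells (e.g. *RPLP0* 0.16 in `F`). The original
tool's variant — deviations around the geometric mean of linearised
quantities — differs negligibly at Ct 18–28 and sits behind
`variant = "geometric"`. The BestKeeper index (per-sample mean Ct) and
per-gene Pearson correlations with it are attached for inspection but
never enter the ranking; a constant gene gets MAD 0 and an `NA`
correlation.

**NormFinder.** Ct values are treated as log2-scale expression. In the
ungrouped default, the matrix is double-centred and each gene's residual
mean square $z_g = \sum_s r_{gs}^2/(n-1)$ is corrected for the bias that
centring over a finite panel of $g$ genes introduces:
$\hat\sigma^2_g = \frac{g}{g-2}\left(z_g - \frac{\sum_h z_h}{(g-1)g}\right)$,
stability $= \sqrt{\max(\hat\sigma^2_g, 0)}$. Two consequences are worth
knowing. First, at very small n the estimate can go negative; the floor
at zero then ties the top genes exactly (this happens in conditions `F`
and `S+IL1` of the packaged data, where the printed two-decimal values
are tied as well). Second, published NormFinder numbers vary between
reimplementations; this package therefore treats NormFinder magnitudes
as implementation-defined and validates *orderings*, plus an exact match
against a literal step-by-step transcription of the formulas in the test
suite. The grouped variant (per-group variances, group differences
shrunk by their estimated signal-to-noise ratio, averaged with the
sampling SE) is available with `groups = `, requiring ≥ 2 samples per
group; the ungrouped model is the default because consensus rankings
here are built from tools run without group labels.

**geNorm.** Pairwise variation $V(i,j)$ is the SD of the per-sample
$Ct_i - Ct_j$ (the log2 expression ratio at efficiency 2);
$M(i) = \mathrm{mean}_j V(i,j)$. The gene with the largest M is removed,
values are recomputed, and the loop stops at the final pair, which
shares $M = V(i,j)$ of its mutual series. The SD denominator defaults to
sample (n − 1), which reproduces the final-pair values of the packaged
dataset (0.07 in `F` and `S`); the intermediate-step values printed for
this dataset are closer to a population (n) denominator, so both are
offered and the default applies uniformly. The discrepancy affects no
ranking, only the third decimal of intermediate M values. Exact ties
during exclusion are broken by removing the gene later in column order —
ties occur only in degenerate constructed data. With exactly two genes,
the final-pair M equals each gene's comparative ΔCt value; the suite
asserts this equivalence.

## Consensus ranking

`consensus_rank()` takes the four results, checks they cover the same
genes and samples, and computes each gene's geometric mean of ranks.
Ranks are taken at full numeric precision — ranking at the printed
two-decimal precision would misorder genes whose values tie only after
rounding (e.g. the BestKeeper cells 0.26/0.26 in condition `F`, which at
full precision are 0.2556 and 0.2644). Exact ties get average ranks. The
geNorm ranks follow the consensus-tool convention: both final-pair genes
at rank 1, the next gene at rank 3, so a gene ranked worst by all four
methods scores exactly $g$. Ties in the geomean are ordered
alphabetically.

## Condition-combinatorial analysis

`default_plan()` encodes the twelve analyses of the study design: each
condition alone, six two-condition couples chosen to contrast serum vs
starvation and the presence or timing of IL-1β, and all samples
together. `run_plan()` guarantees that a subset's result depends only on
its own rows. Plans are plain named lists, so any other condition
algebra is one `analysis_plan()` call away. Subsets smaller than three
samples are rejected: with two samples every SD-based statistic
degenerates.

## Fold changes and significance

`ddct_fold_change()` implements 2^−ΔΔCt with donor-matched pairing:
ΔCt = target − reference within each sample, each donor's ΔCt averaged
within condition, ΔΔCt formed donor-by-donor against the reference
condition, and the summary reported as mean ± SD of the per-donor folds
on the linear scale. Donors are the replicate unit because each donor
contributes one biological isolate to every condition; a donor present
in only one condition is an error, not a silent drop. Calls follow the
convention: `up` at mean fold ≥ 2 with p ≤ 0.05, `down` at ≤ 0.5 with
p ≤ 0.05, and a `tendency` band. The band is implemented as
0.05 < p ≤ 0.1 (a "tendency" that includes p ≤ 0.05 would be vacuous,
so the interval is taken as the non-significant shoulder above the
threshold).

Significance testing screens each group with Shapiro–Wilk at α = 0.01
and then applies an unpaired Student's t-test (two conditions) or
one-way ANOVA with Tukey HSD (all conditions). When normality is
rejected there is no silent non-parametric fallback — the function stops
and says so, because switching tests implicitly would change the
operating characteristics the calls are calibrated against. The t-test
defaults to the ΔCt scale, where the normal-error model is plausible;
testing on the linear 2^−ΔCt scale is available by flag. Degenerate
inputs are handled explicitly: identical constant groups give p = 1,
distinct constants p = 0, and constant groups skip the normality screen.
The suite verifies the implemented t-test's type-I error at n = 3 by
simulation (10,000 null replicates; the rate must fall in 0.04–0.06).

## Multivariate overview

`ct_pca()` treats samples as observations and gene columns as variables,
mean-centred but — by default — *not* scaled to unit variance. On the
packaged data this reproduces the reference variance shares
(PC1 87.2%, PC2 8.6%); scaling each gene to unit variance is offered by
flag but changes the answer (82.8/10.7) because it equalises the very
fluctuation differences the analysis is about. The transposed
orientation is likewise a flag. Zero-variance genes are an error when
scaling.

`ct_hclust()` clusters genes and samples of the row-centred matrix with
correlation distance (1 − Pearson r) and average linkage (UPGMA), leaf
order placing the tighter (lower merge height) subtree first at every
node; leaves count as height 0 and ties keep the input orientation.
Constant genes, or samples constant after row-centring, make correlation
undefined and are rejected by name. On the packaged data the top sample
split separates serum-fed from starved samples — starvation, not
inflammation, is the dominant axis. The UPGMA implementation is checked
against a brute-force oracle (cophenetic matrices equal to 1e-12).

## The synthetic generator

`synthetic_spec()`/`generate_ct()` simulate the full study design —
3 donors × 5 conditions, per-sample PPC/RTC wells — under the standard
qPCR error model: Gaussian noise on the Ct (log2) scale,

$$Ct_{g,s} = \mu_g + \delta_{g,\mathrm{cond}(s)} + b_{\mathrm{donor}(s)} + \varepsilon_{g,s}.$$

Donor effects are additive and shared across genes, mirroring the
donor-wise alignment visible in real heatmaps. The default parameters
emulate the magnitudes observed in the packaged dataset: baselines
18.5–26.3 cycles, noise SDs 0.10–0.30 cycles, controls at 18.65 ± 0.36
(PPC) and 22.62 ± 0.31 (RTC), donor SD 0.25. Each perturbed gene gets
its *own* condition signature — HK1 strongly starvation- plus mildly
IL-1β-responsive (+2.0/+0.5, the classic *ACTB* pattern), HK3 moderately
starvation-responsive (+1.2), HK4 dipping after priming + starvation
(−0.8), HK5 IL-1β-responsive (+0.8) — while HK2 is unperturbed at the
lowest noise. The asymmetry is deliberate and matters: two genes given
*identical* shift profiles are exchangeable for every pairwise method
(their mutual ΔCt terms cancel and their between-condition variances
tie), so no amount of data could decide which is "worst". Distinct
signatures are also what the real dataset shows — each candidate
responded to a different stimulus. With these defaults the designed best
and worst genes are recovered as first/last of the all-sample consensus
in ≈ 98–99% of 200 simulated experiments (asserted at ≥ 90% in the
suite). Ground truth orders genes by total perturbation, the spread of
condition shifts plus the noise SD.

What the generator does *not* emulate: amplification-efficiency
differences between assays (all validated assays are taken at
efficiency 2), heavy-tailed or outlier noise, donor-by-condition
interactions, and missing wells. Passing tests on synthetic data
therefore demonstrate correctness of the algorithms under the stated
model, not robustness to those real-world artefacts.

## Problem sizes and numerical conventions

The packaged analyses are desk-scale (15 × 5 matrix; every statistic
well under a second). Simulation-based checks use 10,000 null replicates
for the t-test calibration and 200 seeded experiments for parameter
recovery. Descriptive SDs use the population (n) denominator — required
to reproduce the reference values 0.44/0.53 — while inferential SDs
(comparative ΔCt, geNorm default, fold-change summaries) use n − 1.
All randomness flows through explicit integer seeds.

## Known limitations

- NormFinder magnitudes are implementation-defined at small n (the
  zero floor ties leaders); orderings are the reliable output.
- geNorm's V(n/n+1) "how many reference genes" statistic is not
  implemented (it plays no role in these analyses).
- Instrument-native export formats are not parsed; data arrive as
  wide or long CSV/TSV.
- The tendency band and the ΔCt-vs-linear testing scale are
  conventions; both are flagged in the output rather than hidden.
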
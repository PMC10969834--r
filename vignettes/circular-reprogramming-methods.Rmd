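---
title: "Methods: the circlex circular-reprogramming comparison"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the circlex circular-reprogramming comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, eval = FALSE}
library(circlex)
```

## The scientific setting

When somatic cells are reprogrammed into induced pluripotent stem cells
(iPSCs) and the iPSCs are differentiated into some *other* cell type, any
molecular difference from a matched embryonic stem cell (ESC) derivative
mixes two causes: alterations introduced by reprogramming itself, and
residual "somatic memory" of the founder cell type.  A *circular* design
removes the second cause: neural stem cells (NSCs) derived from an ESC line
are reprogrammed into iPSCs and then re-differentiated into the very same
NSC type.  ESC-NSCs and iPSC-NSCs are then isogenic and of identical
lineage, so persistent expression or DNA-methylation differences point at
reprogramming-associated changes — in female lines most prominently on the
X chromosome, where erosion of X inactivation can de-repress genes in
clustered genomic regions and split the intermediate methylation of X-linked
CpGs (beta near 0.5) into hyper- and hypomethylated states.

circlex implements the complete comparison for this design and ships a
seeded generator that emulates its statistical structure, so every stage is
testable end to end without access to any primary data.

## The synthetic study

`synthetic_config()` fixes the study conditions.  The expression cohort is
24 arrays: two genetic backgrounds, each contributing one ESC-NSC line and
two iPSC-NSC lines in biological triplicate, plus the parental ESC line and
one iPSC line in triplicate.  Replicates rotate through three batches
("independent experiments"), so batch crosses line — the constellation that
makes batch a genuine confounder.  The methylation cohort holds the six NSC
lines in biological duplicate (12 samples), mirroring the smaller scale of a
450K experiment.

Per gene $g$ and sample $i$ the log2 intensity is

$$y_{gi} = \mu_g + b_g\,\mathrm{bg}_i + c_g\,\mathrm{batch}_i
  + l_g\,\mathrm{lin}_i + \delta\,[\text{$i$ iPSC-derived},\ g \in A]
  + \varepsilon_{gi},$$

with $\mu_g \sim N(7, 1.5)$, per-gene effect sizes $b_g \sim N(0, 0.7)$,
$c_g \sim N(0, 0.5)$, $l_g \sim N(0, 2)$ on integer-coded covariates, noise
$\varepsilon \sim N(0, 0.25)$ and a planted shift $\delta = 1$ log2 unit on
the affected X genes $A$ (12% of X genes).  Effects are drawn per gene
rather than shared so the confounding is heterogeneous — the situation
surrogate variable analysis exists for.  The lineage sd of 2 is the one
constant chosen freely: it makes the pluripotent-vs-NSC contrast dominate
the first principal component, as it does in real stem-cell compendia.
Affected genes sit inside three disjoint 10 Mb clusters on a 155 Mb chrX;
all other X genes are placed outside the clusters, so the recorded intervals
are exact ground truth for the positional scan.

Beta values are generated on the beta scale: non-differential CpGs draw a
baseline mean from $\{0.1, 0.5, 0.9\}$ shared by both groups; planted DM
X-CpGs (10% of X CpGs) have ESC-NSC mean 0.5 and iPSC-NSC mean 0.8 (hyper)
or 0.2 (hypo), half each; Gaussian noise (sd 0.05) is added and values are
clipped to $[0,1]$.  Gaussian-plus-clipping was chosen over a Beta
distribution because the calling rule operates on mean differences, for
which the noise family is immaterial, and it keeps the planted
$\Delta\beta = \pm 0.3$ exact in the noiseless limit.  80% of the DM CpGs
are placed inside the first two expression clusters, creating the
co-localization ground truth.

What the generator does *not* emulate: probe-level microarray artifacts,
intensity-dependent variance, probe cross-hybridization, type I/II Infinium
chemistry differences, and cell-composition heterogeneity.  Passing tests
therefore demonstrate the statistical machinery under the declared model,
not robustness to those platform effects.

## Differential expression with surrogate variables

`estimate_surrogate_variables()` is a two-step residual-SVD procedure: fit
the primary design per gene, take the SVD of the residual matrix, and keep
the leading right singular vectors whose variance fraction exceeds the
$(1-\alpha)$ permutation quantile of the matched component from row-wise
independently permuted residuals (parallel analysis; 20 permutations,
$\alpha = 0.05$ by default).  Each permuted matrix is re-projected onto the
residual subspace of the design so that observed and null spectra share the
same rank — without this the null fractions are systematically too small
and pure noise yields spurious surrogate variables.  Retention stops at the
first component that fails, keeping the leading run only.  This variant was
chosen over iteratively re-weighted SVA because it is deterministic given
the seed, has a transparent null, and its adequacy is defined by a testable
property: recovery of a planted batch ($|r| \ge 0.9$ with SV1).

`test_differential_expression()` then fits, per gene, OLS on
\[intercept, group, SVs\] and reports the group coefficient's t statistic
with $n - p$ degrees of freedom, BH-adjusted across genes.  Without SVs
this reduces exactly to the two-sample equal-variance t test, which the
tests exploit as a closed-form oracle.  The reported log2 fold change is
the raw difference of group means (iPSC-derived minus ESC-derived), the
microarray convention under which "2-fold" means $|\mathrm{log2FC}| \ge 1$.
Genes with zero residual variance and zero effect are flagged and given
$t = 0$, $p = 1$; all thresholds are strict inequalities
(adjusted $p < 0.01$, $|\Delta\beta| > 0.2$).

Pairwise line-level comparisons use the plain equal-variance t test with BH
at adjusted $p < 0.05$ per pair.  Note a scale limitation: with triplicate
lines the per-gene test has 4 degrees of freedom, so at the default noise
and batch settings individual pairs rarely yield genome-wide significant
genes; the pairwise machinery is exercised in the tests at higher
replication, and the pipeline reports whatever each pair yields.

## Enrichment

All enrichment calls are one-sided upper-tail hypergeometric tests
(overrepresentation only, matching how chromosome enrichment of DE genes is
conventionally read).  The universe is always the set of *measured*
features, not a genome-wide count.  Chromosome enrichment is BH-adjusted
across the 23 chromosome categories within each family; when directions are
supplied the up- and down-subsets (hyper/hypo for CpGs) are additionally
tested as their own queries against the full universe — the construction of
a direction-split test is genuinely underdetermined, so both the joint and
the split results are reported.  Gene-set overlap (GMT input) and
imprinted-gene enrichment are the same primitive at gene level, with CpGs
mapped to their nearest gene and deduplicated so a gene counts once however
many DM CpGs it holds.

## Positional scan and co-localization

The "regional accumulation" of hits along chrX is quantified by a sliding
window scan (`window_scan()`): 10 Mb windows every 1 Mb, each tested by a
one-sided binomial tail against the chromosome-wide hit rate, BH across
windows, and an enriched call at adjusted $p < 0.05$ with at least 3 hits
(the guard keeps single-feature windows on sparse chromosomes from firing).
A density-curve estimator would need a bandwidth choice that cannot be
validated; the binomial scan is a transparent stand-in that recovers the
same qualitative calls and is exactly testable (a single whole-chromosome
window equals the direct binomial tail).  Windows are 1-based half-open;
BED export shifts to 0-based half-open.  `colocalize()` pairs overlapping
enriched windows across the two modalities and merges the participating
windows into maximal union intervals.

## Pluripotency and neurality scores

Both score axes use the same reference-based construction: shift the
reference expression matrix to non-negativity by its global minimum
(recorded in the model), factorize with NMF ($k = 8$ components,
multiplicative updates, Frobenius objective, non-negative double-SVD
initialization with seeded fill-in of zeros; tolerance $10^{-4}$ relative
improvement, at most 500 sweeps), rank components by target-vs-rest AUROC
(midrank ties), and combine the mixing weights with a logistic model
constrained to non-negative coefficients (free intercept, ridge $10^{-3}$).
The constrained logistic objective is strictly convex with a unique
optimum; it is solved by a box-constrained quasi-Newton search from the
fixed start $w = 0$, $b = \log\mathrm{odds}$, which is deterministic and, in
the small-ridge limit, margin-maximizing for separable data.  New samples
are projected onto the basis by non-negative least squares after applying
the recorded shift; genes absent from new data are dropped from the basis
with a warning (intersection projection) rather than imputed.  The
reference novelty diagnostic of published pluripotency classifiers is out
of scope; both axes here are self-contained in-package models.

## Clustering, PCA and separation

Sample clustering uses $d = 1 - r$ (Pearson) with average linkage; columns
are sorted lexicographically first so ties break deterministically, and
trees export to Newick with heights as branch lengths.  PCA centres but
does not scale (standard for log2 expression) and fixes component signs by
the largest-magnitude loading.  `separation_score()` is the mean silhouette
of a labeling in a Euclidean score space; the structural X-vs-autosome
contrast is evaluated in the *full* PC score space (a rotation of the
centred data), where the planted origin signal adds between-group distance
on chrX regardless of which leading component it lands on.  On expression
data the per-gene background effects outweigh the planted X effect in
total distance, so the top-level X-subset *tree* split follows the genetic
background; the origin separation appears as the silhouette ordering
(chrX above autosomal) and, cleanly, in the X-CpG methylation tree, where
no background/batch term exists in the generative model.

## Problem sizes and budgets

Defaults — 10,500 genes, 20,000 CpGs, 24 arrays, 12 methylation samples,
a 332-sample reference with a held-out 20% split — were chosen so the
full pipeline runs in seconds and the complete property-test suite
(including twenty-seed calibration and recovery loops at full default
scale) in well under a minute on a single CPU, while keeping every
per-test effect size in the regime the analytical power calculations
predict to be detectable.

## Known limitations

* The delta-beta call is threshold-only by design; it carries no per-CpG
  variance estimate and hence no error control beyond the calibrated
  false-call rate of the generative model.
* Surrogate variable estimation assumes confounders are approximately
  orthogonal to the primary contrast in sample space; a batch fully
  confounded with the group cannot and should not be removed.
* The window scan treats features as exchangeable within a chromosome;
  strong non-uniformity of probe density is absorbed by the local feature
  counts but extreme sparsity will suppress calls via the minimum-hit
  guard.
* Scores are meaningful only relative to the reference cohort the models
  were trained on; projecting profiles from a platform with many missing
  basis genes degrades gracefully (intersection) but is not corrected for.
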
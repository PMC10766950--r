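---
title: "Methods: multi-tissue transcriptome dysregulation analysis for the FD mouse"
author: "fdtx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-tissue transcriptome dysregulation analysis for the FD mouse}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fdtx)
```

## The scientific problem

Familial dysautonomia (FD) is caused by a splice mutation in *ELP1* that
reduces the amount of full-length *ELP1* transcript in a tissue-specific way,
most severely in the peripheral nervous system. In the humanized FD mouse,
five neuronal tissues (dorsal root ganglion DRG, trigeminal ganglion TG,
medulla MED, cortex, spinal cord SC) are profiled by bulk RNA-seq in FD and
control animals (12 control + 13 FD per tissue). The analysis question is:
which genes and networks respond to the reduced dose of full-length ELP1,
and how does that response converge across tissues?

`fdtx` implements the full analysis as a reusable, tested pipeline:

1. **Expression core** — count I/O, a per-tissue expression filter (median
   CPM ≥ 0.1 in at least one genotype), median-of-ratios size factors, and
   quantification of the full-length driver as the CPM sum of two designated
   feature rows (`ELP1_FL_human` + `Elp1_FL_mouse`), mirroring an exon-sum
   definition at gene-fixture level.
2. **Surrogate variables** — hidden confounders estimated from the residuals
   of a per-gene genotype regression.
3. **Differential expression** — per-gene negative-binomial Wald GLMs with
   genotype + surrogate variables and the DEG gate FDR < 0.1 with linear
   fold change > 1.2 or < 0.8.
4. **Co-expression** — signed WGCNA-style modules on the SV-residualized
   matrix, eigengenes, and permutation Zsummary module preservation.
5. **Dose response** — modules whose eigengene correlates with the driver at
   r ≥ 0.8, then genes with \|r\| ≥ 0.8 to their eigengene; the union of
   DEGs and dose-responsive genes is the tissue FD signature.
6. **PPI networks** — STRING-format edges thresholded at 0.4, induced on the
   signature (no added interactors), hubs (degree ≥ 5), and BFS distances
   from the driver with an explicit "0-connectivity" class.
7. **Convergence** — pairwise hypergeometric DEG overlaps on the
   non-redundant union background, fold-change and driver-distance
   concordance, and rank-rank hypergeometric overlap (RRHO) maps.
8. **Single-cell markers** — MCA embedding of cells and genes in a shared
   space, SNN/modularity clustering, top-200 nearest-gene signatures, a
   reconciliation rule against author-provided marker tables, and DEG
   enrichment in the resulting subtype markers.
9. **GO enrichment** — one-sided Fisher tests against explicit backgrounds
   with greedy redundancy pruning by overlap score.

## Models and estimators

### Negative-binomial Wald differential expression

Counts are modeled as $y_{gs} \sim \mathrm{NB}(\mu_{gs}, \alpha_g)$ with
$\mathrm{Var} = \mu + \alpha\mu^2$ and
$\log \mu_{gs} = \log s_s + x_s^\top \beta_g$, where $s_s$ is the
median-of-ratios size factor and $x_s$ holds intercept, genotype, and
surrogate variables. Gene-wise dispersions come from a method-of-moments
estimator on normalized counts, floored at $10^{-8}$ and shrunk 50/50 (log
scale) toward a log-log mean–dispersion trend. Coefficients are fit by IRLS
(tolerance $10^{-8}$, 100 iterations max); genes that fail to converge are
flagged and yield `NA` p-values. The Wald statistic $\beta/\mathrm{se}$ is
referred to a standard normal, two-sided, with Benjamini–Hochberg FDR across
the tissue's tested genes. No fold-change shrinkage is applied: reported
fold changes are raw, and the DEG gates (1.2 / 0.8) act on the linear scale,
which is deliberately asymmetric in log space.

The dispersion estimator and the 0.5 shrinkage weight are this package's
choices (recorded in the fit metadata); the intent is to reproduce the
*class* of test — an NB Wald GLM with size-factor offsets and SV covariates
— not any particular implementation of it. Tests verify calibration (type-I
error within [0.03, 0.07] at nominal 0.05) and agreement of the genotype
coefficient with an independent maximum-likelihood NB fit.

### Surrogate variables

The estimator is a deterministic two-step residual-SVD: regress genotype out
of every gene, decompose the residual matrix by SVD, and keep the leading
components whose eigenvalue proportions exceed the upper-α quantile (α =
0.1) of a Buja–Eyuboglu permutation null. The null permutes the *raw*
matrix within genes and re-residualizes before the SVD, so observed and null
matrices share both per-gene variance and rank deficiency; comparing raw
eigenvalues instead, or omitting the re-residualization, biases k upward —
pure-noise inputs then return spurious components. Retention is sequential:
the first failing component stops the count. Columns are orthogonal,
zero-mean, and sign-fixed (first nonzero loading positive), so results are
reproducible for a fixed seed.

`residualize()` fits each gene on protected covariates (intercept +
genotype) plus the SVs and subtracts only the SV contribution, leaving the
genotype signal intact for co-expression analysis. The operation is
idempotent to 1e-8. Sex is not modeled explicitly; it is left to the
surrogate variables.

### Signed co-expression modules

Adjacency is $a_{ij} = ((1 + r_{ij})/2)^\beta$ — a *signed* network, so
anti-correlated genes are unconnected. The topological overlap measure
$\mathrm{TOM}_{ij} = (\sum_{u \ne i,j} a_{iu}a_{uj} + a_{ij}) /
(\min(k_i, k_j) + 1 - a_{ij})$ feeds average-linkage hierarchical
clustering on $1 - \mathrm{TOM}$. Instead of dynamic tree cutting the
package uses a deterministic static cut at 99% of the maximal merge height,
followed by the minimum-size filter (30 genes) and iterative merging of
modules whose eigengenes have dissimilarity $1 - r < 0.25$ — the merge
threshold follows the published procedure exactly, while the static cut is a
reproducibility-motivated approximation of the dynamic cut. Eigengenes are
the first principal component of the standardized member expression,
unit-norm, sign-aligned so the mean correlation with members is
non-negative (the sign convention is otherwise arbitrary).

Soft powers are configurable per tissue and ship with the published values
(cortex 5, DRG 6, MED 5, SC 6, TG 7); `pick_soft_power()` can also select
the smallest power whose scale-free fit $R^2 \ge 0.8$ (10 connectivity
bins, negative slope required).

Module preservation uses the permutation Zsummary: density (mean
intramodular adjacency in the test network) and connectivity (correlation of
intramodular connectivity between reference and test) are compared against a
null in which the module assignment is randomized *in the test network
only*. Randomizing the gene set in both networks simultaneously is a
subtly wrong null — module-versus-background structure then inflates the
null connectivity correlation and can push genuinely preserved modules below
zero. Zsummary < 2 is "not preserved", > 10 "strongly preserved".

### Dose-responsive genes

Criterion (1) — eigengene–driver Pearson $r \ge 0.8$ — is implemented as a
*signed* threshold, following the asymmetric wording of the rule (criterion
(2) explicitly takes an absolute value; criterion (1) does not). A
`use_abs` switch provides the absolute-value variant since the original
wording does not fully resolve the intent. Criterion (2) keeps member genes
with $|r| \ge 0.8$ to their module eigengene. The FD signature is the
union of DEGs and dose-responsive genes with categories
`deg_up`/`deg_down`/`dose_responsive`/`both`. A gene that is both a DEG and
dose-responsive is genuinely both — strong genotype responders track the
driver for the same reason the driver tracks genotype.

### PPI network statistics

STRING scores (0–1000) are divided by 1000 and thresholded at 0.4 (400 is
kept, 399 dropped); duplicate pairs collapse to their maximum score. The
induced network contains exactly the query set — signature genes plus the
driver — with no additional interactors; query genes without a retained
edge appear as isolated vertices so the "0-connectivity" class is countable.
Distances are unweighted BFS (scores are thresholded, then ignored);
degree-0 nodes are "isolated" and disconnected-but-non-isolated nodes are a
distinct "unreachable" class, since display connectivity and graph
connectivity are different things. Hubs are nodes of degree ≥ 5, ranked by
degree with lexicographic tie-breaks. Percentages are reported half-even at
two decimals (48.21 = 121/251).

### Convergence statistics

Gene-set overlaps use the upper-tail hypergeometric test with four explicit
inputs: \|A\|, \|B\|, the overlap, and the non-redundant background. RRHO
ranks both lists by signed significance ($-\log_{10} p \cdot
\mathrm{sign}(\log_2 \mathrm{FC})$, ties broken by gene id), and for each
rank-threshold pair stores the natural-log odds ratio of the 2×2 membership
table with the Haldane–Anscombe 0.5 correction, alongside a chi-squared
p-value. The default step is $\sqrt{N}$. The map transposes when the
inputs swap; identical rankings give positive diagonals, reversed rankings
negative ones (except in the degenerate whole-list corner). A tissue pair
is called concordant when the median diagonal log OR is positive.

### Single-cell marker signatures

Cells are QC-filtered on feature counts at the 2.5% tails using (n+1)p
linear-interpolation percentiles (R quantile type 6, under which 100
distinct cells retain exactly 96). The MCA embedding min-max scales each
gene, fuzzy double codes it as $(x, 1-x)$, and runs correspondence analysis
(SVD of the chi-square-standardized residual matrix), projecting cells and
genes into a shared 30-axis space with a fixed sign convention. Clustering
builds a 20-NN graph in MCA space, weights edges by neighborhood Jaccard,
prunes below 1/15 (the conventional SNN pruning level; without it, weak
cross-cluster edges make low-resolution modularity merge everything), and
runs Leiden with the modularity objective at resolution 0.2. Clustering in
MCA space rather than a UMAP projection is deliberate: UMAP is stochastic
and distance-distorting, and is treated as visualization only. Cluster
signatures are the 200 genes nearest the member-cell centroid. The
reconciliation rule matches each cluster to the author cell type with the
most significant hypergeometric overlap (p < 0.05; best-p assignment, one
cluster per type, ties by name): matched types take the cluster signature,
unmatched author types are retained verbatim. TG-style normalization is
log-CPM rather than a variance-stabilizing transform — a recorded
deviation that removes a heavyweight dependency.

### GO enrichment

One-sided Fisher's exact tests (equivalently the hypergeometric upper tail)
against a caller-supplied background, BH-FDR across terms, significance at
FDR < 0.1. The redundancy "overlap score" is the overlap coefficient
$|A \cap B| / \min(|A|, |B|)$ on the terms' overlap gene sets — the score
itself is not pinned down by the published description, so the choice is
named in the output metadata; pruning is greedy in ascending FDR order with
cutoffs 0.1 or 0.2. Gene sets come from caller-supplied GMT files; no
ontology is bundled.

## The synthetic-data generators

`generate_bulk()` emulates the study's data regime: five tissues × (12
control + 13 FD), NB counts with Var = μ + αμ² (α = 0.05 by default),
log-normal library sizes (sdlog 0.3), a driver reduced per tissue to the
study fractions (DRG 0.3097, TG 0.3951, MED 0.4456, cortex 0.5445, SC
0.4462), two designated full-length feature rows whose CPM sum is the driver
signal, planted DEGs at configurable fold changes, co-expression modules
driven by latent factors — one tracking the log driver signal, with the
`Elp1` gene placed inside it — a hidden batch confounder
(multiplicative log-scale effects on 30% of genes, sd 0.4), and a 5%
near-silent gene tail that exercises the expression filter. Module
loadings default to 0.6–0.85, which against the NB noise at the default
base expression puts true gene–eigengene correlations near 0.9, the regime
the dose-responsive screen is specified to detect. Dispersion and
library-size characteristics of the original dataset are not published, so
these are generic NB settings, not calibrated ones.

What the generator does **not** emulate: exon-level structure (the
full-length features are synthetic gene-level rows), count overdispersion
heterogeneity across genes, correlated confounders, GC/length biases, or
any real PPI topology. Passing tests therefore demonstrate that the
estimators recover the structures they target under a faithful generative
model of the stated design — not that the original biological conclusions
re-derive from scratch.

`generate_ppi()` plants a mediator chain from the driver to a hub
(emulating the observed pattern where a few dose-responsive tRNA-synthetase
genes mediate all driver-to-DEG connections), gives the hub ≥ 6 edges at
scores ≥ 400, and adds background edges spanning 1–1000 so the 0.4
threshold is exercised. The driver touches the network only through the
chain, making the planted BFS distance exact by construction.

`generate_scrna()` plants 2+ clusters (default three of 80 cells each) with
exclusive markers (default 40 per cluster, 10× elevation — the order of
separation real neuronal subtypes show; weaker settings leave the MCA
spectrum too flat for distance-based clustering), NB noise, dropout by
independent zeroing, and an optionally perturbed author-style marker table
to exercise the reconciliation rule.

All three generators are byte-deterministic under a fixed seed.

## Numerical choices and degenerate inputs

- CPM for filtering uses raw library sizes, not size factors — the simplest
  reading of "counts-per-million"; the log2 pseudocount is 1 on
  size-factor-normalized counts.
- Size factors median *linear* ratios; implementations that median
  log-ratios differ only by interpolation at even gene counts.
- Full-length driver features bypass the expression filter so the profile
  is always computable; noise-free profile fixtures take a degenerate Welch
  branch (t = ±Inf/0, p = 0/1).
- Welch's two-sided t-test is used for the per-tissue driver comparison
  (unequal n and variance; the choice of t-test flavor is otherwise open).
- All-zero genes are flagged, not fitted; rank-deficient designs and
  constant drivers error out with the offending columns named.
- Ties everywhere (hub ranking, RRHO ranks, signature distances) break by
  identifier for determinism.
- Permutation-calibration tests smooth the discrete hypergeometric tail
  with the randomized-p construction $P(X \ge k) - U \cdot P(X = k)$,
  which is exactly uniform under the null; the raw discrete p-values are
  conservative by construction.

## Problem sizes used by the test-suite

The suite favors small, structured fixtures: 5,000 genes × 25 samples for
DEG recovery, 500–800 genes for the SVA/dose-response recoveries, 100-gene
two-block fixtures for module detection, 200-gene universes for
preservation, 240 cells × 300 genes for the single-cell path, graphs of ≤
30 nodes against a Floyd–Warshall oracle, and 1,000 random p-vectors
against a brute-force BH oracle. These sizes were chosen so each planted
effect is comfortably identifiable under its estimator's asymptotics while
the whole suite stays fast.

## Known limitations

- The static tree cut can absorb weakly separated background genes into
  large modules; contamination is mitigated by the eigengene merge and the
  \|r\| ≥ 0.8 gene gate but not eliminated.
- The CPM ratio that defines percent-of-control carries compositional bias
  when much of the transcriptome shifts with genotype (1–2 points under the
  default generator); this is a property of the estimand, not a bug.
- Non-genotype co-expression modules are, by definition, candidate
  surrogate variables; after SV residualization only driver/genotype-linked
  modules reliably survive. Real-data module counts will therefore depend
  on how many SVs the permutation test retains.
- MCA + SNN clustering needs tens of informative genes per population;
  sparse or shallow single-cell data will under-segment.
- The NB Wald test is slightly liberal at very small n, as all Wald tests
  are; the suite pins it inside [0.03, 0.07] at n = 25.
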
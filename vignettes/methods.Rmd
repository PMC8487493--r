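---
title: "Models and methods behind neurodiverge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind neurodiverge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`neurodiverge` packages the statistical machinery for asking how brain gene
expression diverges between ancestral (allopatric) and reinforced
(sympatric) populations of a species undergoing cascade reinforcement, with
sex as the second design axis. It covers the full path from a raw count
matrix to: per-comparison differential-expression (DE) calls, candidate
synaptic-transmission gene identification, expression-divergence trees,
DE-count ratio randomization tests, a weighted co-expression network with
module–trait association, and synaptic-pathway concentration tests. A
synthetic-data generator reproduces the statistical structure of the study
design so that every stage can be exercised and validated end to end
without the original sequencing data.

# Normalization model

Counts are filtered on unnormalized mean CPM (genes with mean CPM below 1
across all samples are discarded; the boundary is kept). The filter is
applied before between-sample normalization because that is the stage
order of the pipeline; a flag is not needed since the filter function
accepts any count matrix.

Between-sample scaling uses the trimmed mean of M-values (TMM). For each
sample against an automatically chosen reference (the sample whose
75th-percentile count fraction is closest to the mean), genes zero in
either sample are excluded, per-gene log ratios (M) are trimmed 30% on
each side and abundances (A) 5% on each side, and the surviving M-values
are combined with inverse asymptotic-variance weights. Factors are
rescaled to geometric mean 1, so the product of factors is 1.

Log2 CPM uses a prior count of 2 scaled per sample by effective library
size,

$$\log_2\!\mathrm{CPM}_{gs} = \log_2\!\left(
  \frac{y_{gs} + p_s}{L_s + 2p_s}\cdot 10^6\right),\qquad
  p_s = p\,\frac{L_s}{\bar L},$$

so a gene with equal relative abundance in two samples has log ratio
exactly zero and zeros stay finite. This matches the effective-library
scaled convention used by the standard count packages; exact depth
invariance holds only at prior 0, since a fixed prior perturbs values by
O(prior/library) — negligible at sequencing depth.

# Negative-binomial testing

Each gene's counts are modelled as NB with gene-wise dispersion
$\varphi_g$ (squared biological coefficient of variation). The design is a
one-way layout — one coefficient per group, the average log count — with
log effective library sizes as offsets. Because the design is block
diagonal, each coefficient is fit by a one-dimensional Newton iteration
vectorized across genes.

Dispersion estimation maximizes the Cox–Reid adjusted profile likelihood
(APL) on a log-spaced grid from $10^{-4}$ to 4 with quadratic
interpolation at the grid maximum:

* **common**: maximizer of the APL summed over genes;
* **trended**: genes are binned into abundance deciles; each gene's trend
  curve is the linear interpolation (in average log2 CPM) of the adjacent
  bins' average APL curves, and the trended value is that curve's
  maximizer. Interpolating the curves rather than the per-bin maximizers
  makes the shrinkage limit below exact;
* **tagwise**: maximizer of $\mathrm{APL}_g + d_0\,\mathrm{APL}_{trend}$,
  an empirical-Bayes compromise with prior degrees of freedom $d_0 = 10$
  by default. As $d_0 \to \infty$ the tagwise estimate equals the trend;
  at $d_0 = 0$ it is the per-gene maximum APL.

The six comparisons (sympatric vs allopatric overall, in females, in
males; female vs male overall, in allopatry, in sympatry) are two-group
likelihood-ratio tests: the full model has two average-log-count
coefficients, the null one, the tagwise dispersion held fixed in both
(standard LRT practice), and the statistic referred to $\chi^2_1$.
Benjamini–Hochberg FDR is applied within each comparison; significance is
FDR < 0.05. The sign convention is positive log2 fold change =
overexpressed in sympatry (geography contrasts) or in females (sex
contrasts). When the candidate gene set is analysed, tests and the FDR
family are restricted to the candidates.

Storey q-values (used for module–trait and module-concentration families)
estimate the null proportion $\pi_0$ with the smoother method: tail
proportions over a $\lambda$ grid, cubic-spline smoothed, evaluated at the
largest $\lambda$; estimates outside (0, 1] fall back to $\pi_0 = 1$,
which reduces q-values to BH exactly.

# Candidate genes and calibration

Candidates are found by case-insensitive substring search of keyword rules
over free-text annotations, with optional include/exclude regular
expressions refining broad keywords (e.g. "kinesin" restricted to
kinesin-associated proteins, pseudogenes excluded). The shipped rule table
covers the classic synaptic protein families in five categories
(ionotropic receptors; synaptic vesicle proteins; vesicle-associated
proteins; synaptic plasma-membrane proteins; reversibly membrane-associated
proteins) and is an input, not ground truth: users should curate their
own. The observed number of DE candidates is calibrated by drawing random
gene sets of the same size and counting significant genes per draw; the
empirical p-value uses the strict inequality (proportion of draws
exceeding the observed count).

# Expression-divergence trees

Per gene: expression is standardized to mean 0, sd 1 across samples; the
four group means then give a 4-point distance matrix (absolute differences
for a single gene); neighbor joining yields tip branch lengths, one per
group, read as that group's contribution to the gene's expression
divergence. Negative NJ branch lengths are clipped to zero and counted.
The four-taxon NJ solver is closed-form and vectorized over genes; it
reproduces additive distance matrices exactly and agrees with `ape::nj`.

Twelve randomization tests compare divergence between group pairs (by
default SF–AF, SM–AM, SF–SM, AF–AM; the pairs are configurable since the
choice is a design decision, not a property of the data): the mean tip
difference per pair within the candidate set and within the non-candidate
set (8 tests), and the candidate-minus-non-candidate contrast (4 tests).
Differences, not ratios, are used because zero-length branches occur. The
null shuffles candidate labels across genes (set sizes preserved),
p-values are the proportion of null replicates at or above the observed
statistic (one-sided; an optional (r+1)/(N+1) estimator is available), and
BH FDR is computed over the 12 tests.

# DE-count ratio tests

Each transcriptome-wide test works on a two-column 0/1 table, one row per
gene: the statistic is the ratio of column sums, and each null replicate
swaps each gene's pair of indicators independently with probability 1/2
("horizontal" shuffling) before recomputing the ratio. The shuffled
quantities are the per-gene significance indicators — the minimal reading
of a table whose column sums form the ratio. The three standard tables
are: geography-DE (union of the two within-sex geography comparisons) vs
sex-DE (union of the two within-geography sex comparisons);
geography-DE in females vs males; sex-DE in sympatry vs allopatry. Unions
count unique genes. Implementation note: only rows where the two
indicators differ can move counts, so the null is drawn exactly as a
difference of two binomials, which makes the 10,000-replicate test
instantaneous; tests verify agreement with full enumeration.

# Co-expression network

The network stage retains the top 10% of genes by CPM variance (ties
broken by gene ID), computes Pearson correlations of log2 CPM, and raises
|r| to a soft-threshold power β (unsigned network; a signed option
exists). The default is the canonical β = 6. Automatic selection by
scale-free topology fit (binned log-log regression of the connectivity
distribution, requiring slope < 0 and R² above 0.9, smallest qualifying β)
is available, but at a few hundred network genes simulated module
structure does not show scale-free topology at moderate β — the fit keeps
creeping up with β — so automatic selection is only advisable at larger
gene counts and the fixed default is used in the bundled pipeline.

Adjacency is converted to topological overlap,
$\omega_{ij} = (\sum_u a_{iu}a_{uj} + a_{ij}) / (\min(k_i,k_j) + 1 -
a_{ij})$, and modules are detected on the average-linkage dendrogram of
$1-\omega$. The tree cut is a static cut at height 0.99 followed by a
recursive within-branch search for the cut height that maximizes the
number of subclusters of at least 40 genes (preferring the highest such
cut), recursing up to `deep_split` = 3 nested levels. This search replaces
fixed height-gap rules because average-linkage TOM dissimilarities
concentrate near 1, where absolute and relative height gaps cannot
separate real branch boundaries from chaining noise; module-recovery
simulations define the contract. Genes in undersized branches stay
unassigned ("grey"); modules are named by the conventional color list in
size order. Over-eager splits are repaired by the merge step: modules
whose eigengene dissimilarity falls below 0.3 are merged iteratively
(average-linkage grouping, eigengenes recomputed each pass).

Eigengenes are unit-norm first principal components of the standardized
module expression, oriented positively with the module-average profile.
Module–trait association is the Pearson correlation of each eigengene with
the binary-coded traits (allopatric = 0/sympatric = 1, male = 0/female =
1), p-values from the t distribution with n−2 degrees of freedom, and
Storey q-values over all module × trait tests at α = 0.05.

Connectivity statistics are computed on the binary graph of gene pairs
with |r| at or above 0.05: degree, local clustering coefficient,
neighborhood connectivity (mean neighbor degree), per-module averages,
counts of connected genes at reporting thresholds 0.1 and 0.3, and hub
genes (maximum within-module |r| strength, plus the best-connected
annotated alternative). The filtered network exports as node/edge TSV and
GraphML.

# Pathway concentration tests

A pathway is flagged synaptic when its name or ancestor/child term text
contains "synap", "neuro" or "neura" (case-insensitive); the term text is
an input column — no ontology service is queried. Four randomization
tests use 10,000 replicates and p = proportion of null values at or above
the observed statistic: per-module synaptic counts under shuffles of the
pathway-to-module assignment (module sizes fixed; this null is exactly
hypergeometric, which the tests exploit as an oracle), with Storey
q-values across modules; the total synaptic count in trait-associated
modules under the same shuffle; the mean synaptic count per significant
module under shuffles of the significance designation; and the ratio of
mean synaptic counts in geography-associated vs other modules under
shuffles of that designation. "Differentially expressed modules" defaults
to either-trait significance, with geography-only available through the
caller-supplied module set.

# The synthetic-data generator

The generator emulates the study design at desk scale. Defaults (chosen
once, stated here with their rationale):

* **Design**: 16 samples — allopatric females 5, allopatric males 3,
  sympatric females 4, sympatric males 4 (the study's post-QC layout).
* **Library sizes**: lognormal, mean 2×10⁶, CV 0.3. A desk-scale stand-in
  for ~55M read pairs; depth scales power but not the statistics
  exercised.
* **Abundances**: per-gene log2 baseline ~ Normal(3, 2) relative
  abundance, normalized per sample so expected counts are
  $\mu_{gs} = L_s q_{gs} / \sum_g q_{gs}$.
* **Dispersion**: $\varphi_g = 0.4^2 + 2/\mu_g$. The source study shows a
  BCV plot without printed values, so BCV 0.4 — the usual magnitude for
  outbred tissue — is an explicit assumption, with a mild abundance trend.
* **Planted effects**: geography DE fractions 0.05 (female-scoped), 0.02
  (male-scoped), 0.03 (both sexes); sex DE 0.01; |log2FC| = 2 with random
  sign. More geography than sex effects and more female than male
  geography effects mirror the study's headline asymmetries. Sex-scoped
  geography effects are sex-biased, not sex-exclusive: the other sex
  expresses half the fold change (`lfc_other_sex_frac = 0.5`). Strictly
  exclusive effects of this size would make every female-geography gene a
  strong sex-DE gene inside sympatry, inverting the geography-vs-sex
  asymmetry the design is supposed to show; half-strength sharing keeps
  within-geography sex contrasts weak while preserving the female bias.
* **Modules**: ten 60-gene modules driven by one latent factor each,
  $z_s = a\,t_s + \sqrt{1-a^2}\,\varepsilon_s$, gene loading 0.8 on the
  log2 scale. Three modules are geography-tied with heterogeneous
  strengths a = 0.9, 0.75 and −0.75 (mirroring the mixed-sign, mixed-
  magnitude module–trait correlations of real data; equal strong
  associations make same-trait modules statistically indistinguishable at
  16 samples), one is sex-tied (a = 0.8), six are free. Module genes draw
  baselines from the upper abundance range (mean shifted 2 SD, spread
  halved) because detected co-expression modules live, by construction,
  inside the top-variance gene selection — planting them at random
  abundance would test the variance filter, not module recovery.
* **Candidates and pathways**: 5% of genes carry candidate annotations
  built from the keyword-rule families; 2% of non-candidates carry decoy
  strings that broad keywords match but restrictions exclude. The pathway
  plan gives each detected module 20 pathways, with synaptic fraction
  0.55 in modules detected as geography-associated and 0.10 elsewhere —
  the concentration structure the pathway tests are meant to detect,
  at roughly the strongest observed per-module scale (15 of 28).

What the generator does **not** emulate: batch effects, library-prep
covariates, isoform structure, correlated (non-factor) residual noise,
ontology-graph structure in annotations, and any real biological
identity of genes. Passing the end-to-end tests therefore shows the
machinery is correct and calibrated under the stated generative model,
not that the biological conclusions of any particular dataset are right.

# Numerical choices and degenerate inputs

* Dispersion grid $10^{-4}$–4 (45 log-spaced points) with quadratic
  refinement; all-zero genes take the trend value and are flagged.
* GLM Newton iterations stop at relative log-likelihood change < 1e-8 or
  100 iterations (non-convergence flagged, last iterate returned); steps
  are clamped to ±5 on the log scale; all-zero groups pin the coefficient
  at the boundary without NaN.
* LRT statistics clip at 0; fitting the same model twice gives p = 1.
* Randomization p-values count ties as "greater or equal" with a 1e-12
  tolerance; seeds derive from one base seed by fixed offsets so stages
  are independently reproducible.
* Constant genes are dropped (with a warning) before standardization;
  constant eigengenes yield NA correlations; zero branch lengths make
  log2 tip ratios NA rather than infinite.
* Ties in the variance filter and in NJ pair selection break
  deterministically (gene ID order; first pair in fixed order).

# Problem sizes used in the bundled validation

The test-suite simulations use 2,000-gene datasets for calibration and
recovery checks (16 samples, BCV 0.4 — roughly 4% of the study's gene
count, which keeps every distributional check well-powered while the full
suite stays fast), 7,000 genes for the end-to-end scenario (so the 10%
variance selection holds the 600 planted module genes), 10,000
randomization replicates where an exact oracle is compared, and 20 seeded
end-to-end runs for the integrated headline check. The headline
concentration pattern is asserted qualitatively (ratio above 1): with
eight to ten desk-scale modules the permutation floor of the
geography-ratio test is 1/C(M, k), which cannot fall below 0.05 when only
one module is geography-significant; the test's power is demonstrated
separately at the 25-module scale of the study.

# Known limitations

* The tree cut is a documented approximation, not a re-implementation of
  the dynamic hybrid algorithm; partitions can differ from WGCNA's on the
  same input even though the recovery contract holds.
* Bootstrap support for sample dendrograms is plain bootstrap percentage,
  not the approximately-unbiased multiscale version; values are not
  comparable to AU p-values.
* Storey's $\pi_0$ smoother is unstable below ~20 p-values; the
  implementation falls back to BH ($\pi_0 = 1$) with a warning, which is
  conservative.
* The NB model assumes independent genes within comparisons; planted
  module structure induces correlated tests, and FDR control there is
  only approximate (as in any real RNA-seq analysis).
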
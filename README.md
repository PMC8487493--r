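# neurodiverge

Brain gene-expression divergence analysis for populations diverging under
cascade reinforcement.

When selection against hybridization drives the divergence of mating
behaviors, populations inside a contact zone (sympatric, "reinforced") can
incidentally diverge from populations outside it (allopatric,
"ancestral"). The molecular side of that process shows up in the brain:
which genes shift expression between geographies, whether females (who pay
the higher cost of hybridizing) diverge more than males, and whether the
shifted genes concentrate in synaptic-transmission pathways.
`neurodiverge` implements the complete statistical pipeline for that
question on a 2×2 geography × sex bulk RNA-seq design, plus a synthetic
data generator that reproduces the design so every stage is testable end
to end.

## What it computes

Starting from a gene × sample count matrix and a sample table:

1. **Normalization** — mean-CPM ≥ 1 filter, TMM scaling factors, log2 CPM
   with an effective-library-scaled prior count of 2.
2. **Differential expression** — NB GLMs with group-mean coefficients and
   library-size offsets; Cox–Reid adjusted-profile-likelihood dispersions
   (common/trended/tagwise with empirical-Bayes shrinkage); likelihood-
   ratio tests for the six geography/sex comparisons; BH FDR within each
   comparison at α = 0.05. Statistic per gene:
   LRT = 2(ℓ_full − ℓ_null) ~ χ²₁, with dispersion held fixed.
3. **Candidate synaptic genes** — keyword rules with include/exclude
   restrictions over free-text annotations (five protein-class
   categories); random-gene-set calibration of the observed DE count.
4. **Expression-divergence trees** — per-gene standardization, four-group
   distance matrices, neighbor-joining tip branch lengths, and 12
   label-shuffling randomization tests (8 per-set group contrasts + 4
   candidate-vs-background contrasts, BH over 12).
5. **DE-count ratio tests** — one-sided horizontal-shuffle permutation
   tests of nA/nB for geography-vs-sex, female-vs-male geography, and
   sympatry-vs-allopatry sex DE counts.
6. **Co-expression network** — top-10% variance filter, soft threshold
   (|r|^β, default β = 6, scale-free auto-selection available),
   topological overlap, average-linkage tree cut (min module size 40,
   cut height 0.99, deep split 3), eigengene merging at dissimilarity
   0.3, eigengene–trait correlations with Storey q-values, connectivity
   statistics and GraphML export at |r| ≥ 0.05.
7. **Pathway concentration** — "synap/neuro/neura" keyword flagging and
   four randomization tests of synaptic-pathway concentration in and
   across modules.

## Worked example

Run the whole pipeline on a synthetic dataset emulating the study design
(16 samples: 5/3/4/4 across allopatric/sympatric × female/male, NB counts
at BCV 0.4, planted geography/sex effects and trait-tied modules):

```r
library(neurodiverge)
res <- run_all(seed = 1, n_reps = 2000)
print(res)
#> Pipeline run (seed 1): 6951 genes tested
#> DE counts: geo_all=821, sex_all=149, geo_female=627, geo_male=391, sex_allopatric=58, sex_sympatric=87
#> ratio geo_vs_sex: 6.7712 (p = 0)
#> ratio female_vs_male_geo: 1.6036 (p = 0)
#> ratio sym_vs_allo_sex: 1.5000 (p = 0.0015)
#> modules: 9 ( 10 before merging), beta = 6
```

The three headline patterns of the generative design are visible directly:
far more genes respond to geography than to sex (ratio 6.77), females
carry more geography-DE genes than males (ratio 1.60), and the planted
trait-tied modules surface in the module–trait table:

```r
subset(as.data.frame(res$network$module_trait), significant,
       c(module, trait, r, q))
#>    module     trait      r        q
#> 1   black geography  0.992 4.81e-13
#> 6    blue       sex  0.876 5.19e-05
#> 13    red geography -0.858 8.33e-05
```

`black` and `red` recover the planted positively- and negatively-
geography-associated modules; `blue` the sex-tied one. The candidate
calibration illustrates the null side — with candidates planted at random
with respect to DE status, the observed candidate DE count sits inside
the random-set distribution:

```r
res$calibration
#> Randomization test: observed = 31, null mean = 41.2, p = 0.961 (2000 replicates)
```

Individual stages are exported (`normalize_counts()`,
`run_comparisons()`, `match_candidates()`, `divergence_tests()`,
`ratio_randomization_test()`, `detect_modules()`,
`per_module_concentration_test()`, ...) and a thin command-line wrapper
lives at `inst/cli/neurodiverge.R`
(`Rscript inst/cli/neurodiverge.R simulate --seed 1 --out data/`).

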
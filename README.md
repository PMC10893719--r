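# igansubtypes

Functional molecular subtyping of IgA nephropathy (IgAN) expression
cohorts.

IgAN is the most common primary glomerulonephritis; its routine
classification is histopathological, but transcriptomes of IgAN kidney
biopsies suggest molecularly distinct patient subgroups. This package
implements, as a reusable and fully tested R pipeline, the analysis style
used to define such *functional subtypes* from a bulk gene-by-sample log2
expression matrix:

1. **Preprocessing** — probe-to-gene collapsing (per-gene median,
   ambiguous probes dropped), per-gene location-scale batch adjustment,
   z-score standardization.
2. **Disease signature** — global case-vs-control DEG screen (Welch t,
   Benjamini–Hochberg, adjusted p < 0.05 and |log2FC| > 1.7).
3. **Subtype discovery** — three clusterers on the DEG features
   (Ward hierarchical, PAM k-medoids, Monti consensus clustering with
   resampling), the number of subtypes k chosen by majority among the gap
   statistic, mean silhouette, and the consensus-CDF area elbow, labels
   harmonized by Hungarian alignment, and a sample labeled only when **2
   of the 3** algorithms agree.
4. **Single-sample classifier** — random forest over the DEG features:
   stratified 3:1 split, OOB-driven grid tuning over (mtry, ntree),
   held-out accuracy, one-vs-rest AUCs (macro average), 5-fold CV.
5. **Subtype characterization** — subtype-vs-rest DEGs at per-subtype
   thresholds ((0.01, 2), (0.01, 1.5), (0.01, 1.2)) and intersection-based
   subtype-specific genes; an expression-bias **pathway activity score**
   (mean over a gene set of |case mean − control mean| / control SD) with
   cross-subtype ANOVA; gene–trait Pearson correlation (eGFR-like,
   proteinuria-like); hypergeometric over-representation and pre-ranked
   GSEA; a **weighted co-expression network** (unsigned adjacency
   |cor|^β, scale-free soft threshold, topological overlap, static-cut
   modules ≥ 30 genes, eigengene merging at cor 0.75, module–subtype
   correlation, |MM| > 0.7 & |GS| > 0.2 hub genes); and **immune-cell
   fraction deconvolution** by nonnegative least squares on a signature
   matrix, with Kruskal–Wallis / Wilcoxon group tests and cell–cell
   correlations.

A synthetic-cohort generator (`generate_cohort()` and friends) plants all
of this structure — subtype DE blocks, a shared disease block, batches,
traits, cell mixtures — with known ground truth, so the entire pipeline is
testable end to end without any external download.

## Worked example

The repository is organised as an analysis: numbered drivers under
`analysis/` run the stages in order and write tables under `results/`.

```sh
Rscript analysis/01_simulate.R
Rscript analysis/04_subtypes.R    # needs 02, 03 first
```

Stage 1 prints the cohort layout:

```
cohort: 2000 genes x 102 samples (90 cases / 12 controls)
planted: 40-gene shared block + 3 x 60-gene subtype blocks
subtype sizes: 30 / 30 / 30
```

Stage 3 (the DEG screen) recovers exactly the planted disease signature —
all 220 planted genes, nothing else:

```
global DEGs: 220 (110 up, 110 down)
planted-gene recall: 1.000; false positives: 0
```

Stage 4 (subtype discovery): all three k criteria point at the planted
k = 3, every sample survives the 2-of-3 vote, and the final labels match
the planted subtypes perfectly (adjusted Rand index 1):

```
optimal k: gap=3 silhouette=3 cdf=3 -> majority 3
2-of-3 vote: 90/90 samples assigned (0.0% unassigned)
ARI against planted subtypes: 1.000
```

Stage 5 (classifier) and stage 7 (pathway activity): the tuned forest
separates the planted subtypes cleanly, and each subtype's signal pathway
scores highest in its own subtype:

```
tuned forest: mtry=9 ntree=100, OOB error 0.000
held-out accuracy 1.000; per-class AUC 1/1/1; macro 1.000
5-fold CV accuracy 1.000
signal_subtype1 scores: 6.49 / 3.26 / 3.28 (highest in subtype 1), ANOVA p = 1.43e-34
```

Stage 8 (co-expression) maps each planted block to one module, each
module's top correlate being its own subtype indicator:

```
modules: 3 detected, 3 after merging at eigengene cor 0.75
module turquoise (n=60): strongest with subtype1 (r = -1.00, p = 1.47e-99)
```

Stage 9 (deconvolution) recovers the planted cell fractions to a mean
absolute error of 0.0018 at noise SD 0.1.

The same computations are available programmatically through
`run_pipeline(run_config(...))`, which executes all stages from one config
with per-stage seeds derived from a single global seed and writes a
manifest with parameter values and file hashes.

## Notes

The methods vignette
(`vignettes/functional-subtyping-methods.Rmd`) documents the model behind
each stage, the generator's design and what it does and does not emulate,
the numerical conventions, and the known limitations (exact location-scale
batch adjustment rather than empirical Bayes, static rather than dynamic
tree cut, conservative shared-control ANOVA).
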
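# thyrotype

Transcriptome-based molecular subtyping of thyroid nodules, as a tested,
reusable R pipeline.

Thyroid nodules are common and mostly benign (BTN), but a fraction are
papillary thyroid carcinoma (PTC); histology alone leaves a diagnostic grey
zone, and bulk RNA-seq of nodule and paired adjacent tissue offers a way to
stratify nodules molecularly. `thyrotype` implements the full downstream
analysis a study of this kind needs, from an RPKM-scale gene-by-sample matrix
onward:

- **Subtype discovery** — consensus non-negative matrix factorization:
  genes are filtered (RPKM < 1 in more than half of samples; coefficient of
  variation < 0.8), log2-transformed, and factorized as *V ≈ WH* with
  Lee–Seung multiplicative updates over random restarts; samples are
  hard-assigned by argmax over *H*, co-assignment frequencies form the
  consensus matrix, and stability is summarized by the cophenetic
  correlation. Exemplar genes for factor *i* are ranked by
  *W[g,i] − max<sub>j≠i</sub> W[g,j]*; per-subtype markers are selected from
  the exemplars by a random-forest feature permutation test
  (Benjamini–Hochberg adjusted p < 0.05).
- **Subtype transfer** — Nearest Template Prediction: cosine distance to
  unit-normalized indicator templates over standardized marker expression,
  with permutation p-values from size-matched random gene sets.
- **Per-sample scores** — thyroid differentiation score (sum of
  median-centered log2 expression over a thyroid-function gene set) and
  single-sample rank-weighted enrichment scores for immune, stromal and
  T-cell-inflamed GEP sets; Wilcoxon rank-sum and chi-square helpers.
- **Hub-gene networks** — ARACNe-style mutual-information edges seeded on
  subtype markers, data-processing-inequality pruning, Maximal Clique
  Centrality hub ranking (MCC(v) = Σ<sub>C∋v</sub>(|C|−1)! over maximal
  cliques), pre-ranked GSEA, and a hub→pathway bipartite graph weighted by
  normalized enrichment scores.
- **Trajectory** — samples embedded by PCA, summarized by a k-means centroid
  minimum spanning tree rooted at benign-adjacent tissue; pseudotime is
  geodesic distance along the tree, the first degree-≥3 node defines the
  bifurcation, and branch-dependent expression is tested by a Gaussian
  spline likelihood ratio (BEAM-style), with significant genes clustered
  into the three canonical fate patterns.
- **Variant post-filters** — deterministic keep/reject rules for candidate
  fusions (≥5 split reads, ≥2 spanning pairs, expressed partners, no
  same-chromosome pair closer than 10 kb) and somatic mutations (≥10×
  coverage in tumor and normal, tumor VAF ≥ 5%, normal VAF < 1%, ≥5 tumor
  alt reads, not in dbSNP), with per-row rejection reasons.
- **Diagnostic signature** — stratified 80/20 split, L2-regularized logistic
  regression with recursive feature elimination scored by stratified
  4/6/8/10-fold cross-validated AUC, and a five-classifier
  (LR/SVM/NB/RF/KNN) ROC comparison on the held-out split.

Because cohorts of this kind are rarely public, the package ships a
first-class synthetic-cohort generator (`simulate_cohort()`,
`simulate_trajectory_cohort()`, `simulate_variant_tables()`) that plants six
expression programs, an immune gradient, paired adjacent tissue, a branching
benign→malignant trajectory, and threshold-bracketing variant calls — so
every stage of the pipeline is verifiable against known ground truth.

## Worked example

```r
library(thyrotype)

# simulate a cohort with 6 planted expression programs (4 malignant, 2 benign)
co <- simulate_cohort(simulation_spec(seed = 7))
nodules <- co$samples$sample_id[co$samples$tissue == "nodule"]

# discover subtypes: gene filter -> consensus NMF (k = 6) -> markers
model <- discover_subtypes(co$expr[, nodules],
                           default_run_config(seed = 7, nmf_restarts = 30))
table(model$assignment)
#> F1 F2 F3 F4 F5 F6
#> 20 20 20 20 20 20
round(model$nmf$cophenetic, 4)
#> [1] 1
lengths(model$marker_sets)
#> F1 F2 F3 F4 F5 F6
#> 12 16 20 16 14 21

truth <- setNames(co$samples$true_subtype[match(nodules, co$samples$sample_id)],
                  nodules)
adjusted_rand(model$assignment, truth)
#> [1] 1
```

The 120 nodules fall into six clusters of 20 that coincide exactly with the
planted subtypes (adjusted Rand index 1), the consensus matrix is perfectly
stable (cophenetic correlation 1), and each subtype gets a 12–21 gene marker
panel. Transferring those markers to an independently simulated cohort:

```r
heldout <- simulate_cohort(simulation_spec(seed = 11))
nod2 <- heldout$samples$sample_id[heldout$samples$tissue == "nodule"]
ntp <- ntp_classify(heldout$expr[, nod2], model$marker_sets,
                    n_permutations = 1000, seed = 7)
head(ntp[, c("sample_id", "subtype", "distance", "p", "q")], 3)
#>   sample_id subtype  distance           p           q
#> 1     S001T      F1 0.2573536 0.000999001 0.001261896
#> 2     S002T      F1 0.3032868 0.001998002 0.002305387
#> 3     S003T      F1 0.3578031 0.014985015 0.014985015
```

Every held-out sample is assigned at a permutation p below 0.05, and the
immune enrichment score tracks the planted infiltration gradient (Spearman
0.956 on this cohort):

```r
scores <- ssgsea_score(co$expr, co$immune_genes, tau = 0.25)
```

A thin command-line interface over the same functions lives at
`inst/scripts/thyrotype.R` (subcommands `simulate`, `subtype`,
`classify-ntp`, `score`, `filter-variants`, `trajectory`, `diagnose`); the
default immune/stromal/GEP/TDS gene sets ship as an editable GMT under
`inst/extdata/`.

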
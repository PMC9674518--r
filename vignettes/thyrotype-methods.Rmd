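---
title: "thyrotype: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{thyrotype: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the statistics it implements:
the models, their assumptions, the tunable parameters, the numerical
choices, and the places where the design was genuinely open and a decision
had to be made. Nothing stated here as an empirical result goes beyond what
the test suite and `scripts/acceptance.R` themselves compute.

## Scientific setting

The pipeline targets bulk RNA-seq cohorts of thyroid nodules: papillary
thyroid carcinoma (PTC) and benign thyroid nodules (BTN), each with a paired
adjacent-tissue sample. Expression arrives as a non-negative gene-by-sample
matrix on the RPKM scale; every downstream stage works on
`log2(RPKM + pseudocount)` (pseudocount 1 by default, so zero maps to zero
and the transform is zero-safe wherever "log2 RPKM" is required).

## Subtype discovery

**Gene filter.** Two rules, applied on the linear scale: drop genes with
RPKM < 1 in strictly more than half of the samples, then drop genes with
coefficient of variation sd/mean < 0.8. A zero-mean gene has an undefined CV
and is removed. The filter concentrates the matrix on genes that are both
expressed and informative, which is what makes the factorization
identifiable.

**Consensus NMF.** The log2 matrix is factorized as $V \approx WH$,
$W, H \ge 0$, by Lee–Seung multiplicative updates minimizing the Frobenius
error — the standard objective for log-expression; a Kullback–Leibler
objective would suit raw counts, which this pipeline never sees. Updates
provably never increase the objective, and the test suite asserts the
monotone trace directly. Each restart initializes $W, H$ uniformly at
random, scaled by $\sqrt{\bar V / k}$; convergence is declared when the
relative objective change falls below `1e-6` (or at 2000 iterations, with a
warning). Per restart, samples are hard-assigned to $\arg\max_f H[f, s]$ —
the standard NMF hard-assignment convention — and the consensus matrix is
the across-restart co-assignment frequency. The restart with the lowest
objective supplies the reported $W, H$. Stability is summarized by the
cophenetic correlation between $1 - \text{consensus}$ and its
average-linkage dendrogram; cutting that dendrogram at $k$ gives a second,
consensus-based clustering that is reported alongside the argmax
assignment. Defaults: $k = 6$ (the cohort design this pipeline mirrors fixes
six subtypes; a BRAF-enriched sub-classification is the same routine re-run
on one subtype's samples with $k = 3$), 50 restarts (30 in the acceptance
runs, which is already far past the point where the consensus stabilizes on
the reference simulation).

Whether adjacent-tissue samples belong in the factorization is genuinely
ambiguous in this study design; the pipeline defaults to nodules only —
adjacent tissue sits near a common baseline and would blur the factors — and
leaves inclusion to the caller, who controls the input matrix.

**Exemplars and markers.** Exemplar genes for factor $i$ are ranked by the
margin $W[g,i] - \max_{j \ne i} W[g,j]$, ties broken by gene symbol so runs
are reproducible; the top 50 per factor (configurable) form the feature pool
for marker selection. Markers are selected by a one-vs-rest random forest
(500 trees) scored by permutation importance — the mean decrease in
out-of-bag accuracy when a feature's values are permuted — with a null
distribution built by refitting under label permutation (default 100
rounds), add-one p-values, and Benjamini–Hochberg adjustment across
features at 0.05. Wherever an adjusted p-value is needed in this package the
procedure is Benjamini–Hochberg. Permutation counts trade runtime for
p-value resolution: with $B$ rounds the smallest attainable p is
$1/(B+1)$, so with the 50-gene pool at least ~50 rounds are needed before
any feature can clear BH at 0.05.

**Nearest Template Prediction.** The new cohort is log2-transformed and
standardized per gene using its *own* means and sds — no training-cohort
statistics cross the platform boundary, which is the point of NTP. The
template for subtype $s$ is the indicator vector (+1 on $s$'s markers, 0
elsewhere on the marker union), unit-normalized; distance is
$1 - \cos$. Significance per sample: the add-one fraction of random gene
sets (size-matched, drawn from all measured genes, distances computed over
the random set's own support) at least as close as the observed template;
BH across samples. Exact ties between templates are broken by subtype name
order and flagged.

## Per-sample scores

**Thyroid differentiation score.** For each gene of the thyroid-function
set, log2 expression is centered at its across-sample median; TDS is the
per-sample sum of centered values. The score is invariant to per-gene
constant shifts (the median absorbs them) and is deterministic.

**Single-sample enrichment.** GSVA-style kernel machinery is deliberately
replaced by the single-sample rank-weighted Kolmogorov–Smirnov statistic:
per sample, genes are ranked by expression, and the score accumulates the
difference between the rank$^\tau$-weighted CDF of in-set genes and the
uniform CDF of out-of-set genes, normalized by the gene count. The scores
are used strictly ordinally (higher immune score = more immune activity),
and the rank statistic preserves that ordering with far fewer
under-specified internals. At $\tau = 0$ the score is a pure rank statistic:
invariant under any strictly monotone transform of a sample's values and
exactly antisymmetric under rank reversal (both asserted in tests). The
default $\tau = 0.25$ emphasizes highly expressed set members at the cost
of a small positive offset for random sets; because only orderings are
consumed, the offset is harmless.

**Stromal score.** The purity/ploidy route to a stromal estimate requires
copy-number input that is out of scope here, so the stromal score is a
stromal gene-set enrichment score (ESTIMATE-style) over an editable set —
a deliberate, documented substitution. The shipped
`inst/extdata/default_gene_sets.gmt` carries the canonical 16
thyroid-function genes, the published 18-gene T-cell-inflamed GEP, and
clearly-labelled editable defaults for the 66-gene immune and the stromal
sets, whose exact published compositions live in cited literature rather
than any single methods section; users with the curated lists should
replace them.

**Group comparisons.** Wilcoxon rank-sum (exact enumeration when both
groups have ≤ 10 untied observations, otherwise normal approximation with
tie correction; two-sided) and Pearson chi-square without continuity
correction, df $=(r-1)(c-1)$.

## Hub-gene networks

Mutual information uses a plug-in estimator on equal-frequency bins
(default $\lceil\sqrt n\rceil$ capped at 10), in nats. The binned estimator
was chosen over adaptive partitioning because it verifies against closed
forms — identical vectors give exactly $\log B$, independent pairs give
$\approx (B-1)^2/2n$ — and the network consumes MI only ordinally. The edge
threshold defaults to a permutation null: the Bonferroni-adjusted
$(1-\alpha)$ quantile of MI between permuted vectors, pooled over 100
draws; a fixed threshold can be supplied instead. DPI pruning examines every
triangle of the thresholded graph in deterministic sorted order against the
pre-pruning MI values and removes the weakest edge when its MI falls below
$(1-\text{tolerance})$ times the smaller of the other two; tolerance 0 is
the classic rule, tolerance 1 disables pruning. Hubs are the subtype
markers; hub ranking uses Maximal Clique Centrality,
$\mathrm{MCC}(v)=\sum_{C \ni v}(|C|-1)!$ over exactly-enumerated maximal
cliques (Bron–Kerbosch with pivoting). The hub→pathway graph ranks each
top-MCC hub's first-layer neighbors by the focal subtype's log2
fold-change and runs pre-ranked GSEA (classic weighted KS running sum,
gene-label permutations — the only scheme available in pre-rank mode — NES
normalized by same-sign null magnitude, BH within each sign family); the
number of hubs reported per subtype defaults to 10 and is configurable.

## Trajectory

Reversed graph embedding is replaced by a transparent backbone with the
same testable claims (ordering, a single bifurcation, branch-dependent
expression): PCA to 2 components, k-means to $\lceil n/10\rceil$ centroids,
a Euclidean minimum spanning tree over centroids, and projection of each
sample onto its nearest tree edge; projections may extend past leaf
centroids so terminal samples keep a strict ordering. Pseudotime is
geodesic distance from the root — the centroid nearest the mean of the
benign-adjacent samples, encoding the biological assumption that adjacent
tissue is the starting state. The first tree node of degree ≥ 3 past the
root is the bifurcation, with one guard: a valid bifurcation must split off
at least two non-trivial subtrees (two or more centroids each), because a
single-leaf noise twig near the root would otherwise hijack branch
detection while the real fork sits further along the backbone. Root-side
samples are `pre`, the two largest subtrees beyond the fork are the fates,
and extra subtrees are merged into the nearest fate with a warning. A
config hook accepts alternative embeddings.

Branch-dependent expression uses a Gaussian likelihood ratio on log2
expression — input is RPKM, so a negative-binomial count model is not
applicable: null, a shared natural cubic spline in pseudotime (df 3);
alternative, added branch-specific spline coefficients for the fate-2
samples (df + 1 added parameters); $n\log(\mathrm{RSS}_0/\mathrm{RSS}_1)$
against $\chi^2$. The test suite checks calibration directly: on 500
pure-noise genes the rejection rate at p < 0.05 must stay within
0.05 ± 0.02 and the p-values must pass a KS uniformity check. Significant
genes (BH q < 0.05) are assigned to the three canonical patterns — I
declining on both fates, II activating on fate 1, III on fate 2 — by
comparing binned mean curves between the pre-branch start and each fate's
end with a 0.5 log2-unit margin; genes clearing no margin are flagged
ambiguous and resolved by a seeded k-means over standardized curves whose
centroids are labelled by the margin-0 rule. Note that fate numbering is
arbitrary (which subtree is "fate 1" depends on subtree sizes), so any
comparison against external fate labels must first map fates by majority
correspondence; the acceptance script does exactly that.

## Variant post-filters

Boundary semantics are taken literally and documented per rule: "at least"
is ≥, "less than" is strict. Fusions: ≥ 5 split reads, ≥ 2 spanning pairs,
both partners present with maximum RPKM across samples ≥ 1 (the only
reading under which "below 1 across all samples" is a removal criterion),
and no same-chromosome pair at distance < 10 kb (read-through). Mutations:
tumor *and* normal depth ≥ 10× (the coverage clause is read as applying to
both samples), tumor VAF ≥ 5% (inclusive), normal VAF < 1% (strict), ≥ 5
tumor alt reads, and absence from dbSNP, consumed as a boolean column — no
database lookup is performed, since version-pinned dbSNP membership is data
plumbing rather than computation. The first failed rule, in that order,
becomes the row's rejection reason; filters are row-local and idempotent.
The synthetic variant tables place rows at ±1 around every threshold so the
boundary semantics are what the concordance checks actually exercise.

## Diagnostic signature

The split is stratified (80/20 by default, ≥ 1 test sample per class) so
both splits preserve the cohort's class ratio. Features are
log2-transformed and standardized by training statistics only; a leakage
canary test corrupts the held-out samples and asserts bit-identical
training output. RFE starts from the candidate pool, fits an L2-regularized
logistic regression (ridge, fixed small λ — regularization only to keep
separable fits finite; AUC is invariant to the score scale), drops the
smallest-|coefficient| feature (10% at a time above 100 features), and
records per-fold stratified CV AUC over the 4/6/8/10-fold schemes at every
subset size. The panel is the smallest size within one standard error of
the best mean AUC (a "best mean" rule is available); the final model is
refit on the full training set.

One behavior of this rule deserves a caveat: when the classes are strongly
separable, CV AUC saturates at exactly 1.0 across a long run of subset
sizes, every size in the run qualifies, and the rule returns the smallest —
often below the number of truly informative genes, since AUC cannot
distinguish among panels that all separate perfectly. That is a property of
any subset score built on AUC, not of the implementation; on data where no
small panel is perfect the one-SE rule behaves conventionally. ROC curves
are built by threshold sweep with ties handled so the trapezoidal AUC
equals the Mann–Whitney identity exactly (asserted in tests). The
five-classifier comparison (ridge LR, RBF SVM decision values, naive
Bayes, random forest, 5-NN) trains each on the standardized panel and
reports training-split CV AUC and held-out ROC/AUC.

Differential expression between histology classes uses the Wilcoxon
rank-sum test for consistency with the package's other group comparisons (a
t-test is available behind a flag), fold-changes as
$\log_2((\bar x_{PTC}+1)/(\bar x_{BTN}+1))$ on the linear scale, and a
"changed" flag implementing the disjunctive volcano cutoff `p < 0.05 OR
|log2FC| > 1` literally; because a disjunction is unusual for a volcano
rule, a conjunctive mode is provided behind a flag, with the disjunction as
the default.

## The synthetic generator: what it emulates, and what it does not

`simulate_cohort()` draws per-gene log2 baselines from
$\mathcal N(3, 1)$, adds a subtype's marker shift (default 2.0 log2 units,
30 disjoint markers per subtype), an immune shift (amplitude 2.0 times a
latent per-sample infiltration level; benign and adjacent samples draw low
levels, malignant samples the full range, so benign programs sit near the
adjacent baseline), observation noise $\mathcal N(0, 0.5)$, and exports
$2^x - 1$ clipped at zero. Defaults — 6 subtypes × 20 nodules with paired
adjacent samples, 1000 genes — are the reference study conditions used by
the acceptance checks. `simulate_trajectory_cohort()` plants latent times
$t \sim U(0,1)$, a bifurcation at $t = 0.5$, and the three fate programs on
50 genes each with noise 0.3. A log-normal expression model was chosen
because every consumer works on log2 RPKM; read counts, library size, and
quantification noise are upstream of this package and are not modelled.

The generator is deliberately idealized: marker blocks are disjoint,
noise is homoskedastic and Gaussian in log space, there is no batch
structure, no gene–gene correlation beyond the planted programs, and no
label noise. Passing the recovery checks therefore demonstrates
correctness of the machinery — that each method recovers structure it is
designed to recover — not clinical performance on real nodules, where
effect sizes are smaller and structure messier.

## Problem sizes and determinism

The test suite runs the reference conditions end to end: the full
120-nodule consensus NMF with 30 restarts, marker selection at 100
permutation rounds, NTP transfer at 1000 permutations, 200-sample
trajectories with 500-gene null calibrations, 200 random graphs against the
exhaustive MCC oracle, and a 240-sample diagnostic simulation — sizes at
which every stochastic bound in the checks is stable across seeds while the
whole suite completes in a few minutes. Every stochastic operation draws
from a child generator derived from `(seed, operation name)`
(`derive_seed()`), so stages are independently reproducible and identical
configurations yield byte-identical outputs; the CLI determinism test
asserts exactly that on the written files.

## Known limitations

- Consensus NMF assignment can be unstable when $k$ is misspecified;
  the cophenetic correlation and consensus matrix are the diagnostics to
  inspect, and model selection over $k$ is intentionally out of scope.
- The MI estimator's plug-in bias ($\approx (B-1)^2/2n$ nats) is fine for
  ranking edges but not for absolute MI values.
- The trajectory backbone assumes one bifurcation; deeper branching trees
  are reduced to two fates with a warning.
- BEAM's Gaussian assumption is adequate for log2 RPKM but not for raw
  counts.
- The one-SE RFE rule under AUC saturation returns minimal panels, as
  discussed above.
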
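---
title: "Pathway activation profiling of melanoma progression: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pathway activation profiling: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Scope

`pasflow` analyses bulk expression matrices of melanocytic tissue —
normal skin, nevus, primary melanoma, metastatic melanoma — at the level
of signaling and metabolic pathway activation. This vignette is the
package's own account of the models it implements, the tunable parameters
and their defaults, the synthetic-data generator that stands in for the
original microarray cohorts, and the numerical decisions taken where the
design was genuinely open.

# The activation score

## Case-to-normal ratio and the tolerance gate

Every score is relative to a set of *norm* samples, by default a
designated `Reference` group emulating a universal RNA reference;
`pasMatrix(refGroup = "Skin")` switches the norms to normal skin, the
alternative baseline used in melanoma work. For gene $n$ with linear-scale
expression $x_n$ and reference log2 mean $\mu_n$ and SD $\sigma_n$:

$$\mathrm{CNR}_n = x_n / 2^{\mu_n}$$

is the ratio to the geometric-mean norm, and the beyond-tolerance-interval
flag is

$$\mathrm{BTIF}_n = \mathbf{1}\left[\, |\log_2 x_n - \mu_n| > z_{\alpha}\,\sigma_n
  \;\wedge\; \mathrm{CNR}_n \ge f \lor \mathrm{CNR}_n \le 1/f \,\right]$$

with $z_{0.05} = 1.96$ (two-sided normal-theory interval) and fold
threshold $f = 1.5$. Both criteria must hold: the flag gates out genes
that are statistical outliers without a meaningful fold change as well as
large-looking ratios inside a noisy gene's normal range. The normal-theory
interval is the simplest construction consistent with a p < 0.05 outlier
notion; $z$ and $f$ are exposed (`alpha`, `foldThreshold`) rather than
hard-coded. The flag's two criteria could in principle be combined with
OR; the conjunction is the conservative reading and the one implemented.

## Pathway activation strength

$$\mathrm{PAS}_p = \sum_{n \in p} \mathrm{ARR}_n \cdot \mathrm{BTIF}_n
  \cdot \lg \mathrm{CNR}_n$$

ARR (activator/repressor role) is a discrete per-gene weight in
$\{-1, -0.5, 0, 0.5, 1\}$ carried by the pathway database: activators
contribute their gated log-ratio with positive sign, repressors with
negative sign, genes of unknown role not at all. Positive PAS means
abnormal activation relative to the norms, negative PAS repression. The
score is linear in the member genes, hence exactly antisymmetric under ARR
negation and additive over disjoint pathway unions — both properties are
kept under test. Genes absent from the expression matrix or the norm
reference are skipped and surfaced in a coverage diagnostic, never
imputed; a pathway with no expressed members is dropped with a warning
while the run continues.

# Preparing multi-platform studies

Microarray cohorts arrive on different platforms with different location
and scale. The preparation is deliberately simple and closed-form:

1. quantile normalization within each platform (every sample's sorted
   vector is mapped onto the cross-sample mean of sorted vectors, ties
   averaged) — rank-preserving and idempotent;
2. merging over the gene *intersection*, so the scoring engine never sees
   missing values;
3. per-gene harmonization: within each platform the log2 values are
   standardized and rescaled to the pooled per-gene mean and pooled
   within-platform SD.

Step 3 removes exactly the affine per-gene batch effects that the
generator (and typical platform pairs) exhibit; after it, per-gene
platform means agree to numerical precision. Full block co-clustering
cross-platform normalization is intentionally out of scope: it brings
tuning parameters and iteration where a testable closed-form transform
suffices for location/scale artefacts. When platforms differ in class
composition the transform can absorb genuine biology into the batch
correction — a known limitation shared by all location/scale methods.

# Classification of the four tissue classes

Features are PAS values per pathway. Two pre-filters mirror standard
practice: near-zero-variance removal (frequency ratio 19, unique fraction
10% — the conventional defaults) and greedy collinearity removal at
$|r| > 0.85$, which drops from the worst pair the member with the larger
mean absolute correlation (deterministic; the retained set is guaranteed
to contain no pair above the cutoff).

The model panel is `svm_linear`, `svm_radial`, `random_forest`,
`regularized_logistic` (multinomial elastic net at its cross-validated
lambda) and `naive_bayes`; PLS-DA is available when mixOmics is
installed. Evaluation is stratified, repeated 10-fold cross-validation
(3 repeats by default); out-of-fold predictions are pooled per repeat and
averaged across repeats, so confusion-matrix rows reproduce the class
sample counts. Metrics are one-vs-rest sensitivity, specificity and their
mean (balanced accuracy); an empty class yields an explicit `NA`, never a
silent zero. Class imbalance is handled by stratification only — no
resampling. SVMs operate on raw PAS units (`scale = FALSE`): the features
share one natural unit, and per-feature standardization was observed
during design to inflate noise pathways relative to the weakly displaced
nevus class, costing the linear kernel most of its nevus sensitivity.

# Consensus selection and direction signatures

The selection is two-step. First, each fitted model ranks pathways by a
model-appropriate importance (linear SVM: summed absolute one-vs-one
coefficients; elastic net: summed absolute class coefficients; random
forest: permutation importance; radial SVM: training-set permutation
importance; naive Bayes: one-vs-rest ROC-AUC filter score; PLS: VIP), all
rescaled to [0, 100]. Signaling and metabolic pathways are ranked and
selected separately. The top 30 per model are intersected strictly across
models; because a strict intersection can be empty on noisy data, an
"appears in ≥ m of M models" relaxation is available (`minModels`).
Second, a Kruskal–Wallis filter retains a candidate only if it is
differentially regulated (p ≤ 0.05) along at least one of the two
progression ladders, Skin → Nevus → Primary and Skin → Primary →
Metastatic. The omnibus per-ladder test is the default reading of that
filter; a pairwise reading is available behind `mode = "pairwise"` since
the verbal description admits both.

Direction signatures are tabulated per pathway across the five contrasts
(Nevus vs Skin, Primary vs Skin, Metastatic vs Skin, Metastatic vs
Primary, Primary vs Nevus): the cell direction is the sign of the
difference of group medians — UP/DOWN, with an exact zero flagged `NA`
rather than silently assigned — and significance is a Welch t-test with
Benjamini–Hochberg adjustment across all cells. Welch and BH are choices;
the method is only committed to "t-test with multiple-testing
correction", and both are the standard defaults for unequal-variance
groups and table-wide control.

# Co-activation modules

Functional coordination is the Pearson correlation between pathway PAS
profiles across samples; structural similarity is the Jaccard index of
their gene sets. Modules are detected by average-linkage hierarchical
clustering on $1 - |r|$ with a fixed-height cut and a minimum module size
of 5; smaller clusters dissolve to unassigned. Unsigned correlation is
used, so congruent repression counts as coordination. The full weighted
co-expression machinery (soft-threshold powers, topological overlap,
dynamic tree cutting) is deliberately not reproduced: its parameters are
not derivable from the published description, whereas the fixed-cut
approximation is fully specified and testable. Module members are then
filtered by the published rule — keep a member if its mean |r| to the rest
exceeds 0.7 or it has at least one correlation above 0.85 with another
member (self-correlation excluded); the rule is evaluated once against
the full membership, so results are order-invariant. Sample-level
structure uses Ward (D2) linkage on Euclidean distances between PAS
profiles; the cut height is a required argument because it depends on the
data's scale (a fixed published height is meaningful only for the
original cohort). `coordinationVsStructure()` pairs the two matrices for a
module and reports mean |r| against mean off-diagonal Jaccard, making
"coordinated but structurally unrelated" modules visible.

# The synthetic-data generator

`simConfig()`/`simulateStudy()` emulate the study design: four tissue
classes plus a reference-norm group, two platform batches with an affine
log-scale distortion (shift 0.5, scale 1.15), log-normal intensities
(baseline log2 means uniform on 6–12, gene noise SD 0.7), and planted
per-pathway activation shifts. Class structure is generated from
per-class pathway-level log2 shifts (deltas) with Skin fixed at zero —
never from per-contrast hacks — so all five contrast directions are
internally consistent by construction. `plantTableSignatures()` converts a
transcribed UP/DOWN table into such deltas by least squares and verifies
sign consistency, erroring on any genuinely contradictory row.

Defaults, chosen once at design time as a desk-scale analogue of a
multi-hundred-sample microarray cohort:

* 2,000 genes, 100 + 100 pathways of 10 genes (disjoint membership when
  the pool allows), ARR drawn activator-heavy
  (P(1) = 0.5, P(±0.5) = 0.15/0.1, P(0) = 0.1, P(−1) = 0.15);
* 30/20/30/30 case samples (Skin/Nevus/Primary/Metastatic) + 10 reference
  samples, mirroring the real cohort's imbalance at reduced scale;
* planted effect size 2 log2 units — a strong, clearly super-threshold
  effect relative to the 1.5-fold gate;
* per-pathway activation jitter SD 0.4 (shared by a pathway's members),
  which both emulates pathway-level co-regulation noise and keeps
  same-signature pathways from being exact duplicates;
* nevi apply their deltas with a per-sample attenuation drawn from
  U(0.6, 1.2) plus extra pathway jitter (SD 0.5): nevi are a variable,
  partially penetrant intermediate, which reproduces the observation that
  they are the hardest class for every classifier. The lower bound keeps
  attenuated nevi above the tolerance gate often enough to remain
  learnable; below it they collapse onto skin and the weakest planted
  nevus contrasts lose their median direction;
* an optional co-activation cluster: 8 non-planted pathways whose member
  genes share a per-sample latent factor (SD 2) — strongly correlated PAS
  profiles with zero gene overlap, the "coordinated but disjoint"
  phenomenon.

What the generator does **not** emulate: probe-level artefacts,
background correction, probe-to-gene summarization, gene–gene correlation
outside pathway membership, non-normal noise, dataset-specific (as
opposed to platform-specific) batch structure, and the actual content of
any deposited cohort. Passing tests therefore demonstrate correctness of
the machinery and recoverability of planted structure under realistic
noise — not that real cohorts would yield any particular accuracy.

# Numerical choices and degenerate inputs

* Tolerance interval uses `qnorm(1 - alpha/2)`; with the default alpha
  this is the conventional 1.96.
* Quantile normalization averages target values over tied ranks.
* A zero-dispersion reference gene has a degenerate interval; any
  deviation is then outside it, and the fold criterion alone gates.
* Collinearity ties (equal mean absolute correlation) drop the
  lexicographically later feature, making the filter order-deterministic.
* Constant features in a direction contrast: zero median change with zero
  variance in both groups is reported with p = 1 (p = 0 if the medians
  differ); `t.test` degeneracies never crash the table.
* Cluster ids are canonicalized by decreasing size (ties by first
  member), so relabeling never changes membership sets.
* All stochastic stages (fold assignment, forests, elastic-net CV,
  permutation importance, the generator) derive their seeds from one user
  seed; pipeline reruns are byte-identical, and the run manifest records
  md5 digests to prove it.

# Problem sizes in the test suite

The suite and the acceptance script run the generator at its defaults
(2,000 genes, 200 pathways, 120 samples) for the classifier and
consensus checks, a 90-pathway / 130-sample configuration for
direction-signature recovery, and a 600-gene / 30-pathway configuration
for pipeline determinism — sizes chosen so a full run stays comfortable
on a laptop while keeping every class large enough for stratified
10-fold cross-validation.

# Known limitations

* The PAS formula treats pathway membership as flat; no topology beyond
  the activator/repressor sign is used.
* The harmonization assumes platform effects are affine per gene on the
  log scale and that platforms share class composition.
* Strict top-30 intersection across five models is aggressive; on weak
  data it can return an empty consensus (reported explicitly, with the
  `minModels` relaxation as the escape hatch).
* The module-detection cut height is a free parameter; there is no
  automatic selection.
* Balanced accuracy is reported per class one-vs-rest; no confidence
  intervals are attached to the cross-validated estimates.
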
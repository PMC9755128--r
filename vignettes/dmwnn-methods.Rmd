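---
title: "Double multi-weighted nearest-neighbor completion for lncRNA–disease association prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Double multi-weighted nearest-neighbor completion for lncRNA–disease association prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmwnn)
```

## The problem

Experimentally confirmed associations between long noncoding RNAs
(lncRNAs) and diseases are scarce: a curated lncRNA–disease matrix
typically has well under 0.1% of its cells set to 1, while the biology
suggests that many of the remaining zeros are simply untested. The task is
to rank those zero cells so that wet-lab validation can start from the
most promising pairs. `dmwnn` does this by memory-based matrix completion:
the score of an unknown pair is a weighted vote of the most similar
lncRNAs (and, symmetrically, the most similar diseases) that *do* carry a
confirmed association. miRNAs enter as a bridging feature layer — lncRNAs
interact with miRNAs, miRNAs associate with diseases — which densifies the
otherwise nearly empty feature space.

## Interaction profiles and the fused similarity

Let $Y \in \{0,1\}^{n_l \times n_d}$ be the lncRNA–disease target matrix,
$ML$ the lncRNA–miRNA and $MD$ the miRNA–disease adjacency. Each lncRNA is
described by the concatenated binary profile $LMD_i = [ML_i \,|\, Y_i]$
and each disease by $DML_j = [MD^{\top}_j \,|\, Y^{\top}_j]$
(`build_profiles()`).

Similarity between two profiles $x, y \in \{0,1\}^n$ is

$$\mathrm{sim}(x, y) \;=\; \frac{\lambda\,\lVert x \circ y \rVert_2
  \;+\; (1-\lambda)\,\lVert x - y \rVert_2}{\sqrt{n}}
  \;=\; \frac{\lambda\sqrt{c} + (1-\lambda)\sqrt{d}}{\sqrt{n}},$$

where $\circ$ is the element-wise product, $c$ counts positions where both
profiles have a confirmed association and $d$ counts positions where
exactly one does. The unusual second term is deliberate: under extreme
sparsity, a position where one entity has a confirmed association and the
other does not is weak evidence of a *potential* shared association, not
of dissimilarity — conventional overlap metrics discard exactly this
signal. A consequence worth stating plainly is that for small $\lambda$
the ranking of neighbors is dominated by profile size, so well-annotated
(hub) entities are preferentially selected as neighbors. On hub-dominated
curated databases this is a feature; on data without degree structure it
would be a liability (see the generator section). Both norms are at most
$\sqrt{n}$, so scores lie in $[0,1]$. The default $\lambda = 0.1$ is the
value at which fivefold cross-validation on the curated benchmark this
model was developed against peaks. Cosine, Pearson and Jaccard
similarities are available as baselines (`baseline_similarity_matrix()`);
pairs involving an all-zero profile (or zero-variance profile, for
Pearson) score 0 rather than NaN.

The diagonal is computed by the same formula
($\lambda\sqrt{c}/\sqrt{n}$, not forced to 1); self-comparison is instead
handled at neighbor selection.

## The completion model

For each row $i$ of the lncRNA similarity matrix, the neighbor index
stores the $k$ most similar *other* rows in descending similarity
(`build_neighbor_index()`), ties broken by ascending index so results are
platform-independent. The $t$-th neighbor ($t = 0, \dots, k-1$) carries
the linearly decreasing weight

$$\omega_t = \frac{2(k - t)}{k(k+1)}, \qquad \sum_t \omega_t = 1.$$

One layer of completion fills every zero cell twice and fuses the results:

* row pass: $\hat{Y}_{1,ij} = \sum_t Y_{K^l_{i,t},\,j}\; S^l_{i,K^l_{i,t}}\;\omega_t$ for cells with $Y_{ij}=0$, known cells kept;
* column pass: the same on $Y^\top$ with the disease-side index and similarity;
* fusion: $\hat{Y}_0 = \eta_1 \hat{Y}_1 + \eta_2 \hat{Y}_2$ with $\eta_1 = \eta_2 = 0.5$.

Because the weights sum to one and similarities lie in $[0,1]$, every
filled value is a sub-convex combination of values in $[0,1]$: scores
remain bounded and known positives remain exactly 1 at every depth.

A single pass cannot reach a cell whose entire row and column
neighborhoods are zero, so layers are stacked: layer $\ell$ repeats the
two passes and the fusion on the layer-$\ell-1$ output, filling only the
cells that are still zero. Stacking stops automatically when no zeros
remain, and is capped at five layers — each layer re-predicts from
predictions, so depth drives scores away from the data; two layers are
the default and empirically the best on the curated benchmark.

Two readings of the update rule are printed in the literature and both
are available here:

* **keep-current** (default): at layers beyond the first, nonzero cells
  keep their real-valued scores. This preserves the ranking that
  candidate screening depends on.
* **literal ones** (`literal_ones = TRUE`): nonzero cells are overwritten
  with the constant 1 at every layer. On the binary first layer the two
  readings coincide; beyond it the literal reading binarizes all
  intermediate scores, and is retained only for auditability.

Similarly, the neighbor index excludes the self-row by default: under the
fill rule the self-term contributes nothing at zero cells yet would
consume the largest weight $\omega_0$; `include_self = TRUE` restores the
literal top-$k$.

`dmwnn_config()` bundles these choices. Defaults (`k = 217`,
`lambda = 0.1`, `layers = 2`, `eta1 = eta2 = 0.5`) are the configuration
found best by fivefold cross-validation on the curated benchmark of 1089
lncRNAs, 246 miRNAs and 373 diseases; on other data, `k` in particular
should be re-tuned (it is a large fraction of the entity count there, and
the CLI's `benchmark-similarity` command sweeps it).

## Evaluation protocol

`kfold_cv()` partitions the known positives into near-equal folds. For
each fold the held-out positives are set to 0, the profiles and **both
similarity matrices are recomputed from the masked target** — scoring a
held-out pair with a similarity that already encodes it would be
leakage — and the completion runs on the masked matrix. Scores are then
collected for the held-out positives (labels 1) and for every cell that
is zero in the *full* matrix (labels 0); training positives are excluded.
Treating all unverified pairs as negatives is the dominant convention for
this task and is the reason precision is intrinsically tiny (hundreds of
positives against hundreds of thousands of candidate cells): a method can
rank well and still show sub-percent precision.

Metrics: rank-based (Mann–Whitney) AUC with midrank ties, step-interpolated
AUPR, and confusion-matrix metrics (accuracy, sensitivity, specificity,
precision, MCC) at a threshold chosen per fold by Youden's $J$ unless a
fixed cutoff is supplied — the benchmark literature reports such tables
without stating a threshold, so the package makes its rule explicit.
Fold summaries are mean ± sample standard deviation. `loocv()` masks one
positive at a time; by default it averages per-iteration AUCs
(`aggregate = "pooled"` instead pools all scored cells into one ranking
and adds an AUPR). `rank_candidates()` produces the per-disease candidate
list that a screening experiment would consume, excluding already-known
pairs.

## The synthetic generator

`generate_networks()` draws, for every lncRNA, miRNA and disease, a
non-negative latent factor vector (dimension 4 by default): a
Bernoulli(0.5) support mask times Gamma(shape 2) loadings, scaled by a
lognormal per-entity activity (`activity_sdlog = 1.25`). Edge
probabilities are proportional to factor inner products, calibrated by
root-finding so the expected density hits the target exactly even where
probabilities clip at 1, then sampled Bernoulli; optional noise flips
each cell independently. The lncRNA–disease probability matrix is
returned as ground truth.

What this emulates: three *coupled* sparse binary networks — the same
factors generate all three matrices, so miRNA profiles genuinely carry
lncRNA–disease signal, which is the method's premise — at densities
(2% / 5% / 5% at the default 200 × 60 × 80 scale) chosen so a full
cross-validation runs in under a second while staying in the
sparse regime the method targets; and heavy-tailed entity activity,
because curated interaction databases are hub-dominated and the fused
similarity is designed around that structure (with homogeneous entities,
`activity_sdlog = 0`, the same model recovers far less signal — a useful
reminder that performance here is partly popularity-driven). What it does
not emulate: literature and annotation bias, disease-ontology structure,
or the exact scale of the curated benchmark; passing recovery tests on
this generator shows the machinery works on data satisfying the model's
assumptions, not that any particular AUC will transfer to real databases.

The negative control deserves a note. Permuting the *rows* of the target
matrix is **not** a null for this model: the disease-side similarity
compares profile positions consistently, so it is invariant under a row
relabeling, and each permuted row is still a genuine lncRNA profile —
empirically, row-permuted data scores essentially as well as intact data
through the column-filling path. The package's null
(`shuffle_adjacency()`) therefore shuffles all cells of the target
uniformly (the Erdős–Rényi null conditional on edge count), which severs
every link between the target and the profile structure; under it the
cross-validated AUC sits at chance (0.48–0.51 across seeds).

## Numerical and degenerate-case choices

* Descending sorts break ties by ascending index everywhere (neighbor
  selection, candidate ranking) — determinism across platforms.
* A requested `k` exceeding the eligible neighbor count is clamped with a
  warning; `k` below 1, or a side with no eligible neighbor after
  self-exclusion (a single-column target), is an error.
* Zero denominators in confusion metrics report 0 with a warning rather
  than NaN.
* Similarity matrices are symmetrized by averaging with their transpose
  to absorb floating-point asymmetry from the Gram-matrix computation;
  differing-position counts are floored at 0 for the same reason.
* All driver functions (`kfold_cv`, `loocv`, `generate_networks`,
  `planted_holdout`, `shuffle_adjacency`) take explicit seeds, and save
  and restore the caller's RNG state.
* Identifier normalization is trim + collapse internal whitespace +
  case-fold; it is applied on every ingestion path, so edge lists from
  different databases merge on a consistent key.

## Problem sizes used by the test suite

The packaged checks run the full pipeline at 200 lncRNAs × 60 miRNAs ×
80 diseases (about 300 positives) for recovery and null checks, 80 × 25 ×
35 for bound/preservation sweeps, and ≤ 12 × 9 instances against literal
loop transcriptions of the update equations. These sizes are the
package's choice of the smallest scale at which the sparse regime and the
multilayer behavior are both exercised meaningfully.

## Known limitations

* The model is a memory-based recommender: it cannot score an entity with
  an entirely empty profile, and its neighbor choice inherits the
  popularity bias discussed above.
* Scores are relative ranks, not calibrated probabilities.
* Inputs are strictly binary; evidence weights or probabilistic
  associations are out of scope.
* Performance is sensitive to the amount and coupling of bridging data;
  on datasets whose miRNA layer is uninformative the fused similarity
  degrades toward its difference term alone.
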
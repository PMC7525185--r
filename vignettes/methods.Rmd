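---
title: "Methods: similarity kernel fusion and convolutional pair classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: similarity kernel fusion and convolutional pair classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Problem

Given a bipartite circRNA–disease association matrix $A \in \{0,1\}^{n_c
\times n_d}$ together with side information about the circRNAs
(sequences, expression profiles, miRNA interaction partners) and about
the diseases (an ontology DAG, miRNA interaction partners, optional
precomputed similarity matrices), the package scores every unobserved
pair $(c_i, d_j)$ for its likelihood of being a true association. The
pipeline has four stages: per-side similarity kernels, cross-diffusion
fusion of each kernel stack into one matrix per side, per-pair feature
assembly, and a small convolutional classifier.

# Stage 1: similarity kernels

Each data source yields one $n \times n$ kernel per side. All kernels
are symmetric with values in $[0, 1]$ and unit diagonal.

**Gaussian interaction profile (GIP).** For profile vectors $p_i$ (rows
of $A$ for circRNAs, columns for diseases),
$K(i, j) = \exp(-\gamma \lVert p_i - p_j \rVert^2)$ with bandwidth
$\gamma = n / \sum_i \lVert p_i \rVert^2$, so the average profile norm
sets the length scale. Computed for both sides (`gip_kernel()`).

**miRNA-regulatory similarity.** With $M_i$ the miRNA partner set of
entity $i$, the cosine-type overlap
$|M_i \cap M_j| / \sqrt{|M_i|\,|M_j|}$ (`regulatory_similarity()`).
This equals the inner product of the binary interaction profiles
normalised by the geometric mean of the set sizes; entities with no
recorded partners get similarity 0 to everything (and 1 to
themselves).

**Expression similarity.** Pearson correlation of expression profiles
across conditions, clipped below at 0 (`expression_similarity()`):
anti-correlation is treated as absence of evidence for similarity, not
negative similarity, so the kernel stays in $[0, 1]$ and plays by the
same rules as the other kernels during fusion.

**Sequence similarity.** A global (Needleman–Wunsch style) alignment
with affine gaps via Gotoh's three-state recursion, implemented in C++.
Scoring is the DNA default: match $+5$, mismatch $-4$, `N` scores 0
against anything; a gap run of length $L$ costs
$\text{open} + (L-1)\,\text{ext}$ with open 16 and extension 4.
Similarity is the fraction of alignment columns with a positive
substitution score. When optimal alignments tie, traceback prefers
diagonal moves, then gaps in the second sequence — a fixed,
deterministic convention (`sequence_similarity()`).

**Semantic similarity.** From the disease DAG, each ancestor $t$ of a
disease $d$ contributes
$D_d(t) = \max(\Delta \cdot D_d(t') : t' \text{ child of } t
\text{ on a path to } d)$ with $D_d(d) = 1$ and decay $\Delta = 0.5$.
Similarity of two diseases is the sum of contributions over shared
ancestors divided by the sum of their total contribution masses
(`semantic_similarity()`). The recursion is memoised; diamond-shaped
ancestor structures are handled by taking the maximum over paths.

`assemble_kernel_stacks()` builds whichever kernels the available
inputs support (at least two per side are required, since fusion needs
a cross-diffusion partner) and reports which sources were skipped.

# Stage 2: similarity kernel fusion

Each side's stack $\{S_m\}_{m=1}^K$ is fused by cross-diffusion.
Two operators are derived from each kernel:

* a column-normalised version $N_m = S_m \operatorname{diag}(1/\text{colSums})$,
  used as the (fixed) anchor, and
* a row-stochastic sparse operator $F_m$ that keeps only each row's
  top-$k$ entries (self always included) and renormalises.

The update is
$$S_m^{(t+1)} = \alpha\, F_m \Big(\tfrac{1}{K-1}\sum_{r \ne m} S_r^{(t)}\Big) F_m^\top
 + (1-\alpha)\, \tfrac{1}{K-1}\sum_{r \ne m} N_r ,$$
i.e. each kernel diffuses the average of the *other* kernels through
its own neighbourhood graph, while being pulled back toward the
average of the other anchors. Because the anchor term is constant, the
iteration contracts at rate $\alpha$; the per-kernel relative Frobenius
change is recorded at every iteration (`skf_iterate()`, `$trace`).

After $T$ iterations the kernels are averaged, and the average is
reweighted by a mutual-neighbour mask: entry $(i, j)$ is kept at full
weight if $i$ and $j$ are each in the other's top-$k$ neighbourhood,
at half weight if only one direction holds, and dropped otherwise. The
result is symmetrised (`skf_fuse()`, `fuse_kernels()`).

Defaults: $\alpha = 0.1$ (strong pull to the anchors, fast geometric
convergence), $k = 36$ neighbours (clamped to $n - 1$ for small
studies), $T = 10$ iterations — at $\alpha = 0.1$ the relative change
after 10 iterations is far below typical numerical tolerances, which
the test suite checks directly.

# Stage 3: per-pair features

miRNA interaction profiles are compressed by PCA: `prcomp` (centred,
unscaled) is fitted on the stacked circRNA and disease profiles
$[Y; O]$ and the first $n_p$ components are kept
(`fit_mirna_projector()`). Default $n_p = \min(50,\; n_c + n_d,\;
n_m)$: 50 components at full scale, gracefully reduced when a study is
smaller than the projection.

The feature for pair $(c_i, d_j)$ is a $2 \times (n_c + n_d + n_p)$
matrix (`build_pair_feature()`):

| block | row 1 (circRNA view) | row 2 (disease view) |
|---|---|---|
| $n_c$ columns | fused circRNA similarities $S_c(i, \cdot)$ | association column $A(\cdot, j)$ |
| $n_d$ columns | association row $A(i, \cdot)$ | fused disease similarities $S_d(j, \cdot)$ |
| $n_p$ columns | projected miRNA profile of $c_i$ | projected miRNA profile of $d_j$ |

With `mask_label = TRUE` (the default) the entry $A(i, j)$ is zeroed
in both association blocks, so a pair's own label never leaks into its
feature. This also makes features independent of the train/test split,
allowing one dataset build per cross-validation repetition.

# Stage 4: convolutional classifier

The classifier (`train_cnn()`) is a deliberately small network written
directly in R on top of BLAS matrix products (im2col convolution), so
that training is exactly reproducible from a seed on any platform:

1. convolution, 8 filters of size $2 \times 32$ (consumes both rows), ReLU;
2. convolution, 8 filters of size $1 \times 16$, ReLU;
3. global max pooling per filter;
4. inverted dropout, rate 0.5 (training only);
5. dense layer to 2 units, softmax.

Training minimises cross-entropy with Adam (learning rate $10^{-3}$,
$\beta_1 = 0.9$, $\beta_2 = 0.999$), batch size 32, 50 epochs. He
initialisation and all stochastic steps (shuffling, dropout) run under
a seed saved and restored around the call, so two runs with the same
config are bit-identical. Gradients are verified against numerical
differentiation in the test suite.

# Evaluation protocol

Known associations are the positives; an equally sized negative set is
drawn uniformly from the zero cells of $A$ (`sample_negatives()`).
`cross_validate()` partitions positives and negatives into $k$
parallel folds (default 5), trains on $k - 1$ folds and scores the
held-out fold, repeating with fresh negatives per repetition. Reported
metrics at threshold 0.5: precision, sensitivity, accuracy, F1, MCC
(with warnings and `NaN` when a denominator vanishes) and the
rank-based AUC (Mann–Whitney statistic with mid-ranks for ties). A
`shuffle_labels` switch permutes training labels to provide a
chance-level control. `predict_novel()` trains an ensemble on the full
label set (default 10 models, one per independent negative sample) and
ranks all unobserved pairs by the averaged score with deterministic
tie-breaking.

# Synthetic studies

`generate_study()` creates a fully specified study with planted
structure, so every stage can be exercised and validated without
external databases. circRNAs and diseases are partitioned into blocks;
associations are Bernoulli with a high within-block rate (0.6) against
a low background (0.02). All side information is generated consistently
with the same blocks: block-specific miRNA partner sets, expression
centroids per block plus noise, per-block consensus sequences with
point mutations, a DAG in which each block is a subtree under a common
root, and precomputed kernels equal to a block indicator pattern plus
noise. `write_study()` emits the study in the package's file formats
(TSV edge lists, FASTA, TSV matrices), and the round trip through the
readers is tested.

What the generator does *not* emulate: realistic degree distributions
(real association networks are heavy-tailed, the generator is
homogeneous within blocks), biologically plausible sequence evolution,
correlated noise between data sources, or missingness patterns. It is
a recovery benchmark — a pipeline that cannot recover planted blocks
is broken, but performance on it does not predict performance on real
data.

# Numerical conventions and design decisions

* **Ties and ordering.** All orderings (neighbour selection, candidate
  ranking) use explicit deterministic tie-breaks (index order, radix
  sort on identifiers).
* **Degenerate inputs fail loudly.** Zero-sum kernel columns, NA
  expression values, non-square or negative kernels, unknown sequence
  characters, cyclic "DAGs", duplicate pairs in a dataset, and
  requests for more negatives than available zero cells are all
  errors, not silent fixes. A kernel that is asymmetric beyond 1e-8 is
  symmetrised with a warning.
* **Expression correlation is clipped, not shifted.** Mapping $[-1,1]$
  affinely to $[0,1]$ would make "uncorrelated" mean 0.5 similarity;
  clipping keeps 0 as the no-evidence point.
* **Fusion update averages over the other kernels** (division by
  $K - 1$), so the update is a proper mean regardless of stack size
  and reduces to partner-swapping for $K = 2$.
* **Gap cost convention** is $\text{open} + (L-1)\,\text{ext}$: the
  opening charge includes the first gapped column. The exhaustive
  alignment oracle in the tests uses the same convention.
* **PCA is centred and unscaled**, fitted once on the stacked profiles
  so circRNA and disease profiles live in the same coordinate system.
* **The classifier is hand-written** rather than delegated to a deep
  learning framework: the model is small enough that im2col + BLAS is
  fast, and full control of the RNG makes training bit-reproducible,
  which the test suite relies on.

# End-to-end example

```{r example}
library(skfcnn)

study <- generate_study(synthetic_spec(seed = 7))
prep <- prepare_study(study)

cv <- cross_validate_study(prep, config = cnn_config(), folds = 5,
                           repetitions = 3, seed = 20)
cv$summary

ranked <- predict_novel(prep, n_models = 10, seed = 1)
head(ranked, 10)
```

The repository's `scripts/acceptance.R` recomputes the headline
quantities (fusion convergence, layer dimensions, planted-recovery and
label-shuffled cross-validation) from a single `--seed` and writes them
to JSON.
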
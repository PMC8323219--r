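---
title: "Multi-label fundus lesion classification with a graph convolutional label head"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-label fundus lesion classification with a graph convolutional label head}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

A colour fundus photograph from a diabetic-retinopathy screening programme
rarely shows a single abnormality: hemorrhages accompany microaneurysms,
hard and soft exudates co-occur with vascular change, and laser scars mark
previously treated eyes. `fundusgcn` treats the reading task as multi-label
image classification over `N = 8` lesion categories and, instead of training
`N` independent binary classifiers, derives the classifiers *jointly* from
the statistical dependencies between the labels.

The model has two halves.

**Image half.** A convolutional backbone maps the RGB image to feature maps,
two 3×3 stride-2 convolutions halve the spatial resolution twice, and
adaptive (global) max-pooling collapses the maps into a single feature
vector $F \in \mathbb{R}^D$. At production scale the geometry is a
1024×1024 input producing 2048×32×32 maps ($D = 2048$); the bundled test
scale is a small CNN on 64×64 images with $D = 64$.

**Label half.** Each lesion name is embedded as a word vector (row of
$X \in \mathbb{R}^{N\times d}$, $d = 300$ for corpus-trained vectors), and a
stack of graph-convolution layers

$$H^{l+1} = \sigma\!\left(\hat{A}\, H^{l}\, W^{l}\right), \qquad H^0 = X,$$

propagates the embeddings over a label-dependency graph $\hat{A}$
(LeakyReLU $\sigma$, negative slope 0.2). The final layer output
$Z \in \mathbb{R}^{N\times D}$ is used as a bank of linear classifiers: the
raw prediction scores for an image are $y = F Z^\top$, thresholded at a
logistic confidence of 0.5 (strictly greater, i.e. raw score $> 0$).

Because the classifiers are produced by message passing over the label
graph, a label with sparse direct visual evidence can borrow strength from
the labels it co-occurs with.

## The label graph

The graph is estimated from annotation co-occurrence **in the training
split only** — test-set co-occurrence must never leak into the operator:

1. **Counts.** $M = Y^\top Y$ over the binary training annotations;
   $M_{ii}$ is the marginal count of label $i$.
2. **Conditional probabilities.** $P_{ij} = M_{ij} / M_{jj}$, the
   probability of lesion $i$ given lesion $j$. $P$ is asymmetric and is kept
   so throughout; nothing is symmetrised.
3. **Binarisation.** $A'_{ij} = \mathbf{1}[P_{ij} \ge \tau]$ with
   $\tau = 0.3$. The comparison is `>=`, so a conditional exactly at the
   threshold is an edge. Thresholding discards the noisy tail of rare
   co-occurrences, which would otherwise overfit the training split.
4. **Re-weighting.** Each existing off-diagonal edge in row $i$ receives
   weight $p / s_i$, where $s_i$ is the number of edges in that row, and
   the diagonal receives $1 - p$, with $p = 0.25$. Only entries that
   survived binarisation carry weight — spreading $p$ over *all*
   off-diagonal entries would undo the sparsification, so zeros stay zero.
   Every row with at least one edge therefore sums to exactly 1; an
   isolated label keeps an all-zero off-diagonal row (sum $1 - p$), which
   we deliberately do not renormalise: such a label should propagate
   nothing and retain most of its own feature.
5. **Normalisation.** $\hat{A} = D^{-1/2} A D^{-1/2}$ with
   $D = \mathrm{diag}(\text{row sums})$. No identity matrix is added — the
   re-weighting stage already placed $1 - p$ on the diagonal. If $A$ is
   asymmetric, $\hat{A}$ is too.

`tau` controls sparsity (larger → fewer edges) and `p` balances a label's
own embedding against its neighbours' (larger → more neighbour influence).
Both are plain config values; 0.3 / 0.25 are the defaults throughout.

## Label embeddings

`load_word_vectors()` reads plain-text vectors (one token, then $d$ floats
per line) and auto-detects the word2vec text dialect whose first line is a
two-integer header — both layouts circulate under the same name, so the
loader accepts either. A multi-word label ("hard exudates", "cup disc
ratio") is lowercased, whitespace-tokenised, and embedded as the **mean**
of its tokens' vectors. The mean is order-invariant and keeps the vector on
the scale of single tokens; tokens missing from the vocabulary are skipped
with a warning, but a label whose tokens are *all* missing is a hard error —
a silent zero vector would make that label's classifier degenerate. A
seeded standard-normal random matrix (`random_feature_matrix()`) is the
baseline control for experiments on the value of the embeddings.

## Training

All parameters — backbone convolutions and GCN weights — are trained
jointly with stochastic gradient descent: momentum 0.9, weight decay
$10^{-4}$, and two parameter groups, the backbone at learning rate 0.01 and
the GCN head at 0.1. The loss is the multi-label one-versus-all soft-margin
objective

$$\mathcal{L}(y, \hat y) = -\frac{1}{N}\sum_{i=1}^{N}
  \Big[\, y_i \log \sigma(\hat y_i) + (1 - y_i)\log\big(1 - \sigma(\hat
  y_i)\big) \Big],$$

averaged over the batch, evaluated in the numerically stable
logits form $\max(s, 0) - s\,y + \log(1 + e^{-|s|})$ so extreme scores
cannot overflow. At all-zero scores the loss is exactly $\ln 2$, a closed
form the test suite pins down.

Epoch count, batch size and schedule are not dictated by the architecture;
the defaults are 30 epochs, batch size 8 and a constant rate, all
configurable. Each epoch logs training loss and validation OF1/CF1, and the
best-validation-CF1 model is retained as the checkpoint. The convolutional
layers are implemented in base R (im2col gather + BLAS matrix products,
with exact hand-derived backward passes); every gradient path is verified
against central finite differences in the test suite, and the forward GCN
is checked against an independently coded dense reference.

Weight initialisation is uniform in $\pm 1/\sqrt{\text{fan-in}}$ and
seeded: a single global seed fans out deterministically into independent
sub-seeds for splitting, initialisation, batch shuffling and simulation, so
an identical config + seed reproduces every artifact byte for byte.

Datasets are split 70/15/15 into train/validation/test by seeded shuffle
and contiguous cut. The default splits at the image level; because both
eyes of a patient can contribute images, an optional `by_patient = TRUE`
assigns whole patients to one split to avoid cross-eye leakage. Image-level
splitting remains the default for fidelity to common practice in fundus
classification, but patient-level is the better epidemiological choice.

## Evaluation suite

For predictions thresholded at confidence 0.5, per-class confusion counts
feed:

* **OF1** — micro F1: precision/recall from globally pooled TP/FP/FN, then
  the harmonic mean;
* **CF1** — macro F1: per-class precision/recall averaged over $N$, then
  the harmonic mean;
* **Acc** — per-class accuracy $(TP + TN)/n$;
* **AUC** — per-class rank (Mann–Whitney) AUC: the probability a random
  positive outscores a random negative, tied pairs counted 0.5.

A precision or recall with an empty denominator is defined as 0 (the common
multi-label convention for rare classes); an AUC for a class with no
positive or no negative sample is *undefined* and reported as `NA` with a
warning — never as 0 or 1 — and excluded from summary means.

## The synthetic data generator

The clinical data this model family targets is not redistributable, so the
package ships a generator that emulates its two essential properties:
correlated binary lesion annotations and images whose visual content
encodes the labels.

**Annotations** come from a mixture of $K$ patient profiles; within a
profile, labels are independent Bernoulli draws. Between-profile
heterogeneity is what induces co-occurrence, and it does so with a closed
form: for $i \ne j$,

$$P(L_i \mid L_j) = \frac{\sum_k w_k\, q_{ki}\, q_{kj}}{\sum_k w_k\, q_{kj}},$$

which gives an exact oracle for the graph-construction pipeline — the
empirical conditional matrix from a finite sample must converge to it. A
general Bayesian network could express richer dependencies but has no such
closed form; the mixture was chosen precisely because it makes the
parameter-recovery test exact.

The default 8-label mixture uses three profiles (largely healthy, vascular
disease, severe multi-lesion disease) with near-deterministic rates. Its
marginals keep the rank order seen in screening cohorts — arteriosclerosis
and hemorrhages most frequent, laser scars least — but deliberately
compress the dynamic range upward so every marginal stays above ~0.35.
This is an estimability decision: the package's own recovery tolerance
requires the empirical conditional matrix at $n = 2000$ to be within 0.05
of the closed form in the worst entry, and a lesion at true clinical rarity
(a few percent) would leave only ~60–160 conditioning samples, with worst-
entry sampling error of 0.05–0.06 — unattainable regardless of
implementation quality. Rarity at that level is therefore *not* part of
what the generator emulates, and results on the synthetic data say nothing
about performance on classes with very low prevalence.

**Images** are drawn on a circular fundus-like disc with radial shading.
Each active label adds its own primitive family, loosely following the
visual character of the real lesion: tiny red dots (microaneurysms), bright
yellow blobs (hard exudates), dark red blotches (hemorrhages), pale fuzzy
patches (soft exudates), rings of small dots (laser scars), yellow specks
(drusen), a bright inner disc (enlarged cup), thick bright strokes
(arteriosclerosis); Gaussian pixel noise is added last. Rendering is a pure
function of `(labels, spec, seed)`. In `contrast = "high"` mode each
label's primitives sit in a label-specific sector with saturated colour —
a deliberately trivially-learnable regime under which a small classifier
must reach near-perfect scores, which is what the end-to-end check
exploits; `contrast = "soft"` scatters fainter primitives for harder
experiments. What passing tests on these images demonstrate is that the
*pipeline* (graph, embeddings, propagation, feature path, optimisation,
metrics) is correct — not that the model reaches clinical accuracy on real
photographs, which differ in texture, acquisition artefacts, lesion
ambiguity and class imbalance.

## Problem sizes used in the checks

The packaged experiments are sized for a laptop CPU: the end-to-end run
simulates 600 images at 64×64 over `N = 4` labels from a 2-profile mixture,
splits 70/15/15, and trains the small CNN plus a 16→32→64 GCN head for 12
epochs (well within the 30-epoch default) with the standard SGD settings;
held-out CF1 is examined across three seeds. The overfit-one-batch sanity
check takes repeated SGD steps on a single fixed batch of 8 images at the
standard learning rates until it reaches perfect micro F1 (a few hundred
steps).
Property tests use hundreds of randomised small instances (annotation
matrices up to 50×10, GCN stacks up to width 16). The production-scale
geometry (1024×1024, $D = 2048$, 300-d embeddings) is exercised through
shape contracts and the pure GCN path rather than full training.

## Known limitations

* No pretrained residual backbone ships with the package; the production
  preset reproduces the *geometry* (input size, stride, $D = 2048$) with
  the package's own plain CNN. Transfer from natural-image pretraining,
  which matters on real photographs, is out of scope.
* The graph is estimated once from training annotations and fixed; it is
  not learned jointly with the classifier.
* Whether an activation follows the final GCN layer is an open
  architectural choice; the package omits it so classifier weights span
  negative values, and exposes `final_activation` for the alternative.
* The loss treats labels as conditionally independent given the scores;
  structured losses over label subsets are not implemented.
* Image-level splitting (the default) can leak patient-level information
  between splits when both eyes are present; use `by_patient = TRUE` when
  patient identifiers are meaningful.
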
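# fundusgcn

Multi-label detection of retinal lesions in colour fundus photographs,
with label dependencies modelled by a graph convolutional network (GCN).

A fundus image from a diabetic-retinopathy screening programme typically
shows several abnormalities at once — hemorrhages alongside
microaneurysms, exudates alongside vascular change. Treating the eight
lesion categories (laser scars, drusen, cup-disc ratio > 0.6, hemorrhages,
retinal arteriosclerosis, microaneurysms, hard exudates, soft exudates) as
independent binary problems throws away exactly that co-occurrence
structure. `fundusgcn` instead derives the per-lesion classifiers jointly
from a label-dependency graph.

## The model

**Label graph.** From the binary training annotations $Y$, co-occurrence
counts $M = Y^\top Y$ give conditional probabilities
$P_{ij} = P(L_i \mid L_j) = M_{ij}/M_{jj}$. These are thresholded
($A'_{ij} = \mathbf{1}[P_{ij} \ge \tau]$, $\tau = 0.3$), re-weighted
($A_{ij} = p / s_i$ on surviving edges, $1 - p$ on the diagonal,
$p = 0.25$), and normalised symmetrically
($\hat A = D^{-1/2} A D^{-1/2}$).

**Classifier head.** Label word-embeddings $X \in \mathbb{R}^{N \times d}$
pass through stacked graph convolutions
$H^{l+1} = \sigma(\hat A H^l W^l)$ (LeakyReLU), producing
$Z \in \mathbb{R}^{N \times D}$ — one $D$-dimensional linear classifier
per lesion.

**Image path.** A CNN backbone yields feature maps, two 3×3 stride-2
convolutions downsample them, and global max-pooling gives the feature
vector $F \in \mathbb{R}^D$. Scores are $y = F Z^\top$; a label is called
positive when its logistic confidence exceeds 0.5.

Everything trains end-to-end with SGD (momentum 0.9, weight decay 1e-4,
backbone at lr 0.01, head at lr 0.1) under the multi-label soft-margin
loss. Evaluation follows the standard multi-label suite: micro F1 (OF1),
macro F1 (CF1), per-class accuracy and rank-based AUC.

Because clinical fundus datasets are rarely redistributable, the package
includes a synthetic generator: correlated 8-label annotations from a
mixture of patient profiles (with closed-form conditional probabilities,
so graph construction is testable against an exact oracle) and rendered
fundus-like images whose primitives encode the active labels.

## Worked example

Simulate a 600-image dataset over 4 correlated lesion labels, build the
label graph from the training split, train the small CNN + GCN head, and
evaluate on the held-out test split:

```r
library(fundusgcn)

dir <- file.path(tempdir(), "demo")
mix <- demo_mixture(4)
manifest <- generate_dataset(600, mix, render_spec(64, contrast = "high"),
                             dir, seed = 42)
manifest <- split_dataset(manifest, seed = 42)   # 70/15/15

graph <- label_graph(as.matrix(manifest[manifest$split == "train", mix$labels]))
print(round(graph$P, 2))
#>                laser scars drusen cup disc ratio hemorrhages
#> laser scars           1.00   0.81           0.16        0.21
#> drusen                0.76   1.00           0.16        0.17
#> cup disc ratio        0.18   0.19           1.00        0.82
#> hemorrhages           0.26   0.22           0.88        1.00

X <- random_feature_matrix(4, 16, seed = 42)
rownames(X) <- mix$labels
fit <- fit_mlgcn(manifest[manifest$split == "train", ],
                 manifest[manifest$split == "validation", ],
                 graph, X, backbone_config("tiny"), gcn_dims = c(16, 32, 64),
                 optim = optim_config(epochs = 12), seed = 42,
                 image_root = dir)
fit
#> <fgcn_fit> 12 epochs, best validation CF1 0.966 at epoch 10

evaluate_model(fit, manifest[manifest$split == "test", ], image_root = dir)
#> Multi-label evaluation report
#>   micro: OP = 0.962  OR = 0.962  OF1 = 0.962
#>   macro: CP = 0.961  CR = 0.960  CF1 = 0.960
#>   per lesion:
#>     laser scars                Acc = 0.878  AUC = 0.910
#>     drusen                     Acc = 0.989  AUC = 1.000
#>     cup disc ratio             Acc = 1.000  AUC = 1.000
#>     hemorrhages                Acc = 0.978  AUC = 0.999
```

The conditional-probability matrix shows the two co-occurrence blocks the
2-profile mixture induces (laser scars with drusen, cup-disc ratio with
hemorrhages); the graph ties those classifier pairs together. The report
reads as: 96% of predicted lesion instances are correct (OP), 96% of true
instances are found (OR), and every lesion is ranked nearly perfectly
(AUC ≈ 1) except the hardest primitive at this resolution.

The same pipeline is available as commands (`run_simulate()`,
`run_build_graph()`, `run_train()`, `run_evaluate()`, `run_predict()`)
driven by one YAML config, or from a shell via
`Rscript inst/cli/fundusgcn.R <command> --config cfg.yaml --seed 1`.

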
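# spinalzfnet

Four-class classification of kidney disease (normal, cyst, tumor, stone)
from 2-D grayscale CT slices, implemented end to end in R: median-filter
denoising, ENet encoder-decoder kidney segmentation, geometric
augmentation, a four-branch handcrafted feature bank, and a hybrid
SpinalNet/ZFNet classifier joined by a gated fusion layer.  A seeded
phantom generator produces synthetic CT-like images with ground-truth
masks and labels, so the whole pipeline is reproducible on a laptop with
no external data.

The package is aimed at readers who want a transparent, fully tested
reference implementation of this hybrid pipeline: every stage is an
exported R function, the networks are trained by a small reverse-mode
autodiff engine with compiled convolution kernels (no external
deep-learning framework), and every numerical claim in the documentation
is recomputed by the test suite or the acceptance script.

## The model

Each image is denoised with a median filter, segmented by an ENet
(bottleneck encoder-decoder with max-unpooling and a final full
convolution to C class maps), and described by the feature record

    H = [ J1 | J2 | H_shape | H_stat ]      (320 + 1323 + 5 + 4 = 1652)

where J1 stacks up to five 64-dimensional SURF descriptors, J2 applies a
441-bin histogram of oriented gradients to the Weber differential
excitation of the LL/LH/HH Haar subbands, H_shape holds area, perimeter,
major/minor axis lengths and solidity, and H_stat holds the masked mean
plus GLCM entropy, correlation and contrast.

The classifier combines a SpinalNet branch C1 (the flattened masked image
cut into segments fed through chained narrow sub-layers) with gated
projections of the feature record,

    C2 = U p + 1/2 U p1 + 1/6 (1-U) p2 + 1/24 (1-U)(2-U) C1,
    U  = sigmoid( w^T [p; p1; p2] + b ),

where p, p1, p2 are learnable linear maps of the full record, the
statistical block and the shape block.  C2 is lifted onto an 8x8 grid and
classified by a ZFNet-style head (five convolutions, local response
normalization after the first two, max pooling after convolutions 1, 2
and 5, then fully connected layers).  Evaluation reports one-vs-rest
accuracy, sensitivity, specificity, precision and F1 (per class and
macro), confusion matrices, and per-class/micro/macro ROC curves with
trapezoidal AUC, under stratified K-fold and learning-set protocols.

## A worked example

```r
library(spinalzfnet)

spec    <- phantom_spec(image_size = 64, n_per_class = 40, seed = 1)
samples <- generate_phantoms(spec)                       # 160 phantoms
samples <- lapply(samples, function(s) { s$image <- median_filter(s$image, 3); s })

net <- build_enet(enet_config(initial_channels = 8,
                              stage_channels = c(16, 32, 32)), seed = 2)
net <- train_segmenter(net, samples, epochs = 25, seed = 3, lr = 8e-3)
for (i in seq_along(samples)) {
  sg <- segment_image(net, samples[[i]]$image)
  samples[[i]]$image       <- sg$masked_image
  samples[[i]]$kidney_mask <- sg$mask
}

res <- learning_set_evaluate(samples, 80, spinalzfnet_trainer(), seed = 4)
res
```

On this 160-image study (40 per class, 64 px) the run reaches a mean
kidney IoU around 0.95 for the segmenter, and printing the held-out
report at the seeds shown ends with the lines

    macro: accuracy=96.88  sensitivity=93.75  specificity=97.92  precision=93.75  f1=93.75
    overall accuracy: 93.75%

(the held-out accuracy varies from the high 70s to the mid 90s percent
across seeds), with the residual confusion concentrated on stone versus
normal: a
five-pixel near-maximum stone speck barely survives the 3x3 median
filter, which is exactly the small-lesion sensitivity limit the phantom
is designed to probe.  The methods vignette
(`vignettes/spinalzfnet-methods.Rmd`) documents every parameter, the
numerical choices, and what the phantom study does and does not show.

## Command line

A thin CLI wraps the same functions:

```sh
spinalzfnet phantom    --out data --n-per-class 40 --seed 1 --size 64
spinalzfnet preprocess --in data --out denoised --window 3
spinalzfnet run        --config run.yaml --seed 1 --out results
```

Verbs: `phantom`, `preprocess`, `segment`, `augment`, `extract`,
`evaluate`, `run`.  `run` executes the whole pipeline from one YAML
configuration and writes masks, feature tables, checkpointed metrics,
confusion and ROC CSVs, and a `summary.json` under the output directory.

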